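---
title: "Decoding a cis-AT PKS assembly line: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a cis-AT PKS assembly line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksdecode)
```

## The problem

Type I *cis*-AT polyketide synthases (PKSs) are multi-modular assembly
lines: each module condenses one extender unit (malonyl or methylmalonyl)
onto the growing chain and optionally processes the new β-keto group
(ketoreductase KR → β-hydroxyl; dehydratase DH → α,β-enoyl; enoylreductase
ER → methylene) before a thioesterase (TE) releases and macrocyclizes the
product. Because each catalytic decision leaves a short sequence signature
in the domain's active site, the final polyketide — backbone, methyl
branches, oxidation states, double-bond geometry and even stereochemistry —
can be predicted from protein sequence alone. `pksdecode` implements that
inference chain end to end for the irumamycin-type assembly line: a
20-membered macrolactone with a six-membered hemiketal ring, a cis double
bond inside it, a 23,24-epoxide and a carbamoylated deoxyhexose.

## Domain detection

Detection is anchored degenerate-pattern scanning, not profile-HMM search.
Each domain kind is located by one or two literal anchor strings with a
±30% spacing band, and classification windows are read at fixed offsets
from the first anchor (`pks_domain_models()`). The choice is deliberate:
the classification rules consume short printed motifs, anchored scanning
requires zero external model files, and the same geometry drives the
synthetic-sequence generator, which makes recovery exactly testable. A
profile-based scanner is an extension point, not a requirement. The
trade-off is honest: real PKS domains would need the profile mode; the
packaged scanner is exact on generated data and on anything embedding the
packaged anchors.

In the degenerate alphabet, `x` matches any residue and `I(V)` matches
exactly one of the listed residues. Ambiguity is resolved leftmost-first;
coordinates are 1-based inclusive throughout.

## Classification rules

* **AT specificity** — methylmalonyl iff motifs I/II/III match
  `xVDVxQ / GHSQGE / xxSH`; malonyl iff they match
  `xTxYTQ / GHSI(V)GE / xAFN`; *inactive* iff the motif II window still has
  a recognizable `GH..GE` frame but the catalytic serine is replaced
  (e.g. `GHGQGE`). Windows with no recognizable signal are `unclassified`
  rather than inactive: a junk window is missing evidence, not evidence of
  a dead domain. When motifs disagree, motif II (the catalytic serine
  position) is weighted double, then a majority vote decides; the fired
  rule is always recorded in the evidence.
* **KR stereotype** — `LDD` (or the rarer `IDD`/`VDD`) marks type B;
  within B, `YxP` gives B2 and `YxA` gives B1; no LDD-family motif plus a
  matched `WxxxxQ` gives type A. Contradictory evidence (both) calls B
  with a `conflict` flag, never silently. A KR with *neither* diagnostic
  motif is called `B_unsubtyped` with a `no_diagnostic_motif` flag — the
  enum has no "unknown" level, B is the majority stereotype, and the flag
  keeps the low confidence explicit. The packaged fixture uses this
  fallback for the three KRs whose types the motif table does not pin down
  (modules 1, 5 and 10).
* **DH activity** — active iff the catalytic `HxxxxxxxxP` motif is intact
  *and* the `YxY` window keeps both tyrosines. A terminal L/V in place of
  the proline (`HxxxxxxxxL/V`), or V/L at the Q/H position of the second
  motif `DxxxQ/H`, marks an enoyl-isomerase (EI) candidate; such a domain
  with intact YxY is still counted catalytically active. The canonical-motif
  DH of module 11 therefore reports `ei_candidate = FALSE`, and the olefin
  shift is taken from the layout configuration — whether that DH truly
  isomerizes is an open question the classifier refuses to answer from
  sequence.
* **KS role** — glutamine at the active site (KSQ) marks the loading
  module (a decarboxylase); cysteine marks extension. Anything else is
  treated as extension with a warning flag.

## Module logic and the backbone

`build_modules()` joins grammar groupings (`KS–AT–[DH–[ER]–KR]–T`, with
optional loading module and exactly one trailing TE) with the calls and
the layout flags. Three flags carry the assembly line's irregularities:

* `ks_gatekeeper_override` (module 8): the AT motifs and the product
  disagree for this module, and extender choice is enforced by the
  ketosynthase; the override substitutes the configured extender for the
  AT call.
* `at_borrowed_from` (module 12 ← 11): module 12's AT lacks the catalytic
  serine; its elongation uses the extender loaded by AT11. Together with
  `iterative` on module 11 this encodes the "stuttering" choreography in
  which one AT serves two condensations. The packaged layout keeps twelve
  elongations total; a generic `iteration_count = k` adds `k − 1` extra
  units and is property-tested separately.
* `olefin_shift` (module 11): the unit's double bond is emitted as a
  shifted (β,γ) *cis* enoyl at C4–C5 instead of the canonical trans α,β
  product of a B-type KR + DH pair.

Stereochemistry is carried as KR-type labels (A/B) on β-hydroxyl units,
not as R/S assignments: the package predicts which reductase type
installed each center, and mapping labels to configurations is an export
concern requiring a per-position convention table the source material does
not print. Double-bond geometry follows the standard rule: E from B-type
KR products, Z from A-type.

Both mechanistic options for the shifted bond are supported and produce
identical final connectivity and formula — they differ only in the
recorded intermediates. Path 1 shifts the double bond on the assembly
line before the final transfers; path 2 dehydrates everything to a triene,
6π-electrocyclizes and re-adds water. The exchangeable hemiketal hydroxyl
that path 2 would install by water addition is the same oxygen slot path 1
arrives at; the heavy-water exchange experiment (below) cannot distinguish
them, which is exactly why the energy profiles exist.

Carbon numbering is the macrolide convention: C1 is the lactone carbonyl
laid down by the last elongation; unit *u* of *n* occupies carbons
`2(n−u)+1` and `2(n−u)+2`, its β-carbon is `2(n−u)+3`; methyl branches are
numbered past the chain. Ring closure at the C19 hydroxyl yields the
20-membered macrolactone (19 carbons + the ester oxygen); the hemiketal
closes six-membered between the C3 β-ketone and the C7 hydroxyl. The
hemiketal carbons are **provisional** — the text does not print them — and
are configuration, not code (`iru_layout()`).

## Formula bookkeeping and masses

The backbone formula is computed relative to the saturated fatty acid
CₙH₂ₙO₂ (β-ketone +O −2H; β-hydroxyl +O; enoyl −2H; lactonization −H₂O;
hemiketal closure formula-neutral). Tailoring steps are signed element
deltas that commute (dehydration −H₂O, epoxidation +O, glycosylation
+C₇H₁₁NO₅, the carbamoyl-deoxyhexose residue net of condensation water);
site validation is order-aware (epoxidation demands a double bond present
at its site after prior steps). The glycosylation delta is data, not
chemistry code, and was validated against the back-calculation oracle:
subtracting the ammonium-adduct delta and one heavy-oxygen shift from the
printed m/z 783.48 fixes the expected neutral formula, and the pipeline's
prediction (C₄₁H₆₅NO₁₂, monoisotopic 763.4507 Da) lands within 0.01 Da of
it. Two consequences of that arithmetic are worth flagging: the degrees of
unsaturation force fully reduced β-positions (ER domains) in modules 3 and
8 and trans/cis double bonds from modules 9 and 7 — plausible but not
individually printed, hence encoded in the fixture and marked provisional
here.

Adduct deltas include the electron mass (proton = 1.00728 Da); the printed
two-decimal values cannot discriminate this convention, so consistency is
the requirement and the convention is documented in `adduct_specs()`.
Isotopologue arithmetic is monoisotopic only — the natural-abundance ¹³C
envelope is out of scope. Heavy-oxygen exchange at enrichment *p* over *k*
exchangeable slots is binomial; at the experimental 50% enrichment and the
single exchangeable hemiketal hydroxyl this is the characteristic 1:1
M/M+2 doublet, 2.0042 Da apart. Peak-list comparison defaults to ±0.05 Da,
matching the spread between naive computation and the printed values
(≤ ~0.03 Da).

## Free-energy profiles

The two hemiketal mechanisms ship as structured text fixtures holding the
printed stage free energies. Transition states are stored as barrier
heights above their *preceding minimum*: the printed barriers do not state
their reference, so the convention is an explicit field rather than an
assumption buried in arithmetic. Telescoping the path 1 stages (−2.9,
−6.84 kcal/mol) gives −9.74, matching the printed overall −9.73 within
rounding; path 2's final stage is not printed and is solved from the
printed overall (−4.2) as −4.89 kcal/mol, marked `derived` in the fixture.
No rate theory is applied — the comparison is barrier bookkeeping, not
kinetics.

## The synthetic generator: what it emulates, what it does not

`generate_assembly()` embeds the intended anchors and active-site windows
into randomized filler at the packaged geometry, partitions modules over
proteins (the packaged fixture mirrors the narrative constraints: the
final protein carries modules 11, 12 and the TE; the penultimate ends in
the module 10 carrier domain; earlier modules sit 2–3 per protein, an
arbitrary choice where the text is silent), then screens the filler so no
anchor string occurs outside its intended position. Wildcard positions in
motif instantiation exclude W, Q, Y, H, P and C so an instantiated window
can never complete a competing diagnostic pattern. Generation is
deterministic per `(truth table, seed)`.

The scaffolds are shuffled low-complexity filler, not PKS homologs: a
green round-trip test establishes that the scanner/classifier/assembly
logic is internally correct against a known truth table, *not* that the
scanner would annotate a real *Streptomyces* megasynthase — that would
require the profile mode and real linker statistics. Domain lengths
(KS 420, AT 300, DH 280, KR 450, T 80, TE 260 residues) are typical
cis-AT spans, configurable, chosen once.

## Numerical and degenerate-input choices

* Windows shorter than their pattern raise errors naming the window.
* A grammar violation (shuffled or orphan hits) yields a diagnostic and a
  best-effort grouping flagged `ambiguous`, never a crash.
* An active DH atop an absent KR is an error (nothing to dehydrate), as is
  a final module with an inactive AT and no borrowing source.
* Isotopologue abundances always sum to 1 within 1e−12 (`dbinom` does the
  work); `p → 0`/`p → 1` collapse to the unlabeled/fully labeled entries.
* All seeds are scoped with `withr::with_seed`; nothing touches the global
  RNG state outside generator calls.

## Known limitations

* Anchored scanning only; real sequences need the (unimplemented) profile
  mode.
* Stereochemistry stops at A/B labels; no R/S export table is shipped.
* Ethylmalonyl extenders (the C24-ethyl congener) are not a recognized AT
  class — no motif for them is available — and fall to `unclassified`.
* The hemiketal ring carbons, the early-protein module distribution, and
  the ER/double-bond placements forced by the formula arithmetic are
  provisional fixture choices, clearly flagged above.
* MS/MS fragmentation, chromatography, quantum chemistry and the sugar
  pathway's enzymology are out of scope; printed stage energies are
  consumed, never recomputed.
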