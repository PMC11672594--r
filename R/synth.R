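#' Instantiate a degenerate motif pattern into a concrete window
#'
#' Wildcard (`x`) positions are drawn uniformly from `residue_set`;
#' alternations like `I(V)` pick one listed residue. The default residue
#' set deliberately excludes W, Q, Y, H, P and C so that an instantiated
#' wildcard can never complete a competing diagnostic pattern (WxxxxQ,
#' YxY, HxxxxxxxxP, a catalytic serine/cysteine context).
#'
#' @param pattern degenerate pattern (see [compile_pattern()]).
#' @param residue_set residues eligible for wildcard positions.
#' @param exclude additional letters to keep out of wildcard positions.
#' @return a concrete window string matching `pattern`. Uses the current
#'   RNG stream (seed it with [withr::with_seed()] for reproducibility).
#' @export
instantiate_motif <- function(pattern,
                              residue_set = strsplit("ADEFGIKLMNRSTV", "")[[1]],
                              exclude = character(0)) {
  pool <- setdiff(residue_set, exclude)
  if (!length(pool)) stop("unsatisfiable pattern: empty wildcard residue set")
  chars <- strsplit(pattern, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      out <- c(out, sample(pool, 1L))
      i <- i + 1L
    } else if (grepl("[A-Z]", ch)) {
      if (i < length(chars) && chars[i + 1L] == "(") {
        close <- which(chars == ")" & seq_along(chars) > i)[1]
        if (is.na(close)) stop("unbalanced '(' in pattern: ", pattern)
        alts <- c(ch, chars[(i + 2L):(close - 1L)])
        out <- c(out, sample(alts, 1L))
        i <- close + 1L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    } else {
      stop("invalid character '", ch, "' in pattern: ", pattern)
    }
  }
  res <- paste(out, collapse = "")
  if (!matches_pattern(res, pattern)) stop("internal: instantiation failed")
  res
}

# window recipes per intended classification outcome
.at_window_patterns <- function(class) {
  switch(class,
    methylmalonyl = list(motif_I = "xVDVxQ", motif_II = "GHSQGE",
                         motif_III = "xxSH"),
    malonyl = list(motif_I = "xTxYTQ", motif_II = "GHSI(V)GE",
                   motif_III = "xAFN"),
    inactive = list(motif_I = "AKAEAG", motif_II = "GHGQGE",
                    motif_III = "AKLG"),
    stop("unknown AT class: ", class))
}

.kr_window_patterns <- function(class, catalytic = "LDD") {
  switch(class,
    B1 = list(catalytic_motif = catalytic, subtype_window = "YxA",
              a_type_window = "LxxxxR"),
    B2 = list(catalytic_motif = catalytic, subtype_window = "YxP",
              a_type_window = "LxxxxR"),
    A = list(catalytic_motif = "ADA", subtype_window = "LRG",
             a_type_window = "WxxxxQ"),
    nondiagnostic = list(catalytic_motif = "GRE", subtype_window = "LRG",
                         a_type_window = "LxxxxR"),
    stop("unknown KR class: ", class))
}

.dh_window_patterns <- function(class) {
  switch(class,
    active = list(catalytic_motif = "HxxxxxxxxP", yxy_window = "YxY",
                  second_motif = "DxxxQ"),
    inactive = list(catalytic_motif = "HxxxxxxxxP", yxy_window = "FxY",
                    second_motif = "DxxxQ"),
    ei = list(catalytic_motif = "HxxxxxxxxL", yxy_window = "YxY",
              second_motif = "DxxxV"),
    stop("unknown DH class: ", class))
}

.module_entry <- function(label, protein, ks = "C", at = "methylmalonyl",
                          kr = "absent", kr_catalytic = "LDD", dh = "absent",
                          er = FALSE, te = FALSE) {
  list(label = label, protein = protein, ks = ks, at = at, kr = kr,
       kr_catalytic = kr_catalytic, dh = dh, er = er, te = te)
}

#' The packaged irumamycin-like truth table
#'
#' Encodes the per-module domain census of the iru assembly line: eight
#' methylmalonyl-motif AT domains (LM, M1-M5, M9, M10), four
#' malonyl-motif (M6-M8, M11; M8's selectivity is gatekept by its KS, see
#' [iru_layout()]), one degenerate AT (M12); KR LDD in M2-M4 and M11,
#' IDD/VDD in M6, M8, M9, A-type in M7, non-diagnostic windows in M1, M5
#' and M10; DH present-but-inactive in M5, M10 and M12. Twelve extension
#' modules plus the loading module, distributed over six proteins with the
#' final protein carrying M11, M12 and the TE.
#'
#' @param mutation_rate scaffold point-mutation rate (default 0).
#' @return object of class `pk_truth_table`.
#' @export
iru_truth_table <- function(mutation_rate = 0) {
  e <- .module_entry
  modules <- list(
    e("LM", 1, ks = "Q", at = "methylmalonyl"),
    e("1", 1, at = "methylmalonyl", kr = "nondiagnostic"),
    e("2", 2, at = "methylmalonyl", kr = "B2", kr_catalytic = "LDD"),
    e("3", 2, at = "methylmalonyl", kr = "B1", kr_catalytic = "LDD",
      dh = "active", er = TRUE),
    e("4", 3, at = "methylmalonyl", kr = "B2", kr_catalytic = "LDD"),
    e("5", 3, at = "methylmalonyl", kr = "nondiagnostic", dh = "inactive"),
    e("6", 4, at = "malonyl", kr = "B1", kr_catalytic = "VDD", dh = "active"),
    e("7", 4, at = "malonyl", kr = "A", dh = "active"),
    e("8", 4, at = "malonyl", kr = "B1", kr_catalytic = "IDD",
      dh = "active", er = TRUE),
    e("9", 5, at = "methylmalonyl", kr = "B1", kr_catalytic = "VDD",
      dh = "active"),
    e("10", 5, at = "methylmalonyl", kr = "nondiagnostic", dh = "inactive"),
    e("11", 6, at = "malonyl", kr = "B1", kr_catalytic = "LDD",
      dh = "active"),
    e("12", 6, at = "inactive", dh = "inactive", te = TRUE))
  truth_table(modules, protein_ids = paste0("synIru", LETTERS[1:6]),
              mutation_rate = mutation_rate)
}

#' Construct and validate a truth table
#'
#' @param modules list of per-module entries (see [iru_truth_table()] for
#'   the packaged example); entries are created internally with fields
#'   `label`, `protein`, `ks`, `at`, `kr`, `kr_catalytic`, `dh`, `er`, `te`.
#' @param protein_ids ids for the proteins, one per distinct `protein`.
#' @param mutation_rate scaffold point-mutation probability per residue.
#' @param linker_range residue-length range of inter-domain linkers.
#' @return object of class `pk_truth_table`.
#' @export
truth_table <- function(modules, protein_ids = NULL, mutation_rate = 0,
                        linker_range = c(12L, 28L)) {
  prot <- vapply(modules, `[[`, numeric(1), "protein")
  if (any(diff(prot) < 0)) stop("modules must be in assembly-line order")
  if (is.null(protein_ids)) protein_ids <- paste0("synPKS", seq_len(max(prot)))
  if (length(protein_ids) != length(unique(prot))) {
    stop("need one protein id per protein in the partition")
  }
  n_te <- sum(vapply(modules, `[[`, logical(1), "te"))
  if (n_te != 1L) stop("truth table must place exactly one TE")
  structure(list(modules = modules, protein_ids = protein_ids,
                 mutation_rate = mutation_rate, linker_range = linker_range),
            class = "pk_truth_table")
}

#' Expected classifier calls implied by a truth table
#' @param truth a `pk_truth_table`.
#' @return data.frame with one row per module: `label`, expected `ks`
#'   role, `at` specificity, `kr` stereotype, `dh` status, `er` presence.
#' @export
expected_calls <- function(truth) {
  rows <- lapply(truth$modules, function(m) {
    data.frame(
      label = m$label,
      ks = if (m$ks == "Q") "loading" else "extension",
      at = m$at,
      kr = switch(m$kr, nondiagnostic = "B_unsubtyped",
                  absent = "absent", m$kr),
      dh = switch(m$dh, absent = "absent", ei = "active", m$dh),
      er = m$er, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.filler <- function(n) {
  if (n <= 0L) return(character(0))
  sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
}

# build one domain's residue vector plus its feature records
.build_domain <- function(kind, windows_content) {
  g <- pks_domain_geometry()[[kind]]
  chars <- .filler(g$span)
  feats <- list()
  put <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    chars[at:(at + length(v) - 1L)] <<- v
  }
  put(g$anchors[1], 1L)
  feats[[length(feats) + 1L]] <- list(element = "anchor1",
                                      start = 1L,
                                      end = nchar(g$anchors[1]),
                                      content = g$anchors[1])
  if (length(g$anchors) > 1L) {
    put(g$anchors[2], g$a2_offset + 1L)
    feats[[length(feats) + 1L]] <- list(element = "anchor2",
                                        start = g$a2_offset + 1L,
                                        end = g$a2_offset + nchar(g$anchors[2]),
                                        content = g$anchors[2])
  }
  for (w in seq_len(nrow(g$windows))) {
    nm <- g$windows$name[w]
    cont <- windows_content[[nm]]
    if (is.null(cont)) stop("missing window content for ", kind, ":", nm)
    put(cont, g$windows$offset[w] + 1L)
    feats[[length(feats) + 1L]] <- list(element = nm,
                                        start = g$windows$offset[w] + 1L,
                                        end = g$windows$offset[w] + nchar(cont),
                                        content = cont)
  }
  list(chars = chars, feats = feats)
}

.module_domains <- function(m) {
  doms <- list()
  doms$KS <- list(
    active_site_context = paste0("DTA", m$ks, "SSL"),
    active_site = m$ks)
  doms$AT <- lapply(.at_window_patterns(m$at), instantiate_motif)
  if (!identical(m$dh, "absent")) {
    doms$DH <- lapply(.dh_window_patterns(m$dh), instantiate_motif)
  }
  if (isTRUE(m$er)) doms$ER <- list()
  if (!identical(m$kr, "absent")) {
    doms$KR <- lapply(.kr_window_patterns(m$kr, m$kr_catalytic),
                      instantiate_motif)
  }
  doms$T <- list()
  if (isTRUE(m$te)) doms$TE <- list()
  doms
}

#' Generate a synthetic assembly line from a truth table
#'
#' Embeds domain anchors and active-site windows into randomized
#' low-complexity protein scaffolds in grammar order, partitions modules
#' over proteins per the truth table, screens the filler for accidental
#' anchor matches, and applies the scaffold mutation rate. Deterministic
#' for a fixed `(truth, seed)` pair.
#'
#' @param truth a `pk_truth_table`.
#' @param seed integer seed.
#' @return object of class `pk_synthetic_bundle`: `proteins` (a
#'   [read_fasta()]-style data.frame), `truth`, `features` (absolute
#'   coordinates of every embedded anchor and window), `provenance`.
#' @export
generate_assembly <- function(truth, seed) {
  stopifnot(inherits(truth, "pk_truth_table"))
  withr::with_seed(as.integer(seed), .generate_assembly_impl(truth, seed))
}

.generate_assembly_impl <- function(truth, seed) {
  prot_of <- vapply(truth$modules, `[[`, numeric(1), "protein")
  n_prot <- length(unique(prot_of))
  sequences <- character(n_prot)
  features <- list()
  for (p in seq_len(n_prot)) {
    chars <- .filler(sample(20:40, 1L))
    for (mi in which(prot_of == sort(unique(prot_of))[p])) {
      m <- truth$modules[[mi]]
      doms <- .module_domains(m)
      for (kind in names(doms)) {
        d <- .build_domain(kind, doms[[kind]])
        offset <- length(chars)
        for (f in d$feats) {
          features[[length(features) + 1L]] <- data.frame(
            protein_id = truth$protein_ids[p], module = m$label, kind = kind,
            element = f$element, start = offset + f$start,
            end = offset + f$end, content = f$content,
            stringsAsFactors = FALSE)
        }
        chars <- c(chars, d$chars,
                   .filler(sample(truth$linker_range[1]:truth$linker_range[2], 1L)))
      }
    }
    chars <- c(chars, .filler(sample(10:30, 1L)))
    sequences[p] <- paste(chars, collapse = "")
  }
  features <- do.call(rbind, features)
  sequences <- .screen_spurious_anchors(sequences, features,
                                        truth$protein_ids)
  if (truth$mutation_rate > 0) {
    sequences <- vapply(sequences, .mutate_sequence, character(1),
                        rate = truth$mutation_rate, USE.NAMES = FALSE)
  }
  proteins <- data.frame(id = truth$protein_ids,
                         order_index = seq_len(n_prot),
                         sequence = sequences, stringsAsFactors = FALSE)
  structure(list(proteins = proteins, truth = truth, features = features,
                 provenance = list(seed = as.integer(seed),
                                   generator = "pksdecode-1")),
            class = "pk_synthetic_bundle")
}

# replace accidental anchor matches in filler so that hits are unique;
# bytes inside intended features are never touched
.screen_spurious_anchors <- function(sequences, features, protein_ids) {
  anchors <- unique(unlist(lapply(pks_domain_geometry(), `[[`, "anchors")))
  for (p in seq_along(sequences)) {
    s <- sequences[p]
    feat <- features[features$protein_id == protein_ids[p], ]
    protected <- unlist(Map(seq, feat$start, feat$end))
    intended <- feat[feat$element %in% c("anchor1", "anchor2"), ]
    for (iter in 1:20) {
      dirty <- FALSE
      for (a in anchors) {
        pos <- gregexpr(a, s, fixed = TRUE)[[1]]
        if (pos[1] == -1L) next
        for (q in as.integer(pos)) {
          if (any(intended$start == q & intended$content == a)) next
          span <- q:(q + nchar(a) - 1L)
          mutable <- setdiff(span, protected)
          if (!length(mutable)) {
            warning("spurious anchor overlaps intended content; left as is")
            next
          }
          b <- mutable[1]
          old <- substr(s, b, b)
          substr(s, b, b) <- sample(setdiff(
            strsplit("ACDEFGIKLMNRSTV", "")[[1]], old), 1L)
          dirty <- TRUE
        }
      }
      if (!dirty) break
    }
    sequences[p] <- s
  }
  sequences
}

.mutate_sequence <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- .filler(sum(hit))
  }
  paste(chars, collapse = "")
}

#' Apply named mutations to a synthetic bundle
#'
#' Each operation targets one embedded window of one module and changes
#' exactly the named bytes; the truth table is updated to the implied new
#' ground truth. Supported operations: `at_inactivate` (motif-II catalytic
#' serine to glycine), `ks_to_loading` (active-site C to Q),
#' `ks_to_extension` (Q to C), `dh_lose_yxy` (first YxY tyrosine to
#' phenylalanine).
#'
#' @param bundle a `pk_synthetic_bundle`.
#' @param operations list of `list(op =, module =)` entries.
#' @return the mutated bundle.
#' @export
corrupt_bundle <- function(bundle, operations) {
  for (o in operations) {
    spec <- switch(o$op,
      at_inactivate = list(kind = "AT", window = "motif_II", pos = 3L,
                           to = "G",
                           update = function(m) { m$at <- "inactive"; m }),
      ks_to_loading = list(kind = "KS", window = "active_site", pos = 1L,
                           to = "Q",
                           update = function(m) { m$ks <- "Q"; m }),
      ks_to_extension = list(kind = "KS", window = "active_site", pos = 1L,
                             to = "C",
                             update = function(m) { m$ks <- "C"; m }),
      dh_lose_yxy = list(kind = "DH", window = "yxy_window", pos = 1L,
                         to = "F",
                         update = function(m) { m$dh <- "inactive"; m }),
      stop("unknown mutation operation: ", o$op))
    f <- bundle$features
    row <- which(f$module == as.character(o$module) & f$kind == spec$kind &
                   f$element == spec$window)
    if (length(row) != 1L) {
      stop("mutation '", o$op, "' targets no unique window in module ",
           o$module)
    }
    pid <- f$protein_id[row]
    at <- f$start[row] + spec$pos - 1L
    pi <- match(pid, bundle$proteins$id)
    s <- bundle$proteins$sequence[pi]
    substr(s, at, at) <- spec$to
    bundle$proteins$sequence[pi] <- s
    new_content <- f$content[row]
    substr(new_content, spec$pos, spec$pos) <- spec$to
    bundle$features$content[row] <- new_content
    # KS context window shares the mutated byte
    if (spec$kind == "KS") {
      ctx <- which(f$module == as.character(o$module) & f$kind == "KS" &
                     f$element == "active_site_context")
      cc <- bundle$features$content[ctx]
      substr(cc, 4, 4) <- spec$to
      bundle$features$content[ctx] <- cc
    }
    labels <- vapply(bundle$truth$modules, `[[`, "", "label")
    mi <- match(as.character(o$module), labels)
    bundle$truth$modules[[mi]] <- spec$update(bundle$truth$modules[[mi]])
  }
  bundle
}

#' Draw a random valid truth table
#'
#' Uses the current RNG stream. Modules get random extender classes and
#' random (grammar-valid) processing-domain sets; the first module is a
#' loading module and the last carries the TE.
#'
#' @param n_modules number of extension modules (default random 3-7).
#' @param n_proteins number of proteins to partition over.
#' @return a `pk_truth_table`.
#' @export
random_truth_table <- function(n_modules = sample(3:7, 1L),
                               n_proteins = sample(1:3, 1L)) {
  n_proteins <- min(n_proteins, n_modules + 1L)
  protein_of <- sort(sample(seq_len(n_proteins), n_modules + 1L,
                            replace = TRUE))
  protein_of <- as.integer(factor(protein_of))
  mods <- list(.module_entry("LM", protein_of[1], ks = "Q",
                             at = sample(c("methylmalonyl", "malonyl"), 1L)))
  for (i in seq_len(n_modules)) {
    at <- sample(c("methylmalonyl", "malonyl"), 1L)
    kr <- sample(c("absent", "B1", "B2", "A", "nondiagnostic"), 1L)
    dh <- "absent"
    er <- FALSE
    if (kr != "absent" && stats::runif(1) < 0.5) {
      dh <- sample(c("active", "inactive", "ei"), 1L)
      if (dh %in% c("active", "ei") && stats::runif(1) < 0.3) er <- TRUE
    }
    mods[[length(mods) + 1L]] <- .module_entry(
      as.character(i), protein_of[i + 1L], at = at, kr = kr,
      kr_catalytic = sample(c("LDD", "IDD", "VDD"), 1L), dh = dh, er = er,
      te = i == n_modules)
  }
  truth_table(mods)
}

#' @export
print.pk_synthetic_bundle <- function(x, ...) {
  cat("<pk_synthetic_bundle> ", nrow(x$proteins), " proteins, ",
      length(x$truth$modules), " modules, seed ", x$provenance$seed,
      "\n", sep = "")
  invisible(x)
}
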