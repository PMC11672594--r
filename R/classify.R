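#' Classify acyltransferase substrate specificity from active-site motifs
#'
#' Methylmalonyl-specific AT domains carry `xVDVxQ / GHSQGE / xxSH`
#' (motifs I/II/III around the catalytic serine); malonyl-specific domains
#' carry `xTxYTQ / GHSI(V)GE / xAFN`. Loss of the catalytic serine of
#' motif II (the `GHS` serine replaced, e.g. by glycine) abolishes AT
#' activity. When the three motifs disagree, motif II dominates (it holds
#' the catalytic serine), then a majority vote; with no evidence at all the
#' call is `unclassified`.
#'
#' @param motif_I,motif_II,motif_III the three extracted motif windows
#'   (6, 6 and 4 residues).
#' @return a list of class `pk_at_call` with `specificity` (one of
#'   `"methylmalonyl"`, `"malonyl"`, `"inactive"`, `"unclassified"`) and
#'   `evidence`.
#' @export
classify_at <- function(motif_I, motif_II, motif_III) {
  .check_window(motif_I, 6L, "motif_I")
  .check_window(motif_II, 6L, "motif_II")
  .check_window(motif_III, 4L, "motif_III")
  mm <- c(I = matches_pattern(motif_I, "xVDVxQ"),
          II = matches_pattern(motif_II, "GHSQGE"),
          III = matches_pattern(motif_III, "xxSH"))
  mal <- c(I = matches_pattern(motif_I, "xTxYTQ"),
           II = matches_pattern(motif_II, "GHSI(V)GE"),
           III = matches_pattern(motif_III, "xAFN"))
  frame_ii <- grepl("^GH..GE$", motif_II)
  serine_ok <- substr(motif_II, 3, 3) == "S"
  evidence <- list(motif_I = motif_I, motif_II = motif_II,
                   motif_III = motif_III)
  call <- if (all(mm)) {
    evidence$rule <- "all three methylmalonyl motifs matched"
    "methylmalonyl"
  } else if (all(mal)) {
    evidence$rule <- "all three malonyl motifs matched"
    "malonyl"
  } else if (frame_ii && !serine_ok) {
    evidence$rule <- "motif-II catalytic serine lost"
    "inactive"
  } else {
    # weighted majority, motif II counted double
    w <- c(I = 1, II = 2, III = 1)
    s_mm <- sum(w[mm])
    s_mal <- sum(w[mal])
    if (s_mm > s_mal && s_mm >= 2) {
      evidence$rule <- "majority vote (methylmalonyl)"
      "methylmalonyl"
    } else if (s_mal > s_mm && s_mal >= 2) {
      evidence$rule <- "majority vote (malonyl)"
      "malonyl"
    } else {
      evidence$rule <- "no rule fired"
      "unclassified"
    }
  }
  structure(list(specificity = call, evidence = evidence),
            class = "pk_at_call")
}

#' Classify a ketoreductase stereotype
#'
#' The `LDD` motif (or its rarer `IDD`/`VDD` variants) marks a type B KR;
#' within type B, a `YxP` subtype window gives B2 and `YxA` gives B1.
#' Absence of an LDD-family motif together with a matched `WxxxxQ` window
#' marks type A. Contradictory evidence (LDD family *and* WxxxxQ) calls B
#' with a `conflict` flag. With no diagnostic motif either way the call is
#' `B_unsubtyped` with a `no_diagnostic_motif` flag (type B is the majority
#' stereotype; the call is explicitly low-confidence, never silent).
#'
#' @param catalytic_motif the 3-residue LDD-position window.
#' @param subtype_window the 3-residue YxP/YxA window.
#' @param a_type_window the 6-residue WxxxxQ window.
#' @return list of class `pk_kr_call` with `stereotype` (one of `"A"`,
#'   `"B1"`, `"B2"`, `"B_unsubtyped"`), `catalytic_motif`, `flags`.
#' @export
classify_kr <- function(catalytic_motif, subtype_window, a_type_window) {
  .check_window(catalytic_motif, 3L, "catalytic_motif")
  .check_window(subtype_window, 3L, "subtype_window")
  .check_window(a_type_window, 6L, "a_type_window")
  ldd_family <- catalytic_motif %in% c("LDD", "IDD", "VDD")
  w_match <- matches_pattern(a_type_window, "WxxxxQ")
  flags <- character(0)
  if (ldd_family && w_match) flags <- c(flags, "conflict")
  stereotype <- if (ldd_family) {
    if (matches_pattern(subtype_window, "YxP")) "B2"
    else if (matches_pattern(subtype_window, "YxA")) "B1"
    else "B_unsubtyped"
  } else if (w_match) {
    "A"
  } else {
    flags <- c(flags, "no_diagnostic_motif")
    "B_unsubtyped"
  }
  structure(list(stereotype = stereotype, catalytic_motif = catalytic_motif,
                 subtype_window = subtype_window,
                 a_type_window = a_type_window, flags = flags),
            class = "pk_kr_call")
}

#' Classify dehydratase activity and enoyl-isomerase candidacy
#'
#' An active DH carries the `HxxxxxxxxP` catalytic motif (conserved
#' histidine, terminal proline) and an intact `YxY` window. Loss of the
#' histidine or of a YxY tyrosine marks the domain inactive. Enoyl
#' isomerase (EI) candidates replace the terminal proline by L/V
#' (`HxxxxxxxxL/V`) or carry V/L at the Q/H position of the second motif
#' `DxxxQ/H`; an EI-candidate motif with intact YxY still counts as
#' catalytically competent (`active`).
#'
#' @param catalytic_motif 10-residue window at the catalytic histidine.
#' @param yxy_window 3-residue YxY window.
#' @param second_motif 5-residue DxxxQ/H window.
#' @return list of class `pk_dh_call` with `status` (`"active"` or
#'   `"inactive"`), `ei_candidate` and `evidence`.
#' @export
classify_dh <- function(catalytic_motif, yxy_window, second_motif) {
  .check_window(catalytic_motif, 10L, "catalytic_motif")
  .check_window(yxy_window, 3L, "yxy_window")
  .check_window(second_motif, 5L, "second_motif")
  terminal <- substr(catalytic_motif, 10, 10)
  h_ok <- substr(catalytic_motif, 1, 1) == "H"
  motif_ok <- h_ok && terminal %in% c("P", "L", "V")
  yxy_ok <- grepl("^Y.Y$", yxy_window)
  ei <- (h_ok && terminal %in% c("L", "V")) ||
    substr(second_motif, 5, 5) %in% c("V", "L")
  status <- if (motif_ok && yxy_ok) "active" else "inactive"
  structure(list(status = status, ei_candidate = ei,
                 evidence = list(catalytic_motif = catalytic_motif,
                                 yxy_window = yxy_window,
                                 second_motif = second_motif)),
            class = "pk_dh_call")
}

#' Classify a ketosynthase as loading (KSQ) or extending
#'
#' Loading-module KS domains carry a glutamine in place of the catalytic
#' cysteine (KSQ) and act as decarboxylases for the starter unit.
#'
#' @param active_site_residue single-letter active-site residue.
#' @return list of class `pk_ks_call` with `role` (`"loading"` or
#'   `"extension"`), `active_site_residue`, `warning` flag.
#' @export
classify_ks <- function(active_site_residue) {
  if (!is.character(active_site_residue) || length(active_site_residue) != 1L ||
      !nzchar(active_site_residue)) {
    stop("active_site_residue must be a single letter")
  }
  r <- active_site_residue
  role <- if (r == "Q") "loading" else "extension"
  warn <- !(r %in% c("Q", "C"))
  structure(list(role = role, active_site_residue = r, warning = warn),
            class = "pk_ks_call")
}

.check_window <- function(x, len, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("window '", name, "' is missing or empty")
  }
  if (nchar(x) < len) {
    stop("window '", name, "' is shorter (", nchar(x),
         ") than its pattern length (", len, ")")
  }
  invisible(TRUE)
}

#' Classify every domain hit in a hit table
#'
#' Applies the per-kind classifiers to the extracted windows and returns a
#' call table with evidence columns. Kinds without classification rules
#' (T, TE, ER) get a `present` call.
#'
#' @param hits output of [scan_assembly_line()].
#' @return data.frame with columns `protein_id`, `order_index`, `kind`,
#'   `start`, `end`, `call`, `detail`, `flags`.
#' @export
classify_hits <- function(hits) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    res <- switch(h$kind,
      KS = {
        k <- classify_ks(h$active_site)
        list(call = k$role, detail = k$active_site_residue,
             flags = if (k$warning) "warning" else "")
      },
      AT = {
        a <- classify_at(h$motif_I, h$motif_II, h$motif_III)
        list(call = a$specificity, detail = a$evidence$rule, flags = "")
      },
      KR = {
        k <- classify_kr(h$catalytic_motif, h$subtype_window, h$a_type_window)
        list(call = k$stereotype, detail = k$catalytic_motif,
             flags = paste(k$flags, collapse = ";"))
      },
      DH = {
        d <- classify_dh(h$catalytic_motif, h$yxy_window, h$second_motif)
        list(call = d$status,
             detail = if (d$ei_candidate) "ei_candidate" else "",
             flags = "")
      },
      list(call = "present", detail = "", flags = "")
    )
    data.frame(protein_id = h$protein_id,
               order_index = if ("order_index" %in% names(hits)) h$order_index else NA_integer_,
               kind = h$kind, start = h$start, end = h$end,
               call = res$call, detail = res$detail, flags = res$flags,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
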