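#' Scan one protein for PKS domains
#'
#' Anchored degenerate-pattern scanning: for each domain model, occurrences
#' of the first anchor are tried leftmost-first; subsequent anchors must
#' fall within the model's spacing intervals (earliest viable match wins).
#' A successful chain yields a hit spanning from the first anchor to the
#' last anchor plus the model tail, with all declared classification
#' windows extracted. Hits never overlap: scanning resumes past each
#' accepted hit. All coordinates are 1-based inclusive.
#'
#' @param protein one row of [read_fasta()] output (or a list with `id`,
#'   `sequence`).
#' @param models named list of [domain_model()] objects; must cover at
#'   least KS, AT and T.
#' @param warn_if_empty emit a warning when a module-bearing protein shows
#'   no KS/AT anchor at all.
#' @return a hit `data.frame` with columns `protein_id`, `kind`, `start`,
#'   `end` and one column per declared window (NA where not applicable).
#' @export
scan_domains <- function(protein, models = pks_domain_models(),
                         warn_if_empty = TRUE) {
  stopifnot(all(c("KS", "AT", "T") %in% vapply(models, `[[`, "", "kind")))
  seqc <- protein$sequence
  id <- protein$id
  hits <- list()
  for (model in models) {
    hits <- c(hits, .scan_one_model(seqc, id, model))
  }
  df <- .hits_to_frame(hits)
  if (nrow(df)) df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (warn_if_empty && !any(df$kind %in% c("KS", "AT"))) {
    warning("no KS/AT anchors found in protein '", id, "'")
  }
  df
}

.scan_one_model <- function(seqc, id, model) {
  n <- nchar(seqc)
  rx1 <- compile_pattern(model$anchors[1], anchored = FALSE)
  starts <- gregexpr(rx1, seqc)[[1]]
  if (starts[1] == -1L) return(list())
  out <- list()
  cursor <- 1L
  for (p in as.integer(starts)) {
    if (p < cursor) next
    anchor_pos <- p
    last_start <- p
    last_width <- attr(regexpr(rx1, substr(seqc, p, n)), "match.length")
    ok <- TRUE
    if (length(model$anchors) > 1L) {
      for (k in seq_along(model$spacing)) {
        sp <- model$spacing[[k]]
        rxk <- compile_pattern(model$anchors[k + 1L], anchored = FALSE)
        lo <- last_start + sp[1]
        hi <- min(n, last_start + sp[2])
        if (lo > n) { ok <- FALSE; break }
        m <- regexpr(rxk, substr(seqc, lo, hi + pattern_width(model$anchors[k + 1L])))
        if (m == -1L) { ok <- FALSE; break }
        cand <- lo + as.integer(m) - 1L
        if (cand > hi) { ok <- FALSE; break }
        last_start <- cand
        last_width <- attr(m, "match.length")
      }
    }
    if (!ok) next
    end <- min(n, last_start + last_width - 1L + model$tail)
    wins <- list()
    win_ok <- TRUE
    wdf <- model$windows
    for (w in seq_len(nrow(wdf))) {
      ws <- p + wdf$offset[w]
      we <- ws + wdf$width[w] - 1L
      if (we > end) { win_ok <- FALSE; break }
      wins[[wdf$name[w]]] <- substr(seqc, ws, we)
    }
    if (!win_ok) next
    out[[length(out) + 1L]] <- c(
      list(protein_id = id, kind = model$kind, start = p, end = end), wins)
    cursor <- end + 1L
  }
  out
}

.window_columns <- c("active_site_context", "active_site",
                     "motif_I", "motif_II", "motif_III",
                     "catalytic_motif", "subtype_window", "a_type_window",
                     "yxy_window", "second_motif")

.hits_to_frame <- function(hits) {
  cols <- c("protein_id", "kind", "start", "end", .window_columns)
  if (!length(hits)) {
    df <- data.frame(protein_id = character(0), kind = character(0),
                     start = integer(0), end = integer(0))
    for (w in .window_columns) df[[w]] <- character(0)
    return(df)
  }
  rows <- lapply(hits, function(h) {
    for (w in cols) if (is.null(h[[w]])) h[[w]] <- NA
    as.data.frame(h[cols], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan a whole assembly line
#'
#' @param proteins [read_fasta()]-style data.frame.
#' @inheritParams scan_domains
#' @return hit data.frame over all proteins, ordered by protein
#'   `order_index` then `start`, with an `order_index` column added.
#' @export
scan_assembly_line <- function(proteins, models = pks_domain_models()) {
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    h <- scan_domains(as.list(proteins[i, ]), models, warn_if_empty = FALSE)
    if (nrow(h)) h$order_index <- proteins$order_index[i]
    h
  })
  res <- res[vapply(res, nrow, 1L) > 0L]
  if (!length(res)) {
    df <- .hits_to_frame(list())
    df$order_index <- integer(0)
    return(df)
  }
  df <- do.call(rbind, res)
  df <- df[order(df$order_index, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Group domain hits into PKS modules
#'
#' Applies the canonical cis-AT module grammar
#' `KS - AT - [DH - [ER] - KR] - T` (optional loading module first, optional
#' trailing TE). A new module opens at each KS; processing domains must
#' appear in grammar order; T closes the module; a TE after the final T is
#' attached to the last module. Hits violating the grammar are reported in
#' the `diagnostics` attribute and the affected grouping is flagged
#' `ambiguous` (best effort, never a crash).
#'
#' @param hits output of [scan_assembly_line()] (must be sorted by
#'   `order_index`, then `start`).
#' @return a list of module groupings; each grouping is a list with
#'   `module_number`, `hits` (data.frame rows), `te_present`, `ambiguous`.
#'   Attribute `diagnostics` collects grammar violations.
#' @export
segment_modules <- function(hits) {
  order_rank <- c(KS = 1, AT = 2, DH = 3, ER = 4, KR = 5, T = 6, TE = 7)
  modules <- list()
  diagnostics <- character(0)
  current <- NULL
  current_rank <- 0
  flush <- function() {
    if (!is.null(current)) modules[[length(modules) + 1L]] <<- current
    current <<- NULL
    current_rank <<- 0
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    k <- h$kind
    r <- order_rank[[k]]
    if (k == "KS") {
      if (!is.null(current) && is.null(current$closed)) {
        diagnostics <- c(diagnostics, paste0(
          "module ", length(modules) + 1L, " not closed by T before next KS (",
          h$protein_id, ":", h$start, ")"))
        current$ambiguous <- TRUE
      }
      flush()
      current <- list(module_number = length(modules) + 1L, hits = h,
                      te_present = FALSE, ambiguous = FALSE)
      current_rank <- r
    } else if (k == "TE") {
      if (length(modules) == 0L && is.null(current)) {
        diagnostics <- c(diagnostics, "TE with no preceding module")
        next
      }
      if (!is.null(current)) flush()
      modules[[length(modules)]]$te_present <- TRUE
      modules[[length(modules)]]$hits <- rbind(modules[[length(modules)]]$hits, h)
    } else {
      if (is.null(current)) {
        diagnostics <- c(diagnostics, paste0(
          k, " hit without open module (", h$protein_id, ":", h$start, ")"))
        current <- list(module_number = length(modules) + 1L, hits = h,
                        te_present = FALSE, ambiguous = TRUE)
        current_rank <- r
        next
      }
      if (r <= current_rank) {
        diagnostics <- c(diagnostics, paste0(
          "out-of-order ", k, " in module ", current$module_number, " (",
          h$protein_id, ":", h$start, ")"))
        current$ambiguous <- TRUE
      }
      current$hits <- rbind(current$hits, h)
      current_rank <- max(current_rank, r)
      if (k == "T") current$closed <- TRUE
    }
  }
  flush()
  structure(modules, diagnostics = diagnostics, class = "pk_module_groupings")
}

#' @export
print.pk_module_groupings <- function(x, ...) {
  cat("<pk_module_groupings> ", length(x), " modules\n", sep = "")
  for (m in x) {
    cat(sprintf("  module %2d: %s%s%s\n", m$module_number,
                paste(m$hits$kind, collapse = "-"),
                if (m$te_present) " [TE]" else "",
                if (isTRUE(m$ambiguous)) " (ambiguous)" else ""))
  }
  d <- attr(x, "diagnostics")
  if (length(d)) cat("  diagnostics:", length(d), "grammar issue(s)\n")
  invisible(x)
}

#' Export domain hits as TSV
#' @param hits hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
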