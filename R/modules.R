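#' Build module specifications from segmented, classified domain hits
#'
#' Joins the grammar groupings from [segment_modules()] with the per-domain
#' calls from [classify_hits()] and applies the assembly-line layout
#' (iterative/stuttering flags, acyltransferase borrowing, ketosynthase
#' gatekeeping). The first grouping whose KS classifies as loading becomes
#' the loading module `"LM"`; the rest are numbered 1..n.
#'
#' @param groupings result of [segment_modules()].
#' @param calls result of [classify_hits()] on the same hits.
#' @param layout assembly-line configuration, see [iru_layout()]. Only the
#'   `modules` component (flags keyed by module label) is consulted here.
#' @return list of `pk_module_spec` objects.
#' @export
build_modules <- function(groupings, calls, layout = list(modules = list())) {
  key <- function(p, s) paste(p, s, sep = "@")
  call_map <- stats::setNames(
    split(calls, seq_len(nrow(calls))),
    key(calls$protein_id, calls$start))
  te_count <- 0L
  specs <- vector("list", length(groupings))
  n_ext <- 0L
  for (i in seq_along(groupings)) {
    g <- groupings[[i]]
    dom <- list(ks = NULL, at = NULL, dh = NULL, er = FALSE, kr = NULL,
                t_present = FALSE, te_present = FALSE)
    dh_detail <- ""
    kr_flags <- ""
    for (j in seq_len(nrow(g$hits))) {
      h <- g$hits[j, ]
      cl <- call_map[[key(h$protein_id, h$start)]]
      if (is.null(cl)) stop("no classification for hit ", key(h$protein_id, h$start))
      switch(h$kind,
             KS = dom$ks <- cl$call,
             AT = dom$at <- cl$call,
             DH = { dom$dh <- cl$call; dh_detail <- cl$detail },
             ER = dom$er <- TRUE,
             KR = { dom$kr <- cl$call; kr_flags <- cl$flags },
             T = dom$t_present <- TRUE,
             TE = NULL)
    }
    if (g$te_present) {
      dom$te_present <- TRUE
      te_count <- te_count + 1L
    }
    loading <- identical(dom$ks, "loading") && i == 1L
    label <- if (loading) "LM" else { n_ext <- n_ext + 1L; as.character(n_ext) }
    lay <- layout$modules[[label]] %||rnull% list()
    spec <- structure(list(
      index = label,
      ks = dom$ks,
      at = dom$at,
      dh = if (is.null(dom$dh)) "absent" else dom$dh,
      dh_ei_candidate = identical(dh_detail, "ei_candidate"),
      er = dom$er,
      kr = if (is.null(dom$kr)) "absent" else dom$kr,
      kr_flags = kr_flags,
      t_present = dom$t_present,
      te_present = dom$te_present,
      flags = list(
        iterative = isTRUE(lay$iterative),
        iteration_count = lay$iteration_count %||rnull% 1L,
        at_borrowed_from = lay$at_borrowed_from %||rnull% NA,
        ks_gatekeeper_override = lay$ks_gatekeeper_override %||rnull% NA,
        olefin_shift = isTRUE(lay$olefin_shift))),
      class = "pk_module_spec")
    specs[[i]] <- spec
  }
  if (te_count != 1L) {
    stop("assembly line must carry exactly one TE domain (found ", te_count, ")")
  }
  if (!specs[[length(specs)]]$te_present) {
    stop("TE must sit on the final module")
  }
  final <- specs[[length(specs)]]
  if (identical(final$at, "inactive") && is.na(final$flags$at_borrowed_from)) {
    stop("final module has an inactive AT and no at_borrowed_from source; ",
         "the layout must decide where its extender comes from")
  }
  for (i in seq_along(specs)) {
    f <- specs[[i]]$flags
    if ((isTRUE(f$iterative) || !is.na(f$at_borrowed_from)) &&
        i < length(specs) - 1L) {
      stop("iterative / at_borrowed_from flags are only allowed on the ",
           "final two modules (module ", specs[[i]]$index, ")")
    }
  }
  specs
}

`%||rnull%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pk_module_spec <- function(x, ...) {
  cat(sprintf("<module %s> KS:%s AT:%s DH:%s%s ER:%s KR:%s%s%s\n",
              x$index, x$ks, x$at, x$dh,
              if (x$dh_ei_candidate) "(EI?)" else "",
              if (x$er) "+" else "-", x$kr,
              if (x$te_present) " [TE]" else "",
              if (x$flags$olefin_shift) " {olefin shift}" else ""))
  invisible(x)
}
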