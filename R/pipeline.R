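#' Load the packaged iru assembly-line layout
#'
#' The layout names the module flags (KS gatekeeping on M8, iterative
#' elongation on M11, AT borrowing for M12), the ring-closure carbons
#' (lactone oxygen at C19; provisional hemiketal C3/C7), the tailoring
#' steps and the heavy-oxygen labeling setup.
#'
#' @param path optional path to a layout JSON file; defaults to the
#'   packaged iru layout.
#' @return layout list.
#' @export
iru_layout <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "iru_layout.json", package = "pksdecode",
                        mustWork = TRUE)
  }
  lay <- jsonlite::read_json(path, simplifyVector = FALSE)
  lay$tailoring <- lapply(lay$tailoring, function(s) {
    tailoring_step(s$kind, site = unlist(s$site),
                   delta = if (!is.null(s$delta)) unlist(s$delta) else NULL)
  })
  lay
}

#' Generate the packaged iru-like synthetic bundle
#' @param seed integer seed (default 42, the packaged fixture seed).
#' @return a `pk_synthetic_bundle`.
#' @export
iru_bundle <- function(seed = 42) {
  generate_assembly(iru_truth_table(), seed)
}

#' Decode an assembly line end to end
#'
#' Runs the full pipeline: domain scanning, module segmentation, domain
#' classification, module-spec construction, chain extension, ring
#' closure, tailoring, and adduct/labeling arithmetic.
#'
#' @param proteins [read_fasta()]-style data.frame of assembly-line
#'   proteins.
#' @param layout layout list (see [iru_layout()]).
#' @param models domain models (default [pks_domain_models()]).
#' @param olefin_shift_path 1 or 2; overrides the layout default.
#' @return list with `hits`, `groupings`, `calls`, `modules`, `backbone`,
#'   `aglycone_formula`, `product_formula`, `labeled_formula`, `adducts`
#'   (data.frame of labeled-product m/z values).
#' @export
decode_assembly_line <- function(proteins, layout = iru_layout(),
                                 models = pks_domain_models(),
                                 olefin_shift_path = NULL) {
  hits <- scan_assembly_line(proteins, models)
  groupings <- segment_modules(hits)
  calls <- classify_hits(hits)
  modules <- build_modules(groupings, calls, layout)
  path <- olefin_shift_path %||rnull% (layout$olefin_shift_path %||rnull% 1)
  backbone <- extend_chain(modules, options = list(olefin_shift_path = path))
  rc <- layout$ring_closure
  if (!is.null(rc)) {
    backbone <- close_rings(
      backbone,
      lactone_oxygen_carbon = rc$lactone_oxygen_carbon,
      hemiketal = if (!is.null(rc$hemiketal)) {
        list(ketone_carbon = rc$hemiketal$ketone_carbon,
             hydroxyl_carbon = rc$hemiketal$hydroxyl_carbon)
      })
  }
  aglycone <- backbone_formula(backbone)
  product <- apply_tailoring(backbone, layout$tailoring %||rnull% list())
  k <- layout$labeling$exchangeable_slots %||rnull% backbone$exchangeable_oxygens
  labeled <- set_labeled_oxygen(product, k)
  adducts <- adduct_specs()
  adducts$mz_labeled <- vapply(adducts$name, function(a)
    adduct_mz(labeled, a), numeric(1))
  adducts$mz_unlabeled <- vapply(adducts$name, function(a)
    adduct_mz(product, a), numeric(1))
  list(hits = hits, groupings = groupings, calls = calls, modules = modules,
       backbone = backbone, aglycone_formula = aglycone,
       product_formula = product, labeled_formula = labeled,
       adducts = adducts)
}

#' Decode the packaged iru fixture
#' @param seed fixture seed (default 42).
#' @param olefin_shift_path 1 or 2.
#' @return see [decode_assembly_line()].
#' @export
decode_iru <- function(seed = 42, olefin_shift_path = 1) {
  bundle <- iru_bundle(seed)
  decode_assembly_line(bundle$proteins, iru_layout(),
                       olefin_shift_path = olefin_shift_path)
}
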