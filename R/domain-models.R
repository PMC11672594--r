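#' Domain models for anchored motif scanning
#'
#' A `DomainModel` locates one PKS domain kind by a chain of literal anchor
#' strings with bounded spacing, and declares classification windows at
#' fixed offsets from the first anchor. The packaged default models (see
#' [pks_domain_models()]) share their geometry with the synthetic-sequence
#' generator, so a generated assembly line is recovered exactly.
#'
#' @param kind one of `"KS"`, `"AT"`, `"DH"`, `"ER"`, `"KR"`, `"T"`, `"TE"`.
#' @param anchors character vector of anchor patterns in N- to C-order
#'   (degenerate alphabet of [compile_pattern()]; the defaults are literal).
#' @param spacing list of length `length(anchors) - 1` with `c(lo, hi)`
#'   allowed distances (residues) between consecutive anchor starts.
#' @param windows `data.frame(name, offset, width)`; `offset` is 0-based
#'   from the first anchor's start.
#' @param tail residues of domain extent past the last anchor's end.
#' @return an object of class `pk_domain_model`.
#' @export
domain_model <- function(kind, anchors, spacing = list(), windows = NULL,
                         tail = 0L) {
  kind <- match.arg(kind, c("KS", "AT", "DH", "ER", "KR", "T", "TE"))
  stopifnot(length(anchors) >= 1L, all(nzchar(anchors)))
  if (length(spacing) != length(anchors) - 1L) {
    stop("need one spacing interval per consecutive anchor pair")
  }
  for (sp in spacing) {
    if (length(sp) != 2L || sp[2] < sp[1] || sp[1] <= 0) {
      stop("spacing intervals must be positive-width c(lo, hi)")
    }
  }
  if (is.null(windows)) {
    windows <- data.frame(name = character(0), offset = integer(0),
                          width = integer(0))
  }
  structure(list(kind = kind, anchors = anchors, spacing = spacing,
                 windows = windows, tail = as.integer(tail)),
            class = "pk_domain_model")
}

# Shared scanner/generator geometry. Offsets are 0-based from the first
# anchor start; spans are the nominal domain lengths (typical cis-AT PKS
# domain sizes; the motif literature prints motifs, not coordinates).
pks_domain_geometry <- function() {
  list(
    KS = list(anchors = c("EPIAIVGM", "HGTGT"), a2_offset = 360L,
              windows = data.frame(
                name = c("active_site_context", "active_site"),
                offset = c(160L, 163L), width = c(7L, 1L)),
              tail = 55L, span = 420L),
    AT = list(anchors = c("VFPGQGAQ", "HAFHSPLM"), a2_offset = 260L,
              windows = data.frame(
                name = c("motif_I", "motif_II", "motif_III"),
                offset = c(90L, 150L, 210L), width = c(6L, 6L, 4L)),
              tail = 32L, span = 300L),
    DH = list(anchors = c("EPWLADE", "GYEYGPAF"), a2_offset = 240L,
              windows = data.frame(
                name = c("catalytic_motif", "yxy_window", "second_motif"),
                offset = c(60L, 130L, 185L), width = c(10L, 3L, 5L)),
              tail = 32L, span = 280L),
    ER = list(anchors = c("AAGGVGMA", "GVDVVLNS"), a2_offset = 250L,
              windows = data.frame(name = character(0), offset = integer(0),
                                   width = integer(0)),
              tail = 42L, span = 300L),
    KR = list(anchors = c("GGTGALGA", "YAAANAFL"), a2_offset = 390L,
              windows = data.frame(
                name = c("catalytic_motif", "subtype_window", "a_type_window"),
                offset = c(130L, 195L, 240L), width = c(3L, 3L, 6L)),
              tail = 52L, span = 450L),
    T = list(anchors = "GIDSLG", a2_offset = NA_integer_,
             windows = data.frame(name = character(0), offset = integer(0),
                                  width = integer(0)),
             tail = 74L, span = 80L),
    TE = list(anchors = c("GWSAGG", "NGNHFT"), a2_offset = 200L,
              windows = data.frame(name = character(0), offset = integer(0),
                                   width = integer(0)),
              tail = 54L, span = 260L)
  )
}

#' Packaged default domain models
#'
#' One model per domain kind, with spacing intervals set to +/- `slack`
#' (default 30%) around the packaged reference geometry.
#'
#' @param slack fractional slack on anchor spacings.
#' @return named list of `pk_domain_model` objects.
#' @export
pks_domain_models <- function(slack = 0.3) {
  geo <- pks_domain_geometry()
  Map(function(kind, g) {
    spacing <- list()
    if (length(g$anchors) > 1L) {
      d <- g$a2_offset
      spacing <- list(c(max(1L, floor(d * (1 - slack))),
                        ceiling(d * (1 + slack))))
    }
    domain_model(kind = kind, anchors = g$anchors, spacing = spacing,
                 windows = g$windows, tail = g$tail)
  }, names(geo), geo)
}
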