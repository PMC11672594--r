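#' Construct a tailoring step
#'
#' A tailoring step is a named chemical edit with a signed element-count
#' delta: dehydration is -H2O, epoxidation +O, glycosylation adds the sugar
#' residue net of the condensation water. Deltas commute, so the total
#' formula is order-independent; site validation is not (an epoxidation
#' needs a double bond present at its site after the prior steps).
#'
#' @param kind `"dehydration"`, `"epoxidation"` or `"glycosylation"`.
#' @param site carbon number(s) the step acts on.
#' @param delta signed named numeric of element-count changes; defaults to
#'   the canonical delta for `kind` (glycosylation has no universal default
#'   and must be given explicitly).
#' @return list of class `pk_tailoring_step`.
#' @export
tailoring_step <- function(kind, site, delta = NULL) {
  kind <- match.arg(kind, c("dehydration", "epoxidation", "glycosylation"))
  if (is.null(delta)) {
    delta <- switch(kind,
                    dehydration = c(H = -2, O = -1),
                    epoxidation = c(O = 1),
                    stop("glycosylation needs an explicit formula delta"))
  }
  stopifnot(is.numeric(delta), !is.null(names(delta)))
  structure(list(kind = kind, site = site, delta = delta),
            class = "pk_tailoring_step")
}

#' The packaged tailoring steps of the irumamycin pipeline
#'
#' Dehydration of the C23 hydroxyl, epoxidation of the resulting C23-C24
#' double bond, and glycosylation at C25 with the carbamoylated deoxyhexose
#' residue (C7H11NO5 net of the condensation water; the residue delta is
#' data validated against the adduct back-calculation, not hard-coded
#' chemistry).
#'
#' @return list of [tailoring_step()]s.
#' @export
iru_tailoring_steps <- function() {
  list(
    tailoring_step("dehydration", site = 23),
    tailoring_step("epoxidation", site = c(23, 24)),
    tailoring_step("glycosylation", site = 25,
                   delta = c(C = 7, H = 11, N = 1, O = 5)))
}

#' Apply tailoring steps and return the product molecular formula
#'
#' Validates each step against the backbone state (dehydration and
#' glycosylation need a hydroxyl at the site; epoxidation needs a double
#' bond at the site, either from the assembly line or from a prior
#' dehydration), then sums the formula deltas onto the aglycone formula.
#'
#' @param backbone a closed `pk_backbone` (see [close_rings()]).
#' @param steps list of [tailoring_step()]s.
#' @return the product `pk_formula`.
#' @export
apply_tailoring <- function(backbone, steps) {
  carbons <- backbone_carbons(backbone)
  # oxygen/bond state per chain carbon, as far as tailoring needs it
  hydroxyl_at <- integer(0)
  bond_at <- list()
  for (u in seq_len(nrow(backbone$units))) {
    bc <- beta_carbon(backbone, u)
    st <- backbone$units$beta_state[u]
    if (st == "hydroxyl") hydroxyl_at <- c(hydroxyl_at, bc)
    if (st == "enoyl") bond_at[[length(bond_at) + 1L]] <- c(bc - 1L, bc)
    if (st == "shifted_enoyl") bond_at[[length(bond_at) + 1L]] <- c(bc - 1L, bc)
  }
  if (!is.null(backbone$lactone_ring)) {
    lact <- length(backbone$lactone_ring) - 1L
    hydroxyl_at <- setdiff(hydroxyl_at, lact)
  }
  if (!is.null(backbone$hemiketal)) {
    hydroxyl_at <- setdiff(hydroxyl_at, backbone$hemiketal$hydroxyl_carbon)
  }
  total <- backbone_formula(backbone)
  for (s in steps) {
    if (!all(s$site <= carbons$chain)) {
      stop("tailoring step '", s$kind, "' references carbon(s) beyond the chain")
    }
    if (s$kind == "dehydration") {
      if (!s$site[1] %in% hydroxyl_at) {
        stop("dehydration at C", s$site[1], ": no hydroxyl there")
      }
      hydroxyl_at <- setdiff(hydroxyl_at, s$site[1])
      bond_at[[length(bond_at) + 1L]] <- sort(c(s$site[1], s$site[1] + 1L))
    } else if (s$kind == "epoxidation") {
      want <- sort(s$site)
      have <- any(vapply(bond_at, function(b) all(b == want), logical(1)))
      if (!have) {
        stop("epoxidation at C", want[1], "-C", want[2],
             ": no double bond at that site after prior steps")
      }
      bond_at <- Filter(function(b) !all(b == want), bond_at)
    } else if (s$kind == "glycosylation") {
      if (!s$site[1] %in% hydroxyl_at) {
        stop("glycosylation at C", s$site[1], ": no hydroxyl there")
      }
    }
    total <- .apply_delta(total, s$delta)
  }
  total
}

.apply_delta <- function(formula, delta) {
  v <- unclass(formula)
  all_sym <- union(names(v), names(delta))
  out <- stats::setNames(numeric(length(all_sym)), all_sym)
  out[names(v)] <- out[names(v)] + v
  out[names(delta)] <- out[names(delta)] + delta
  if (any(out < 0)) stop("tailoring delta drives an element count negative")
  do.call(pk_formula, as.list(out))
}
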