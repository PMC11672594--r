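#' Monoisotopic mass of a molecular formula
#'
#' Sums per-isotope monoisotopic masses; oxygen atoms in the labeled slot
#' (`O18`) use the heavy-oxygen mass.
#'
#' @param formula a `pk_formula` or formula string.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))   # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "pk_formula"))
  masses <- pk_isotope_masses()
  sum(unclass(formula) * masses[names(formula)])
}

#' Supported singly charged adduct specifications
#'
#' Mass deltas are the monoisotopic masses of the adduct group minus one
#' electron (proton convention 1.00728 Da), applied consistently across all
#' adducts.
#'
#' @return data.frame with `name`, `mass_delta`, `charge`.
#' @export
adduct_specs <- function() {
  m <- pk_isotope_masses()
  e <- .pk_electron_mass
  data.frame(
    name = c("[M+H]+", "[M+NH4]+", "[M+Na]+"),
    mass_delta = c(m[["H"]] - e,
                   m[["N"]] + 4 * m[["H"]] - e,
                   m[["Na"]] - e),
    charge = 1L, stringsAsFactors = FALSE)
}

#' m/z of a singly charged adduct
#'
#' @param formula neutral `pk_formula` (may carry labeled-oxygen slots).
#' @param adduct adduct name, one of `adduct_specs()$name`.
#' @return m/z value.
#' @export
adduct_mz <- function(formula, adduct) {
  specs <- adduct_specs()
  i <- match(adduct, specs$name)
  if (is.na(i)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(specs$name, collapse = ", "))
  }
  (monoisotopic_mass(formula) + specs$mass_delta[i]) / specs$charge[i]
}

#' Heavy-oxygen exchange isotopologue pattern
#'
#' With `k` exchangeable oxygen positions and solvent enrichment `p`, the
#' abundance of the j-heavy-atom isotopologue is binomial,
#' `choose(k, j) p^j (1-p)^(k-j)`; consecutive entries are spaced by the
#' 18O-16O mass difference (2.0042 Da) on the chosen adduct.
#'
#' @param formula unlabeled neutral `pk_formula`.
#' @param k number of exchangeable oxygen slots (`0 <= k <=` oxygen count).
#' @param p heavy-water enrichment fraction in `[0, 1]`.
#' @param adduct adduct on which the m/z ladder is reported.
#' @return object of class `pk_isotopologue_pattern`: data.frame with
#'   `heavy_atoms`, `mz`, `abundance`; attributes `p`, `k`, `adduct`.
#' @export
exchange_pattern <- function(formula, k, p, adduct = "[M+NH4]+") {
  if (p < 0 || p > 1) stop("enrichment p must be in [0, 1]")
  if (k < 0 || k > element_count(formula, "O")) {
    stop("k must be between 0 and the oxygen count of the formula")
  }
  masses <- pk_isotope_masses()
  shift <- masses[["O18"]] - masses[["O"]]
  base <- adduct_mz(formula, adduct)
  j <- 0:k
  out <- data.frame(heavy_atoms = j,
                    mz = base + j * shift,
                    abundance = stats::dbinom(j, size = k, prob = p))
  structure(out, p = p, k = k, adduct = adduct,
            class = c("pk_isotopologue_pattern", "data.frame"))
}

#' Match a predicted isotopologue pattern against an observed peak list
#'
#' Greedy nearest-m/z matching within `tolerance`: predicted entries are
#' taken in abundance order and paired to the closest unused observed peak.
#'
#' @param predicted a `pk_isotopologue_pattern`.
#' @param observed data.frame with columns `mz` and `intensity`.
#' @param tolerance match tolerance in Da (default 0.05, the package-wide
#'   comparison default for two-decimal printed values).
#' @return list with `matches` (data.frame of predicted m/z, observed m/z,
#'   delta, predicted and observed relative abundance, ratio deviation),
#'   `unmatched_predicted`, `unmatched_observed`.
#' @export
compare_peaklists <- function(predicted, observed, tolerance = 0.05) {
  if (is.null(observed) || nrow(observed) == 0L) {
    stop("observed peak list is empty")
  }
  stopifnot(all(c("mz", "intensity") %in% names(observed)))
  obs_rel <- observed$intensity / sum(observed$intensity)
  used <- logical(nrow(observed))
  ord <- order(predicted$abundance, decreasing = TRUE)
  rows <- list()
  unmatched_pred <- integer(0)
  for (i in ord) {
    d <- abs(observed$mz - predicted$mz[i])
    d[used] <- Inf
    jbest <- which.min(d)
    if (is.finite(d[jbest]) && d[jbest] <= tolerance) {
      used[jbest] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        predicted_mz = predicted$mz[i], observed_mz = observed$mz[jbest],
        delta_mz = observed$mz[jbest] - predicted$mz[i],
        predicted_abundance = predicted$abundance[i],
        observed_abundance = obs_rel[jbest],
        abundance_deviation = obs_rel[jbest] - predicted$abundance[i])
    } else {
      unmatched_pred <- c(unmatched_pred, i)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(predicted_mz = numeric(0), observed_mz = numeric(0),
               delta_mz = numeric(0), predicted_abundance = numeric(0),
               observed_abundance = numeric(0),
               abundance_deviation = numeric(0))
  matches <- matches[order(matches$predicted_mz), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_predicted = predicted[sort(unmatched_pred), , drop = FALSE],
       unmatched_observed = observed[!used, , drop = FALSE])
}
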