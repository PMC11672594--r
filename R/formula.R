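#' Molecular formula objects
#'
#' A `pk_formula` is a named integer vector of element (and isotope-slot)
#' counts. Besides the plain element symbols, the special symbol `O18`
#' counts oxygen atoms carried as the heavy isotope (one slot per
#' exchange-labeled position); the invariant `O18 <= O18 + O` is trivially
#' kept by storing labeled and common oxygen in separate slots.
#'
#' @param ... element counts, e.g. `pk_formula(C = 41, H = 65, N = 1, O = 12)`.
#' @return an object of class `pk_formula`.
#' @examples
#' f <- pk_formula(C = 2, H = 6, O = 1)
#' format(f)
#' @export
pk_formula <- function(...) {
  counts <- c(...)
  if (length(counts) == 0L) counts <- integer(0)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all formula components must be named element symbols")
  }
  bad <- setdiff(names(counts), names(pk_isotope_masses()))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  counts <- vapply(split(counts, names(counts)), sum, numeric(1))
  if (any(counts < 0)) stop("element counts must be non-negative")
  counts <- counts[counts != 0]
  counts <- counts[order(names(counts))]
  structure(as.double(counts), names = names(counts), class = "pk_formula")
}

#' Monoisotopic masses of the supported elements and isotope slots
#'
#' Values in Da (u). `O18` is the heavy-oxygen slot used for exchange
#' labeling; `e` is not listed here (the electron mass enters only through
#' adduct deltas, see [adduct_specs()]).
#'
#' @return named numeric vector of monoisotopic masses.
#' @export
pk_isotope_masses <- function() {
  c(C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    O18 = 17.9991610,
    S = 31.97207100,
    P = 30.97376163,
    Na = 22.9897692809)
}

.pk_electron_mass <- 0.00054857990

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings such as `"C41H65NO12"`. A trailing
#' `[18O]j`-style slot is written as `O18` (e.g. `"C2H6O18"` is ambiguous
#' and therefore not supported in string form; build labeled formulas with
#' [set_labeled_oxygen()] instead).
#'
#' @param x a single formula string.
#' @return a `pk_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts) || sum(nchar(parts)) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  sym <- sub("[0-9]*$", "", parts)
  n <- as.integer(sub("^[A-Za-z]+", "", paste0(parts, "")))
  n[is.na(n)] <- 1L
  do.call(pk_formula, as.list(stats::setNames(n, sym)))
}

#' @export
format.pk_formula <- function(x, ...) {
  counts <- unclass(x)
  o18 <- if ("O18" %in% names(counts)) counts[["O18"]] else 0
  counts <- counts[setdiff(names(counts), "O18")]
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  body <- paste0(vapply(hill, function(s) {
    n <- counts[[s]]
    if (n == 1) s else paste0(s, n)
  }, character(1)), collapse = "")
  if (o18 > 0) body <- paste0(body, "[18O]", if (o18 > 1) o18 else "")
  body
}

#' @export
print.pk_formula <- function(x, ...) {
  cat("<pk_formula> ", format(x), "  (monoisotopic ",
      sprintf("%.4f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
"+.pk_formula" <- function(e1, e2) {
  stopifnot(inherits(e1, "pk_formula"), inherits(e2, "pk_formula"))
  all_sym <- union(names(e1), names(e2))
  v <- stats::setNames(numeric(length(all_sym)), all_sym)
  v[names(e1)] <- v[names(e1)] + unclass(e1)
  v[names(e2)] <- v[names(e2)] + unclass(e2)
  do.call(pk_formula, as.list(v))
}

#' @export
"-.pk_formula" <- function(e1, e2) {
  stopifnot(inherits(e1, "pk_formula"), inherits(e2, "pk_formula"))
  all_sym <- union(names(e1), names(e2))
  v <- stats::setNames(numeric(length(all_sym)), all_sym)
  v[names(e1)] <- v[names(e1)] + unclass(e1)
  v[names(e2)] <- v[names(e2)] - unclass(e2)
  if (any(v < 0)) stop("subtraction would give a negative element count")
  do.call(pk_formula, as.list(v))
}

#' Mark oxygen atoms as exchange-labeled heavy oxygen
#'
#' Moves `k` atoms from the common-oxygen slot to the heavy (18O) slot.
#'
#' @param formula a `pk_formula`.
#' @param k number of labeled oxygens.
#' @return the labeled `pk_formula`.
#' @export
set_labeled_oxygen <- function(formula, k = 1L) {
  stopifnot(inherits(formula, "pk_formula"), k >= 0)
  v <- as.list(unclass(formula))
  o <- v$O %||% 0
  if (k > o) stop("cannot label ", k, " oxygens; formula has only ", o)
  v$O <- o - k
  v$O18 <- (v$O18 %||% 0) + k
  do.call(pk_formula, v)
}

#' Count an element in a formula
#' @param formula a `pk_formula`.
#' @param element element symbol; `"O"` counts common plus labeled oxygen.
#' @return integer count.
#' @export
element_count <- function(formula, element) {
  v <- unclass(formula)
  n <- if (element %in% names(v)) v[[element]] else 0
  if (element == "O" && "O18" %in% names(v)) n <- n + v[["O18"]]
  unname(n)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
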