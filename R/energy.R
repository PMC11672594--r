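#' Assemble a reaction free-energy profile from stage values
#'
#' States are a connected chain starting at the reactant `R` (0 kcal/mol by
#' convention); each stage carries the free-energy change between
#' consecutive minima, and transition states are stored as barrier heights
#' relative to their preceding minimum (the reference convention is
#' recorded in the object; the printed barriers do not state their
#' reference explicitly).
#'
#' @param stages data.frame with columns `from`, `to`, `delta_g` and
#'   optionally `barrier` (TS height above the `from` minimum, NA if none)
#'   and `ts_label`.
#' @param path_id identifier for the pathway.
#' @return object of class `pk_reaction_path` with cumulative state
#'   energies, stage deltas and barriers.
#' @export
build_profile <- function(stages, path_id = NA) {
  if (is.null(stages) || nrow(stages) == 0L) {
    states <- data.frame(label = "R", delta_g = 0, kind = "minimum",
                         stringsAsFactors = FALSE)
    return(structure(list(path_id = path_id, states = states,
                          stage_deltas = stages, overall = 0,
                          barriers = data.frame(),
                          ts_reference = "preceding_minimum"),
                     class = "pk_reaction_path"))
  }
  stopifnot(all(c("from", "to", "delta_g") %in% names(stages)))
  if (stages$from[1] != "R") stop("the chain must start at state 'R'")
  for (i in seq_len(nrow(stages) - 1L)) {
    if (stages$to[i] != stages$from[i + 1L]) {
      stop("disconnected chain: stage ", i, " ends at '", stages$to[i],
           "' but stage ", i + 1L, " starts at '", stages$from[i + 1L], "'")
    }
  }
  cum <- cumsum(stages$delta_g)
  states <- data.frame(label = c("R", stages$to),
                       delta_g = c(0, cum),
                       kind = "minimum", stringsAsFactors = FALSE)
  barriers <- data.frame()
  if ("barrier" %in% names(stages)) {
    has <- which(!is.na(stages$barrier))
    if (length(has)) {
      if (any(stages$barrier[has] < 0)) {
        stop("barriers must be non-negative relative to the preceding minimum")
      }
      barriers <- data.frame(
        ts_label = if ("ts_label" %in% names(stages)) stages$ts_label[has]
                   else paste0("TS", seq_along(has)),
        between = paste(stages$from[has], stages$to[has], sep = "->"),
        barrier = stages$barrier[has],
        absolute_vs_R = c(0, cum)[has] + stages$barrier[has],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(path_id = path_id, states = states, stage_deltas = stages,
                 overall = cum[length(cum)], barriers = barriers,
                 ts_reference = "preceding_minimum"),
            class = "pk_reaction_path")
}

#' Solve one unknown stage from the printed overall free-energy change
#'
#' Telescoping: the sum of the stage deltas over minima equals
#' `delta_g(P) - delta_g(R)`, so one missing stage is
#' `overall - sum(known)`.
#'
#' @param known_deltas numeric vector of the known stage deltas (kcal/mol).
#' @param overall the printed overall delta G (P - R), kcal/mol.
#' @return the missing stage delta, kcal/mol.
#' @export
solve_stage <- function(known_deltas, overall) {
  overall - sum(known_deltas)
}

#' Rank reaction pathways by their highest activation barrier
#'
#' @param paths list of `pk_reaction_path` objects.
#' @return list with `ranking` (data.frame: path_id, highest barrier and
#'   its label, rank; ties share a rank and are flagged), `excluded`
#'   (paths without transition states, with a notice).
#' @export
compare_barriers <- function(paths) {
  has_ts <- vapply(paths, function(p) nrow(p$barriers) > 0L, logical(1))
  excluded <- character(0)
  for (p in paths[!has_ts]) {
    excluded <- c(excluded, paste0("path ", p$path_id,
                                   " has no transition states; excluded"))
  }
  paths <- paths[has_ts]
  if (!length(paths)) return(list(ranking = data.frame(), excluded = excluded))
  rows <- lapply(paths, function(p) {
    i <- which.max(p$barriers$barrier)
    data.frame(path_id = p$path_id,
               highest_barrier = p$barriers$barrier[i],
               ts_label = p$barriers$ts_label[i],
               stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$highest_barrier), , drop = FALSE]
  ranking$rank <- rank(ranking$highest_barrier, ties.method = "min")
  ranking$tie <- duplicated(ranking$highest_barrier) |
    duplicated(ranking$highest_barrier, fromLast = TRUE)
  rownames(ranking) <- NULL
  list(ranking = ranking, excluded = excluded)
}

#' Check a profile's telescoped overall value against a printed value
#'
#' @param path a `pk_reaction_path`.
#' @param printed_overall printed overall delta G (kcal/mol).
#' @param tolerance non-negative tolerance (kcal/mol).
#' @return list with `consistent` (logical), `computed`, `printed`,
#'   `difference`.
#' @export
check_consistency <- function(path, printed_overall, tolerance) {
  stopifnot(tolerance >= 0)
  diff <- abs(path$overall - printed_overall)
  list(consistent = diff <= tolerance, computed = path$overall,
       printed = printed_overall, difference = diff)
}

#' Load a packaged hemiketal-mechanism free-energy profile
#'
#' Two fixtures ship with the package: path 1 (PKS-assisted olefin shift,
#' then cyclization) and path 2 (triene electrocyclization, then water
#' addition). Stage values are the printed ones; path 2's final stage is
#' not printed and is solved from the printed overall (-4.2 kcal/mol) by
#' telescoping — it is marked `derived` in the fixture file.
#'
#' @param path 1 or 2.
#' @return a `pk_reaction_path`.
#' @export
energy_profile <- function(path = 1) {
  stopifnot(path %in% c(1, 2))
  file <- system.file("extdata", paste0("energy_path", path, ".tsv"),
                      package = "pksdecode", mustWork = TRUE)
  stages <- utils::read.delim(file, comment.char = "#",
                              stringsAsFactors = FALSE)
  build_profile(stages, path_id = path)
}

#' @export
print.pk_reaction_path <- function(x, ...) {
  cat("<pk_reaction_path> path ", x$path_id, ": ",
      paste(x$states$label, collapse = " -> "),
      "  overall ", sprintf("%.2f", x$overall), " kcal/mol\n", sep = "")
  if (nrow(x$barriers)) {
    for (i in seq_len(nrow(x$barriers))) {
      cat(sprintf("  %s (%s): %.1f kcal/mol above preceding minimum\n",
                  x$barriers$ts_label[i], x$barriers$between[i],
                  x$barriers$barrier[i]))
    }
  }
  invisible(x)
}
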