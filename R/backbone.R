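#' Execute the module logic and predict the polyketide backbone
#'
#' One ketide unit is emitted per elongation: every extension module
#' contributes its `iteration_count` elongations (stuttering modules more
#' than one). Extender choice honors `ks_gatekeeper_override` and
#' `at_borrowed_from`; the loading module's KSQ decarboxylates its extender
#' into the starter (methylmalonyl gives propionyl, malonyl gives acetyl).
#' Beta-carbon processing: no/absent KR leaves a ketone; an active KR gives
#' a hydroxyl with stereo label A or B from the KR stereotype; an active DH
#' on top dehydrates to an enoyl (E from B-type, Z from A-type); ER reduces
#' to methylene; a module flagged `olefin_shift` emits a shifted
#' (beta,gamma) cis enoyl instead.
#'
#' Both mechanistic options for the shifted double bond produce the same
#' final connectivity; they differ only in the recorded intermediates
#' (path 1: PKS-assisted olefin shift on the assembly line; path 2:
#' triene 6-pi-electrocyclization followed by water addition).
#'
#' @param modules list of `pk_module_spec` from [build_modules()].
#' @param options list; `olefin_shift_path` is 1 (default) or 2.
#' @return object of class `pk_backbone`.
#' @export
extend_chain <- function(modules, options = list(olefin_shift_path = 1)) {
  path <- options$olefin_shift_path %||rnull% 1
  if (!path %in% c(1, 2)) stop("olefin_shift_path must be 1 or 2")
  is_loading <- vapply(modules, function(m) identical(m$ks, "loading"),
                       logical(1))
  lm <- if (any(is_loading)) modules[[which(is_loading)[1]]] else NULL
  ext <- modules[!is_loading]
  starter <- if (is.null(lm)) {
    list(kind = "propionyl", carbons = 3L)
  } else {
    switch(lm$at,
           methylmalonyl = list(kind = "propionyl", carbons = 3L),
           malonyl = list(kind = "acetyl", carbons = 2L),
           list(kind = "other", carbons = 2L))
  }
  at_call_of <- function(label) {
    for (m in ext) if (identical(m$index, as.character(label))) return(m$at)
    stop("at_borrowed_from points to unknown module ", label)
  }
  units <- list()
  intermediates <- character(0)
  for (m in ext) {
    at <- m$at
    if (!is.na(m$flags$at_borrowed_from)) at <- at_call_of(m$flags$at_borrowed_from)
    if (!is.na(m$flags$ks_gatekeeper_override)) at <- m$flags$ks_gatekeeper_override
    if (identical(at, "inactive")) {
      stop("module ", m$index, " has no usable extender (inactive AT, ",
           "no borrowing source)")
    }
    alpha <- if (identical(at, "methylmalonyl")) "methyl" else "H"
    kr_active <- !identical(m$kr, "absent")
    dh_active <- identical(m$dh, "active")
    if (dh_active && !kr_active) {
      stop("module ", m$index, ": active DH atop absent/inactive KR ",
           "(nothing to dehydrate)")
    }
    stereo <- if (kr_active) {
      if (identical(m$kr, "A")) "A" else "B"
    } else "none"
    state <- "ketone"; geom <- "none"; lab <- "none"
    if (kr_active) { state <- "hydroxyl"; lab <- stereo }
    if (dh_active) {
      state <- "enoyl"
      geom <- if (stereo == "A") "Z" else "E"
      lab <- "none"
    }
    if (m$er) {
      if (!dh_active) stop("module ", m$index, ": ER without an active DH")
      state <- "methylene"; geom <- "none"
    }
    if (m$flags$olefin_shift) {
      state <- "shifted_enoyl"; geom <- "Z"; lab <- "none"
      if (path == 1) {
        intermediates <- c(intermediates, paste0(
          "module ", m$index, ": alpha,beta-enoyl formed on the carrier ",
          "protein, then PKS-assisted double-bond shift to the beta,gamma ",
          "(cis) position before the next transfer"))
      } else {
        intermediates <- c(intermediates, paste0(
          "module ", m$index, ": all-dehydrated triene precursor, ",
          "6-pi-electrocyclization of the cis-triene, then water addition ",
          "at the ring carbon restores the exchangeable hydroxyl"))
      }
    }
    reps <- max(1L, as.integer(m$flags$iteration_count))
    for (r in seq_len(reps)) {
      units[[length(units) + 1L]] <- list(
        unit_index = length(units) + 1L,
        source_module = m$index,
        alpha_substituent = alpha,
        beta_state = state,
        stereo_label = lab,
        geometry = geom)
    }
  }
  units_df <- do.call(rbind, lapply(units, function(u)
    as.data.frame(u, stringsAsFactors = FALSE)))
  backbone <- structure(list(
    starter = starter,
    units = units_df,
    path = path,
    mechanism = if (path == 1) "pks_olefin_shift" else
      "electrocyclization_water_addition",
    intermediates = intermediates,
    lactone_ring = NULL,
    hemiketal_ring = NULL,
    exchangeable_oxygens = 0L), class = "pk_backbone")
  backbone$carbon_numbering <- .number_carbons(backbone)
  backbone
}

# Macrolide numbering: C1 is the (eventual) lactone carbonyl carbon laid
# down by the last elongation; the chain is numbered to the starter's
# terminal methyl; methyl branches get numbers past the chain, ordered by
# attachment carbon.
.number_carbons <- function(backbone) {
  n_units <- nrow(backbone$units)
  rows <- list()
  for (u in seq_len(n_units)) {
    base <- 2L * (n_units - u)
    rows[[length(rows) + 1L]] <- data.frame(
      carbon = c(base + 1L, base + 2L),
      role = c("carbonyl", "alpha"),
      unit = u, stringsAsFactors = FALSE)
  }
  chain <- 2L * n_units
  for (k in seq_len(backbone$starter$carbons)) {
    rows[[length(rows) + 1L]] <- data.frame(
      carbon = chain + k, role = if (k == 1L) "starter_carbonyl" else "starter",
      unit = NA_integer_, stringsAsFactors = FALSE)
  }
  total_chain <- chain + backbone$starter$carbons
  df <- do.call(rbind, rows)
  methyl_attach <- sort(df$carbon[df$role == "alpha"][
    backbone$units$alpha_substituent[df$unit[df$role == "alpha"]] == "methyl"])
  if (length(methyl_attach)) {
    df <- rbind(df, data.frame(
      carbon = total_chain + seq_along(methyl_attach),
      role = paste0("methyl@C", methyl_attach),
      unit = NA_integer_, stringsAsFactors = FALSE))
  }
  df[order(df$carbon), , drop = FALSE]
}

#' Beta-carbon chain position of a ketide unit
#'
#' The beta carbon of unit `u` is the carbonyl carbon laid down by the
#' previous unit (or the starter), i.e. chain carbon `2 * (n - u) + 3` for
#' `n` units.
#' @param backbone a `pk_backbone`.
#' @param unit unit index (1-based from the starter end).
#' @return integer carbon number.
#' @export
beta_carbon <- function(backbone, unit) {
  2L * (nrow(backbone$units) - unit) + 3L
}

.unit_at_beta <- function(backbone, carbon) {
  n <- nrow(backbone$units)
  u <- n - (carbon - 3L) / 2L
  if (u != round(u) || u < 1L || u > n) return(NA_integer_)
  as.integer(u)
}

#' Total chain and branch carbon counts of a backbone
#' @param backbone a `pk_backbone`.
#' @return list with `chain`, `methyl`, `total`.
#' @export
backbone_carbons <- function(backbone) {
  chain <- backbone$starter$carbons + 2L * nrow(backbone$units)
  methyl <- sum(backbone$units$alpha_substituent == "methyl")
  list(chain = chain, methyl = methyl, total = chain + methyl)
}

#' Close the macrolactone (and optionally the hemiketal ring)
#'
#' The thioesterase closes the macrolactone between the C1 carboxyl and the
#' hydroxyl at `lactone_oxygen_carbon`; the ring atom list counts all cycle
#' atoms including the ester oxygen. When a hemiketal is requested, the
#' beta-ketone at `ketone_carbon` condenses with the hydroxyl at
#' `hydroxyl_carbon` into a cyclic hemiketal whose carbon bears one
#' exchangeable hydroxyl — recorded as the labeled-oxygen slot.
#'
#' @param backbone a `pk_backbone`.
#' @param lactone_oxygen_carbon chain carbon bearing the lactone hydroxyl.
#' @param hemiketal `NULL`, or `list(ketone_carbon =, hydroxyl_carbon =)`.
#' @return the backbone with `lactone_ring`, `hemiketal_ring`,
#'   `exchangeable_oxygens` populated.
#' @export
close_rings <- function(backbone, lactone_oxygen_carbon, hemiketal = NULL) {
  carbons <- backbone_carbons(backbone)
  if (lactone_oxygen_carbon > carbons$chain) {
    stop("lactone carbon C", lactone_oxygen_carbon, " does not exist")
  }
  u <- .unit_at_beta(backbone, lactone_oxygen_carbon)
  if (is.na(u) || backbone$units$beta_state[u] != "hydroxyl") {
    stop("carbon C", lactone_oxygen_carbon, " does not bear a hydroxyl; ",
         "cannot form the lactone there")
  }
  backbone$lactone_ring <- c(paste0("C", seq_len(lactone_oxygen_carbon)), "O")
  if (!is.null(hemiketal)) {
    ku <- .unit_at_beta(backbone, hemiketal$ketone_carbon)
    hu <- .unit_at_beta(backbone, hemiketal$hydroxyl_carbon)
    if (is.na(ku) || backbone$units$beta_state[ku] != "ketone") {
      stop("carbon C", hemiketal$ketone_carbon, " is not a beta-ketone")
    }
    if (is.na(hu) || backbone$units$beta_state[hu] != "hydroxyl") {
      stop("carbon C", hemiketal$hydroxyl_carbon, " does not bear a hydroxyl")
    }
    lo <- min(hemiketal$ketone_carbon, hemiketal$hydroxyl_carbon)
    hi <- max(hemiketal$ketone_carbon, hemiketal$hydroxyl_carbon)
    backbone$hemiketal_ring <- c(paste0("C", lo:hi), "O")
    # the former ketone carbon now bears the readily exchangeable hydroxyl
    backbone$exchangeable_oxygens <- 1L
    backbone$hemiketal <- list(ketone_carbon = hemiketal$ketone_carbon,
                               hydroxyl_carbon = hemiketal$hydroxyl_carbon)
  }
  backbone
}

#' Ring size of a closed ring
#' @param ring ring atom vector from a `pk_backbone`.
#' @return number of cycle atoms (including ring oxygens).
#' @export
ring_size <- function(ring) length(ring)

#' Molecular formula of the (closed or open) backbone
#'
#' Element bookkeeping relative to the fully saturated fatty acid
#' CnH2nO2: a beta-ketone is +O -2H, a beta-hydroxyl +O, an enoyl (shifted
#' or not) -2H, a methylene unchanged. Macrolactonization removes one
#' water; hemiketal closure is formula-neutral.
#'
#' @param backbone a `pk_backbone`.
#' @return a `pk_formula` (aglycone before tailoring).
#' @export
backbone_formula <- function(backbone) {
  carbons <- backbone_carbons(backbone)
  C <- carbons$total
  H <- 2L * C
  O <- 2L
  for (i in seq_len(nrow(backbone$units))) {
    st <- backbone$units$beta_state[i]
    if (st == "ketone") { O <- O + 1L; H <- H - 2L }
    else if (st == "hydroxyl") O <- O + 1L
    else if (st %in% c("enoyl", "shifted_enoyl")) H <- H - 2L
  }
  if (!is.null(backbone$lactone_ring)) { H <- H - 2L; O <- O - 1L }
  pk_formula(C = C, H = H, O = O)
}

#' @export
print.pk_backbone <- function(x, ...) {
  carbons <- backbone_carbons(x)
  cat("<pk_backbone> ", nrow(x$units), " ketide units, ", x$starter$kind,
      " starter, C", carbons$chain, " chain + ", carbons$methyl,
      " methyl branches\n", sep = "")
  if (!is.null(x$lactone_ring)) {
    cat("  macrolactone: ", ring_size(x$lactone_ring), "-membered\n", sep = "")
  }
  if (!is.null(x$hemiketal_ring)) {
    cat("  hemiketal ring: ", ring_size(x$hemiketal_ring), "-membered, ",
        x$exchangeable_oxygens, " exchangeable oxygen slot(s)\n", sep = "")
  }
  cat("  mechanism: ", x$mechanism, "\n", sep = "")
  invisible(x)
}
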