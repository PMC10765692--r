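# Annual carbon dynamics: volume/carbon conversion, yield-curve growth,
# live-pool turnover and first-order DOM decay.

#' Convert merchantable volume to live-pool carbon
#'
#' Merchantable stem carbon is volume times the species-class carbon density;
#' the remaining live pools (other wood, foliage, coarse and fine roots) are
#' fixed component ratios of the stem carbon. The map is linear in volume and
#' therefore invertible (see [carbon_to_volume()]).
#'
#' @param volume numeric vector, merchantable volume (m3/ha, under bark).
#' @param forest_type character vector (recycled) of forest type codes.
#' @param params an [default_params()] object.
#' @return tibble with one row per input and the five live pool columns
#'   (t C/ha).
#' @export
#' @examples
#' volume_to_carbon(100, "SP", default_params())
volume_to_carbon <- function(volume, forest_type, params = default_params()) {
  stopifnot(all(volume >= 0))
  check_forest_type(forest_type)
  n <- max(length(volume), length(forest_type))
  volume <- rep_len(volume, n)
  forest_type <- rep_len(forest_type, n)
  merch <- volume * density_of(forest_type, params)
  sw <- is_softwood(forest_type)
  rmat <- rbind(
    do.call(rbind, lapply(ifelse(sw, "softwood", "hardwood"),
                          function(s) params$ratios[[s]]))
  )
  tibble::tibble(
    merch_stem = merch,
    other_wood = merch * unname(rmat[, "other_wood"]),
    foliage = merch * unname(rmat[, "foliage"]),
    coarse_roots = merch * unname(rmat[, "coarse_roots"]),
    fine_roots = merch * unname(rmat[, "fine_roots"])
  )
}

#' Invert stem carbon back to merchantable volume
#'
#' @param merch_stem numeric vector, merchantable stem carbon (t C/ha).
#' @inheritParams volume_to_carbon
#' @return numeric vector of merchantable volume (m3/ha).
#' @export
carbon_to_volume <- function(merch_stem, forest_type, params = default_params()) {
  check_forest_type(forest_type)
  merch_stem / density_of(forest_type, params)
}

check_forest_type <- function(forest_type) {
  bad <- setdiff(unique(forest_type), FOREST_TYPES)
  if (length(bad) > 0) {
    stop("unknown forest_type code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(forest_type)
}

# ---- yield curves -----------------------------------------------------------

#' Validate a yield curve table
#'
#' A yield curve gives merchantable volume (m3/ha under bark) against stand
#' age for one forest type. Curves must start at zero volume and be
#' non-decreasing; ages between grid points are linearly interpolated and
#' ages beyond the grid sit on the plateau (last value held).
#'
#' @param curves data frame with columns `forest_type`, `age`, `volume_m3ha`.
#' @return the validated curves as a tibble, invisibly usable downstream.
#' @export
validate_yield_curves <- function(curves) {
  stopifnot(all(c("forest_type", "age", "volume_m3ha") %in% names(curves)))
  curves <- dplyr::arrange(tibble::as_tibble(curves), .data$forest_type, .data$age)
  chk <- curves |>
    dplyr::group_by(.data$forest_type) |>
    dplyr::summarise(
      zero_start = .data$age[1] == 0 && .data$volume_m3ha[1] == 0,
      monotone = !is.unsorted(.data$volume_m3ha),
      .groups = "drop"
    )
  if (!all(chk$zero_start)) {
    stop("yield curve must have volume 0 at age 0 for: ",
         paste(chk$forest_type[!chk$zero_start], collapse = ", "), call. = FALSE)
  }
  if (!all(chk$monotone)) {
    stop("yield curve has a decreasing segment for: ",
         paste(chk$forest_type[!chk$monotone], collapse = ", "), call. = FALSE)
  }
  curves
}

#' Evaluate yield curves at given ages
#'
#' @param curves validated yield curve table.
#' @param forest_type character vector of types.
#' @param age numeric vector of ages (years), recycled against `forest_type`.
#' @return numeric vector of merchantable volumes (m3/ha). Types without a
#'   curve (e.g. `CLEARCUT`, `SPx`) evaluate to 0.
#' @export
yield_volume <- function(curves, forest_type, age) {
  n <- max(length(forest_type), length(age))
  forest_type <- rep_len(forest_type, n)
  age <- rep_len(age, n)
  out <- numeric(n)
  for (ft in unique(forest_type)) {
    idx <- forest_type == ft
    cc <- curves[curves$forest_type == ft, ]
    if (nrow(cc) == 0) next
    out[idx] <- stats::approx(cc$age, cc$volume_m3ha, xout = pmin(age[idx], max(cc$age)),
                              rule = 2, ties = "ordered")$y
  }
  out
}

# annual volume increment curve(age+1) - curve(age)
yield_increment <- function(curves, forest_type, age) {
  yield_volume(curves, forest_type, age + 1) - yield_volume(curves, forest_type, age)
}

# ---- annual processes (vectorized over cohort rows) -------------------------

#' Grow cohorts by one year
#'
#' Increments each cohort's age by one and adds the merchantable stem carbon
#' of the yield-curve volume increment between the old and new age. The
#' non-merchantable live components (other wood, foliage, roots) are grown
#' back up to their allometric proportion of the new stem carbon, so annual
#' production both extends the stem and replaces component turnover losses
#' (growth never removes carbon: components above their proportion are left
#' alone). DOM pools are untouched. Cohorts without a curve (clearcut, snag
#' stands) only age.
#'
#' @param state cohort tibble (see [load_inventory()]).
#' @param curves yield curve table.
#' @param params dynamics parameters.
#' @return the grown state.
#' @export
grow_annual <- function(state, curves, params = default_params()) {
  curves <- validate_yield_curves(curves)
  dv <- yield_increment(curves, state$forest_type, state$age)
  merch_inc <- dv * density_of(state$forest_type, params)
  state$merch_stem <- state$merch_stem + merch_inc
  sw <- ifelse(is_softwood(state$forest_type), "softwood", "hardwood")
  for (p in setdiff(LIVE_POOLS, "merch_stem")) {
    r <- vapply(sw, function(s) params$ratios[[s]][[p]], numeric(1))
    state[[p]] <- pmax(state[[p]], r * state$merch_stem)
  }
  state$age <- state$age + 1
  state
}

#' Apply annual live-pool turnover
#'
#' Moves the turnover fraction of each live pool into its destination DOM
#' pool(s). Turnover conserves mass: no carbon reaches the atmosphere or
#' products here.
#'
#' @inheritParams grow_annual
#' @return the state after turnover.
#' @export
apply_turnover <- function(state, params = default_params()) {
  sw <- is_softwood(state$forest_type)
  cls <- ifelse(sw, "softwood", "hardwood")
  for (p in LIVE_POOLS) {
    t <- params$turnover[[p]]
    frac <- unname(t$frac[cls])
    moved <- state[[p]] * frac
    state[[p]] <- state[[p]] - moved
    for (d in names(t$dest)) {
      state[[d]] <- state[[d]] + moved * t$dest[[d]]
    }
  }
  state
}

#' Apply annual first-order DOM decay
#'
#' Each DOM pool loses `rate * stock`; the atmosphere fraction of the loss is
#' emitted and the remainder humifies into the downstream pool. The slow
#' pools are terminal (all decayed carbon emitted).
#'
#' @inheritParams grow_annual
#' @return list with `state` (decayed state) and `flux_tC` (total emitted
#'   carbon, t C, area-weighted over cohorts).
#' @export
decay_dom <- function(state, params = default_params()) {
  flux_ha <- numeric(nrow(state))
  new <- state
  for (p in DOM_POOLS) {
    d <- params$decay[[p]]
    loss <- state[[p]] * d$rate
    new[[p]] <- new[[p]] - loss
    flux_ha <- flux_ha + loss * d$atm
    if (d$atm < 1 && !is.na(d$down)) {
      new[[d$down]] <- new[[d$down]] + loss * (1 - d$atm)
    }
  }
  list(state = new, flux_tC = sum(flux_ha * state$area))
}

#' Net annual increment by forest type
#'
#' Area-weighted mean of the yield-curve volume increment at each cohort's
#' current age, per forest type. Types with zero total area (or no curve)
#' are omitted.
#'
#' @inheritParams grow_annual
#' @return tibble with `forest_type` and `nai_m3ha` (m3/ha/yr).
#' @export
compute_nai <- function(state, curves) {
  stopifnot(nrow(state) > 0)
  curves <- validate_yield_curves(curves)
  state |>
    dplyr::filter(.data$forest_type %in% unique(curves$forest_type),
                  .data$area > 0) |>
    dplyr::mutate(inc = yield_increment(curves, .data$forest_type, .data$age)) |>
    dplyr::group_by(.data$forest_type) |>
    dplyr::summarise(nai_m3ha = sum(.data$inc * .data$area) / sum(.data$area),
                     .groups = "drop")
}

# total ecosystem carbon of a state (t C)
total_carbon <- function(state) {
  if (nrow(state) == 0) return(0)
  sum(vapply(ALL_POOLS, function(p) sum(state[[p]] * state$area), numeric(1)))
}
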