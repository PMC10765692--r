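# Harvest-demand construction primitives: Gaussian calamity-pulse fitting,
# demand extrapolation, exponential share interpolation, and the sustainable
# logging potential.

#' Fit a Gaussian calamity pulse to an annual harvest series
#'
#' Nonlinear least-squares fit of `v(t) = A * exp(-(t - mu)^2 / (2 sigma^2))`
#' to a (year, volume) series, as used to describe the bell-shaped course of
#' calamity-driven harvest in each region. Initial values are fixed
#' (A = max, mu = argmax year, sigma = 2) so the fit is deterministic.
#'
#' @param series data frame with columns `year` and `volume` (at least 4
#'   points).
#' @return one-row tibble: `amplitude`, `peak_year`, `width`, `resid_norm`,
#'   `degenerate` (TRUE for an all-zero series, returned as a flagged
#'   zero-amplitude fit).
#' @export
#' @examples
#' yrs <- 2012:2021
#' fit_calamity_curve(data.frame(year = yrs,
#'   volume = 35 * exp(-(yrs - 2020)^2 / 8)))
fit_calamity_curve <- function(series) {
  stopifnot(all(c("year", "volume") %in% names(series)), nrow(series) >= 4)
  y <- series$volume
  t <- series$year
  if (all(y == 0)) {
    return(tibble::tibble(amplitude = 0, peak_year = mean(t), width = 2,
                          resid_norm = 0, degenerate = TRUE))
  }
  start <- list(A = max(y), mu = t[which.max(y)], sigma = 2)
  # the pulse peak must lie near the observation window, otherwise a series
  # still rising at its end is fitted as an implausibly distant Gaussian
  fit <- try(minpack.lm::nlsLM(
    volume ~ A * exp(-(year - mu)^2 / (2 * sigma^2)),
    data = series, start = start,
    lower = c(A = 0, mu = min(t) - 2, sigma = 0.5),
    upper = c(A = 2 * max(y), mu = max(t) + 2, sigma = 8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(tibble::tibble(amplitude = max(y), peak_year = t[which.max(y)],
                          width = 2, resid_norm = sqrt(sum((y - mean(y))^2)),
                          degenerate = TRUE))
  }
  cf <- stats::coef(fit)
  tibble::tibble(amplitude = unname(cf["A"]),
                 peak_year = unname(cf["mu"]),
                 width = abs(unname(cf["sigma"])),
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 degenerate = FALSE)
}

#' Fit calamity pulses for every region
#'
#' Sums an observed harvest table over the harvest disturbance types
#' (2, 3a, 3b, 4) per region and year and fits [fit_calamity_curve()] to
#' each regional total.
#'
#' @param observed observed harvest tibble: `year`, `region_id`,
#'   `forest_type`, `dist_id`, `volume_mm3`.
#' @return tibble with one row per region and the fit columns.
#' @export
fit_calamity_curves <- function(observed) {
  observed |>
    dplyr::filter(.data$dist_id %in% c("2", "3a", "3b", "4")) |>
    dplyr::group_by(.data$region_id, .data$year) |>
    dplyr::summarise(volume = sum(.data$volume_mm3), .groups = "drop") |>
    dplyr::group_by(.data$region_id) |>
    dplyr::group_modify(~ fit_calamity_curve(.x)) |>
    dplyr::ungroup()
}

#' Extrapolate regional harvest demand from fitted pulses
#'
#' Evaluates each region's fitted Gaussian pulse over the extrapolation
#' years, floored at the region's post-calamity sustainable level.
#'
#' @param fits tibble from [fit_calamity_curves()].
#' @param years years to extrapolate (default 2022:2030).
#' @param floor named numeric: per-region sustainable level (same volume
#'   units as the fit), or a single number recycled; default 0.
#' @return tibble `region_id`, `year`, `volume` (floored pulse value).
#' @export
extrapolate_demand <- function(fits, years = 2022:2030, floor = 0) {
  if (length(floor) == 1 && is.null(names(floor))) {
    floor <- stats::setNames(rep(floor, nrow(fits)), fits$region_id)
  }
  tidyr::crossing(fits, year = years) |>
    dplyr::mutate(
      volume = pmax(.data$amplitude *
                      exp(-(.data$year - .data$peak_year)^2 / (2 * .data$width^2)),
                    unname(floor[.data$region_id]))
    ) |>
    dplyr::select("region_id", "year", "volume")
}

#' Exponentially interpolate composition shares
#'
#' Geometric (exponential) interpolation of a share vector between two
#' anchor years: `s(t) = s0 * (s1/s0)^((t - t0)/(t1 - t0))`, renormalized to
#' sum to one. A zero start share with a nonzero end share is floored at
#' 1e-6 before interpolation so the geometric path is defined.
#'
#' @param shares_start,shares_end named numeric vectors over the same keys.
#' @param year year at which to evaluate.
#' @param t0,t1 anchor years (defaults 2021 and 2031).
#' @return named numeric vector of shares summing to 1.
#' @export
#' @examples
#' interpolate_shares(c(a = .8, b = .2), c(a = .2, b = .8), 2026)
interpolate_shares <- function(shares_start, shares_end, year,
                               t0 = 2021, t1 = 2031) {
  stopifnot(setequal(names(shares_start), names(shares_end)))
  shares_end <- shares_end[names(shares_start)]
  s0 <- pmax(shares_start, ifelse(shares_end > 0, 1e-6, 0))
  s1 <- pmax(shares_end, ifelse(shares_start > 0, 1e-6, 0))
  w <- (year - t0) / (t1 - t0)
  s <- ifelse(s0 == 0 & s1 == 0, 0, s0 * ifelse(s0 > 0, (s1 / s0)^w, 0))
  if (sum(s) == 0) return(s)
  s / sum(s)
}

#' Sustainable logging potential
#'
#' Annual harvest potential per region and forest type under ordinary
#' planned management: the merchantable carbon of final-cut-eligible stock
#' (stands within `window` years of the rotation age) amortized over the
#' planning window, plus a thinning potential (thinnable stock times the
#' thinning intensity amortized over the thinning return interval). The
#' thinning component is capped by the net annual increment left after the
#' final-cut component, so planned removals beyond the amortized mature
#' stock never exceed net growth and the projected standing stock is
#' non-decreasing over the window.
#'
#' @param state spun-up `fcbs_state`.
#' @param curves yield curve table.
#' @param params dynamics parameters.
#' @param window final-cut planning window in years (default 20).
#' @param thinning_interval thinning return interval in years (default 10).
#' @return tibble: `region_id`, `forest_type`, `final_tC`, `thin_tC`,
#'   `total_tC` (t C/yr of merchantable product carbon).
#' @export
sustainable_potential <- function(state, curves, params = default_params(),
                                  window = 20, thinning_interval = 10) {
  curves <- validate_yield_curves(curves)
  if (nrow(state) == 0) {
    return(tibble::tibble(region_id = character(), forest_type = character(),
                          final_tC = numeric(), thin_tC = numeric(),
                          total_tC = numeric()))
  }
  th <- params$thinning
  df <- tibble::as_tibble(state[state$forest_type %in% GROWING_TYPES &
                                  state$area > 0, ])
  if (nrow(df) == 0) {
    return(tibble::tibble(region_id = character(), forest_type = character(),
                          final_tC = numeric(), thin_tC = numeric(),
                          total_tC = numeric()))
  }
  df$rot <- unname(params$rotation[df$forest_type])
  df$inc_tC <- yield_increment(curves, df$forest_type, df$age) *
    density_of(df$forest_type, params) * df$area
  df$merch_tC <- df$merch_stem * df$area
  df |>
    dplyr::mutate(
      final_el = .data$age >= .data$rot - window & !.data$retained,
      thin_el = .data$age >= th$min_age & .data$age <= th$max_age
    ) |>
    dplyr::group_by(.data$region_id, .data$forest_type) |>
    dplyr::summarise(
      final_tC = sum(.data$merch_tC[.data$final_el]) / window,
      thin_raw = sum(.data$merch_tC[.data$thin_el]) * th$intensity /
        thinning_interval,
      nai_tC = sum(.data$inc_tC),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      thin_tC = pmin(.data$thin_raw, pmax(.data$nai_tC - .data$final_tC, 0)),
      total_tC = .data$final_tC + .data$thin_tC
    ) |>
    dplyr::select("region_id", "forest_type", "final_tC", "thin_tC", "total_tC")
}
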