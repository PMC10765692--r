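# Seeded synthetic national datasets: inventory, yield curves, region
# metadata and the observed harvest series with its Gaussian calamity pulse.

#' Synthetic dataset configuration
#'
#' Defaults emulate the structure of a spruce-dominated Central-European
#' forest estate at the national scale: 14 regions, 2 610 kha, the reference
#' forest-type area shares, a mid-age-heavy age-class distribution, and a
#' drought-induced calamity pulse peaking around 2020 at roughly 35.8 Mm3
#' total harvest with a ~95% sanitary share.
#'
#' @param n_regions number of regions (default 14; `mini = TRUE` gives 2).
#' @param total_area_kha total forest area (default 2610).
#' @param area_shares named forest-type area shares summing to 1.
#' @param age_decay geometric decay of age-class weights away from the modal
#'   classes 4-5 (default 0.60).
#' @param age_classes number of 10-year age classes carrying area (default
#'   12: stands above 115 years are rare in the emulated 2018 baseline).
#' @param pulse_sigma width of the regional calamity pulse in years.
#' @param total_2020_mm3 calibration target for the 2020 country harvest.
#' @param planned_baseline_mm3 pre-calamity planned harvest level.
#' @param sanitary_baseline_mm3 pre-calamity sanitary harvest level.
#' @param planned_crowding share of planned harvest displaced at the pulse
#'   peak (sanitary interventions crowd out planned ones).
#' @param unprocessed_fraction share of the spruce sanitary pulse 2018-2021
#'   left standing dead (entering the snag backlog via Dist. 6).
#' @param noise_sd_frac Gaussian noise sd as a fraction of the regional
#'   pulse amplitude.
#' @param spx_volume_m3ha merchantable volume of standing-dead spruce.
#' @param mini 2-region, 3-type preset for fast unit tests.
#' @return `fcbs_synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(mini = TRUE)
synth_config <- function(n_regions = 14,
                         total_area_kha = 2610,
                         area_shares = c(SP = .496, PI = .202, BE = .086,
                                         OA = .074, LLB = .061, SLB = .053,
                                         AA = .014, CLEARCUT = .012,
                                         SPx = .002),
                         age_decay = 0.60,
                         age_classes = 12,
                         pulse_sigma = 2,
                         total_2020_mm3 = 35.8,
                         planned_baseline_mm3 = 12.6,
                         sanitary_baseline_mm3 = 3.2,
                         planned_crowding = 0.9,
                         unprocessed_fraction = 0.10,
                         noise_sd_frac = 0.05,
                         spx_volume_m3ha = 400,
                         mini = FALSE) {
  if (mini) {
    n_regions <- 2
    area_shares <- c(SP = 0.6, BE = 0.3, PI = 0.1)
    total_area_kha <- 100
  }
  if (abs(sum(area_shares) - 1) > 1e-9) {
    stop("area shares must sum to 1", call. = FALSE)
  }
  check_forest_type(names(area_shares))
  structure(list(
    n_regions = n_regions,
    total_area_kha = total_area_kha,
    area_shares = area_shares,
    volume_shares = c(SP = .595, PI = .199, BE = .067, OA = .054, LLB = .040,
                      SLB = .026, AA = .015, CLEARCUT = 0, SPx = .003),
    age_decay = age_decay,
    age_classes = age_classes,
    pulse_sigma = pulse_sigma,
    total_2020_mm3 = total_2020_mm3,
    planned_baseline_mm3 = planned_baseline_mm3,
    sanitary_baseline_mm3 = sanitary_baseline_mm3,
    planned_crowding = planned_crowding,
    unprocessed_fraction = unprocessed_fraction,
    noise_sd_frac = noise_sd_frac,
    spx_volume_m3ha = spx_volume_m3ha,
    # planned harvest composition (heavily coniferous, as before the calamity)
    planned_type_shares = c(SP = .60, PI = .26, AA = .02, BE = .05, OA = .03,
                            LLB = .03, SLB = .01),
    planned_dist_split = c("2" = 0.30, "4" = 0.70),
    sanitary_dist_split = c("3a" = 0.70, "3b" = 0.30),
    mini = mini
  ), class = "fcbs_synth_config")
}

# fixed region metadata templates (altitude gradient, alternating enhanced
# species, staggered episode end-years, spread flags); recycled for other
# region counts
region_template <- function(n) {
  alt <- c(286, 414, 631, 609, 684, 516, 522, 548, 486, 574, 378, 592, 503, 591)
  enh <- c("Oak", "Oak", "Fir", "Fir", "Fir", "Oak", "Oak", "Oak", "Oak",
           "Fir", "Oak", "Fir", "Oak", "Fir")
  endy <- c(2037, 2025, 2030, 2035, 2023, 2030, 2036, 2047, 2033, 2022, 2021,
            2032, 2031, 2036)
  sprd <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
            FALSE, FALSE, FALSE, FALSE)
  wt <- c(4.8, 294, 372, 304, 141, 159, 137, 146, 131, 204, 193, 181, 155, 188)
  i <- rep_len(seq_len(14), n)
  tibble::tibble(
    region_id = sprintf("R%02d", seq_len(n)),
    name = sprintf("Region %02d", seq_len(n)),
    altitude_m = alt[i],
    enhanced_species = enh[i],
    end_year = endy[i],
    spread_flag = sprd[i],
    weight = wt[i] / sum(wt[i]),
    peak_year = ifelse(endy[i] <= 2022, 2019,
                       ifelse(endy[i] >= 2040, 2021, 2020))
  )
}

# split `total` over `weights` in integer units by largest remainder
largest_remainder <- function(weights, total) {
  raw <- weights / sum(weights) * total
  fl <- floor(raw)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}

#' Generate a synthetic forest inventory
#'
#' Builds the stand and region tables: per region and forest type, area is
#' split across 10-year age classes with geometric weights decaying away
#' from the modal classes 4-5, cohorts sit at class-midpoint ages, and
#' merchantable volume follows the default yield curves at those ages
#' (standing-dead stands carry a fixed snag volume). Areas are integer
#' hectares from largest-remainder rounding so the configured total is
#' matched exactly. Deterministic given (config, seed).
#'
#' @param config an [synth_config()].
#' @param seed integer seed (mandatory).
#' @return list with `stands` and `regions` tibbles.
#' @export
generate_inventory <- function(config, seed) {
  stopifnot(inherits(config, "fcbs_synth_config"), !missing(seed))
  set.seed(seed)
  regions <- region_template(config$n_regions)
  curves <- generate_yield_curves(config)
  total_ha <- round(config$total_area_kha * 1000)
  region_ha <- largest_remainder(regions$weight, total_ha)
  classes <- seq_len(config$age_classes)
  wts <- config$age_decay^abs(classes - 4.5)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    type_ha <- largest_remainder(config$area_shares, region_ha[r])
    for (ti in seq_along(config$area_shares)) {
      ft <- names(config$area_shares)[ti]
      if (type_ha[ti] == 0) next
      if (ft == "CLEARCUT") {
        rows[[length(rows) + 1]] <- tibble::tibble(
          region_id = regions$region_id[r], forest_type = ft, age = 0L,
          area_ha = type_ha[ti], merch_volume_m3ha = 0)
        next
      }
      if (ft == "SPx") {
        rows[[length(rows) + 1]] <- tibble::tibble(
          region_id = regions$region_id[r], forest_type = ft, age = 80L,
          area_ha = type_ha[ti], merch_volume_m3ha = config$spx_volume_m3ha)
        next
      }
      cls_ha <- largest_remainder(wts, type_ha[ti])
      keep <- cls_ha > 0
      ages <- as.integer(classes * 10 - 5)
      rows[[length(rows) + 1]] <- tibble::tibble(
        region_id = regions$region_id[r],
        forest_type = ft,
        age = ages[keep],
        area_ha = cls_ha[keep],
        merch_volume_m3ha = yield_volume(curves, ft, ages[keep]))
    }
  }
  list(stands = dplyr::bind_rows(rows),
       regions = regions[, c("region_id", "name", "altitude_m",
                             "enhanced_species", "end_year", "spread_flag")])
}

#' Generate synthetic yield curves
#'
#' Chapman-Richards curves `v(a) = Vmax (1 - exp(-k a))^p` per forest type
#' on an annual age grid to 160 years. The spruce parameters are calibrated
#' so the area-weighted spruce net annual increment on the default inventory
#' age structure is close to 11 m3/ha/yr.
#'
#' @param config an [synth_config()].
#' @return tibble `forest_type`, `age`, `volume_m3ha`.
#' @export
generate_yield_curves <- function(config = synth_config()) {
  pars <- list(
    SP = c(1090, 0.025, 2.0),
    PI = c(650, 0.025, 2.2),
    BE = c(800, 0.020, 2.0),
    OA = c(650, 0.020, 2.0),
    LLB = c(600, 0.022, 2.0),
    SLB = c(400, 0.035, 2.0),
    AA = c(1000, 0.025, 2.0)
  )
  stopifnot(all(vapply(pars, function(p) all(p > 0), logical(1))))
  ages <- 0:160
  dplyr::bind_rows(lapply(names(pars), function(ft) {
    p <- pars[[ft]]
    tibble::tibble(forest_type = ft, age = ages,
                   volume_m3ha = p[1] * (1 - exp(-p[2] * ages))^p[3])
  }))
}

#' Generate a synthetic observed harvest series (2012-2021)
#'
#' Per region: a planned baseline partially crowded out at the calamity
#' peak, a pre-calamity sanitary baseline, and a Gaussian spruce sanitary
#' pulse with seeded Gaussian noise (sd a configured fraction of the pulse
#' amplitude). Amplitudes are scaled so the 2020 country total matches the
#' configured maximum, which also drives the sanitary share at the peak to
#' about 95%. Unprocessed standing mortality (Dist. 6) is emitted for
#' 2018-2021 as a configured fraction of the spruce sanitary pulse.
#'
#' @param config an [synth_config()].
#' @param seed integer seed (mandatory).
#' @param years series years (default 2012:2021).
#' @return tibble: `year`, `region_id`, `forest_type`, `dist_id`,
#'   `volume_mm3`.
#' @export
generate_observed_harvest <- function(config, seed, years = 2012:2021) {
  stopifnot(inherits(config, "fcbs_synth_config"), !missing(seed))
  set.seed(seed + 1L)
  regions <- region_template(config$n_regions)
  sig <- config$pulse_sigma
  g <- function(t, mu) exp(-(t - mu)^2 / (2 * sig^2))
  # amplitude scale so the 2020 country total hits the configured maximum
  g20 <- g(2020, regions$peak_year)
  planned20 <- sum(config$planned_baseline_mm3 * regions$weight *
                     (1 - config$planned_crowding * g20))
  resid20 <- config$total_2020_mm3 - planned20 - config$sanitary_baseline_mm3
  amp_scale <- max(resid20, 0) / sum(regions$weight * g20)
  regions$amplitude <- amp_scale * regions$weight

  pts <- config$planned_type_shares / sum(config$planned_type_shares)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    w <- regions$weight[r]
    mu <- regions$peak_year[r]
    A <- regions$amplitude[r]
    noise <- stats::rnorm(length(years), 0, config$noise_sd_frac * A)
    pulse <- pmax(A * g(years, mu) + noise, 0)
    planned <- config$planned_baseline_mm3 * w *
      (1 - config$planned_crowding * g(years, mu))
    sanit_base <- config$sanitary_baseline_mm3 * w
    for (ti in seq_along(pts)) {
      ft <- names(pts)[ti]
      for (d in names(config$planned_dist_split)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          year = years, region_id = regions$region_id[r], forest_type = ft,
          dist_id = d,
          volume_mm3 = planned * pts[ti] * config$planned_dist_split[[d]])
      }
      for (d in names(config$sanitary_dist_split)) {
        extra <- if (ft == "SP") pulse else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          year = years, region_id = regions$region_id[r], forest_type = ft,
          dist_id = d,
          volume_mm3 = (sanit_base * pts[ti] + extra) *
            config$sanitary_dist_split[[d]])
      }
    }
    # unprocessed standing mortality, 2018-2021 only
    mort_years <- intersect(years, 2018:2021)
    if (length(mort_years) > 0 && config$unprocessed_fraction > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        year = mort_years, region_id = regions$region_id[r],
        forest_type = "SP", dist_id = "6",
        volume_mm3 = config$unprocessed_fraction * A * g(mort_years, mu))
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$volume_mm3 > 0) |>
    dplyr::arrange(.data$year, .data$region_id, .data$forest_type,
                   .data$dist_id)
}

#' Generate the full default synthetic dataset
#'
#' Convenience wrapper bundling inventory, region metadata, yield curves and
#' the observed harvest series for one seed.
#'
#' @param config an [synth_config()].
#' @param seed integer seed.
#' @return list: `stands`, `regions`, `curves`, `observed`.
#' @export
generate_dataset <- function(config = synth_config(), seed = 42) {
  inv <- generate_inventory(config, seed)
  list(stands = inv$stands, regions = inv$regions,
       curves = generate_yield_curves(config),
       observed = generate_observed_harvest(config, seed))
}
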