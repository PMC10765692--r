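# IPCC pool aggregation, CO2 conversion, LULUCF accounting arithmetic and
# indicator tables.

#' Aggregate cohort pools to the four IPCC categories
#'
#' Living biomass holds the five live pools; deadwood holds the snag pools,
#' coarse woody debris and dead coarse roots in mineral soil; litter the
#' aboveground fast, very fast and slow (forest-floor) pools; soil the
#' belowground very fast and slow pools.
#'
#' @param state cohort state.
#' @return named numeric: `living_biomass`, `deadwood`, `litter`, `soil`
#'   (t C, area-weighted totals).
#' @export
#' @examples
#' aggregate_ipcc(load_inventory(
#'   data.frame(region_id = "R01", forest_type = "SP", age = 50,
#'              area_ha = 1, merch_volume_m3ha = 100),
#'   data.frame(region_id = "R01", altitude_m = 500,
#'              enhanced_species = "Fir", end_year = 2030,
#'              spread_flag = TRUE)))
aggregate_ipcc <- function(state) {
  grp <- list(
    living_biomass = LIVE_POOLS,
    deadwood = c("snag_stem", "snag_branch", "medium_dom", "bg_fast"),
    litter = c("ag_fast", "ag_very_fast", "ag_slow"),
    soil = c("bg_very_fast", "bg_slow")
  )
  vapply(grp, function(ps) {
    if (nrow(state) == 0) return(0)
    sum(vapply(ps, function(p) sum(state[[p]] * state$area), numeric(1)))
  }, numeric(1))
}

#' Convert a carbon stock change to CO2-equivalent emissions
#'
#' Sign convention: a stock gain is a removal (negative emissions), a stock
#' loss a source (positive emissions); the factor is the molar mass ratio
#' 44/12.
#'
#' @param delta_c stock change, in any mass unit of carbon (the result is in
#'   the same mass unit of CO2).
#' @return emissions, `-delta_c * 44/12`.
#' @export
#' @examples
#' stock_change_to_emissions(1.2)  # 1.2 Mt C gained -> -4.4 Mt CO2 eq.
stock_change_to_emissions <- function(delta_c) {
  stopifnot(all(is.finite(delta_c)))
  -delta_c * 44 / 12
}

#' LULUCF accounting arithmetic for a compliance period
#'
#' Combines a projected annual emission series with the forest reference
#' level (FRL) and exogenous offsets (harvested wood products plus
#' afforestation) into the period's accounting balance: the FRL contributes
#' `|frl_annual| * length(period)` accounting units, offsets contribute
#' `|offsets_annual| * length(period)`, the gross deficit is the cumulative
#' projected balance plus the FRL units and the net deficit subtracts the
#' offsets.
#'
#' @param emissions annual net emission series (Mt CO2 eq./yr, positive =
#'   source), either named by year or in period order covering `period`.
#' @param frl_annual FRL (Mt CO2 eq./yr; the magnitude is used).
#' @param offsets_annual combined annual offset (Mt CO2 eq./yr; magnitude).
#' @param period integer years of the compliance period.
#' @return `fcbs_accounting` list: `period`, `cumulative_balance`,
#'   `annual_mean`, `frl_units`, `offset_units`, `gross_deficit`,
#'   `net_deficit` (all Mt CO2 eq.).
#' @export
#' @examples
#' accounting_arithmetic(rep(14.6 / 5, 5), frl_annual = -4.739,
#'                       offsets_annual = -1.75, period = 2021:2025)
accounting_arithmetic <- function(emissions, frl_annual, offsets_annual,
                                  period) {
  if (length(period) == 0) stop("empty accounting period", call. = FALSE)
  if (!is.null(names(emissions))) {
    miss <- setdiff(as.character(period), names(emissions))
    if (length(miss) > 0) {
      stop("emission series does not cover year(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    emissions <- emissions[as.character(period)]
  } else {
    stopifnot(length(emissions) == length(period))
  }
  n <- length(period)
  cumulative <- sum(emissions)
  frl_units <- abs(frl_annual) * n
  offset_units <- abs(offsets_annual) * n
  gross <- cumulative + frl_units
  structure(list(
    period = period,
    cumulative_balance = cumulative,
    annual_mean = cumulative / n,
    frl_units = frl_units,
    offset_units = offset_units,
    gross_deficit = gross,
    net_deficit = gross - offset_units
  ), class = "fcbs_accounting")
}

#' @export
print.fcbs_accounting <- function(x, ...) {
  cat(sprintf("<fcbs_accounting %d-%d>\n", min(x$period), max(x$period)))
  cat(sprintf("  cumulative balance: %.1f Mt CO2 eq. (%.1f /yr)\n",
              x$cumulative_balance, x$annual_mean))
  cat(sprintf("  FRL units: %.1f, offsets: %.1f\n", x$frl_units,
              x$offset_units))
  cat(sprintf("  deficit: %.1f gross, %.1f net\n", x$gross_deficit,
              x$net_deficit))
  invisible(x)
}

#' Indicator tables from a scenario result
#'
#' Produces the per-year reporting tables: harvest by disturbance type,
#' species shares by area and merchantable volume, the relative growing
#' stock index (living biomass versus the first simulated year), age-class
#' area distributions at selected snapshot years, and NAI by forest type.
#'
#' @param result an `fcbs_result` from [run_scenario()].
#' @param snapshot_years years for the age-structure table (default
#'   c(2040, 2070), clipped to the simulated horizon).
#' @return list of tibbles: `harvest`, `species_shares`, `growing_stock`,
#'   `age_structure`, `nai`.
#' @export
report_indicators <- function(result, snapshot_years = c(2040, 2070)) {
  stopifnot(nrow(result) > 0)
  harvest <- attr(result, "harvest") %||% tibble::tibble()
  species <- attr(result, "species") %||% tibble::tibble()
  shares <- if (nrow(species) > 0) {
    species |>
      dplyr::group_by(.data$year) |>
      dplyr::mutate(area_share = .data$area / sum(.data$area),
                    volume_share = if (sum(merch_tC) > 0)
                      .data$merch_tC / sum(.data$merch_tC) else 0) |>
      dplyr::ungroup()
  } else {
    species
  }
  growing <- tibble::tibble(
    year = result$year,
    living_biomass_tC = result$living_biomass_tC,
    index = result$living_biomass_tC / result$living_biomass_tC[1]
  )
  age <- attr(result, "age_structure") %||% tibble::tibble()
  if (nrow(age) > 0) {
    snap <- intersect(snapshot_years, unique(age$year))
    age <- age[age$year %in% snap, ]
  }
  list(harvest = harvest, species_shares = shares, growing_stock = growing,
       age_structure = age, nai = attr(result, "nai") %||% tibble::tibble())
}

#' Write a result's indicator tables to CSV files
#'
#' Writes `emissions.csv`, `harvest.csv`, `species_shares.csv`,
#' `age_structure.csv` and `nai.csv` into a directory.
#'
#' @param result an `fcbs_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ind <- report_indicators(result)
  utils::write.csv(tibble::as_tibble(result),
                   file.path(dir, "emissions.csv"), row.names = FALSE)
  utils::write.csv(ind$harvest, file.path(dir, "harvest.csv"),
                   row.names = FALSE)
  utils::write.csv(ind$species_shares, file.path(dir, "species_shares.csv"),
                   row.names = FALSE)
  utils::write.csv(ind$age_structure, file.path(dir, "age_structure.csv"),
                   row.names = FALSE)
  utils::write.csv(ind$nai, file.path(dir, "nai.csv"), row.names = FALSE)
  invisible(dir)
}
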