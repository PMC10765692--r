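# broom-style accessors and ggplot2 methods for fitted/simulated objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a scenario result
#'
#' One row per year and IPCC pool with the annual stock change, plus the
#' net total.
#'
#' @param x an `fcbs_result`.
#' @param ... unused.
#' @return tibble: `year`, `pool`, `stock_tC`, `change_tC`.
#' @export
tidy.fcbs_result <- function(x, ...) {
  long <- tibble::as_tibble(x) |>
    dplyr::select("year", "living_biomass_tC", "deadwood_tC", "litter_tC",
                  "soil_tC", "d_living", "d_deadwood", "d_litter", "d_soil")
  stocks <- long |>
    tidyr::pivot_longer(dplyr::ends_with("_tC"), names_to = "pool",
                        values_to = "stock_tC") |>
    dplyr::mutate(pool = sub("_tC$", "", .data$pool)) |>
    dplyr::select("year", "pool", "stock_tC")
  changes <- long |>
    tidyr::pivot_longer(dplyr::starts_with("d_"), names_to = "pool",
                        values_to = "change_tC") |>
    dplyr::mutate(pool = dplyr::recode(sub("^d_", "", .data$pool),
                                       living = "living_biomass")) |>
    dplyr::select("year", "pool", "change_tC")
  dplyr::left_join(stocks, changes, by = c("year", "pool"))
}

#' Summarise a scenario result
#'
#' @param x an `fcbs_result`.
#' @param ... unused.
#' @return one-row tibble: scenario name, first net-sink year (NA when the
#'   sector never turns), cumulative emissions, end-of-horizon spruce area
#'   share, cumulative harvest deficit share.
#' @export
glance.fcbs_result <- function(x, ...) {
  sc <- attr(x, "scenario")
  sink_years <- x$year[x$emissions_mtco2 < 0]
  species <- attr(x, "species")
  sp_share <- NA_real_
  if (!is.null(species) && nrow(species) > 0) {
    last <- species[species$year == max(species$year), ]
    sp_share <- sum(last$area[last$forest_type == "SP"]) / sum(last$area)
  }
  tibble::tibble(
    scenario = if (is.null(sc)) NA_character_ else sc$name,
    first_sink_year = if (length(sink_years) > 0) min(sink_years) else
      NA_integer_,
    cumulative_emissions_mtco2 = sum(x$emissions_mtco2),
    spruce_area_share_end = sp_share,
    deficit_share = if (sum(x$demand_tC) > 0)
      sum(x$deficit_tC) / sum(x$demand_tC) else 0
  )
}

#' Tidy an accounting report
#' @param x an `fcbs_accounting`.
#' @param ... unused.
#' @return two-column tibble of the accounting quantities (Mt CO2 eq.).
#' @export
tidy.fcbs_accounting <- function(x, ...) {
  tibble::tibble(
    quantity = c("cumulative_balance", "annual_mean", "frl_units",
                 "offset_units", "gross_deficit", "net_deficit"),
    mtco2 = c(x$cumulative_balance, x$annual_mean, x$frl_units,
              x$offset_units, x$gross_deficit, x$net_deficit)
  )
}

#' Plot a scenario's emission trajectory
#'
#' Annual net CO2 emissions (positive = source) with the zero line marking
#' the sink/source transition.
#'
#' @param object an `fcbs_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fcbs_result <- function(object, ...) {
  sc <- attr(object, "scenario")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$year, y = .data$emissions_mtco2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "Net emissions (Mt CO2 eq./yr)",
                  title = if (is.null(sc)) NULL else
                    paste(sc$name, "scenario")) +
    ggplot2::theme_minimal()
}

#' Plot annual carbon pool changes
#'
#' Stacked per-pool stock changes with the net total overlaid, the standard
#' carbon-balance view of a projection.
#'
#' @param result an `fcbs_result`.
#' @return a ggplot.
#' @export
plot_pool_changes <- function(result) {
  td <- tidy(result)
  net <- tibble::as_tibble(result)[, c("year", "d_total_tC")]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$year, y = .data$change_tC / 1e6,
                                   fill = .data$pool)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(data = net,
                       ggplot2::aes(x = .data$year, y = .data$d_total_tC / 1e6),
                       inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "Carbon stock change (Mt C/yr)",
                  fill = "Pool") +
    ggplot2::theme_minimal()
}

#' Plot species area shares over time
#'
#' @param result an `fcbs_result`.
#' @return a ggplot.
#' @export
plot_species_shares <- function(result) {
  species <- attr(result, "species")
  stopifnot(!is.null(species))
  df <- species |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(share = .data$area / sum(.data$area)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$share,
                                   fill = .data$forest_type)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = NULL, y = "Area share", fill = "Forest type") +
    ggplot2::theme_minimal()
}
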