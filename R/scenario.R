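# Scenario engines: scenario specifications, demand schedules, sanitary-
# priority harvest allocation, species-change replanting, and the annual
# simulation driver.

#' Scenario specification
#'
#' The four scenario engines encode contrasting courses of the bark-beetle
#' calamity: `Green` (rapid attenuation, 17 Mm3/yr target, old-growth
#' retention), `Red` (slow regional decline at observed 2021 intensities,
#' 16 Mm3/yr), `Black` (as Red plus a 20% spread of spruce sanitary logging
#' in not-yet-culminated regions) and `BlackRep` (as Black plus a 2-year
#' calamity recurrence every decade from 2038 with escalating planned demand
#' for non-fir species).
#'
#' @param name one of `"Green"`, `"Red"`, `"Black"`, `"BlackRep"`.
#' @return an `fcbs_scenario` list.
#' @export
#' @examples
#' scenario_spec("Green")
scenario_spec <- function(name = c("Green", "Red", "Black", "BlackRep")) {
  name <- match.arg(name)
  sp <- list(
    name = name,
    target_mm3 = if (name == "Green") 17 else 16,
    spread = name %in% c("Black", "BlackRep"),
    spread_factor = 1.2,
    recurrence = name == "BlackRep",
    episode_first = 2038, episode_period = 10, episode_length = 2,
    escalation = list(c(2038, 2047, 1.10), c(2048, 2057, 1.15),
                      c(2058, 2070, 1.20)),
    retention = name == "Green",
    retention_conifer_age = 120, retention_broadleaf_age = 140,
    retention_from = 2025
  )
  structure(sp, class = "fcbs_scenario")
}

#' @export
print.fcbs_scenario <- function(x, ...) {
  cat(sprintf("<fcbs_scenario %s> target %d Mm3/yr, spread %s, recurrence %s, retention %s\n",
              x$name, x$target_mm3, x$spread, x$recurrence, x$retention))
  invisible(x)
}

# BlackRep recurrence episode years within a horizon
episode_years <- function(scenario, years) {
  if (!scenario$recurrence) return(integer())
  starts <- seq(scenario$episode_first, max(years), by = scenario$episode_period)
  ep <- unlist(lapply(starts, function(s) s + 0:(scenario$episode_length - 1)))
  intersect(ep, years)
}

# ---- demand schedule --------------------------------------------------------

#' Build a scenario's harvest demand schedule
#'
#' Constructs the complete (year, region, forest type, disturbance type)
#' demand table for the simulation horizon, in t C of merchantable product
#' carbon. The known years (2018-2021) replicate the observed harvest
#' verbatim in every scenario; thereafter each scenario's rules apply:
#' fitted-pulse extrapolation with exponential share interpolation (Green),
#' frozen 2021 intensities until the regional end of the disturbance episode
#' (Red/Black, with the Black 20% spruce sanitary increase in spread-flag
#' regions), decadal recurrence episodes at 2018/2019 average spruce
#' intensities plus planned-demand escalation (BlackRep), and the
#' sustainable-potential regime scaled to the scenario target elsewhere.
#' The sanitary share of potential-regime demand is capped at one-third.
#'
#' @param scenario an [scenario_spec()].
#' @param state spun-up `fcbs_state` (used for the sustainable potential).
#' @param observed observed harvest tibble (`year`, `region_id`,
#'   `forest_type`, `dist_id`, `volume_mm3`) covering 2012-2021.
#' @param curves yield curve table.
#' @param params dynamics parameters.
#' @param years simulation horizon (default 2018:2070).
#' @param sanitary_share sanitary share of potential-regime demand
#'   (default 0.28, capped at 1/3).
#' @return tibble: `year`, `region_id`, `forest_type`, `dist_id`,
#'   `demand_tC`, `provenance`.
#' @export
build_demand_schedule <- function(scenario, state, observed, curves,
                                  params = default_params(),
                                  years = 2018:2070,
                                  sanitary_share = 0.28) {
  stopifnot(inherits(scenario, "fcbs_scenario"))
  regions <- state_regions(state)
  if (is.null(regions)) stop("state carries no region metadata", call. = FALSE)
  miss <- setdiff(unique(observed$region_id), regions$region_id)
  if (length(miss) > 0) {
    stop("region(s) in observed harvest missing from metadata: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::as_tibble(observed) |>
    dplyr::mutate(dist_id = as.character(.data$dist_id),
                  demand_tC = .data$volume_mm3 * 1e6 *
                    density_of(.data$forest_type, params))

  # 1. known years: observed verbatim (identical in every scenario)
  known <- obs |>
    dplyr::filter(.data$year %in% intersect(years, 2018:2021)) |>
    dplyr::transmute(.data$year, .data$region_id, .data$forest_type,
                     .data$dist_id, .data$demand_tC, provenance = "observed")

  proj_years <- years[years >= 2022]
  if (length(proj_years) == 0) {
    return(dplyr::arrange(known, .data$year, .data$region_id))
  }

  # 2. potential-regime cell demands scaled to the scenario target
  pot <- potential_regime_demand(scenario, state, curves, params,
                                 sanitary_share)

  # 3. calamity-period demand per scenario
  obs21 <- obs |>
    dplyr::filter(.data$year == 2021,
                  .data$dist_id %in% c("2", "3a", "3b", "4")) |>
    dplyr::select("region_id", "forest_type", "dist_id", "demand_tC")

  sched <- switch(scenario$name,
    Green = green_projection(scenario, obs, pot, proj_years, params),
    Red = red_black_projection(scenario, obs21, pot, regions, proj_years,
                               spread = FALSE),
    Black = red_black_projection(scenario, obs21, pot, regions, proj_years,
                                 spread = TRUE),
    BlackRep = blackrep_projection(scenario, obs, obs21, pot, regions,
                                   proj_years, years)
  )
  out <- dplyr::bind_rows(known, sched) |>
    dplyr::filter(.data$demand_tC > 0) |>
    dplyr::arrange(.data$year, .data$region_id, .data$forest_type,
                   .data$dist_id)
  stopifnot(all(out$demand_tC >= 0), all(out$year %in% years))
  out
}

# potential-regime demand cells (region x type x dist, t C/yr), scaled so the
# country volume total equals min(target, potential)
potential_regime_demand <- function(scenario, state, curves, params,
                                    sanitary_share) {
  s <- min(sanitary_share, 1 / 3)
  pot <- sustainable_potential(state, curves, params)
  cells <- pot |>
    dplyr::mutate(sanitary_tC = s / (1 - s) * .data$total_tC) |>
    tidyr::pivot_longer(c("thin_tC", "final_tC", "sanitary_tC"),
                        names_to = "component", values_to = "demand_tC") |>
    dplyr::mutate(dist_id = dplyr::recode(.data$component,
                                          thin_tC = "2", final_tC = "4",
                                          sanitary_tC = "3a")) |>
    dplyr::select("region_id", "forest_type", "dist_id", "demand_tC")
  # split sanitary demand between full (3a) and spot (3b) salvage
  s3 <- cells[cells$dist_id == "3a", ]
  cells$demand_tC[cells$dist_id == "3a"] <- s3$demand_tC * 0.5
  s3$dist_id <- "3b"
  s3$demand_tC <- s3$demand_tC * 0.5
  cells <- dplyr::bind_rows(cells, s3)
  total_mm3 <- sum(cells$demand_tC /
                     density_of(cells$forest_type, params)) / 1e6
  scale <- if (total_mm3 > 0) min(scenario$target_mm3 / total_mm3, 1) else 0
  cells$demand_tC <- cells$demand_tC * scale
  cells[cells$demand_tC > 0, ]
}

# Green: fitted-pulse extrapolation 2022-2029 with exponentially
# interpolated composition shares, potential regime from 2030
green_projection <- function(scenario, obs, pot, proj_years, params) {
  harvest_obs <- obs |>
    dplyr::filter(.data$dist_id %in% c("2", "3a", "3b", "4"))
  fits <- fit_calamity_curves(harvest_obs)
  pot_region_mm3 <- pot |>
    dplyr::mutate(mm3 = .data$demand_tC / density_of(.data$forest_type, params) / 1e6) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(floor = sum(.data$mm3), .groups = "drop")
  floors <- stats::setNames(pot_region_mm3$floor, pot_region_mm3$region_id)
  floors <- floors[fits$region_id]
  floors[is.na(floors)] <- 0
  names(floors) <- fits$region_id
  extra_years <- intersect(proj_years, 2022:2029)
  extr <- extrapolate_demand(fits, extra_years, floor = floors)

  # composition shares: observed 2021 vs potential-regime anchors per region
  share_tbl <- function(df, val) {
    sh <- df[[val]] / sum(df[[val]])
    stats::setNames(sh, paste(df$forest_type, df$dist_id, sep = "."))
  }
  rows <- list()
  for (r in unique(extr$region_id)) {
    o21 <- harvest_obs |>
      dplyr::filter(.data$year == 2021, .data$region_id == r) |>
      dplyr::group_by(.data$forest_type, .data$dist_id) |>
      dplyr::summarise(demand_tC = sum(.data$demand_tC), .groups = "drop")
    p_r <- pot[pot$region_id == r, ]
    if (nrow(p_r) == 0 || sum(p_r$demand_tC) == 0) next
    keys <- union(paste(o21$forest_type, o21$dist_id, sep = "."),
                  paste(p_r$forest_type, p_r$dist_id, sep = "."))
    s0 <- stats::setNames(numeric(length(keys)), keys)
    s1 <- s0
    if (nrow(o21) > 0 && sum(o21$demand_tC) > 0) {
      s0[paste(o21$forest_type, o21$dist_id, sep = ".")] <-
        o21$demand_tC / sum(o21$demand_tC)
    }
    s1[paste(p_r$forest_type, p_r$dist_id, sep = ".")] <-
      p_r$demand_tC / sum(p_r$demand_tC)
    for (yr in extra_years) {
      sh <- interpolate_shares(s0, s1, yr)
      tot_mm3 <- extr$volume[extr$region_id == r & extr$year == yr]
      ft <- sub("\\..*$", "", names(sh))
      di <- sub("^.*\\.", "", names(sh))
      dem <- tot_mm3 * 1e6 * sh * density_of(ft, params)
      rows[[length(rows) + 1]] <- tibble::tibble(
        year = yr, region_id = r, forest_type = ft, dist_id = di,
        demand_tC = unname(dem), provenance = "fitted-extrapolation")
    }
  }
  pot_years <- proj_years[proj_years >= 2030]
  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tidyr::crossing(year = pot_years, pot) |>
      dplyr::mutate(provenance = "potential-regime")
  )
}

# Red/Black: 2021 intensities until the regional end-year (spruce sanitary
# scaled up in spread regions under Black), potential regime after
red_black_projection <- function(scenario, obs21, pot, regions, proj_years,
                                 spread) {
  rows <- list()
  for (r in regions$region_id) {
    endy <- regions$end_year[regions$region_id == r]
    cal_years <- proj_years[proj_years <= endy]
    o <- obs21[obs21$region_id == r, ]
    if (spread && isTRUE(regions$spread_flag[regions$region_id == r])) {
      idx <- o$forest_type == "SP" & o$dist_id %in% c("3a", "3b")
      o$demand_tC[idx] <- o$demand_tC[idx] * scenario$spread_factor
    }
    if (length(cal_years) > 0 && nrow(o) > 0) {
      rows[[length(rows) + 1]] <- tidyr::crossing(year = cal_years, o) |>
        dplyr::mutate(provenance = "observed-2021-regime")
    }
    pot_years <- proj_years[proj_years > endy]
    p_r <- pot[pot$region_id == r, ]
    if (length(pot_years) > 0 && nrow(p_r) > 0) {
      rows[[length(rows) + 1]] <- tidyr::crossing(year = pot_years, p_r) |>
        dplyr::mutate(provenance = "potential-regime")
    }
  }
  dplyr::bind_rows(rows)
}

# BlackRep: Black base, spruce sanitary episodes at 2018/2019 average every
# decade, escalated planned demand for non-fir species
blackrep_projection <- function(scenario, obs, obs21, pot, regions,
                                proj_years, years) {
  base <- red_black_projection(scenario, obs21, pot, regions, proj_years,
                               spread = TRUE)
  ep <- episode_years(scenario, years)
  # episode spruce sanitary demand: mean of observed 2018 and 2019
  ep_dem <- obs |>
    dplyr::filter(.data$year %in% c(2018, 2019), .data$forest_type == "SP",
                  .data$dist_id %in% c("3a", "3b")) |>
    dplyr::group_by(.data$region_id, .data$forest_type, .data$dist_id) |>
    dplyr::summarise(demand_tC = sum(.data$demand_tC) / 2, .groups = "drop")
  in_ep <- base$year %in% ep & base$forest_type == "SP" &
    base$dist_id %in% c("3a", "3b")
  base <- base[!in_ep, ]
  ep_rows <- tidyr::crossing(year = ep, ep_dem) |>
    dplyr::mutate(provenance = "recurrence")
  # planned-demand escalation on potential-regime cells, non-fir species
  for (st in scenario$escalation) {
    idx <- base$provenance == "potential-regime" &
      base$year >= st[1] & base$year <= st[2] &
      base$dist_id %in% c("2", "4") & base$forest_type != "AA"
    base$demand_tC[idx] <- base$demand_tC[idx] * st[3]
  }
  dplyr::bind_rows(base, ep_rows)
}

# ---- allocation -------------------------------------------------------------

#' Allocate one year's harvest demand to cohorts
#'
#' Fills demand in sanitary-priority order (3a, 3b before thinning 2, then
#' final cut 4, then standing mortality 6), allocating each
#' (region, forest type, disturbance) cell to eligible, non-retained cohorts
#' oldest-first and clipping to availability. Shortfall is returned as
#' deficit, never an error.
#'
#' @param state cohort state.
#' @param demand demand tibble for a single year (`region_id`,
#'   `forest_type`, `dist_id`, `demand_tC`).
#' @param params dynamics parameters.
#' @param matrices optional pre-built list of disturbance matrices.
#' @param year year stamp for created cohorts.
#' @return list: `state` (after all events), `flux` (summed HarvestFlux per
#'   dist_id and forest type), `deficit` (per demand cell: demand,
#'   allocated, deficit).
#' @export
allocate_harvest <- function(state, demand, params = default_params(),
                             matrices = NULL, year = NA_integer_) {
  if (is.null(matrices)) {
    matrices <- stats::setNames(lapply(DIST_IDS, build_disturbance_matrix),
                                DIST_IDS)
  }
  stages <- c("3a", "3b", "2", "4", "6")
  fluxes <- list()
  deficits <- list()
  for (d in stages) {
    dem <- demand[demand$dist_id == d & demand$demand_tC > 0, ]
    if (nrow(dem) == 0) next
    dem <- dem |>
      dplyr::group_by(.data$region_id, .data$forest_type) |>
      dplyr::summarise(demand_tC = sum(.data$demand_tC), .groups = "drop") |>
      dplyr::mutate(dist_id = d)
    mat <- matrices[[d]]
    elig <- eligible_mask(state, mat, params)
    cap <- if (mat$unit == "tC") {
      products_capacity_ha(state, mat) * state$area
    } else {
      state$merch_stem * state$area   # Dist. 6 demand expressed in t C
    }
    avail <- tibble::tibble(
      idx = which(elig & cap > 0),
      region_id = state$region_id[elig & cap > 0],
      forest_type = state$forest_type[elig & cap > 0],
      age = state$age[elig & cap > 0],
      cap = cap[elig & cap > 0]
    )
    alloc <- avail |>
      dplyr::inner_join(dem[, c("region_id", "forest_type", "demand_tC")],
                        by = c("region_id", "forest_type")) |>
      dplyr::arrange(.data$region_id, .data$forest_type, dplyr::desc(.data$age)) |>
      dplyr::group_by(.data$region_id, .data$forest_type) |>
      dplyr::mutate(take = pmin(.data$cap,
                                pmax(.data$demand_tC -
                                       (cumsum(.data$cap) - .data$cap), 0))) |>
      dplyr::ungroup()
    targets <- numeric(nrow(state))
    targets[alloc$idx] <- alloc$take
    if (mat$unit == "ha") {
      # convert allocated carbon back to area per cohort
      targets[alloc$idx] <- alloc$take /
        pmax(state$merch_stem[alloc$idx], .Machine$double.eps)
    }
    res <- apply_disturbance(state, mat, targets, params, year = year,
                             check_eligible = FALSE)
    fl <- res$flux
    fl$dist_id <- d
    fl$forest_type <- state$forest_type
    fl$region_id <- state$region_id
    fluxes[[d]] <- fl[targets > 0, ]
    state <- res$state
    got <- alloc |>
      dplyr::group_by(.data$region_id, .data$forest_type) |>
      dplyr::summarise(allocated_tC = sum(.data$take), .groups = "drop")
    deficits[[d]] <- dem |>
      dplyr::left_join(got, by = c("region_id", "forest_type")) |>
      dplyr::mutate(allocated_tC = dplyr::coalesce(.data$allocated_tC, 0),
                    allocated_tC = pmin(.data$allocated_tC, .data$demand_tC),
                    deficit_tC = .data$demand_tC - .data$allocated_tC)
  }
  flux <- if (length(fluxes) > 0) {
    dplyr::bind_rows(fluxes) |>
      dplyr::group_by(.data$dist_id, .data$forest_type) |>
      dplyr::summarise(dplyr::across(c("products", "residues", "to_dom",
                                       "to_atmosphere"), sum),
                       .groups = "drop")
  } else {
    tibble::tibble(dist_id = character(), forest_type = character(),
                   products = numeric(), residues = numeric(),
                   to_dom = numeric(), to_atmosphere = numeric())
  }
  deficit <- if (length(deficits) > 0) dplyr::bind_rows(deficits) else
    tibble::tibble(region_id = character(), forest_type = character(),
                   dist_id = character(), demand_tC = numeric(),
                   allocated_tC = numeric(), deficit_tC = numeric())
  list(state = rewrap_state(state, state), flux = flux, deficit = deficit)
}

# ---- species change ---------------------------------------------------------

#' Species-change replanting of cleared areas
#'
#' Replants every pending `CLEARCUT` cohort according to the adaptation
#' rules: spruce-origin areas cleared by sanitary logging are fully replaced
#' (beech 20%, the region's enhanced species 30%, the other of fir/oak 10%,
#' long-lived 20% and short-lived broadleaves 20%); spruce-origin areas
#' after a planned final cut keep 50% spruce and gain fir 10%, beech 20% and
#' long-lived broadleaves 20%; non-spruce origins are replanted to their own
#' type. DOM (and any seed-tree live residual) is inherited per-hectare.
#'
#' @param state cohort state containing `CLEARCUT` rows tagged with
#'   `trigger` and `origin_type`.
#' @param params dynamics parameters.
#' @param year origin-year stamp for the new cohorts.
#' @return the state with cleared areas replanted.
#' @export
apply_species_change <- function(state, params = default_params(),
                                 year = NA_integer_) {
  idx <- which(state$forest_type == "CLEARCUT" & !is.na(state$trigger))
  if (length(idx) == 0) return(state)
  regions <- state_regions(state)
  new_rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    row <- state[i, ]
    comp <- species_change_composition(row$origin_type, row$trigger,
                                       row$region_id, regions)
    new_rows[[k]] <- reforest(row$area, comp, row$region_id,
                              dom_template = row, year = year)
  }
  out <- dplyr::bind_rows(state[-idx, ], dplyr::bind_rows(new_rows))
  rewrap_state(out, state)
}

species_change_composition <- function(origin_type, trigger, region_id,
                                       regions) {
  if (is.na(origin_type) || origin_type != "SP") {
    return(stats::setNames(1, origin_type))
  }
  if (identical(trigger, "final")) {
    return(c(SP = 0.5, AA = 0.1, BE = 0.2, LLB = 0.2))
  }
  enh <- regions$enhanced_species[regions$region_id == region_id]
  if (length(enh) != 1 || !enh %in% c("Oak", "Fir")) {
    stop("region ", region_id, " has no valid enhanced-species entry",
         call. = FALSE)
  }
  if (enh == "Fir") {
    c(BE = 0.2, AA = 0.3, OA = 0.1, LLB = 0.2, SLB = 0.2)
  } else {
    c(BE = 0.2, OA = 0.3, AA = 0.1, LLB = 0.2, SLB = 0.2)
  }
}

# ---- annual driver ----------------------------------------------------------

#' Run one scenario over the horizon
#'
#' The annual sequence is: old-growth retention flagging (Green, from 2025),
#' growth, live-pool turnover, DOM decay, snag-backlog cutting, demand
#' allocation and disturbance application, species-change replanting, and
#' bookkeeping. Deterministic given the inputs; randomness lives only in the
#' synthetic input generators.
#'
#' @param state spun-up `fcbs_state`.
#' @param scenario an [scenario_spec()] (or its name).
#' @param curves yield curve table.
#' @param observed observed harvest tibble 2012-2021.
#' @param params dynamics parameters.
#' @param years horizon (default 2018:2070).
#' @param demand optional pre-built demand schedule (built if NULL).
#' @return an `fcbs_result`: one row per year with IPCC pool stocks and
#'   changes, emissions, harvest, deficits and area totals; detail tables in
#'   attributes `harvest`, `deficit`, `age_structure`, `species`, `nai`, and
#'   the end state in `final_state`.
#' @export
run_scenario <- function(state, scenario, curves, observed,
                         params = default_params(), years = 2018:2070,
                         demand = NULL) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (length(years) == 0) {
    return(new_result(annual_result_row()[0, ], scenario, state))
  }
  curves <- validate_yield_curves(curves)
  if (is.null(demand)) {
    demand <- build_demand_schedule(scenario, state, observed, curves,
                                    params, years)
  }
  matrices <- stats::setNames(lapply(DIST_IDS, build_disturbance_matrix),
                              DIST_IDS)
  st <- state
  st$origin_year[st$forest_type == "SPx" & is.na(st$origin_year)] <-
    as.integer(years[1] - 1)
  regions <- state_regions(state)
  sw_rot <- params$rotation

  rows <- vector("list", length(years))
  detail <- list(harvest = list(), deficit = list(), age = list(),
                 species = list(), nai = list())
  prev_ipcc <- aggregate_ipcc(st)
  cum <- list(growth = 0, products = 0, atm = 0)

  for (k in seq_along(years)) {
    yr <- years[k]
    # retention flagging (Green): healthy old stands set aside
    if (scenario$retention && yr >= scenario$retention_from) {
      conif <- is_softwood(st$forest_type) & st$forest_type %in% GROWING_TYPES
      broad <- !is_softwood(st$forest_type) & st$forest_type %in% GROWING_TYPES
      st$retained <- st$retained |
        (conif & st$age >= scenario$retention_conifer_age) |
        (broad & st$age >= scenario$retention_broadleaf_age)
    }
    c0 <- total_carbon(st)
    st <- grow_annual(st, curves, params)
    growth <- total_carbon(st) - c0
    st <- apply_turnover(st, params)
    dec <- decay_dom(st, params)
    st <- dec$state
    decay_flux <- dec$flux_tC

    # snag backlog: delayed cutting of last year's standing dead spruce
    snag_products <- 0
    ev <- process_snag_backlog(st, yr)
    snag_flux <- NULL
    if (nrow(ev) > 0) {
      targets <- numeric(nrow(st))
      targets[ev$row] <- ev$target_tC
      res <- apply_disturbance(st, matrices[["7"]], targets, params,
                               year = yr, check_eligible = FALSE)
      snag_products <- sum(res$flux$products)
      snag_flux <- tibble::tibble(dist_id = "7", forest_type = "SPx",
                                  products = sum(res$flux$products),
                                  residues = 0,
                                  to_dom = sum(res$flux$to_dom),
                                  to_atmosphere = sum(res$flux$to_atmosphere))
      st <- rewrap_state(res$state, st)
    }

    dem_y <- demand[demand$year == yr, ]
    al <- allocate_harvest(st, dem_y, params, matrices, year = yr)
    st <- al$state
    st <- apply_species_change(st, params, year = yr)
    st <- consolidate_state(st)

    flux <- dplyr::bind_rows(al$flux, snag_flux)
    products <- sum(flux$products) + sum(flux$residues)
    dist_atm <- sum(flux$to_atmosphere)
    cum$growth <- cum$growth + growth
    cum$products <- cum$products + products
    cum$atm <- cum$atm + decay_flux + dist_atm

    ipcc <- aggregate_ipcc(st)
    d_pools <- ipcc - prev_ipcc
    prev_ipcc <- ipcc
    d_total <- sum(d_pools)
    nai_y <- compute_nai(st, curves)

    rows[[k]] <- tibble::tibble(
      year = yr,
      living_biomass_tC = ipcc[["living_biomass"]],
      deadwood_tC = ipcc[["deadwood"]],
      litter_tC = ipcc[["litter"]],
      soil_tC = ipcc[["soil"]],
      d_living = d_pools[["living_biomass"]],
      d_deadwood = d_pools[["deadwood"]],
      d_litter = d_pools[["litter"]],
      d_soil = d_pools[["soil"]],
      d_total_tC = d_total,
      emissions_mtco2 = stock_change_to_emissions(d_total / 1e6),
      growth_tC = growth,
      decay_flux_tC = decay_flux,
      dist_atm_tC = dist_atm,
      products_tC = products,
      demand_tC = sum(dem_y$demand_tC),
      allocated_tC = sum(al$deficit$allocated_tC),
      snag_products_tC = snag_products,
      deficit_tC = sum(al$deficit$deficit_tC),
      area_ha = sum(st$area)
    )
    hv <- flux
    if (nrow(hv) > 0) {
      hv$year <- yr
      hv$volume_mm3 <- (hv$products + hv$residues) /
        density_of(hv$forest_type, params) / 1e6
      detail$harvest[[k]] <- hv
    }
    if (nrow(al$deficit) > 0) {
      dd <- al$deficit
      dd$year <- yr
      detail$deficit[[k]] <- dd
    }
    detail$age[[k]] <- st |>
      tibble::as_tibble() |>
      dplyr::mutate(age_class = pmin(.data$age %/% 10 + 1, 17)) |>
      dplyr::group_by(.data$forest_type, .data$age_class) |>
      dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
      dplyr::mutate(year = yr)
    detail$species[[k]] <- st |>
      tibble::as_tibble() |>
      dplyr::group_by(.data$forest_type) |>
      dplyr::summarise(area = sum(.data$area),
                       merch_tC = sum(.data$merch_stem * .data$area),
                       .groups = "drop") |>
      dplyr::mutate(year = yr)
    if (nrow(nai_y) > 0) {
      nai_y$year <- yr
      detail$nai[[k]] <- nai_y
    }
  }

  result <- dplyr::bind_rows(rows)
  out <- new_result(result, scenario, st)
  attr(out, "harvest") <- dplyr::bind_rows(detail$harvest)
  attr(out, "deficit") <- dplyr::bind_rows(detail$deficit)
  attr(out, "age_structure") <- dplyr::bind_rows(detail$age)
  attr(out, "species") <- dplyr::bind_rows(detail$species)
  attr(out, "nai") <- dplyr::bind_rows(detail$nai)
  attr(out, "mass_balance") <- cum
  attr(out, "initial_carbon") <- total_carbon(state)
  out
}

annual_result_row <- function() {
  tibble::tibble(year = integer(), living_biomass_tC = numeric(),
                 deadwood_tC = numeric(), litter_tC = numeric(),
                 soil_tC = numeric(), d_living = numeric(),
                 d_deadwood = numeric(), d_litter = numeric(),
                 d_soil = numeric(), d_total_tC = numeric(),
                 emissions_mtco2 = numeric(), growth_tC = numeric(),
                 decay_flux_tC = numeric(), dist_atm_tC = numeric(),
                 products_tC = numeric(), demand_tC = numeric(),
                 allocated_tC = numeric(), snag_products_tC = numeric(),
                 deficit_tC = numeric(), area_ha = numeric())
}

new_result <- function(df, scenario, final_state) {
  structure(df, scenario = scenario, final_state = final_state,
            class = c("fcbs_result", class(tibble::tibble())))
}

#' @export
print.fcbs_result <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<fcbs_result %s> %d years\n",
              if (is.null(sc)) "?" else sc$name, nrow(x)))
  NextMethod()
}

# merge cohorts sharing all classification keys (area-weighted pools)
consolidate_state <- function(state) {
  if (nrow(state) <= 1) return(state)
  merged <- state |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$region_id, .data$forest_type, .data$age,
                    .data$retained, .data$trigger, .data$origin_type,
                    .data$origin_year) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(ALL_POOLS),
                    ~ if (sum(area) > 0) sum(.x * area) / sum(area) else 0),
      area = sum(.data$area),
      .groups = "drop"
    )
  rewrap_state(merged, state)
}
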