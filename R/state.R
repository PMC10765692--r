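# Forest state: inventory ingestion, validation, serialization, and the
# dead-organic-matter spinup that establishes the initial condition.

#' Load a forest inventory into a simulation state
#'
#' Builds the cohort state from a stand table (region x forest type x age:
#' area and merchantable volume) and a region metadata table. Live pools are
#' initialized from merchantable volume via the carbon-density conversion;
#' for standing-dead `SPx` stands the volume is loaded into the snag stem
#' pool instead (all merchantable carbon of a dead stand is snag carbon).
#' DOM pools start at zero pending [spinup_dom()].
#'
#' @param stand_table data frame with columns `region_id`, `forest_type`,
#'   `age`, `area_ha`, `merch_volume_m3ha`.
#' @param region_table data frame with columns `region_id`, `altitude_m`,
#'   `enhanced_species` (`"Oak"` or `"Fir"`), `end_year`, `spread_flag`
#'   (and optionally `name`).
#' @param params dynamics parameters.
#' @return a cohort tibble of class `fcbs_state` with attributes `regions`
#'   (the region table) and `validation` (a tibble of row-level notes, empty
#'   when the input is clean). Area shares by forest type are attached as
#'   attribute `shares`.
#' @export
#' @examples
#' inv <- generate_inventory(synth_config(), seed = 1)
#' st <- load_inventory(inv$stands, inv$regions)
#' sum(st$area)
load_inventory <- function(stand_table, region_table, params = default_params()) {
  need <- c("region_id", "forest_type", "age", "area_ha", "merch_volume_m3ha")
  miss <- setdiff(need, names(stand_table))
  if (length(miss) > 0) stop("stand table missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  need_r <- c("region_id", "altitude_m", "enhanced_species", "end_year", "spread_flag")
  miss_r <- setdiff(need_r, names(region_table))
  if (length(miss_r) > 0) stop("region table missing column(s): ",
                               paste(miss_r, collapse = ", "), call. = FALSE)
  st <- tibble::as_tibble(stand_table)
  rt <- tibble::as_tibble(region_table)

  bad_ft <- which(!st$forest_type %in% FOREST_TYPES)
  if (length(bad_ft) > 0) {
    stop(sprintf("unknown forest_type %s in stand table row(s) %s",
                 paste(unique(st$forest_type[bad_ft]), collapse = ", "),
                 paste(bad_ft, collapse = ", ")), call. = FALSE)
  }
  bad_num <- which(st$area_ha < 0 | st$merch_volume_m3ha < 0 | st$age < 0)
  if (length(bad_num) > 0) {
    stop("negative area, volume or age in stand table row(s) ",
         paste(bad_num, collapse = ", "), call. = FALSE)
  }
  bad_reg <- which(!st$region_id %in% rt$region_id)
  if (length(bad_reg) > 0) {
    stop(sprintf("region %s referenced in stand table row(s) %s but not described",
                 paste(unique(st$region_id[bad_reg]), collapse = ", "),
                 paste(bad_reg, collapse = ", ")), call. = FALSE)
  }

  cohorts <- empty_cohorts()
  if (nrow(st) > 0) {
    cohorts <- tibble::tibble(
      region_id = as.character(st$region_id),
      forest_type = st$forest_type,
      age = as.integer(st$age),
      area = as.numeric(st$area_ha),
      retained = FALSE,
      trigger = ifelse(st$forest_type == "CLEARCUT", "sanitary", NA_character_),
      origin_type = ifelse(st$forest_type %in% c("CLEARCUT", "SPx"),
                           "SP", NA_character_),
      origin_year = NA_integer_
    )
    for (p in ALL_POOLS) cohorts[[p]] <- 0
    live_idx <- st$forest_type %in% GROWING_TYPES
    if (any(live_idx)) {
      lv <- volume_to_carbon(st$merch_volume_m3ha[live_idx],
                             st$forest_type[live_idx], params)
      for (p in LIVE_POOLS) cohorts[[p]][live_idx] <- lv[[p]]
    }
    spx <- st$forest_type == "SPx"
    if (any(spx)) {
      cohorts$snag_stem[spx] <-
        st$merch_volume_m3ha[spx] * density_of("SPx", params)
    }
  }
  validation <- tibble::tibble(row = integer(), message = character())
  zero_area <- which(st$area_ha == 0)
  if (length(zero_area) > 0) {
    validation <- tibble::add_row(validation, row = zero_area,
                                  message = "zero-area cohort")
  }
  shares <- if (nrow(cohorts) > 0) {
    cohorts |>
      dplyr::group_by(forest_type) |>
      dplyr::summarise(area = sum(area), .groups = "drop") |>
      dplyr::mutate(share = area / sum(area))
  } else {
    tibble::tibble(forest_type = character(), area = numeric(), share = numeric())
  }
  new_forest_state(cohorts, rt, validation = validation, shares = shares)
}

new_forest_state <- function(cohorts, regions, validation = NULL, shares = NULL) {
  structure(cohorts,
            regions = regions,
            validation = validation,
            shares = shares,
            class = c("fcbs_state", class(tibble::tibble())))
}

#' @export
print.fcbs_state <- function(x, ...) {
  cat(sprintf("<fcbs_state> %d cohorts, %.0f kha, %d regions\n",
              nrow(x), sum(x$area) / 1e3,
              length(unique(x$region_id))))
  NextMethod()
}

#' Region metadata of a state
#' @param state an `fcbs_state`.
#' @return the region tibble attached at load time.
#' @export
state_regions <- function(state) attr(state, "regions")

# rebuild the class/attrs after dplyr surgery on the cohort table
rewrap_state <- function(cohorts, template) {
  new_forest_state(tibble::as_tibble(cohorts), attr(template, "regions"),
                   validation = attr(template, "validation"),
                   shares = attr(template, "shares"))
}

#' Serialize a state to a plain cohort table
#'
#' One row per cohort with the stand-table columns (merchantable volume
#' recovered from stem carbon) plus all pool columns, suitable for
#' `write.csv`. Reloading the serialized table with [load_inventory()]
#' reproduces the same load-level state.
#'
#' @param state an `fcbs_state`.
#' @param params dynamics parameters (for the inverse volume conversion).
#' @return tibble.
#' @export
serialize_state <- function(state, params = default_params()) {
  vol <- carbon_to_volume(state$merch_stem, state$forest_type, params)
  vol[state$forest_type == "SPx"] <-
    carbon_to_volume(state$snag_stem[state$forest_type == "SPx"], "SPx", params)
  tibble::tibble(
    region_id = state$region_id,
    forest_type = state$forest_type,
    age = state$age,
    area_ha = state$area,
    merch_volume_m3ha = vol
  ) |>
    dplyr::bind_cols(state[ALL_POOLS])
}

# ---- spinup -----------------------------------------------------------------

#' Initialize DOM pools by spinup
#'
#' Brings each cohort's dead-organic-matter pools to the quasi-equilibrium of
#' a historic disturbance-return regime: repeated cycles of growth to the
#' rotation age (with annual turnover and decay) terminated by a clear-cut
#' with slash burn (Dist. 5), iterated until the belowground slow pool
#' changes by less than `tolerance` (relative) between cycles. The converged
#' stand is then regrown and each cohort receives the DOM profile at its
#' inventory age. Live pools are left exactly as loaded from inventory
#' volume.
#'
#' Standing-dead (`SPx`) cohorts receive the spruce ground-DOM profile at
#' their age on top of their inventory snag carbon; clearcut cohorts receive
#' the spruce age-0 (post-disturbance) profile.
#'
#' @param state an `fcbs_state` from [load_inventory()].
#' @param curves yield curve table.
#' @param params dynamics parameters.
#' @param tolerance relative change of the belowground slow pool between
#'   cycles at which iteration stops (default 1e-6).
#' @param max_cycles iteration cap; exceeding it is an error reporting the
#'   last residual.
#' @return the state with DOM pools filled.
#' @export
spinup_dom <- function(state, curves, params = default_params(),
                       tolerance = 1e-6, max_cycles = 200) {
  curves <- validate_yield_curves(curves)
  out <- state
  types <- unique(state$forest_type)
  grow_types <- intersect(types, GROWING_TYPES)
  need_sp <- any(types %in% c("SPx", "CLEARCUT"))
  profile_types <- union(grow_types, if (need_sp) "SP" else character())
  profiles <- list()
  for (ft in profile_types) {
    ages_ft <- state$age[state$forest_type %in%
                           c(ft, if (ft == "SP") c("SPx", "CLEARCUT"))]
    max_age <- max(c(ages_ft, 0))
    profiles[[ft]] <- spinup_profile(ft, curves, params, tolerance,
                                     max_cycles, max_age)
  }
  for (ft in types) {
    idx <- which(state$forest_type == ft)
    prof_ft <- if (ft %in% c("SPx", "CLEARCUT")) "SP" else ft
    prof <- profiles[[prof_ft]]
    if (is.null(prof)) next
    ages <- if (ft == "CLEARCUT") rep(0L, length(idx)) else state$age[idx]
    ages <- pmin(ages, nrow(prof) - 1L)
    for (p in DOM_POOLS) {
      add <- prof[ages + 1L, p]
      if (p == "snag_stem" && ft == "SPx") {
        out$snag_stem[idx] <- out$snag_stem[idx] + add
      } else {
        out[[p]][idx] <- add
      }
    }
  }
  rewrap_state(out, state)
}

# DOM profile by age for one forest type: matrix (max_age+1) x 9 DOM pools,
# row a+1 = DOM after growing a years from the post-Dist.5 fixed point.
spinup_profile <- function(ft, curves, params, tolerance, max_cycles, max_age) {
  rot <- unname(params$rotation[ft])
  if (is.na(rot)) rot <- 100
  horizon <- max(rot, max_age)
  sw <- is_softwood(ft)
  cls <- if (sw) "softwood" else "hardwood"
  dv <- yield_increment(curves, rep(ft, horizon), 0:(horizon - 1))
  merch_inc <- dv * density_of(ft, params)
  comp_pools <- setdiff(LIVE_POOLS, "merch_stem")
  comp_ratio <- vapply(comp_pools, function(p) params$ratios[[cls]][[p]],
                       numeric(1))
  tf <- vapply(LIVE_POOLS, function(p) unname(params$turnover[[p]]$frac[cls]),
               numeric(1))
  dest <- lapply(LIVE_POOLS, function(p) params$turnover[[p]]$dest)
  rates <- vapply(DOM_POOLS, function(p) params$decay[[p]]$rate, numeric(1))
  atms <- vapply(DOM_POOLS, function(p) params$decay[[p]]$atm, numeric(1))
  downs <- vapply(DOM_POOLS, function(p) params$decay[[p]]$down %||% NA_character_,
                  character(1))
  m5 <- build_disturbance_matrix("5")

  step <- function(pools, a) {
    # growth: extend the stem, regrow components to allometric proportion
    pools["merch_stem"] <- pools["merch_stem"] + merch_inc[a + 1]
    pools[comp_pools] <- pmax(pools[comp_pools],
                              comp_ratio * pools[["merch_stem"]])
    moved <- pools[LIVE_POOLS] * tf
    pools[LIVE_POOLS] <- pools[LIVE_POOLS] - moved
    for (i in seq_along(LIVE_POOLS)) {
      d <- dest[[i]]
      pools[names(d)] <- pools[names(d)] + moved[i] * d
    }
    loss <- pools[DOM_POOLS] * rates
    pools[DOM_POOLS] <- pools[DOM_POOLS] - loss
    resid <- loss * (1 - atms)
    for (j in which(resid > 0 & !is.na(downs))) {
      pools[downs[j]] <- pools[downs[j]] + resid[j]
    }
    pools
  }
  dist5 <- function(pools) {
    tfr <- m5$transfers
    for (src in unique(tfr$source)) {
      moved <- pools[src]
      pools[src] <- 0
      sub <- tfr[tfr$source == src, ]
      for (i in seq_len(nrow(sub))) {
        d <- sub$dest[i]
        if (!d %in% c("products", "atmosphere", "residues")) {
          pools[d] <- pools[d] + moved * sub$fraction[i]
        }
      }
    }
    pools
  }

  pools <- stats::setNames(numeric(length(ALL_POOLS)), ALL_POOLS)
  prev_slow <- NA_real_
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    pools[LIVE_POOLS] <- 0
    for (a in 0:(rot - 1)) pools <- step(pools, a)
    pools <- dist5(pools)
    slow <- pools["bg_slow"]
    if (!is.na(prev_slow)) {
      resid <- abs(slow - prev_slow) / max(prev_slow, .Machine$double.eps)
      if (resid < tolerance) { converged <- TRUE; break }
    }
    prev_slow <- slow
  }
  if (!converged && max_cycles > 1) {
    stop(sprintf("spinup did not converge for %s within %d cycles (last relative residual %.3g)",
                 ft, max_cycles, resid), call. = FALSE)
  }
  prof <- matrix(0, nrow = horizon + 1, ncol = length(DOM_POOLS),
                 dimnames = list(NULL, DOM_POOLS))
  pools[LIVE_POOLS] <- 0
  prof[1, ] <- pools[DOM_POOLS]
  for (a in 0:(horizon - 1)) {
    pools <- step(pools, a)
    prof[a + 2, ] <- pools[DOM_POOLS]
  }
  prof
}
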