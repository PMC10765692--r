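# Shared fixtures: single-cohort builders, tiny parameter sets, and a cached
# default-scale simulation used by the behavioural tests.

# a one-region metadata table
fixture_regions <- function(enhanced = "Fir", end_year = 2030,
                            spread = TRUE, id = "R01") {
  tibble::tibble(region_id = id, name = id, altitude_m = 550,
                 enhanced_species = enhanced, end_year = end_year,
                 spread_flag = spread)
}

# build a state with one cohort directly from pool values
fixture_cohort <- function(forest_type = "SP", age = 50, area = 1,
                           pools = list(), region_id = "R01",
                           regions = fixture_regions(id = region_id)) {
  row <- tibble::tibble(region_id = region_id, forest_type = forest_type,
                        age = as.integer(age), area = area, retained = FALSE,
                        trigger = NA_character_, origin_type = NA_character_,
                        origin_year = NA_integer_)
  for (p in ALL_POOLS) row[[p]] <- 0
  for (p in names(pools)) row[[p]] <- pools[[p]]
  fcbs:::new_forest_state(row, regions)
}

# a piecewise-linear yield curve with constant slope up to a plateau
fixture_curve <- function(forest_type = "SP", slope = 8, plateau_age = 100,
                          max_age = 200) {
  ages <- c(0, plateau_age, max_age)
  tibble::tibble(forest_type = forest_type, age = ages,
                 volume_m3ha = c(0, slope * plateau_age, slope * plateau_age))
}

# params with all turnover and decay switched off (inert dynamics)
inert_params <- function(...) {
  p <- default_params()
  for (nm in names(p$turnover)) {
    p$turnover[[nm]]$frac[] <- 0
  }
  for (nm in names(p$decay)) {
    p$decay[[nm]]$rate <- 0
  }
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

# random positive cohort for mass-balance property tests
random_cohort <- function(ft, age = 90, area = NULL) {
  pools <- stats::setNames(as.list(stats::runif(length(ALL_POOLS), 0, 50)),
                           ALL_POOLS)
  if (ft == "SPx") pools$merch_stem <- 0
  fixture_cohort(ft, age = age, area = if (is.null(area))
    stats::runif(1, 0.5, 100) else area, pools = pools)
}

# cached full-scale default simulation shared by behavioural and acceptance
# tests (built once per test run)
default_sim_env <- new.env(parent = emptyenv())

default_simulation <- function() {
  if (!is.null(default_sim_env$runs)) return(default_sim_env)
  cfg <- synth_config()
  ds <- generate_dataset(cfg, seed = 42)
  st <- load_inventory(ds$stands, ds$regions)
  st <- spinup_dom(st, ds$curves)
  runs <- lapply(c(Green = "Green", Red = "Red", Black = "Black",
                   BlackRep = "BlackRep"), function(sc) {
    run_scenario(st, sc, ds$curves, ds$observed)
  })
  default_sim_env$config <- cfg
  default_sim_env$dataset <- ds
  default_sim_env$state <- st
  default_sim_env$runs <- runs
  default_sim_env
}
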