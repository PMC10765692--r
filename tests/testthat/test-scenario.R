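# Demand construction, allocation, species change and the annual driver.

test_that("the Gaussian pulse fitter recovers known parameters", {
  yrs <- 2012:2021
  clean <- tibble::tibble(year = yrs,
                          volume = 35 * exp(-(yrs - 2020)^2 / (2 * 2^2)))
  f <- fit_calamity_curve(clean)
  expect_equal(f$amplitude, 35, tolerance = 1e-6)
  expect_equal(f$peak_year, 2020, tolerance = 1e-6)
  expect_equal(f$width, 2, tolerance = 1e-6)
  expect_false(f$degenerate)

  # symmetry pins the peak year
  sym <- tibble::tibble(year = 2015:2023,
                        volume = 20 * exp(-(2015:2023 - 2019)^2 / 10))
  expect_equal(fit_calamity_curve(sym)$peak_year, 2019, tolerance = 1e-6)

  # an all-zero series is a flagged zero-amplitude fit
  z <- fit_calamity_curve(tibble::tibble(year = yrs, volume = 0))
  expect_true(z$degenerate)
  expect_equal(z$amplitude, 0)

  # 5% noise, fixed seed: parameters recovered within 10%
  set.seed(99)
  noisy <- clean
  noisy$volume <- pmax(noisy$volume + stats::rnorm(10, 0, 0.05 * 35), 0)
  fn <- fit_calamity_curve(noisy)
  expect_lt(abs(fn$amplitude / 35 - 1), 0.10)
  expect_lt(abs(fn$peak_year - 2020), 0.5)
  expect_lt(abs(fn$width / 2 - 1), 0.10)
})

test_that("demand extrapolation declines from the peak and respects floors", {
  fits <- tibble::tibble(region_id = "R01", amplitude = 30, peak_year = 2020,
                         width = 2, resid_norm = 0, degenerate = FALSE)
  ex <- extrapolate_demand(fits, 2022:2030, floor = 0)
  expect_equal(ex$volume[ex$year == 2026], 30 * exp(-4.5), tolerance = 1e-12)
  expect_true(all(diff(ex$volume) < 0))
  expect_true(all(ex$volume >= 0))

  zf <- tibble::tibble(region_id = "R01", amplitude = 0, peak_year = 2020,
                       width = 2, resid_norm = 0, degenerate = TRUE)
  exf <- extrapolate_demand(zf, 2022:2030, floor = c(R01 = 4))
  expect_true(all(exf$volume == 4))
})

test_that("exponential share interpolation hits its anchors", {
  s0 <- c(a = 0.8, b = 0.2)
  s1 <- c(a = 0.2, b = 0.8)
  expect_equal(interpolate_shares(s0, s0, 2026), s0)
  expect_equal(interpolate_shares(s0, s1, 2031), s1, tolerance = 1e-12)
  # midpoint: geometric mean, then renormalized
  gm <- sqrt(s0 * s1)
  expect_equal(interpolate_shares(s0, s1, 2026), gm / sum(gm),
               tolerance = 1e-12)
  # a vanished start share is floored, not an error
  s0z <- c(a = 1, b = 0)
  out <- interpolate_shares(s0z, s1, 2026)
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1)
})

test_that("sustainable potential amortizes eligible stock", {
  expect_equal(nrow(sustainable_potential(
    fixture_cohort("SP", age = 10, area = 0), fixture_curve())), 0)

  # one 100-ha cohort with 50 t C/ha eligible merch over a 20-year window
  st <- fixture_cohort("SP", age = 150, area = 100,
                       pools = list(merch_stem = 50))
  pot <- sustainable_potential(st, fixture_curve(), window = 20)
  expect_equal(pot$final_tC, 250)
  expect_equal(pot$total_tC, 250)

  # a young stand below both eligibility windows has no potential
  young <- fixture_cohort("SP", age = 10, area = 100,
                          pools = list(merch_stem = 5))
  pot_y <- sustainable_potential(young, fixture_curve(), window = 20)
  expect_equal(pot_y$total_tC, 0)
})

test_that("potential grows year over year for an undisturbed growing estate", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 8)
  st <- load_inventory(ds$stands, ds$regions)
  p <- default_params()
  totals <- numeric(6)
  for (i in 1:6) {
    totals[i] <- sum(sustainable_potential(st, ds$curves, p)$total_tC)
    st <- grow_annual(st, ds$curves, p)
  }
  expect_true(all(diff(totals) >= 0))
})

test_that("all scenarios share the observed 2018-2021 demand verbatim", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 4)
  st <- spinup_dom(load_inventory(ds$stands, ds$regions), ds$curves)
  p <- default_params()
  dems <- lapply(c("Green", "Red", "Black", "BlackRep"), function(s) {
    build_demand_schedule(scenario_spec(s), st, ds$observed, ds$curves, p) |>
      dplyr::filter(year <= 2021) |>
      dplyr::arrange(year, region_id, forest_type, dist_id)
  })
  for (i in 2:4) {
    expect_equal(dems[[i]]$demand_tC, dems[[1]]$demand_tC)
    expect_equal(dems[[i]]$dist_id, dems[[1]]$dist_id)
  }
  # and they equal the observed series converted to carbon
  obs18 <- ds$observed[ds$observed$year == 2018, ]
  d18 <- dems[[1]][dems[[1]]$year == 2018, ]
  expect_equal(sum(d18$demand_tC),
               sum(obs18$volume_mm3 * 1e6 *
                     fcbs:::density_of(obs18$forest_type, p)))
})

test_that("scenario demand rules shape the projection period", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 4)
  st <- spinup_dom(load_inventory(ds$stands, ds$regions), ds$curves)
  p <- default_params()

  # BlackRep episode years demand the 2018/2019 mean spruce sanitary harvest
  dbr <- build_demand_schedule(scenario_spec("BlackRep"), st, ds$observed,
                               ds$curves, p)
  obs <- ds$observed |>
    dplyr::mutate(demand_tC = volume_mm3 * 1e6 *
                    fcbs:::density_of(forest_type, p))
  want <- obs |>
    dplyr::filter(year %in% c(2018, 2019), forest_type == "SP",
                  dist_id %in% c("3a", "3b")) |>
    dplyr::summarise(x = sum(demand_tC) / 2) |>
    dplyr::pull(x)
  got <- dbr |>
    dplyr::filter(year == 2048, forest_type == "SP",
                  dist_id %in% c("3a", "3b")) |>
    dplyr::summarise(x = sum(demand_tC)) |>
    dplyr::pull(x)
  expect_equal(got, want, tolerance = 1e-9)
  expect_true(all(dbr$provenance[dbr$year == 2048 & dbr$forest_type == "SP" &
                                   dbr$dist_id == "3a"] == "recurrence"))

  # escalation: planned non-fir demand in 2050 is 1.15x its potential level
  # (compared within a region already in the potential regime at both years)
  regions0 <- fcbs:::region_template(cfg$n_regions)
  r_pot <- regions0$region_id[regions0$end_year <= 2035][1]
  base_cell <- dbr |>
    dplyr::filter(year == 2036, dist_id == "4", forest_type == "BE",
                  region_id == r_pot, provenance == "potential-regime")
  esc_cell <- dbr |>
    dplyr::filter(year == 2050, dist_id == "4", forest_type == "BE",
                  region_id == r_pot)
  expect_equal(sum(esc_cell$demand_tC), 1.15 * sum(base_cell$demand_tC),
               tolerance = 1e-9)

  # Black: spruce sanitary demand in spread regions is 1.2x the 2021 level
  dbk <- build_demand_schedule(scenario_spec("Black"), st, ds$observed,
                               ds$curves, p)
  regions <- fcbs:::region_template(cfg$n_regions)
  r_spread <- regions$region_id[regions$spread_flag][1]
  lvl21 <- obs |>
    dplyr::filter(year == 2021, region_id == r_spread, forest_type == "SP",
                  dist_id == "3a") |>
    dplyr::pull(demand_tC)
  lvl23 <- dbk |>
    dplyr::filter(year == 2023, region_id == r_spread, forest_type == "SP",
                  dist_id == "3a") |>
    dplyr::pull(demand_tC)
  expect_equal(lvl23, 1.2 * lvl21, tolerance = 1e-9)

  # Green settles at min(target, potential) in the potential regime
  dg <- build_demand_schedule(scenario_spec("Green"), st, ds$observed,
                              ds$curves, p)
  pot <- sustainable_potential(st, ds$curves, p)
  pot_mm3 <- sum(pot$total_tC / fcbs:::density_of(pot$forest_type, p)) / 1e6
  g35 <- dg[dg$year == 2035, ]
  # include the sanitary head-room added on top of planned potential
  g35_mm3 <- sum(g35$demand_tC / fcbs:::density_of(g35$forest_type, p)) / 1e6
  expect_lte(g35_mm3, 17 + 1e-9)
  if (pot_mm3 >= 17) expect_equal(g35_mm3, 17, tolerance = 0.02)
})

test_that("allocation clips to availability and accounts deficits exactly", {
  p <- default_params()
  st <- fixture_cohort("SP", age = 100, area = 1,
                       pools = list(merch_stem = 60))
  dem0 <- tibble::tibble(region_id = "R01", forest_type = "SP",
                         dist_id = "3a", demand_tC = 0)
  res0 <- allocate_harvest(st, dem0, p)
  expect_equal(nrow(res0$flux), 0)
  expect_equal(sum(res0$deficit$deficit_tC), 0)

  dem <- dem0
  dem$demand_tC <- 100
  res <- allocate_harvest(st, dem, p, year = 2020)
  expect_equal(res$deficit$allocated_tC, 60)
  expect_equal(res$deficit$deficit_tC, 40)
  expect_equal(res$deficit$allocated_tC + res$deficit$deficit_tC,
               res$deficit$demand_tC)

  # sanitary priority: salvage is served before thinning empties the stock
  st2 <- fixture_cohort("SP", age = 40, area = 1,
                        pools = list(merch_stem = 50))
  dem2 <- tibble::tibble(region_id = "R01", forest_type = "SP",
                         dist_id = c("3a", "2"), demand_tC = c(45, 45))
  res2 <- allocate_harvest(st2, dem2, p, year = 2020)
  alloc <- res2$deficit
  expect_equal(alloc$allocated_tC[alloc$dist_id == "3a"], 45)
  expect_lt(alloc$allocated_tC[alloc$dist_id == "2"], 45)
})

test_that("retained old growth is exempt from felling even under unmet demand", {
  p <- default_params()
  st <- fixture_cohort("SP", age = 130, area = 10,
                       pools = list(merch_stem = 80))
  st$retained <- TRUE
  for (d in c("3a", "4")) {
    dem <- tibble::tibble(region_id = "R01", forest_type = "SP",
                          dist_id = d, demand_tC = 100)
    res <- allocate_harvest(st, dem, p, year = 2030)
    expect_equal(res$deficit$allocated_tC, 0)
    expect_equal(res$deficit$deficit_tC, 100)
    expect_false(any(res$state$forest_type == "CLEARCUT"))
  }
})

test_that("species change replants by trigger, origin and region", {
  p <- default_params()
  mk_clear <- function(trigger, origin, enhanced) {
    st <- fixture_cohort("CLEARCUT", age = 0, area = 100,
                         regions = fixture_regions(enhanced = enhanced))
    st$trigger <- trigger
    st$origin_type <- origin
    st
  }
  out <- apply_species_change(mk_clear("sanitary", "SP", "Fir"), p)
  comp <- stats::setNames(out$area, out$forest_type)
  expect_equal(comp[c("AA", "OA", "BE", "LLB", "SLB")],
               c(AA = 30, OA = 10, BE = 20, LLB = 20, SLB = 20))

  out2 <- apply_species_change(mk_clear("final", "SP", "Fir"), p)
  comp2 <- stats::setNames(out2$area, out2$forest_type)
  expect_equal(comp2[c("SP", "AA", "BE", "LLB")],
               c(SP = 50, AA = 10, BE = 20, LLB = 20))

  out3 <- apply_species_change(mk_clear("sanitary", "PI", "Oak"), p)
  expect_equal(out3$forest_type, "PI")
  expect_equal(out3$area, 100)
})

test_that("the driver conserves area and handles an empty horizon", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 4)
  st <- spinup_dom(load_inventory(ds$stands, ds$regions), ds$curves)

  empty <- run_scenario(st, "Green", ds$curves, ds$observed,
                        years = integer())
  expect_equal(nrow(empty), 0)

  res <- run_scenario(st, "Red", ds$curves, ds$observed, years = 2018:2032)
  expect_true(all(abs(res$area_ha - sum(st$area)) < 1e-6 * sum(st$area)))
  expect_equal(res$allocated_tC + res$deficit_tC - res$demand_tC,
               rep(0, nrow(res)), tolerance = 1e-6)
})

test_that("a demand-free plateau forest trends to carbon equilibrium", {
  p <- default_params()
  curve <- fixture_curve(slope = 8, plateau_age = 60)
  st <- fixture_cohort("SP", age = 120, area = 10,
                       pools = as.list(volume_to_carbon(480, "SP", p)))
  st <- spinup_dom(st, curve, p)
  obs <- tibble::tibble(year = integer(), region_id = character(),
                        forest_type = character(), dist_id = character(),
                        volume_mm3 = numeric())
  dem <- tibble::tibble(year = integer(), region_id = character(),
                        forest_type = character(), dist_id = character(),
                        demand_tC = numeric(), provenance = character())
  res <- run_scenario(st, "Red", curve, obs, p, years = 2018:2057,
                      demand = dem)
  # annual net change equals growth minus decay flux, and shrinks towards
  # the spinup equilibrium
  expect_equal(res$d_total_tC, res$growth_tC - res$decay_flux_tC,
               tolerance = 1e-9)
  late <- abs(res$d_total_tC[30:40])
  expect_lt(mean(late), max(abs(res$d_total_tC[1:5])))
  expect_lt(mean(late) / fcbs:::total_carbon(st), 5e-3)
})
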