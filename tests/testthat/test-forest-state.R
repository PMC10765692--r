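# Inventory loading, validation, serialization and the DOM spinup.

table5_stands <- function() {
  tibble::tibble(
    region_id = "R01",
    forest_type = c("SP", "PI", "BE", "OA", "LLB", "SLB", "AA",
                    "CLEARCUT", "SPx"),
    age = c(60, 60, 80, 80, 70, 40, 60, 0, 80),
    area_ha = c(1293, 528, 225, 194, 159, 139, 37, 31, 5) * 1000,
    merch_volume_m3ha = c(350, 280, 300, 250, 220, 150, 320, 0, 400)
  )
}

test_that("loading a national-totals table reproduces the summed area", {
  st <- load_inventory(table5_stands(), fixture_regions())
  # the nine reference rows sum to 2 611 kha (their printed total rounds to
  # 2 610); the loader reports against the true sum
  expect_equal(sum(st$area), 2611e3)
  shares <- attr(st, "shares")
  expect_equal(shares$share[shares$forest_type == "PI"], 528 / 2611,
               tolerance = 1e-12)
  expect_equal(round(100 * shares$share[shares$forest_type == "PI"], 1), 20.2)
  # standing-dead spruce loads its volume as snag carbon, not live
  spx <- st[st$forest_type == "SPx", ]
  expect_equal(spx$merch_stem, 0)
  expect_gt(spx$snag_stem, 0)
})

test_that("degenerate and invalid stand tables are handled row-wise", {
  empty <- table5_stands()[0, ]
  st <- load_inventory(empty, fixture_regions())
  expect_equal(nrow(st), 0)
  expect_equal(sum(st$area), 0)

  bad <- table5_stands()
  bad$forest_type[3] <- "XX"
  expect_error(load_inventory(bad, fixture_regions()), "XX.*row.* 3")

  neg <- table5_stands()
  neg$area_ha[2] <- -1
  expect_error(load_inventory(neg, fixture_regions()), "row.* 2")

  orphan <- table5_stands()
  orphan$region_id[5] <- "R99"
  expect_error(load_inventory(orphan, fixture_regions()), "R99")
})

test_that("reloading a serialized state is idempotent at the load level", {
  st <- load_inventory(table5_stands(), fixture_regions())
  ser <- serialize_state(st)
  st2 <- load_inventory(ser, fixture_regions())
  expect_equal(st2$area, st$area)
  expect_equal(st2$merch_stem, st$merch_stem, tolerance = 1e-12)
  expect_equal(st2$forest_type, st$forest_type)
})

test_that("spinup fills DOM, preserves live pools and total area", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 3)
  st <- load_inventory(ds$stands, ds$regions)
  sp <- spinup_dom(st, ds$curves)
  expect_equal(sum(sp$area), sum(st$area))
  expect_equal(sp$merch_stem, st$merch_stem)
  expect_equal(sp$foliage, st$foliage)
  expect_true(all(sp$bg_slow > 0))
  expect_true(all(sp$ag_slow > 0))
})

test_that("memoryless decay collapses the spinup to single-cycle inputs", {
  # with every decay rate 1 and full atmosphere release, DOM carries no
  # memory between years, so the fixed point is reached immediately
  p <- default_params()
  for (nm in names(p$decay)) p$decay[[nm]] <- list(rate = 1, atm = 1,
                                                   down = NA_character_)
  st <- fixture_cohort("SP", age = 10, area = 1,
                       pools = as.list(volume_to_carbon(80, "SP", p)))
  curve <- fixture_curve(slope = 8)
  sp1 <- spinup_dom(st, curve, p, tolerance = 1e-9, max_cycles = 5)
  sp2 <- spinup_dom(st, curve, p, tolerance = 1e-3, max_cycles = 5)
  expect_equal(as.numeric(sp1[1, DOM_POOLS]), as.numeric(sp2[1, DOM_POOLS]),
               tolerance = 1e-12)
})

test_that("the slow-pool fixed point matches an independent recurrence", {
  # isolate one chain: coarse roots turn over into bg_fast which decays with
  # full atmospheric release; everything else is inert
  p <- inert_params()
  p$turnover$coarse_roots <- list(frac = c(softwood = 0.5, hardwood = 0.5),
                                  dest = c(bg_fast = 1))
  r <- 0.2
  p$decay$bg_fast <- list(rate = r, atm = 1, down = NA_character_)
  p$rotation["SP"] <- 40
  slope <- 8
  curve <- fixture_curve(slope = slope, plateau_age = 100)
  st <- fixture_cohort("SP", age = 0, area = 1)
  sp <- spinup_dom(st, curve, p, tolerance = 1e-10, max_cycles = 500)

  # independent oracle: replay the annual recurrence directly
  ratio <- p$ratios$softwood[["coarse_roots"]]
  dens <- p$density[["softwood"]]
  S <- 0
  for (cycle in 1:300) {
    merch <- 0
    coarse <- 0
    for (a in 0:39) {
      merch <- merch + slope * dens
      coarse <- max(coarse, ratio * merch)       # allometric regrowth
      moved <- 0.5 * coarse
      coarse <- coarse - moved
      S <- (S + moved) * (1 - r)
    }
    S <- S + coarse                               # clear-cut root transfer
  }
  expect_equal(sp$bg_fast[1], S, tolerance = 1e-6)
})

test_that("spinup is stable against the convergence tolerance", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 3)
  st <- load_inventory(ds$stands, ds$regions)
  a <- spinup_dom(st, ds$curves, tolerance = 1e-6)
  b <- spinup_dom(st, ds$curves, tolerance = 1e-9)
  for (pool in DOM_POOLS) {
    expect_equal(a[[pool]], b[[pool]], tolerance = 1e-5)
  }
})

test_that("non-convergence within the cycle cap is an error", {
  cfg <- synth_config(mini = TRUE)
  ds <- generate_dataset(cfg, seed = 3)
  st <- load_inventory(ds$stands, ds$regions)
  expect_error(spinup_dom(st, ds$curves, tolerance = 1e-15, max_cycles = 3),
               "did not converge")
})
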