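# Disturbance matrices, event application, snag backlog and reforestation.

test_that("every transfer matrix routes each source pool completely", {
  for (d in fcbs:::DIST_IDS) {
    m <- build_disturbance_matrix(d)
    if (nrow(m$transfers) == 0) next
    sums <- tapply(m$transfers$fraction, m$transfers$source, sum)
    expect_true(all(abs(sums - 1) < 1e-12), label = paste("Dist.", d))
    expect_gte(m$affected, 0)
    expect_lte(m$affected, 1)
  }
  expect_error(build_disturbance_matrix("9"), "unknown dist_id")
})

test_that("salvage extracts 20% of residues and final cut leaves seed trees", {
  p <- default_params()
  # cohort with 100 t C of harvest residues (other wood), nothing else live
  st <- fixture_cohort("SP", age = 90, area = 1,
                       pools = list(merch_stem = 10, other_wood = 100))
  m3a <- build_disturbance_matrix("3a")
  res <- apply_disturbance(st, m3a, target = 10, params = p)
  expect_equal(res$flux$residues, 20)
  expect_equal(res$flux$to_dom, 80)
  expect_equal(res$flux$products, 10)

  # final cut of 100 t C merch: 95 to products, 5 remain as live seed trees
  st4 <- fixture_cohort("SP", age = 120, area = 1,
                        pools = list(merch_stem = 100))
  m4 <- build_disturbance_matrix("4")
  cap <- 0.95 * 100
  res4 <- apply_disturbance(st4, m4, target = cap, params = p)
  expect_equal(res4$flux$products, 95)
  newc <- res4$state[res4$state$forest_type == "CLEARCUT", ]
  expect_equal(nrow(newc), 1)
  expect_equal(newc$merch_stem, 5)
  expect_equal(newc$trigger, "final")
})

test_that("zero targets are the identity", {
  st <- random_cohort("SP", age = 60)
  for (d in c("2", "3a", "3b", "4", "6")) {
    res <- apply_disturbance(st, build_disturbance_matrix(d), 0)
    expect_identical(tibble::as_tibble(res$state)[fcbs:::ALL_POOLS],
                     tibble::as_tibble(st)[fcbs:::ALL_POOLS])
    expect_equal(sum(unlist(res$flux)), 0)
  }
})

test_that("event mass balance closes for randomized cohorts and all types", {
  set.seed(23)
  p <- default_params()
  for (rep in 1:40) {
    for (d in c("2", "3a", "3b", "4", "5", "6", "7")) {
      ft <- if (d == "7") "SPx" else sample(c("SP", "PI", "BE", "OA"), 1)
      age <- if (d == "2") sample(20:59, 1) else sample(90:140, 1)
      st <- random_cohort(ft, age = age)
      if (d == "7") {
        st$origin_year <- 2019L
        st$snag_stem <- stats::runif(1, 10, 60)
      }
      m <- build_disturbance_matrix(d)
      cap <- if (m$unit == "tC") {
        fcbs:::products_capacity_ha(st, m) * st$area
      } else {
        st$area
      }
      target <- stats::runif(1, 0, cap)
      before <- fcbs:::total_carbon(st)
      res <- apply_disturbance(st, m, target, p, year = 2020,
                               check_eligible = FALSE)
      after <- fcbs:::total_carbon(res$state)
      leak <- before - after - res$flux$products - res$flux$residues -
        res$flux$to_atmosphere
      expect_lt(abs(leak), 1e-9 * max(before, 1))
    }
  }
})

test_that("standing mortality converts live spruce to a snag stand", {
  st <- fixture_cohort("SP", age = 80, area = 10,
                       pools = list(merch_stem = 60, other_wood = 20,
                                    foliage = 5))
  m6 <- build_disturbance_matrix("6")
  res <- apply_disturbance(st, m6, target = 10, year = 2019)
  spx <- res$state[res$state$forest_type == "SPx", ]
  expect_equal(nrow(spx), 1)
  expect_equal(spx$merch_stem, 0)
  expect_equal(spx$snag_stem, 60)
  expect_equal(spx$snag_branch, 20)
  expect_equal(spx$origin_year, 2019L)
})

test_that("only clear-cutting events reset the stand", {
  st <- fixture_cohort("SP", age = 90, area = 10,
                       pools = list(merch_stem = 80, other_wood = 20))
  res3b <- apply_disturbance(st, build_disturbance_matrix("3b"), 100)
  expect_false(any(res3b$state$forest_type == "CLEARCUT"))
  expect_equal(nrow(res3b$state), 1)

  res3a <- apply_disturbance(st, build_disturbance_matrix("3a"), 100)
  expect_true(any(res3a$state$forest_type == "CLEARCUT"))
  st4 <- st
  st4$age <- 120L
  res4 <- apply_disturbance(st4, build_disturbance_matrix("4"), 100)
  expect_true(any(res4$state$forest_type == "CLEARCUT"))
})

test_that("snag backlog removes 90% one year after the dieback", {
  empty <- fixture_cohort("SP", pools = list(merch_stem = 10))
  expect_equal(nrow(process_snag_backlog(empty, 2020)), 0)

  spx <- fixture_cohort("SPx", age = 80, area = 1,
                        pools = list(snag_stem = 10))
  spx$origin_year <- 2019L
  ev <- process_snag_backlog(spx, 2020)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$target_tC, 9)
  # outside the backlog window nothing is scheduled
  expect_equal(nrow(process_snag_backlog(spx, 2035, window = 2018:2022)), 0)

  # the residual decays along the snag closed form
  p <- default_params()
  res <- apply_disturbance(spx, build_disturbance_matrix("7"), ev$target_tC,
                           p, year = 2020, check_eligible = FALSE)
  resid <- res$state$snag_stem[1]
  expect_equal(resid, 1, tolerance = 1e-12)
  s <- res$state
  for (i in 1:5) s <- decay_dom(s, p)$state
  expect_equal(s$snag_stem[1], 1 * (1 - p$decay$snag_stem$rate)^5,
               tolerance = 1e-12)
})

test_that("reforestation splits area per composition and conserves it", {
  expect_equal(nrow(reforest(0, c(BE = 1), "R01")), 0)

  out <- reforest(100, c(BE = 0.5, OA = 0.5), "R01")
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$area), c(50, 50))
  expect_true(all(out$age == 0))

  expect_error(reforest(10, c(BE = 0.6, OA = 0.2), "R01"), "sum to 1")

  set.seed(5)
  for (i in 1:10) {
    w <- stats::runif(4)
    comp <- stats::setNames(w / sum(w), c("SP", "BE", "OA", "LLB"))
    a <- stats::runif(1, 1, 500)
    expect_equal(sum(reforest(a, comp, "R01")$area), a, tolerance = 1e-9)
  }
})
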