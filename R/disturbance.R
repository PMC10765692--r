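# Disturbance transfer matrices and event application.
#
# Eight event types are supported, mirroring classical Central-European
# forestry practice plus the calamity-specific snag handling:
#   2   commercial thinning (partial removal, mid-aged stands)
#   3a  salvage logging with clear-cut (stand reset)
#   3b  selective salvage logging (no clear-cut)
#   4   final commercial felling (5% seed trees retained, stand reset)
#   5   clear-cut with slash burn (used only for DOM spinup)
#   6   standing mortality (live biomass to snag pools, area-based)
#   7   harvest of snag stemwood after standing mortality
#   8   reforestation of cleared areas (area-based, via reforest())
# Harvest-type events are targeted in t C of merchantable (product) carbon;
# Dist. 6 and Dist. 8 are targeted in hectares.

DIST_IDS <- c("2", "3a", "3b", "4", "5", "6", "7", "8")

#' Build a disturbance transfer matrix
#'
#' Returns the proportional source-to-sink transfer table for one disturbance
#' type, together with the affected-biomass fraction, eligibility rule and
#' stand-reset semantics. Transfer rows give, for each source pool, the
#' destinations of the *affected* share of that pool; each source's fractions
#' sum to one. Destinations are pool names plus the out-of-system sinks
#' `products` (merchantable removals), `residues` (extracted harvest
#' residues, also products) and `atmosphere`.
#'
#' @param dist_id one of `"2"`, `"3a"`, `"3b"`, `"4"`, `"5"`, `"6"`, `"7"`,
#'   `"8"`.
#' @param config optional overrides: `thinning_intensity` (default 0.20, must
#'   lie in \[0.10, 0.30\]), `burn_fraction` (share of unextracted residues
#'   burned in 3a/4, default 0), `residue_extraction` (named, sanitary 0.20 /
#'   planned 0.25), `seed_tree_fraction` (default 0.05),
#'   `snag_removal_fraction` (default 0.90).
#' @return object of class `fcbs_dist_matrix`.
#' @export
#' @examples
#' m <- build_disturbance_matrix("3a")
#' m$transfers
build_disturbance_matrix <- function(dist_id, config = list()) {
  dist_id <- as.character(dist_id)
  if (!dist_id %in% DIST_IDS) {
    stop("unknown dist_id: ", dist_id, call. = FALSE)
  }
  thin <- config$thinning_intensity %||% 0.20
  stopifnot(thin >= 0.10, thin <= 0.30)
  burn <- config$burn_fraction %||% 0
  rex <- config$residue_extraction %||% c(sanitary = 0.20, planned = 0.25)
  seed <- config$seed_tree_fraction %||% 0.05
  snagf <- config$snag_removal_fraction %||% 0.90

  tr <- function(...) {
    d <- tibble::tribble(~source, ~dest, ~fraction, ...)
    d[d$fraction > 0, ]
  }
  root_rows <- function() tr(
    "coarse_roots", "bg_fast", 1,
    "fine_roots", "ag_very_fast", 0.5,
    "fine_roots", "bg_very_fast", 0.5
  )
  salvage_rows <- function(extract) dplyr::bind_rows(
    tr("merch_stem", "products", 1,
       "other_wood", "residues", extract,
       "other_wood", "medium_dom", (1 - extract) * (1 - burn),
       "other_wood", "atmosphere", (1 - extract) * burn,
       "foliage", "ag_very_fast", 1),
    root_rows()
  )

  m <- switch(dist_id,
    "2" = list(
      transfers = dplyr::bind_rows(
        tr("merch_stem", "products", 1,
           "other_wood", "ag_fast", 1,
           "foliage", "ag_very_fast", 1),
        root_rows()
      ),
      affected = thin, unit = "tC", resets = FALSE, trigger = NA_character_,
      eligibility = list(min_age = 20, max_age = 59, min_merch = 1e-9)
    ),
    "3a" = list(
      transfers = salvage_rows(rex[["sanitary"]]),
      affected = 1, unit = "tC", resets = TRUE, trigger = "sanitary",
      eligibility = list(min_age = 20, max_age = Inf, min_merch = 1e-9)
    ),
    "3b" = list(
      transfers = salvage_rows(rex[["sanitary"]]),
      affected = 1, unit = "tC", resets = FALSE, trigger = NA_character_,
      eligibility = list(min_age = 20, max_age = Inf, min_merch = 1e-9)
    ),
    "4" = list(
      transfers = salvage_rows(rex[["planned"]]),
      affected = 1 - seed, unit = "tC", resets = TRUE, trigger = "final",
      eligibility = list(min_age = NA, max_age = Inf, min_merch = 1e-9,
                         rotation_based = TRUE)
    ),
    "5" = list(
      transfers = dplyr::bind_rows(
        tr("merch_stem", "products", 0.85,
           "merch_stem", "medium_dom", 0.15,
           "other_wood", "atmosphere", 1,
           "foliage", "atmosphere", 1),
        root_rows()
      ),
      affected = 1, unit = "tC", resets = TRUE, trigger = NA_character_,
      eligibility = list(min_age = 0, max_age = Inf, min_merch = 0)
    ),
    "6" = list(
      transfers = dplyr::bind_rows(
        tr("merch_stem", "snag_stem", 1,
           "other_wood", "snag_branch", 1,
           "foliage", "ag_very_fast", 1),
        root_rows()
      ),
      affected = 1, unit = "ha", resets = FALSE, trigger = NA_character_,
      to_type = "SPx",
      eligibility = list(min_age = 0, max_age = Inf, min_merch = 1e-9)
    ),
    "7" = list(
      transfers = tr("snag_stem", "products", 1),
      affected = snagf, unit = "tC", resets = TRUE, trigger = "sanitary",
      eligibility = list(min_age = 0, max_age = Inf, min_merch = 0,
                         requires_snag = TRUE)
    ),
    "8" = list(
      transfers = tibble::tibble(source = character(), dest = character(),
                                 fraction = numeric()),
      affected = 1, unit = "ha", resets = FALSE, trigger = NA_character_,
      eligibility = list(min_age = 0, max_age = Inf, min_merch = 0)
    )
  )
  m$dist_id <- dist_id
  # row-sum invariant: the affected share of each source is fully routed
  if (nrow(m$transfers) > 0) {
    s <- tapply(m$transfers$fraction, m$transfers$source, sum)
    stopifnot(all(abs(s - 1) < 1e-12))
  }
  structure(m, class = "fcbs_dist_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fcbs_dist_matrix <- function(x, ...) {
  cat(sprintf("<disturbance matrix Dist. %s> affected %.2f, unit %s, %s\n",
              x$dist_id, x$affected, x$unit,
              if (x$resets) "stand reset" else "no stand reset"))
  print(x$transfers)
  invisible(x)
}

# per-hectare product capacity of a cohort under a matrix (t C/ha):
# affected fraction times the products-bound share of the source pools
products_capacity_ha <- function(state, matrix) {
  pr <- matrix$transfers[matrix$transfers$dest %in% "products", ]
  cap <- numeric(nrow(state))
  for (i in seq_len(nrow(pr))) {
    cap <- cap + state[[pr$source[i]]] * pr$fraction[i]
  }
  cap * matrix$affected
}

# eligibility mask for cohorts under a matrix
eligible_mask <- function(state, matrix, params) {
  e <- matrix$eligibility
  ok <- rep(TRUE, nrow(state))
  if (isTRUE(e$requires_snag)) {
    ok <- ok & state$forest_type == "SPx" & state$snag_stem > e$min_merch
  } else if (isTRUE(e$rotation_based)) {
    rot <- params$rotation[state$forest_type]
    ok <- ok & !is.na(rot) & state$age >= rot & state$merch_stem > e$min_merch
  } else {
    ok <- ok & state$age >= e$min_age & state$age <= e$max_age
    if (e$min_merch > 0) ok <- ok & state$merch_stem > e$min_merch
  }
  ok & state$area > 0 & !(state$retained & matrix$dist_id %in% c("3a", "3b", "4"))
}

#' Apply a disturbance event to cohorts
#'
#' Applies one disturbance matrix to one or more cohorts with per-cohort
#' targets. Harvest-type events (`unit == "tC"`) are targeted in t C of
#' product carbon; area events (Dist. 6) in hectares. Targets must not
#' exceed availability — the harvest allocator clips before calling.
#'
#' Stand-resetting events (3a, 4, 5, 7) split the cohort: the harvested area
#' becomes a `CLEARCUT` cohort at age 0 (carrying its DOM and any retained
#' live seed trees) tagged with the species-change trigger and origin type.
#' Dist. 6 converts the affected area to a standing-dead `SPx` cohort.
#'
#' @param state cohort tibble (one or more rows).
#' @param matrix an `fcbs_dist_matrix` from [build_disturbance_matrix()].
#' @param target numeric vector (recycled): t C products or ha per cohort.
#' @param params dynamics parameters (for eligibility checks).
#' @param year simulation year stamped on newly created cohorts.
#' @param check_eligible error on ineligible cohorts (default TRUE).
#' @return list with `state` (surviving + newly created cohort rows) and
#'   `flux`, a tibble per input row with `products`, `residues`, `to_dom`,
#'   `to_atmosphere` (t C).
#' @export
apply_disturbance <- function(state, matrix, target, params = default_params(),
                              year = NA_integer_, check_eligible = TRUE) {
  n <- nrow(state)
  target <- rep_len(target, n)
  stopifnot(all(target >= 0))
  active <- target > 0
  if (check_eligible && any(active)) {
    ok <- eligible_mask(state[active, , drop = FALSE], matrix, params)
    if (!all(ok)) {
      bad <- which(active)[!ok][1]
      stop(sprintf(
        "cohort %d (%s %s age %d) is not eligible for Dist. %s",
        bad, state$region_id[bad], state$forest_type[bad], state$age[bad],
        matrix$dist_id), call. = FALSE)
    }
  }
  flux <- tibble::tibble(products = numeric(n), residues = numeric(n),
                         to_dom = numeric(n), to_atmosphere = numeric(n))
  if (!any(active)) return(list(state = state, flux = flux))

  # fraction of the whole cohort's stock transferred, and area harvested
  if (matrix$unit == "tC") {
    cap_ha <- products_capacity_ha(state, matrix)
    if (matrix$resets) {
      area_h <- ifelse(active & cap_ha > 0, pmin(target / cap_ha, state$area), 0)
      g <- rep(matrix$affected, n)           # within harvested area
    } else {
      avail <- cap_ha * state$area
      f <- ifelse(active & avail > 0, pmin(target / avail, 1), 0)
      g <- f * matrix$affected               # on the whole area
      area_h <- rep(0, n)
    }
  } else {                                    # area-based (Dist. 6)
    area_h <- ifelse(active, pmin(target, state$area), 0)
    g <- rep(matrix$affected, n)
  }

  new_rows <- NULL
  out <- state
  split_evt <- matrix$resets || !is.null(matrix$to_type)
  if (split_evt) {
    idx <- which(area_h > 0)
    if (length(idx) > 0) {
      harv <- state[idx, , drop = FALSE]
      harv$area <- area_h[idx]
      out$area[idx] <- out$area[idx] - area_h[idx]
      # apply transfers to the affected share on the harvested area
      res <- transfer_pools(harv, matrix, g[idx])
      flux[idx, ] <- res$flux
      newc <- res$state
      if (!is.null(matrix$to_type)) {
        newc$forest_type <- matrix$to_type
        newc$origin_type <- state$forest_type[idx]
        newc$origin_year <- year
      } else {
        newc$origin_type <- ifelse(state$forest_type[idx] == "SPx",
                                   "SP", state$forest_type[idx])
        newc$forest_type <- "CLEARCUT"
        newc$age <- 0L
        newc$trigger <- matrix$trigger
        newc$origin_year <- year
        newc$retained <- FALSE
      }
      new_rows <- newc
    }
  } else {
    idx <- which(g > 0)
    if (length(idx) > 0) {
      res <- transfer_pools(out[idx, , drop = FALSE], matrix, g[idx])
      out[idx, ] <- res$state
      flux[idx, ] <- res$flux
    }
  }
  out <- dplyr::bind_rows(out[out$area > 1e-12, , drop = FALSE], new_rows)
  list(state = out, flux = flux)
}

# move fraction g of each source pool per the matrix; returns updated rows
# and per-row flux (t C, area-weighted)
transfer_pools <- function(rows, matrix, g) {
  fl <- tibble::tibble(products = numeric(nrow(rows)),
                       residues = numeric(nrow(rows)),
                       to_dom = numeric(nrow(rows)),
                       to_atmosphere = numeric(nrow(rows)))
  tfr <- matrix$transfers
  for (src in unique(tfr$source)) {
    moved_total <- rows[[src]] * g
    rows[[src]] <- rows[[src]] - moved_total
    sub <- tfr[tfr$source == src, ]
    for (i in seq_len(nrow(sub))) {
      amt <- moved_total * sub$fraction[i]
      d <- sub$dest[i]
      if (d == "products") {
        fl$products <- fl$products + amt * rows$area
      } else if (d == "residues") {
        fl$residues <- fl$residues + amt * rows$area
      } else if (d == "atmosphere") {
        fl$to_atmosphere <- fl$to_atmosphere + amt * rows$area
      } else {
        rows[[d]] <- rows[[d]] + amt
        fl$to_dom <- fl$to_dom + amt * rows$area
      }
    }
  }
  list(state = rows, flux = fl)
}

#' Snag backlog events for one year
#'
#' Standing dead spruce (`SPx`) that arose in the previous year is processed
#' with a one-year delay: 90% of its merchantable snag carbon is removed
#' (Dist. 7) and the remaining 10% is left to decompose. The regime applies
#' only inside the configured backlog window.
#'
#' @param state cohort tibble.
#' @param year current simulation year.
#' @param window years in which snag cutting is executed (default 2018:2022,
#'   the one-year-delayed execution of the 2018-2021 mortality regime).
#' @param removal_fraction share of snag stem carbon removed (default 0.90).
#' @return tibble of Dist. 7 events: `year`, `row` (cohort row index),
#'   `target_tC`; zero rows when nothing is due.
#' @export
process_snag_backlog <- function(state, year, window = 2018:2022,
                                 removal_fraction = 0.90) {
  if (!year %in% window) {
    return(tibble::tibble(year = integer(), row = integer(),
                          target_tC = numeric()))
  }
  idx <- which(state$forest_type == "SPx" &
                 !is.na(state$origin_year) & state$origin_year == year - 1 &
                 state$snag_stem * state$area > 0)
  tibble::tibble(
    year = rep(as.integer(year), length(idx)),
    row = idx,
    target_tC = removal_fraction * state$snag_stem[idx] * state$area[idx]
  )
}

#' Reforest a cleared area
#'
#' Creates new age-0 cohorts splitting `area` across forest types per the
#' composition fractions. Live pools start at zero (any seed-tree residual is
#' carried by the template); DOM pools are inherited per-hectare from the
#' cleared cohort.
#'
#' @param area hectares to replant.
#' @param composition named numeric, forest type to fraction, summing to 1.
#' @param region_id region of the new cohorts.
#' @param dom_template single-row cohort tibble supplying per-ha pool values
#'   to inherit (typically the cleared `CLEARCUT` cohort); `NULL` for zero
#'   pools.
#' @param year origin year stamp.
#' @return tibble of new cohorts (zero rows when `area` is 0).
#' @export
reforest <- function(area, composition, region_id, dom_template = NULL,
                     year = NA_integer_) {
  stopifnot(area >= 0)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  if (area == 0) return(empty_cohorts())
  check_forest_type(names(composition))
  n <- length(composition)
  out <- empty_cohorts()[rep(1L, 0), ]
  rows <- tibble::tibble(
    region_id = region_id,
    forest_type = names(composition),
    age = 0L,
    area = area * unname(composition),
    retained = FALSE,
    trigger = NA_character_,
    origin_type = NA_character_,
    origin_year = as.integer(year)
  )
  for (p in ALL_POOLS) {
    rows[[p]] <- if (is.null(dom_template)) 0 else rep(dom_template[[p]][1], n)
  }
  if (!is.null(dom_template)) {
    for (p in LIVE_POOLS) rows[[p]] <- rep(dom_template[[p]][1], n)
  }
  rows[rows$area > 0, ]
}

empty_cohorts <- function() {
  base <- tibble::tibble(
    region_id = character(), forest_type = character(), age = integer(),
    area = numeric(), retained = logical(), trigger = character(),
    origin_type = character(), origin_year = integer()
  )
  for (p in ALL_POOLS) base[[p]] <- numeric()
  base
}
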