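# Pool name constants and the default dynamics parameter set.

#' Model carbon pools
#'
#' The simulator tracks 14 named per-hectare carbon pools per cohort. The
#' CBM-style softwood/hardwood duplication of the five live pools and the two
#' snag pools (making 21 distinct model pools) is carried by the cohort's
#' leading-species softwood flag: a cohort populates exactly one family, so a
#' single set of named columns suffices and the full 21-pool resolution is
#' recovered by grouping cohorts on that flag.
#'
#' @format Character vectors of pool names.
#' @name pools
NULL

#' @rdname pools
#' @export
LIVE_POOLS <- c("merch_stem", "other_wood", "foliage", "coarse_roots", "fine_roots")

#' @rdname pools
#' @export
DOM_POOLS <- c("snag_stem", "snag_branch", "medium_dom",
               "ag_fast", "ag_very_fast", "ag_slow",
               "bg_fast", "bg_very_fast", "bg_slow")

#' @rdname pools
#' @export
ALL_POOLS <- c(LIVE_POOLS, DOM_POOLS)

# Forest type codes and their leading-species class
FOREST_TYPES <- c("SP", "PI", "BE", "OA", "LLB", "SLB", "AA", "CLEARCUT", "SPx")
SOFTWOOD_TYPES <- c("SP", "PI", "AA", "SPx")
HARDWOOD_TYPES <- c("BE", "OA", "LLB", "SLB")
GROWING_TYPES <- c("SP", "PI", "BE", "OA", "LLB", "SLB", "AA")

#' Is a forest type softwood-led?
#'
#' `CLEARCUT` cohorts carry no live biomass; they are classed softwood for
#' bookkeeping (most originate from spruce salvage) but hold zero live pools
#' until replanted.
#'
#' @param forest_type character vector of forest type codes.
#' @return logical vector.
#' @export
is_softwood <- function(forest_type) {
  !forest_type %in% HARDWOOD_TYPES
}

#' Default carbon dynamics parameters
#'
#' Returns the parameter set driving volume-to-carbon conversion, live-pool
#' turnover and dead-organic-matter (DOM) decay. Magnitudes follow published
#' European CBM calibration archives; they are deliberately generic defaults,
#' not a national calibration.
#'
#' @details The components are:
#' \describe{
#'   \item{density}{t C per m3 merchantable volume, by softwood/hardwood.}
#'   \item{ratios}{live component pools as fractions of merchantable stem
#'     carbon (other wood, foliage, coarse roots, fine roots).}
#'   \item{turnover}{annual fraction of each live pool transferred to its
#'     destination DOM pool(s); stem mortality feeds the snag stem pool.}
#'   \item{decay}{per DOM pool: annual decay rate, the fraction of decayed
#'     carbon released to the atmosphere, and the downstream pool receiving
#'     the humified residue. The slow pools are terminal (atmosphere fraction
#'     1).}
#'   \item{rotation}{historic rotation age in years per forest type, used for
#'     spinup and final-cut eligibility.}
#' }
#'
#' @param ... named overrides replacing top-level components.
#' @return object of class `fcbs_params` (a list).
#' @export
#' @examples
#' p <- default_params()
#' p$density
default_params <- function(...) {
  p <- list(
    density = c(softwood = 0.22, hardwood = 0.28),
    ratios = list(
      softwood = c(other_wood = 0.30, foliage = 0.08,
                   coarse_roots = 0.20, fine_roots = 0.02),
      hardwood = c(other_wood = 0.35, foliage = 0.04,
                   coarse_roots = 0.20, fine_roots = 0.02)
    ),
    # turnover: fraction per year and destination split among DOM pools
    turnover = list(
      merch_stem   = list(frac = c(softwood = 0.005, hardwood = 0.005),
                          dest = c(snag_stem = 1)),
      other_wood   = list(frac = c(softwood = 0.04, hardwood = 0.04),
                          dest = c(ag_fast = 1)),
      foliage      = list(frac = c(softwood = 0.10, hardwood = 1.0),
                          dest = c(ag_very_fast = 1)),
      coarse_roots = list(frac = c(softwood = 0.02, hardwood = 0.02),
                          dest = c(bg_fast = 1)),
      fine_roots   = list(frac = c(softwood = 0.64, hardwood = 0.64),
                          dest = c(ag_very_fast = 0.5, bg_very_fast = 0.5))
    ),
    # decay: rate 1/yr, atmosphere fraction of the decayed amount, downstream
    # pool for the residue (NA = terminal, all to atmosphere)
    decay = list(
      snag_stem    = list(rate = 0.03,  atm = 0.83, down = "medium_dom"),
      snag_branch  = list(rate = 0.03,  atm = 0.83, down = "ag_fast"),
      medium_dom   = list(rate = 0.037, atm = 0.83, down = "ag_slow"),
      ag_fast      = list(rate = 0.14,  atm = 0.83, down = "ag_slow"),
      ag_very_fast = list(rate = 0.355, atm = 0.83, down = "ag_slow"),
      ag_slow      = list(rate = 0.015, atm = 1.0,  down = NA_character_),
      bg_fast      = list(rate = 0.14,  atm = 0.83, down = "bg_slow"),
      bg_very_fast = list(rate = 0.355, atm = 0.83, down = "bg_slow"),
      bg_slow      = list(rate = 0.015, atm = 1.0,  down = NA_character_)
    ),
    rotation = c(SP = 100, PI = 100, AA = 100,
                 BE = 120, OA = 120, LLB = 120, SLB = 80),
    # salvage/planned residue (other wood) extraction intensities
    residue_extraction = c(sanitary = 0.20, planned = 0.25),
    thinning = list(intensity = 0.20, min_age = 20, max_age = 59),
    sanitary_min_age = 20,
    seed_tree_fraction = 0.05,
    snag_removal_fraction = 0.90
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  validate_params(p)
  structure(p, class = "fcbs_params")
}

validate_params <- function(p) {
  stopifnot(all(p$density > 0), all(is.finite(p$density)))
  for (sp in c("softwood", "hardwood")) {
    r <- p$ratios[[sp]]
    stopifnot(all(r >= 0), all(is.finite(r)))
  }
  for (nm in names(p$turnover)) {
    t <- p$turnover[[nm]]
    stopifnot(all(t$frac >= 0), all(t$frac <= 1))
    stopifnot(abs(sum(t$dest) - 1) < 1e-12)
    stopifnot(all(names(t$dest) %in% DOM_POOLS))
  }
  for (nm in names(p$decay)) {
    d <- p$decay[[nm]]
    stopifnot(d$rate >= 0, d$rate <= 1, d$atm >= 0, d$atm <= 1)
    if (d$atm < 1) stopifnot(!is.na(d$down), d$down %in% DOM_POOLS)
  }
  stopifnot(identical(is.na(p$decay$bg_slow$down), TRUE) ||
              p$decay$bg_slow$atm == 1)
  invisible(p)
}

#' @export
print.fcbs_params <- function(x, ...) {
  cat("<fcbs_params>\n")
  cat("  carbon density (t C/m3):",
      sprintf("softwood %.2f, hardwood %.2f", x$density["softwood"],
              x$density["hardwood"]), "\n")
  cat("  rotation ages:", paste(names(x$rotation), x$rotation,
                                sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# carbon density for a vector of forest types
density_of <- function(forest_type, params) {
  unname(params$density[ifelse(is_softwood(forest_type), "softwood", "hardwood")])
}

ratios_of <- function(forest_type, params) {
  sp <- ifelse(is_softwood(forest_type), "softwood", "hardwood")
  lapply(sp, function(s) params$ratios[[s]])
}
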