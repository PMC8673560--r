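#' Growth configuration for the synthetic airway generator
#'
#' Bundles the experimental condition (transpulmonary pressure and culture
#' time) with the growth schedules that the generator uses to emulate
#' pseudoglandular-stage explant cultures: terminal branches are added at a
#' rate that declines with the magnitude of negative transpulmonary
#' pressure, basal surface area grows linearly in time independently of
#' pressure, the RCr branch neck narrows with pressure and time, and
#' terminal buds become enlarged ("cystic") under strong negative pressure.
#'
#' The default schedules are calibrated so that, across timepoints, the
#' fold-change in terminal branch count y and the fold-change in basal
#' surface area x obey y = x^a with pooled exponent
#' `allometric_exponent`; the per-pressure branching-intensity factor
#' (`branching_rate_schedule`) tilts the effective exponent by at most
#' +/- 4 percent so that branching decreases with pressure magnitude while
#' all pressures still collapse onto one scaling curve.
#'
#' @param pressure_Pa transpulmonary pressure in Pa; negative values mean
#'   negative transpulmonary pressure (reservoir above lumen).
#' @param time_h culture time in hours (>= 0).
#' @param allometric_exponent target pooled scaling exponent between branch
#'   fold-change and area fold-change.
#' @param baseline_area_growth_rate linear growth rate of basal surface
#'   area, in fold units per hour: area fold-change = 1 + rate * t.
#' @param branching_rate_schedule function(pressure_Pa) returning the
#'   relative branching intensity (dimensionless, ~1); it multiplies the
#'   allometric exponent used for the target branch count.
#' @param rcr_radius_schedule function(pressure_Pa, time_h) returning the
#'   fraction (0, 1] of the initial RCr radius remaining.
#' @param cystic_tip_factor function(pressure_Pa) returning the terminal
#'   bud radius multiplier (>= 1 widens tips).
#' @param segment_elongation_rate fractional segment elongation per hour.
#' @param rng_seed integer seed fixing all stochastic choices.
#' @param geometry list of canonical-tree geometry defaults (radii and
#'   segment lengths in micrometres, branch angle ranges in degrees).
#'
#' @return an object of class `growth_config`.
#' @export
growth_config <- function(pressure_Pa = -100,
                          time_h = 0,
                          allometric_exponent = 1.67,
                          baseline_area_growth_rate = 0.018,
                          branching_rate_schedule = default_branching_rate_schedule,
                          rcr_radius_schedule = default_rcr_radius_schedule,
                          cystic_tip_factor = default_cystic_tip_factor,
                          segment_elongation_rate = 0.003,
                          rng_seed = 1L,
                          geometry = list()) {
  geo <- utils::modifyList(default_tree_geometry(), geometry)
  cfg <- structure(list(
    pressure_Pa = pressure_Pa,
    time_h = time_h,
    allometric_exponent = allometric_exponent,
    baseline_area_growth_rate = baseline_area_growth_rate,
    branching_rate_schedule = branching_rate_schedule,
    rcr_radius_schedule = rcr_radius_schedule,
    cystic_tip_factor = cystic_tip_factor,
    segment_elongation_rate = segment_elongation_rate,
    rng_seed = as.integer(rng_seed),
    geometry = geo
  ), class = "growth_config")
  validate_growth_config(cfg)
  cfg
}

#' @export
print.growth_config <- function(x, ...) {
  cat("<growth_config>\n")
  cat(sprintf("  pressure: %g Pa, time: %g h, seed: %d\n",
              x$pressure_Pa, x$time_h, x$rng_seed))
  cat(sprintf("  allometric exponent a* = %g, area growth %g fold/h\n",
              x$allometric_exponent, x$baseline_area_growth_rate))
  invisible(x)
}

validate_growth_config <- function(cfg) {
  stopifnot(is.numeric(cfg$pressure_Pa), length(cfg$pressure_Pa) == 1)
  if (!is.numeric(cfg$time_h) || cfg$time_h < 0) {
    stop("time_h must be >= 0")
  }
  if (cfg$baseline_area_growth_rate < 0) stop("area growth rate must be >= 0")
  if (cfg$allometric_exponent <= 0) stop("allometric exponent must be > 0")
  for (f in c("branching_rate_schedule", "rcr_radius_schedule", "cystic_tip_factor")) {
    if (!is.function(cfg[[f]])) stop(f, " must be a function")
  }
  rfrac <- cfg$rcr_radius_schedule(cfg$pressure_Pa, cfg$time_h)
  if (!is.finite(rfrac) || rfrac <= 0 || rfrac > 1) {
    stop("rcr_radius_schedule must return a fraction in (0, 1]")
  }
  if (cfg$branching_rate_schedule(cfg$pressure_Pa) < 0) {
    stop("branching_rate_schedule must return a rate >= 0")
  }
  invisible(cfg)
}

#' Default pressure schedules
#'
#' Piecewise-linear interpolations in pressure magnitude, anchored at the
#' study pressures -100, -400, and -1000 Pa and extrapolated as constants.
#' `default_branching_rate_schedule` returns the relative branching
#' intensity (1.04, 1.00, 0.96 at the anchors), so branch addition slows
#' with increasingly negative pressure. `default_rcr_radius_schedule`
#' shrinks the RCr neck linearly in time, reaching 80/60/40 percent of the
#' initial radius after 72 h at the anchors, i.e. a 50 percent
#' -1000-vs-control ratio at 72 h. `default_cystic_tip_factor` widens
#' terminal buds (1.0/1.12/1.3 at the anchors).
#'
#' @param pressure_Pa transpulmonary pressure in Pa.
#' @param time_h culture time in hours.
#' @return a numeric scalar (rate factor, radius fraction, or tip factor).
#' @export
default_branching_rate_schedule <- function(pressure_Pa) {
  approx(c(100, 400, 1000), c(1.04, 1.00, 0.96),
         xout = abs(pressure_Pa), rule = 2)$y
}

#' @rdname default_branching_rate_schedule
#' @export
default_rcr_radius_schedule <- function(pressure_Pa, time_h) {
  slope <- approx(c(100, 400, 1000), c(0.2, 0.4, 0.6),
                  xout = abs(pressure_Pa), rule = 2)$y
  max(0.05, 1 - (time_h / 72) * slope)
}

#' @rdname default_branching_rate_schedule
#' @export
default_cystic_tip_factor <- function(pressure_Pa) {
  approx(c(100, 400, 1000), c(1.0, 1.12, 1.3),
         xout = abs(pressure_Pa), rule = 2)$y
}

# canonical E12.5 geometry defaults (micrometres, degrees); only relative
# (fold-change) quantities are analysed downstream, so these set scale only
default_tree_geometry <- function() {
  list(
    trachea_radius = 50,
    trachea_length = c(150, 170),
    primary_radius = 40,
    primary_length = c(245, 275),
    primary_angle = c(35, 50),
    secondary_radius = 35,
    secondary_length = c(140, 165),
    lateral_angle = c(45, 65),
    terminal_angle = c(35, 55),
    new_branch_angle = c(40, 70),
    new_branch_length = c(80, 120),
    child_radius_factor = 0.72,
    child_length_factor = 0.75,
    taper = 0.85,
    min_radius = 8,
    radius_floor = 6.5,
    sample_step = 12,
    clearance = 8,
    certify_spacings = c(3.5, 3, 2.5, 2)
  )
}

# deterministic target terminal-branch count at time t for a config
target_terminal_count <- function(cfg, n0 = 9L) {
  a_eff <- cfg$allometric_exponent * cfg$branching_rate_schedule(cfg$pressure_Pa)
  fold_area <- 1 + cfg$baseline_area_growth_rate * cfg$time_h
  max(n0, as.integer(round(n0 * fold_area^a_eff)))
}
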