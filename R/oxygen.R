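# Steady-state diffusion-consumption model of dissolved oxygen in the
# column of culture medium above the explants.
#
# At steady state the concentration profile is linear: the surface value
# is set by Henry's law, phi(0) = P_O2 / Kc with
# P_O2 = F_O2 (P_ATM - P_H2O), and the gradient by the flux balance
# dphi/dx = -r / (D A), where r is the total consumption rate of the
# tissue at the bottom and A the vessel bottom area, giving
#   phi(x) = phi(0) - x r / (D A).
# The inputs mix customary units (mmHg dL/ml, cm^2/s, ml O2/min, cm^2);
# all quantities are converted to a single coherent unit system before
# evaluation (cm-s, ml O2/cm^3 by default; SI available for a dimensional
# audit) and converted back to ml O2/dL for reporting.

#' Parameters of the oxygen diffusion-consumption model
#'
#' Defaults are the culture conditions of the explant system: one well of
#' a 6-well plate under a humidified incubator atmosphere at 37 C, with
#' the tissue consumption rate estimated from literature per-volume
#' consumption and the volume of an early pseudoglandular lung.
#'
#' @param Kc Henry constant for O2 in plasma, mmHg dL/ml (default
#'   1/0.0031).
#' @param P_H2O vapor pressure of water at 37 C, mmHg.
#' @param P_ATM atmospheric pressure, mmHg.
#' @param F_O2 atmospheric O2 fraction (0-1).
#' @param r total O2 consumption rate, ml O2/min (default 0.023e-5, one
#'   lung).
#' @param D diffusivity of O2 in water, cm^2/s.
#' @param A vessel bottom area, cm^2 (one well of a 6-well plate).
#' @param x_b medium column height, cm.
#' @return an `oxygen_params` list.
#' @export
oxygen_params <- function(Kc = 1 / 0.0031,
                          P_H2O = 47.067,
                          P_ATM = 760,
                          F_O2 = 0.21,
                          r = 0.023e-5,
                          D = 2.76e-5,
                          A = 9.6,
                          x_b = 1) {
  p <- structure(list(Kc = Kc, P_H2O = P_H2O, P_ATM = P_ATM, F_O2 = F_O2,
                      r = r, D = D, A = A, x_b = x_b),
                 class = "oxygen_params")
  validate_oxygen_params(p)
  p
}

validate_oxygen_params <- function(p) {
  for (f in c("Kc", "P_H2O", "P_ATM", "D", "A", "x_b")) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) stop(f, " must be > 0")
  }
  if (p$r < 0) stop("r must be >= 0")
  if (p$F_O2 < 0 || p$F_O2 >= 1) stop("F_O2 must be in [0, 1)")
  invisible(p)
}

#' @export
print.oxygen_params <- function(x, ...) {
  cat("<oxygen_params>\n")
  cat(sprintf("  Kc %.4g mmHg dL/ml, P_ATM %.4g mmHg, P_H2O %.4g mmHg, F_O2 %.2g\n",
              x$Kc, x$P_ATM, x$P_H2O, x$F_O2))
  cat(sprintf("  r %.3g ml O2/min, D %.3g cm2/s, A %.3g cm2, x_b %.3g cm\n",
              x$r, x$D, x$A, x$x_b))
  invisible(x)
}

#' Partial pressure of oxygen in humidified atmosphere
#'
#' `P_O2 = F_O2 * (P_ATM - P_H2O)` (water vapor displaces dry gas).
#'
#' @param params an [oxygen_params()].
#' @return partial pressure in mmHg.
#' @export
partial_pressure_o2 <- function(params) {
  if (params$P_H2O >= params$P_ATM) {
    stop("P_H2O must be below P_ATM")
  }
  params$F_O2 * (params$P_ATM - params$P_H2O)
}

#' Henry's-law oxygen concentration at the air-liquid interface
#'
#' `phi(0) = P_O2 / Kc`, in ml O2 per dL of medium.
#'
#' @param params an [oxygen_params()].
#' @return surface concentration, ml O2/dL.
#' @export
surface_concentration <- function(params) {
  partial_pressure_o2(params) / params$Kc
}

# slope of the linear profile, ml O2/dL per cm of depth, in the requested
# coherent unit system (identical numbers up to rounding; the "si" route
# exists as a dimensional audit)
profile_slope_per_cm <- function(params, units = c("cgs", "si")) {
  units <- match.arg(units)
  if (units == "cgs") {
    # cm - s - (ml O2 / cm^3)
    r_cc_s <- params$r / 60            # ml O2 / s
    slope_cc <- r_cc_s / (params$D * params$A)  # (ml O2/cm^3) / cm
    slope_cc * 100                     # ml O2/dL per cm
  } else {
    # SI: m - s - (m^3 O2 / m^3)
    r_si <- params$r * 1e-6 / 60       # m^3 O2 / s
    D_si <- params$D * 1e-4            # m^2/s
    A_si <- params$A * 1e-4            # m^2
    slope_si <- r_si / (D_si * A_si)   # (m^3/m^3) / m
    # 1 m^3/m^3 = 1 ml/ml = 100 ml/dL; per m -> per cm
    slope_si * 100 / 100
  }
}

#' Steady-state oxygen concentration profile
#'
#' Evaluates the linear steady-state profile
#' `phi(x) = phi(0) - x r / (D A)` at uniformly spaced depths from the
#' air-liquid interface (x = 0) to the bottom of the medium column
#' (x = x_b). Negative values are clamped to zero and flagged, and the
#' anoxic depth (where the profile reaches zero) is reported.
#'
#' @param params an [oxygen_params()].
#' @param n_depths number of evaluation depths.
#' @param units internal coherent unit system ("cgs" or "si"; results are
#'   identical, the option exists as a dimensional audit).
#' @return an `oxygen_profile`: tibble of depth_cm and concentration
#'   (ml O2/dL) with attributes `anoxic` and `anoxic_depth_cm`.
#' @export
concentration_profile <- function(params, n_depths = 101,
                                  units = c("cgs", "si")) {
  validate_oxygen_params(params)
  units <- match.arg(units)
  phi0 <- surface_concentration(params)
  slope <- profile_slope_per_cm(params, units)
  x <- seq(0, params$x_b, length.out = n_depths)
  phi <- phi0 - slope * x
  anoxic <- any(phi < 0)
  anoxic_depth <- if (slope > 0) phi0 / slope else Inf
  prof <- tibble(depth_cm = x, concentration_ml_dL = pmax(phi, 0))
  structure(list(profile = prof, params = params,
                 surface_ml_dL = phi0,
                 slope_ml_dL_per_cm = slope,
                 anoxic = anoxic,
                 anoxic_depth_cm = anoxic_depth),
            class = "oxygen_profile")
}

#' @export
print.oxygen_profile <- function(x, ...) {
  cat("<oxygen_profile>\n")
  cat(sprintf("  phi(0) = %.4f ml O2/dL, slope = %.3g ml O2/dL/cm\n",
              x$surface_ml_dL, x$slope_ml_dL_per_cm))
  bot <- tail(x$profile$concentration_ml_dL, 1)
  cat(sprintf("  bottom (x = %.3g cm): %.4f ml O2/dL%s\n",
              x$params$x_b, bot,
              if (x$anoxic) sprintf(" [anoxic below %.3g cm]", x$anoxic_depth_cm) else ""))
  invisible(x)
}

#' Independent finite-difference solution of the steady-state problem
#'
#' Solves `D phi'' = 0` with `phi(0) = phi0` (Henry's law) and
#' `phi'(x_b) = -r/(D A)` (consumption flux) on a uniform grid by the
#' Thomas algorithm. Serves as a numerical oracle for the closed form.
#'
#' @param params an [oxygen_params()].
#' @param n number of grid points.
#' @return tibble of depth_cm and concentration_ml_dL.
#' @export
concentration_profile_fd <- function(params, n = 401) {
  validate_oxygen_params(params)
  phi0 <- surface_concentration(params) / 100  # ml O2/cm^3
  gprime <- -(params$r / 60) / (params$D * params$A)  # per cm
  h <- params$x_b / (n - 1)
  # discretized Laplace equation: Dirichlet (Henry's law) at the surface,
  # second-order one-sided Neumann (consumption flux) at the bottom
  M <- matrix(0, n, n)
  d <- rep(0, n)
  M[1, 1] <- 1
  d[1] <- phi0
  for (i in 2:(n - 1)) {
    M[i, i - 1] <- 1; M[i, i] <- -2; M[i, i + 1] <- 1
  }
  M[n, n - 2] <- 1; M[n, n - 1] <- -4; M[n, n] <- 3
  d[n] <- 2 * h * gprime
  phi <- solve(M, d)
  tibble(depth_cm = seq(0, params$x_b, length.out = n),
         concentration_ml_dL = pmax(phi * 100, 0))
}

#' Sweep of consumption rates and column heights
#'
#' Recomputes the bottom-of-column O2 concentration over a grid of column
#' heights and consumption-rate multipliers (the per-well tissue load is
#' uncertain, so rates up to forty times the single-lung estimate are
#' scanned), and for each multiplier reports the depth at which the
#' concentration falls to the 1 percent O2 equivalent,
#' `phi_1% = 0.01 (P_ATM - P_H2O) / Kc`.
#'
#' @param params an [oxygen_params()].
#' @param multipliers consumption-rate multipliers.
#' @param heights_mm column heights in millimetres.
#' @return list with `grid` (tibble: multiplier, height_mm,
#'   bottom_ml_dL) and `threshold` (tibble: multiplier,
#'   depth_1pct_mm), plus the threshold concentration used.
#' @export
sweep_consumption <- function(params, multipliers = 1:40,
                              heights_mm = seq(0, 100, by = 2)) {
  validate_oxygen_params(params)
  phi0 <- surface_concentration(params)
  slope1 <- profile_slope_per_cm(params)  # for multiplier 1
  phi_1pct <- 0.01 * (params$P_ATM - params$P_H2O) / params$Kc
  grid <- tidyr::expand_grid(multiplier = multipliers,
                             height_mm = heights_mm)
  grid$bottom_ml_dL <- pmax(phi0 - grid$multiplier * slope1 *
                              (grid$height_mm / 10), 0)
  thr <- tibble(
    multiplier = multipliers,
    depth_1pct_mm = ifelse(multipliers > 0 & slope1 > 0,
                           10 * (phi0 - phi_1pct) / (multipliers * slope1),
                           Inf)
  )
  list(grid = grid, threshold = thr, phi_1pct_ml_dL = phi_1pct,
       surface_ml_dL = phi0)
}

#' Hydrostatic reservoir pressure
#'
#' `P_reservoir = rho g h`: the pressure of the medium column of height h
#' above the explant; the transpulmonary pressure of the culture system is
#' `P_lumen - P_reservoir`.
#'
#' @param h_m column height in metres.
#' @param rho medium density, kg/m^3.
#' @param g gravitational acceleration, m/s^2.
#' @return pressure in Pa.
#' @export
reservoir_pressure <- function(h_m, rho = 1000, g = 9.81) {
  rho * g * h_m
}
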