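#' Spherical probe geometry
#'
#' Force probes are quoted by their tip diameter (30, 60, 100, 200 um in the
#' poking experiments); all contact formulas are written in terms of the tip
#' radius, stored here as `diameter / 2`.
#'
#' @param diameter Probe tip diameter in um. Must be positive.
#' @return An object of class `probe_spec` with fields `diameter` and
#'   `radius` (um).
#' @examples
#' probe_spec(60)$radius  # 30 um
#' @export
probe_spec <- function(diameter) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, is.finite(diameter))
  if (diameter <= 0) stop("probe diameter must be positive")
  structure(list(diameter = diameter, radius = diameter / 2),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("spherical probe: diameter %g um (radius %g um)\n",
              x$diameter, x$radius))
  invisible(x)
}

#' Linear elastic medium
#'
#' @param modulus Elastic (Young's) modulus in MPa, positive.
#' @param poisson Poisson ratio, in `[0, 0.5)`.
#' @return An object of class `elastic_medium`.
#' @export
elastic_medium <- function(modulus, poisson) {
  stopifnot(is.numeric(modulus), length(modulus) == 1L,
            is.numeric(poisson), length(poisson) == 1L)
  if (!is.finite(modulus) || modulus <= 0) {
    stop("invalid medium: modulus must be positive")
  }
  if (!is.finite(poisson) || poisson < 0 || poisson >= 0.5) {
    stop("invalid medium: poisson ratio must lie in [0, 0.5)")
  }
  structure(list(modulus = modulus, poisson = poisson),
            class = "elastic_medium")
}

#' @export
print.elastic_medium <- function(x, ...) {
  cat(sprintf("elastic medium: E = %g MPa, nu = %g\n", x$modulus, x$poisson))
  invisible(x)
}

#' Effective contact modulus of a compliant substrate
#'
#' For a rigid sphere pressed into a compliant medium the Hertz force-depth
#' relation uses the plane-strain effective modulus `E* = E / (1 - nu^2)`.
#'
#' @param medium An [elastic_medium()].
#' @return Effective modulus in MPa.
#' @examples
#' effective_modulus(elastic_medium(2.6, 0.45))  # 3.2602 MPa
#' @export
effective_modulus <- function(medium) {
  if (!inherits(medium, "elastic_medium")) {
    medium <- elastic_medium(medium$modulus, medium$poisson)
  }
  medium$modulus / (1 - medium$poisson^2)
}

#' Indentation depth from piezo step and beam deflection
#'
#' The poking device drives the probe with a piezo stack; part of the step
#' `D` is absorbed by deflection `B` of the force-sensing beam, so the
#' tissue indentation depth is `d = D - B`.
#'
#' @param piezo_step Piezo stepping displacement D (um), `>= 0`.
#' @param beam_deflection Beam deflection B (um), `0 <= B <= D`.
#' @return Indentation depth in um.
#' @export
indentation_depth <- function(piezo_step, beam_deflection) {
  stopifnot(is.numeric(piezo_step), is.numeric(beam_deflection))
  if (any(beam_deflection < 0) || any(piezo_step < 0)) {
    stop("piezo step and beam deflection must be nonnegative")
  }
  if (any(beam_deflection > piezo_step)) {
    stop("negative indentation depth: beam deflection exceeds piezo step")
  }
  piezo_step - beam_deflection
}

# shared validity check for the sphere-surface model: 0 <= d < r
check_depth <- function(probe, depth) {
  stopifnot(is.numeric(depth))
  if (any(depth < 0)) stop("indentation depth must be nonnegative")
  if (any(depth >= probe$radius)) {
    stop("sphere-surface model invalid: indentation depth must be smaller ",
         "than the probe radius")
  }
  invisible(TRUE)
}

#' Hertz contact force for a spherical probe
#'
#' Evaluates `f = (4/3) E* sqrt(r) d^(3/2)` with the effective modulus in
#' MPa and lengths in um; the result is returned in mN. The model requires
#' `d < r`.
#'
#' @param Estar Effective modulus (MPa), see [effective_modulus()].
#' @param probe A [probe_spec()].
#' @param depth Indentation depth d (um); may be a vector.
#' @return Contact force in mN.
#' @examples
#' p <- probe_spec(60)
#' contact_force(effective_modulus(elastic_medium(4, 0.45)), p, 20) # ~3.28 mN
#' @export
contact_force <- function(Estar, probe, depth) {
  stopifnot(is.numeric(Estar), Estar > 0)
  check_depth(probe, depth)
  un_to_mn(4 / 3 * Estar * sqrt(probe$radius) * depth^1.5)
}

#' Hertz contact radius
#'
#' `a = sqrt(r d)`, valid for `d < r`.
#'
#' @inheritParams contact_force
#' @return Contact radius in um.
#' @export
contact_radius <- function(probe, depth) {
  check_depth(probe, depth)
  sqrt(probe$radius * depth)
}

#' Spherical-cap contact area
#'
#' Curved area of the probe-tissue interface,
#' `A_c = 2 pi r (r - sqrt(r^2 - r d))`, valid for `d < r`. For small `d`
#' this tends to the projected-disc area `pi r d`.
#'
#' @inheritParams contact_force
#' @return Contact area in um^2.
#' @export
contact_area <- function(probe, depth) {
  check_depth(probe, depth)
  r <- probe$radius
  2 * pi * r * (r - sqrt(r^2 - r * depth))
}

#' Central contact pressure
#'
#' Peak (centre) pressure of the Hertz contact patch, `P0 = 3 f / (2 pi a^2)`.
#'
#' @param force Contact force in mN; may be a vector.
#' @param a Contact radius in um, positive.
#' @return Pressure in MPa.
#' @export
central_pressure <- function(force, a) {
  stopifnot(is.numeric(force), is.numeric(a))
  if (any(a <= 0)) stop("undefined pressure: contact radius must be positive")
  3 * mn_to_un(force) / (2 * pi * a^2)
}

#' Radial pressure profile of the contact patch
#'
#' Hertz pressure at distance `x` from the centre of the contact patch,
#' `P(x) = P0 sqrt(1 - x^2 / a^2)` for `x <= a` and 0 beyond the patch.
#'
#' @param P0 Central pressure (MPa).
#' @param a Contact radius (um).
#' @param x Distance(s) to the contact centre (um), `>= 0`.
#' @return Pressure(s) in MPa.
#' @export
pressure_profile <- function(P0, a, x) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("x must be nonnegative")
  P0 * sqrt(pmax(0, 1 - x^2 / a^2))
}

#' Weight of a water calibration step
#'
#' The strain gauge is calibrated by adding pure water in known volumes;
#' with density 1 g/mL and g = 9.8 m/s^2, 100 uL weighs 0.98 mN.
#'
#' @param volume Water volume in uL, `>= 0`.
#' @return Force in mN.
#' @examples
#' water_step_force(100)  # 0.98
#' @export
water_step_force <- function(volume) {
  stopifnot(is.numeric(volume))
  if (any(volume < 0)) stop("volume must be nonnegative")
  volume * G_MN_PER_UL
}

#' Fit the strain-gauge force calibration line
#'
#' Ordinary least-squares line mapping gauge voltage readout to force,
#' fitted with a free intercept.
#'
#' @param force Known forces (mN), e.g. from [water_step_force()].
#' @param voltage Gauge voltage readouts (V).
#' @return An object of class `gauge_calibration` with fields `slope`
#'   (mN/V), `intercept` (mN) and `residual` (root-mean-square residual,
#'   mN). Use [predict()] to convert voltages to forces.
#' @export
fit_gauge_calibration <- function(force, voltage) {
  stopifnot(is.numeric(force), is.numeric(voltage),
            length(force) == length(voltage))
  if (length(force) < 2L || length(unique(voltage)) < 2L) {
    stop("gauge calibration needs at least 2 points with distinct voltages")
  }
  fit <- stats::lm(force ~ voltage)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    warning("gauge calibration slope is not positive; check the readout sign")
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 fit = fit),
            class = "gauge_calibration")
}

#' @export
print.gauge_calibration <- function(x, ...) {
  cat(sprintf(
    "gauge calibration: force = %.4g mN/V * V %+.4g mN (rms residual %.3g mN)\n",
    x$slope, x$intercept, x$residual))
  invisible(x)
}

#' @param object A `gauge_calibration` object.
#' @param voltage Voltage readouts to convert.
#' @param ... Unused.
#' @return Forces in mN.
#' @rdname fit_gauge_calibration
#' @export
predict.gauge_calibration <- function(object, voltage, ...) {
  object$intercept + object$slope * voltage
}

#' Bracketing Hertz force-depth curves
#'
#' Lower and upper model force curves obtained from the extreme literature
#' values of the substrate modulus; measured force-depth data are expected
#' to fall between the two.
#'
#' @param probe A [probe_spec()].
#' @param depths Indentation depth grid (um), all `< r`.
#' @param E_low,E_high Substrate modulus bounds (MPa), `E_low < E_high`.
#' @param poisson Poisson ratio of the substrate.
#' @return A data frame with columns `depth`, `f_low`, `f_high` (mN).
#' @export
model_force_bounds <- function(probe, depths, E_low, E_high, poisson) {
  if (!(E_low < E_high)) stop("E_low must be smaller than E_high")
  el <- effective_modulus(elastic_medium(E_low, poisson))
  eh <- effective_modulus(elastic_medium(E_high, poisson))
  data.frame(depth = depths,
             f_low = contact_force(el, probe, depths),
             f_high = contact_force(eh, probe, depths))
}
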