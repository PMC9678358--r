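#' Layered elastic stack
#'
#' Describes the tissue composite under the probe as ordered linear-elastic
#' layers (top to bottom) bonded to each other, with the bottom surface
#' fixed. The default experimental preparation is a 10 um cuticle bonded to
#' a 1000 um PDMS pad.
#'
#' @param thickness Layer thicknesses, top to bottom (um).
#' @param modulus Layer elastic moduli (MPa).
#' @param poisson Layer Poisson ratios, each in `[0, 0.5)`.
#' @return A data frame of class `layer_stack`.
#' @seealso [default_layer_stack()]
#' @export
layer_stack <- function(thickness, modulus, poisson) {
  stopifnot(length(thickness) >= 1L,
            length(modulus) == length(thickness),
            length(poisson) == length(thickness))
  if (any(thickness <= 0) || any(modulus <= 0)) {
    stop("layer thicknesses and moduli must be positive")
  }
  if (any(poisson < 0 | poisson >= 0.5)) {
    stop("layer poisson ratios must lie in [0, 0.5)")
  }
  structure(data.frame(thickness = thickness, modulus = modulus,
                       poisson = poisson),
            class = c("layer_stack", "data.frame"))
}

#' Default cuticle-on-PDMS stack
#'
#' Cuticle: 10 um thick, Poisson 0.45. Reported cuticle moduli span
#' 1-10 MPa; the default of 2.6 MPa is the value in that range for which
#' the solved lateral-tension peak sits 20-25 um from the probe centre for
#' a 60 um probe at 20 um depth, the behaviour reported for this
#' preparation (stiffer cuticles push the bending-dominated tension peak
#' beyond 25 um). PDMS: 1000 um thick, 2.6 MPa, Poisson 0.45. The far more
#' compliant muscle layer is omitted.
#'
#' @param E_cuticle Cuticle modulus in MPa.
#' @param E_pdms PDMS modulus in MPa.
#' @return A [layer_stack()].
#' @export
default_layer_stack <- function(E_cuticle = 2.6, E_pdms = 2.6) {
  layer_stack(thickness = c(10, 1000),
              modulus = c(E_cuticle, E_pdms),
              poisson = c(0.45, 0.45))
}

#' Mesh controls for the indentation solver
#'
#' @param extent Radial extent of the computational domain (um).
#' @param h_surface Fine radial node spacing across the contact patch (um);
#'   default `sqrt(r d) / 70`.
#' @param fine_factor The fine region spans `fine_factor * sqrt(r d)`.
#' @param growth Geometric growth ratio of the radial spacing outside the
#'   fine region.
#' @param h_top Element height at the free surface (um); defaults to the
#'   fine radial spacing, giving well-shaped surface elements.
#' @param depth_growth Geometric growth ratio of element height with depth.
#' @param max_iter Maximum active-set contact iterations.
#' @return A list of class `mesh_control`.
#' @export
mesh_control <- function(extent = 600, h_surface = NULL, fine_factor = 2,
                         growth = 1.06, h_top = NULL, depth_growth = 1.35,
                         max_iter = 30) {
  structure(list(extent = extent, h_surface = h_surface,
                 fine_factor = fine_factor, growth = growth,
                 h_top = h_top, depth_growth = depth_growth,
                 max_iter = max_iter),
            class = "mesh_control")
}

#' Solve rigid-sphere indentation of a layered composite
#'
#' Axisymmetric small-strain linear-elastic solution for a frictionless
#' rigid spherical probe pressed a fixed depth into a bonded layer stack
#' whose bottom surface is fixed. The contact patch is found by an
#' active-set iteration on the surface gap (nonnegative pressure,
#' nonnegative gap, complementarity). Returns the surface radial profiles
#' of perpendicular pressure `P_P` (the contact pressure) and lateral
#' tension `T_L` (the maximum tensile in-plane principal stress at the top
#' surface, clipped at zero where compressive).
#'
#' @param stack A [layer_stack()].
#' @param probe A [probe_spec()].
#' @param depth Indentation depth (um), `0 < depth < r`.
#' @param mesh A [mesh_control()].
#' @param profile Indenter profile: exact `"sphere"` (default) or its
#'   `"paraboloid"` small-slope approximation, which is the geometry the
#'   closed-form Hertz solution assumes.
#' @return A data frame of class `radial_profile` with columns `rho`, `P_P`
#'   and `T_L` (um, MPa, MPa), and attributes `force_mN` (total contact
#'   force), `contact_radius` (um), `iterations` and `n_surface_nodes`.
#' @examples
#' \donttest{
#' sol <- solve_indentation(default_layer_stack(), probe_spec(60), 20)
#' peak_location(sol$rho, sol$T_L)  # ~20-25 um from the probe centre
#' }
#' @export
solve_indentation <- function(stack, probe, depth, mesh = mesh_control(),
                              profile = c("sphere", "paraboloid")) {
  profile <- match.arg(profile)
  stopifnot(inherits(stack, "layer_stack"), inherits(probe, "probe_spec"))
  if (depth <= 0) stop("indentation depth must be positive")
  if (depth >= probe$radius) {
    stop("indentation depth must be smaller than the probe radius")
  }
  a_est <- sqrt(probe$radius * depth)
  h <- if (is.null(mesh$h_surface)) a_est / 70 else mesh$h_surface
  h_top <- if (is.null(mesh$h_top)) h / 2 else mesh$h_top
  r <- radial_grid(a_est, mesh$extent, h, mesh$fine_factor, mesh$growth)
  z <- depth_grid(stack$thickness, h_top, mesh$depth_growth)
  lame <- layer_lame(stack, z)
  K <- assemble_axisym(r, z, lame)
  sol <- contact_solve(K, r, z, probe, depth, profile,
                       max_iter = mesh$max_iter)
  if (sum(sol$active) < 8L) {
    stop("mesh too coarse: fewer than 8 nodes across the contact patch")
  }
  st <- surface_stress(r, z, sol$u, lame, sol$pressure, sol$active)
  T_L <- pmax(pmax(st$sigma_rr, st$sigma_tt), 0)
  out <- data.frame(rho = r, P_P = sol$pressure, T_L = T_L)
  class(out) <- c("radial_profile", "data.frame")
  attr(out, "force_mN") <- un_to_mn(sol$force_un)
  attr(out, "contact_radius") <- max(r[sol$active])
  attr(out, "iterations") <- sol$iterations
  attr(out, "n_surface_nodes") <- length(r)
  attr(out, "stack") <- stack
  attr(out, "probe") <- probe
  attr(out, "depth") <- depth
  out
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf(
    "surface stress profile: %d radial nodes to %g um\n",
    nrow(x), max(x$rho)))
  if (!is.null(attr(x, "force_mN"))) {
    cat(sprintf("  total force %.3g mN, contact radius %.3g um (%d contact iterations)\n",
                attr(x, "force_mN"), attr(x, "contact_radius"),
                attr(x, "iterations")))
  }
  cat(sprintf("  P_P peak %.3g MPa at rho = %.3g um; T_L peak %.3g MPa at rho = %.3g um\n",
              max(x$P_P), peak_location(x$rho, x$P_P),
              max(x$T_L), peak_location(x$rho, x$T_L)))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, normalized = TRUE, xlim = NULL, ...) {
  y1 <- x$P_P
  y2 <- x$T_L
  if (normalized) {
    y1 <- y1 / max(y1)
    y2 <- y2 / max(y2)
  }
  if (is.null(xlim)) xlim <- c(0, min(max(x$rho), 4 * peak_location(x$rho, x$T_L) + 20))
  graphics::plot(x$rho, y1, type = "l", col = "firebrick", xlim = xlim,
                 xlab = "distance to probe centre (um)",
                 ylab = if (normalized) "normalized stress" else "stress (MPa)",
                 ...)
  graphics::lines(x$rho, y2, col = "steelblue")
  graphics::legend("topright", legend = c("P_P", "T_L"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Closed-form Hertz surface stresses for a homogeneous half-space
#'
#' Validation reference for the homogeneous limit of
#' [solve_indentation()]: inside the contact patch the perpendicular
#' pressure is the Hertz ellipse `P0 sqrt(1 - rho^2/a^2)`; outside it the
#' surface radial stress `(1 - 2 nu) a^2 P0 / (3 rho^2)` is tensile and is
#' reported as the lateral tension channel (the in-plane surface stress
#' inside the patch is compressive, hence 0 after clipping).
#'
#' @param medium An [elastic_medium()].
#' @param probe A [probe_spec()].
#' @param depth Indentation depth (um), `0 <= depth < r`.
#' @param rho Radial distances (um).
#' @return A data frame with columns `rho`, `P_P`, `T_L` (MPa).
#' @export
hertz_surface_stress <- function(medium, probe, depth, rho) {
  check_depth(probe, depth)
  a <- contact_radius(probe, depth)
  f <- contact_force(effective_modulus(medium), probe, depth)
  P0 <- central_pressure(f, a)
  inside <- rho < a
  T_L <- ifelse(inside, 0,
                (1 - 2 * medium$poisson) * a^2 * P0 / (3 * pmax(rho, 1e-12)^2))
  data.frame(rho = rho,
             P_P = pressure_profile(P0, a, rho),
             T_L = T_L)
}

#' Normalize each stress channel of a radial profile to its own maximum
#'
#' @param profile A `radial_profile` (or any data frame with `P_P` and
#'   `T_L` columns).
#' @return The profile with each channel divided by its maximum.
#' @export
normalize_profile <- function(profile) {
  for (ch in c("P_P", "T_L")) {
    m <- max(profile[[ch]])
    if (!is.finite(m) || m <= 0) {
      stop("cannot normalize: channel ", ch, " is all zero")
    }
    profile[[ch]] <- profile[[ch]] / m
  }
  profile
}

#' Radius of the maximum of a sampled radial profile
#'
#' Discrete argmax refined by parabolic interpolation through the three
#' samples around it (exact for quadratic peaks). A maximum at the first or
#' last grid point is returned unrefined; ties return the smallest
#' maximizing radius with a warning.
#'
#' @param rho Radii (um), strictly increasing, at least 3 values.
#' @param values Profile values at `rho`.
#' @return Peak radius (um).
#' @export
peak_location <- function(rho, values) {
  stopifnot(length(rho) == length(values), length(rho) >= 3L)
  k <- which(values == max(values))
  if (length(k) > 1L) {
    warning("non-unique maximum; returning the smallest maximizing radius")
    return(rho[k[1L]])
  }
  if (k == 1L || k == length(values)) return(rho[k])
  x <- rho[(k - 1):(k + 1)]
  y <- values[(k - 1):(k + 1)]
  # vertex of the parabola through three (possibly unevenly spaced) points
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  c2 <- (d2 - d1) / (x[3] - x[1])
  if (c2 >= 0) return(rho[k])
  vx <- (x[1] + x[2]) / 2 - d1 / (2 * c2)
  if (vx < x[1] || vx > x[3]) rho[k] else vx
}

#' Revolve a radial profile into a 2D field map
#'
#' Builds square pixel maps of `P_P` and `T_L` centred on the probe by
#' revolving the radial profile about the origin with linear interpolation.
#'
#' @param profile A `radial_profile`.
#' @param pixel_size Pixel size (um).
#' @param extent Half-width of the map (um); the map covers
#'   `[-extent, extent]^2` and its corners must stay inside the profile
#'   range (`extent * sqrt(2) <= max(rho)`).
#' @return An object of class `field_map`: a list with pixel-centre
#'   coordinates `x`, `y`, the `pixel_size`, and matrices `P_P` and `T_L`
#'   (rows indexed by `x`, columns by `y`).
#' @export
radial_to_map <- function(profile, pixel_size = 1, extent = 100) {
  if (extent * sqrt(2) > max(profile$rho) + 1e-9) {
    stop("requested extent reaches beyond the radial profile; ",
         "solve with a larger domain or reduce the extent")
  }
  n <- floor(extent / pixel_size)
  x <- (-n:n) * pixel_size
  rho_pix <- sqrt(outer(x^2, x^2, "+"))
  mk <- function(ch) {
    v <- stats::approx(profile$rho, profile[[ch]], xout = as.numeric(rho_pix),
                       rule = 1)$y
    matrix(v, nrow = length(x))
  }
  structure(list(x = x, y = x, pixel_size = pixel_size,
                 P_P = mk("P_P"), T_L = mk("T_L")),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("field map: %d x %d pixels of %g um; P_P peak %.3g, T_L peak %.3g\n",
              length(x$x), length(x$y), x$pixel_size,
              max(x$P_P), max(x$T_L)))
  invisible(x)
}

# Bilinear interpolation of a field-map channel at arbitrary points
# (n x 2 matrix, same coordinate frame as the map). Points outside the
# map evaluate to 0.
field_values <- function(field, points, channel = c("P_P", "T_L")) {
  channel <- match.arg(channel)
  M <- field[[channel]]
  h <- field$pixel_size
  fx <- (points[, 1] - field$x[1]) / h
  fy <- (points[, 2] - field$y[1]) / h
  i0 <- floor(fx)
  j0 <- floor(fy)
  ok <- i0 >= 0 & i0 <= length(field$x) - 2L & j0 >= 0 & j0 <= length(field$y) - 2L
  out <- numeric(nrow(points))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]
  tx <- fx[ok] - i0
  ty <- fy[ok] - j0
  v00 <- M[cbind(i0 + 1L, j0 + 1L)]
  v10 <- M[cbind(i0 + 2L, j0 + 1L)]
  v01 <- M[cbind(i0 + 1L, j0 + 2L)]
  v11 <- M[cbind(i0 + 2L, j0 + 2L)]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}
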