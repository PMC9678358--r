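# Axisymmetric linear-elastic finite elements on a structured grid of
# bilinear quadrilaterals, used to solve rigid-sphere indentation of a
# layered composite. Near-incompressible layers (nu = 0.45) would lock with
# plain bilinear elements, so the volumetric strain is replaced by its
# element mean (B-bar / selective reduced integration).
#
# Coordinates: r radial (um), z depth below the free surface (um, positive
# downward). Node (i, j) has id (j - 1) * Nr + i; dofs are interleaved
# (u_r = 2 id - 1, u_z = 2 id). Stresses in MPa, nodal forces in uN.

# Graded radial surface grid: uniform fine spacing across the expected
# contact patch, geometric growth outside it.
radial_grid <- function(a_est, extent, h_fine, fine_factor = 2, growth = 1.06) {
  fine_end <- min(fine_factor * a_est, extent)
  r <- seq(0, fine_end, by = h_fine)
  h <- h_fine
  while (r[length(r)] < extent - 1e-9) {
    h <- h * growth
    r <- c(r, min(r[length(r)] + h, extent))
  }
  r
}

# Depth grid through the layer stack: element height starts at h_top at
# the free surface (where the surface stress recovery needs resolution) and
# grows geometrically downwards; layer interfaces always coincide with grid
# lines.
depth_grid <- function(thicknesses, h_top, growth = 1.35) {
  z <- 0
  h <- h_top
  base <- 0
  for (t in thicknesses) {
    sizes <- h
    while (sum(sizes) < t) {
      h <- h * growth
      sizes <- c(sizes, h)
    }
    sizes <- sizes * (t / sum(sizes))  # snap to the layer interface
    z <- c(z, base + cumsum(sizes))
    base <- base + t
    h <- sizes[length(sizes)]
  }
  z
}

# Element-wise Lame parameters from the layer stack (elements ordered with
# radial index fastest, matching the assembly below).
layer_lame <- function(stack, z) {
  zc <- (z[-1] + z[-length(z)]) / 2            # element-row centre depths
  bounds <- cumsum(stack$thickness)
  idx <- findInterval(zc, bounds, left.open = TRUE) + 1L
  idx[idx > nrow(stack)] <- nrow(stack)
  E <- stack$modulus[idx]
  nu <- stack$poisson[idx]
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)),
       row_layer = idx)
}

# Shape function helpers for the bilinear quad, natural coords (xi, eta).
XI_A <- c(-1, 1, 1, -1)
ETA_A <- c(-1, -1, 1, 1)

shape_q4 <- function(xi, eta) {
  list(N = (1 + XI_A * xi) * (1 + ETA_A * eta) / 4,
       dN_dxi = XI_A * (1 + ETA_A * eta) / 4,
       dN_deta = ETA_A * (1 + XI_A * xi) / 4)
}

# Strain-displacement rows at one natural point for all elements at once.
# Returns matrices (Ne x 8): B1 = eps_rr, B2 = eps_zz, B3 = eps_tt, B4 =
# gamma_rz. r_pt is the physical radius of the point in each element; at
# the axis (r = 0) eps_tt -> eps_rr.
bmat_q4 <- function(sh, dr, dz, r_pt) {
  ne <- length(dr)
  B1 <- B2 <- B3 <- B4 <- matrix(0, ne, 8)
  ur <- seq(1, 8, by = 2)
  uz <- seq(2, 8, by = 2)
  for (a in 1:4) {
    dNr <- sh$dN_dxi[a] * 2 / dr
    dNz <- sh$dN_deta[a] * 2 / dz
    B1[, ur[a]] <- dNr
    B2[, uz[a]] <- dNz
    B3[, ur[a]] <- ifelse(r_pt > 1e-9, sh$N[a] / pmax(r_pt, 1e-9), dNr)
    B4[, ur[a]] <- dNz
    B4[, uz[a]] <- dNr
  }
  list(B1 = B1, B2 = B2, B3 = B3, B4 = B4)
}

GAUSS_PT <- 1 / sqrt(3)

# Assemble the global stiffness matrix (sparse, symmetric) for the grid
# (r, z) with per-element-row Lame parameters.
assemble_axisym <- function(r, z, lame) {
  nr <- length(r)
  nz <- length(z)
  ner <- nr - 1L
  nez <- nz - 1L
  ne <- ner * nez

  # per-element geometry, radial index fastest
  dr <- rep(diff(r), times = nez)
  dz <- rep(diff(z), each = ner)
  r0 <- rep(r[-nr], times = nez)
  lambda <- rep(lame$lambda, each = ner)
  mu <- rep(lame$mu, each = ner)

  gx <- c(-1, 1, 1, -1) * GAUSS_PT
  ge <- c(-1, -1, 1, 1) * GAUSS_PT
  detJ <- dr * dz / 4

  # pass 1: element volume and mean volumetric strain operator (B-bar)
  vol <- numeric(ne)
  bvol_mean <- matrix(0, ne, 8)
  Bg <- vector("list", 4L)
  rg <- vector("list", 4L)
  for (g in 1:4) {
    sh <- shape_q4(gx[g], ge[g])
    r_pt <- r0 + dr * (1 + gx[g]) / 2
    B <- bmat_q4(sh, dr, dz, r_pt)
    w <- 2 * pi * r_pt * detJ
    vol <- vol + w
    bvol_mean <- bvol_mean + (B$B1 + B$B2 + B$B3) * w
    Bg[[g]] <- B
    rg[[g]] <- r_pt
  }
  bvol_mean <- bvol_mean / vol

  # pass 2: stiffness with the volumetric part of B replaced by its mean
  K36 <- vector("list", 64L)
  for (g in 1:4) {
    B <- Bg[[g]]
    w <- 2 * pi * rg[[g]] * detJ
    corr <- (bvol_mean - (B$B1 + B$B2 + B$B3)) / 3
    B1 <- B$B1 + corr
    B2 <- B$B2 + corr
    B3 <- B$B3 + corr
    B4 <- B$B4
    s <- B1 + B2 + B3
    for (a in 1:8) {
      for (b in 1:8) {
        k <- (a - 1L) * 8L + b
        val <- (lambda * s[, a] * s[, b] +
                  2 * mu * (B1[, a] * B1[, b] + B2[, a] * B2[, b] +
                              B3[, a] * B3[, b]) +
                  mu * B4[, a] * B4[, b]) * w
        K36[[k]] <- if (g == 1) val else K36[[k]] + val
      }
    }
  }

  # global dof indices of the 8 local dofs of every element
  ei <- rep(seq_len(ner), times = nez)
  ej <- rep(seq_len(nez), each = ner)
  n1 <- (ej - 1L) * nr + ei
  nodes <- cbind(n1, n1 + 1L, n1 + nr + 1L, n1 + nr)
  dofs <- matrix(0L, ne, 8)
  dofs[, seq(1, 8, 2)] <- 2L * nodes - 1L
  dofs[, seq(2, 8, 2)] <- 2L * nodes

  ii <- integer(ne * 64L)
  jj <- integer(ne * 64L)
  xx <- numeric(ne * 64L)
  pos <- 1L
  for (a in 1:8) {
    for (b in 1:8) {
      k <- (a - 1L) * 8L + b
      idx <- pos:(pos + ne - 1L)
      ii[idx] <- dofs[, a]
      jj[idx] <- dofs[, b]
      xx[idx] <- K36[[k]]
      pos <- pos + ne
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(2L * nr * nz, 2L * nr * nz))
}

# Initial gap between the undeformed surface and the indenter tip at radius
# rho, for a sphere of radius R or its paraboloid (Hertz) approximation.
indenter_gap <- function(rho, R, profile = c("sphere", "paraboloid")) {
  profile <- match.arg(profile)
  if (profile == "sphere") {
    ifelse(rho < R, R - sqrt(pmax(R^2 - rho^2, 0)), Inf)
  } else {
    rho^2 / (2 * R)
  }
}

# Consistent nodal area of each surface node (um^2): integral of the linear
# surface shape function against 2 pi rho, used to convert nodal contact
# reactions to pressures. (A plain midpoint tributary area is wrong by 4/3
# at the axis node.)
tributary_area <- function(r) {
  n <- length(r)
  area <- numeric(n)
  h <- diff(r)
  # right element of node i: int (1 - s/h)(r_i + s) ds = r_i h/2 + h^2/6
  area[-n] <- area[-n] + 2 * pi * (r[-n] * h / 2 + h^2 / 6)
  # left element of node i: int (s/h)(r_{i-1} + s) ds = r_{i-1} h/2 + h^2/3
  area[-1] <- area[-1] + 2 * pi * (r[-n] * h / 2 + h^2 / 3)
  area
}

# Active-set solve of the frictionless rigid-indenter contact problem under
# displacement control. Returns displacements, contact pressures and the
# active node set.
contact_solve <- function(K, r, z, probe, depth, profile, max_iter = 30) {
  nr <- length(r)
  nz <- length(z)
  ndof <- 2L * nr * nz
  gap <- indenter_gap(r, probe$radius, profile)
  overlap <- depth - gap                      # prescribed u_z where active

  bottom_nodes <- (nz - 1L) * nr + seq_len(nr)
  axis_nodes <- (seq_len(nz) - 1L) * nr + 1L
  fixed_dofs <- c(2L * bottom_nodes - 1L, 2L * bottom_nodes,
                  2L * axis_nodes - 1L)
  surf_uz <- 2L * seq_len(nr)                 # u_z dofs of surface nodes

  active <- overlap > 0
  if (sum(active) < 2L) stop("contact solver: indentation too small for grid")

  u <- numeric(ndof)
  for (iter in seq_len(max_iter)) {
    pres <- c(fixed_dofs, surf_uz[active])
    upres <- c(numeric(length(fixed_dofs)), overlap[active])
    free <- setdiff(seq_len(ndof), pres)
    rhs <- -K[free, pres, drop = FALSE] %*% upres
    u <- numeric(ndof)
    u[pres] <- upres
    u[free] <- as.numeric(Matrix::solve(K[free, free], rhs))

    react <- as.numeric(K[surf_uz, , drop = FALSE] %*% u)
    rtol <- 1e-9 * max(abs(react), 1e-12)
    gtol <- 1e-9 * max(abs(overlap[is.finite(overlap)]))
    release <- active & react < -rtol
    penetr <- !active & is.finite(overlap) & (u[surf_uz] < overlap - gtol)
    if (!any(release) && !any(penetr)) {
      pressure <- numeric(nr)
      pressure[active] <- react[active] / tributary_area(r)[active]
      return(list(u = u, active = active, pressure = pmax(pressure, 0),
                  force_un = sum(react[active]), iterations = iter))
    }
    active <- (active & !release) | penetr
  }
  stop("contact solver failed to converge after ", max_iter,
       " active-set iterations (", sum(active), " active nodes); ",
       "refine the mesh or reduce the indentation depth")
}

# Derivative at x = xt of the quadratic through three samples.
deriv3 <- function(x, y, xt) {
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  c2 <- (d2 - d1) / (x[3] - x[1])
  d1 + c2 * (2 * xt - x[1] - x[2])
}

# First derivative on a non-uniform grid by the 3-point central stencil
# (one-sided at the ends). If `kbreak` is given, the derivative is
# discontinuous across the interval (kbreak, kbreak + 1) and one-sided
# stencils are used on each side, which keeps a kink (e.g. the contact
# edge) sharp to one grid cell.
grad_nonuniform <- function(x, y, kbreak = NULL) {
  n <- length(x)
  g <- numeric(n)
  hl <- x[2:(n - 1)] - x[1:(n - 2)]
  hr <- x[3:n] - x[2:(n - 1)]
  g[2:(n - 1)] <- (hl^2 * y[3:n] + (hr^2 - hl^2) * y[2:(n - 1)] -
                     hr^2 * y[1:(n - 2)]) / (hl * hr * (hl + hr))
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (!is.null(kbreak) && kbreak >= 3L && kbreak <= n - 3L) {
    k <- kbreak
    g[k] <- deriv3(x[(k - 2):k], y[(k - 2):k], x[k])
    g[k + 1L] <- deriv3(x[(k + 1):(k + 3)], y[(k + 1):(k + 3)], x[k + 1L])
  }
  g
}

# In-plane surface stresses (sigma_rr, sigma_tt, MPa) at the surface nodes.
# Recovered from the surface radial displacement and the known surface
# traction: eps_rr = du_r/dr and eps_tt = u_r/r come from the nodal
# displacements, and eps_zz is eliminated through sigma_zz = -p (contact
# pressure under the indenter, 0 on the free surface). This avoids
# z-derivatives of the near-incompressible field, which dominate the error
# of naive element-stress recovery here.
surface_stress <- function(r, z, u, lame, pressure, active = NULL) {
  nr <- length(r)
  ur <- u[2L * seq_len(nr) - 1L]
  lambda <- lame$lambda[1]
  mu <- lame$mu[1]
  kbreak <- if (!is.null(active) && any(active)) max(which(active)) else NULL
  e_rr <- grad_nonuniform(r, ur, kbreak)
  e_tt <- c(e_rr[1], ur[-1] / r[-1])  # at the axis eps_tt -> eps_rr
  szz <- -pressure
  cpl <- 2 * mu * lambda / (lambda + 2 * mu)
  cz <- lambda / (lambda + 2 * mu)
  s_rr <- cpl * (e_rr + e_tt) + 2 * mu * e_rr + cz * szz
  s_tt <- cpl * (e_rr + e_tt) + 2 * mu * e_tt + cz * szz
  list(sigma_rr = s_rr, sigma_tt = s_tt)
}
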