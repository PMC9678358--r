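# One moderate homogeneous solve shared by several blocks (paraboloid
# indenter, for which the closed-form Hertz solution is the continuum
# limit) and one layered default solve.
hom_medium <- elastic_medium(2.6, 0.45)
hom_stack <- layer_stack(c(10, 1000), c(2.6, 2.6), c(0.45, 0.45))
hom_probe <- probe_spec(60)
hom_depth <- 5
hom_sol <- solve_indentation(hom_stack, hom_probe, hom_depth,
                             profile = "paraboloid")
hom_a <- contact_radius(hom_probe, hom_depth)
hom_f <- contact_force(effective_modulus(hom_medium), hom_probe, hom_depth)
hom_P0 <- central_pressure(hom_f, hom_a)

lay_sol <- solve_indentation(default_layer_stack(), probe_spec(60), 20)

test_that("closed-form Hertz surface stresses behave as derived", {
  med <- elastic_medium(2.6, 0.45)
  p <- probe_spec(60)
  a <- contact_radius(p, 5)
  f <- contact_force(effective_modulus(med), p, 5)
  P0 <- central_pressure(f, a)
  st <- hertz_surface_stress(med, p, 5, c(0, a, 2 * a, 4 * a))
  expect_equal(st$P_P[1], P0)
  expect_equal(st$T_L[2], (1 - 2 * 0.45) / 3 * P0)
  expect_equal(st$T_L[2], 0.03333 * P0, tolerance = 1e-3)
  # inverse-square decay outside the contact
  expect_equal(st$T_L[2] / st$T_L[3], 4)
  expect_equal(st$T_L[3] / st$T_L[4], 4)
})

test_that("homogeneous-limit solver matches the Hertz oracle", {
  ref <- hertz_surface_stress(hom_medium, hom_probe, hom_depth, hom_sol$rho)
  sel <- hom_sol$rho <= 0.9 * hom_a
  expect_lt(max(abs(hom_sol$P_P[sel] - ref$P_P[sel])) / hom_P0, 0.05)
  # resultant force agrees with the Hertz force-depth law
  expect_equal(attr(hom_sol, "force_mN"), hom_f, tolerance = 0.05)
  # lateral tension peaks at the contact edge, to one grid cell
  k <- which.max(hom_sol$T_L)
  cell <- diff(hom_sol$rho)[k - 1]
  expect_lt(abs(hom_sol$rho[k] - hom_a), cell + 1e-9)
  # and its magnitude approaches the closed-form edge value
  expect_equal(max(hom_sol$T_L), (1 - 2 * 0.45) / 3 * hom_P0,
               tolerance = 0.1)
})

test_that("halving the mesh moves the lateral tension peak by under a cell", {
  h <- sqrt(hom_probe$radius * hom_depth) / 70
  fine <- solve_indentation(hom_stack, hom_probe, hom_depth,
                            mesh_control(h_surface = h / 2),
                            profile = "paraboloid")
  expect_lt(abs(peak_location(fine$rho, fine$T_L) -
                  peak_location(hom_sol$rho, hom_sol$T_L)), h)
})

test_that("layered solve keeps lateral tension far out where pressure is gone", {
  i40 <- which.min(abs(lay_sol$rho - 40))
  relT <- lay_sol$T_L[i40] / max(lay_sol$T_L)
  relP <- lay_sol$P_P[i40] / max(lay_sol$P_P)
  expect_gt(relT, relP)
  expect_gt(relT, 0.2)   # substantial tension 40 um out
  expect_equal(relP, 0)  # no contact pressure there
})

test_that("solver rejects invalid depths and unresolvable contacts", {
  expect_error(solve_indentation(hom_stack, probe_spec(30), 20), "smaller")
  expect_error(solve_indentation(hom_stack, hom_probe, -1), "positive")
  expect_error(
    solve_indentation(hom_stack, hom_probe, hom_depth,
                      mesh_control(h_surface = hom_a / 3)),
    "fewer than 8|too small")
})

test_that("revolved field maps reproduce the radial profile", {
  prof <- data.frame(rho = seq(0, 150, by = 1))
  prof$P_P <- pmax(0, 1 - prof$rho / 100)
  prof$T_L <- rep(2, nrow(prof))
  fm <- radial_to_map(prof, pixel_size = 2, extent = 100)
  # a constant channel revolves to a constant map
  expect_true(all(abs(fm$T_L - 2) < 1e-12))
  # map pixels agree with the profile at their radius
  i <- which(fm$x == 40)
  j <- which(fm$y == 30)
  expect_equal(fm$P_P[i, j], 1 - 50 / 100, tolerance = 1e-6)
  # radial symmetry: invariant under 90 degree rotation
  rot <- t(fm$P_P[rev(seq_along(fm$x)), ])
  expect_equal(fm$P_P, rot, tolerance = 1e-12)
  expect_error(radial_to_map(prof, pixel_size = 2, extent = 140), "beyond")
})

test_that("profile normalization is per-channel, idempotent, peak-preserving", {
  prof <- data.frame(rho = seq(0, 100, by = 1))
  prof$P_P <- exp(-prof$rho / 30) * 5
  prof$T_L <- prof$rho * exp(-prof$rho / 20)
  np <- normalize_profile(prof)
  expect_equal(max(np$P_P), 1)
  expect_equal(max(np$T_L), 1)
  expect_equal(normalize_profile(np), np)
  expect_equal(peak_location(np$rho, np$T_L), peak_location(prof$rho, prof$T_L))
  prof$T_L <- 0
  expect_error(normalize_profile(prof), "all zero")
})

test_that("peak location refines symmetric peaks and respects boundaries", {
  expect_equal(peak_location(c(0, 10, 20), c(0, 1, 0)), 10)
  # monotone decreasing profile peaks at the centre, like P_P
  expect_equal(peak_location(seq(0, 50, 10), exp(-seq(0, 50, 10) / 15)), 0)
  # exact on quadratics, even on an uneven grid
  x <- c(2, 5, 9, 13.2, 18, 25)
  y <- 5 - (x - 11.3)^2
  expect_equal(peak_location(x, y), 11.3, tolerance = 1e-9)
  expect_warning(pk <- peak_location(c(0, 10, 20, 30), c(0, 1, 1, 0)),
                 "non-unique")
  expect_equal(pk, 10)
})
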