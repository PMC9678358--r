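test_that("effective modulus follows E/(1 - nu^2) and rejects bad media", {
  expect_equal(effective_modulus(elastic_medium(2.6, 0.45)), 2.6 / (1 - 0.45^2))
  expect_equal(effective_modulus(elastic_medium(2.6, 0.45)), 3.2602, tolerance = 1e-4)
  expect_equal(effective_modulus(elastic_medium(1, 0)), 1)
  expect_equal(effective_modulus(elastic_medium(4, 0.45)), 5.0157, tolerance = 1e-4)
  expect_error(elastic_medium(2.6, 0.5), "poisson")
  expect_error(elastic_medium(-1, 0.3), "modulus")
})

test_that("indentation depth is piezo step minus beam deflection", {
  expect_equal(indentation_depth(50, 50), 0)
  expect_equal(indentation_depth(50, 10), 40)
  expect_error(indentation_depth(10, 20), "negative")
})

test_that("contact force matches an independent SI-unit evaluation", {
  # same Hertz formula evaluated in metres and pascals, converted to mN
  Estar <- effective_modulus(elastic_medium(4, 0.45))
  f_si <- 4 / 3 * (Estar * 1e6) * sqrt(30e-6) * (20e-6)^1.5 * 1e3
  expect_equal(contact_force(Estar, probe_spec(60), 20), f_si, tolerance = 1e-12)
  expect_equal(f_si, 3.28, tolerance = 2e-3)
  expect_equal(contact_force(5, probe_spec(60), 0), 0)
  expect_error(contact_force(5, probe_spec(30), 20), "smaller")
})

test_that("contact force is strictly increasing in depth", {
  d <- seq(0.5, 25, by = 0.5)
  f <- contact_force(3.26, probe_spec(60), d)
  expect_true(all(diff(f) > 0))
})

test_that("contact radius is sqrt(r d) with the d < r validity bound", {
  expect_equal(contact_radius(probe_spec(60), 20), sqrt(600))
  expect_equal(contact_radius(probe_spec(60), 0), 0)
  expect_error(contact_radius(probe_spec(30), 15), "smaller")
})

test_that("contact area equals the spherical-cap surface integral", {
  r <- 30; d <- 20
  a <- sqrt(r * d)
  # independent oracle: area of revolution of the sphere over the patch
  cap <- stats::integrate(function(s) 2 * pi * s * r / sqrt(r^2 - s^2),
                          0, a, rel.tol = 1e-10)$value
  expect_equal(contact_area(probe_spec(60), 20), cap, tolerance = 1e-8)
  expect_equal(contact_area(probe_spec(60), 20), 2390.2, tolerance = 1e-4)
  expect_equal(contact_area(probe_spec(60), 0), 0)
  # small-depth limit: cap area approaches the projected disc pi r d
  expect_equal(contact_area(probe_spec(200), 0.1), pi * 100 * 0.1,
               tolerance = 1e-3)
})

test_that("contact area is at least the projected disc area", {
  p <- probe_spec(60)
  for (d in seq(0.5, 29, by = 0.5)) {
    expect_gte(contact_area(p, d), pi * contact_radius(p, d)^2)
  }
})

test_that("central pressure is 3f/(2 pi a^2), linear in force", {
  f_si <- 3 * 3.28e-3 / (2 * pi * (24.495e-6)^2)   # Pa
  expect_equal(central_pressure(3.28, 24.495), f_si / 1e6, tolerance = 1e-12)
  expect_equal(central_pressure(3.28, 24.495), 2.61, tolerance = 5e-3)
  expect_equal(central_pressure(0, 10), 0)
  expect_equal(central_pressure(4, 10), 2 * central_pressure(2, 10))
  expect_error(central_pressure(1, 0), "undefined")
})

test_that("pressure profile has Hertz shape and conserves the total force", {
  p <- probe_spec(60)
  d <- 20
  a <- contact_radius(p, d)
  f <- contact_force(3.26, p, d)
  P0 <- central_pressure(f, a)
  expect_equal(pressure_profile(P0, a, 0), P0)
  expect_equal(pressure_profile(P0, a, a), 0)
  expect_equal(pressure_profile(P0, a, 2 * a), 0)  # zero outside the patch
  # disc integral of the profile returns the contact force to < 0.1 %
  f_int <- stats::integrate(function(x) pressure_profile(P0, a, x) * 2 * pi * x,
                            0, a, rel.tol = 1e-9)$value / 1000  # uN -> mN
  expect_equal(f_int, f, tolerance = 1e-3)
})

test_that("water calibration steps weigh volume x g", {
  expect_identical(water_step_force(100), 0.98)
  expect_equal(water_step_force(0), 0)
  expect_equal(water_step_force(250), 2.45)
  expect_error(water_step_force(-1), "nonnegative")
})

test_that("gauge calibration recovers a known line", {
  cal <- fit_gauge_calibration(c(0, 1, 2), c(0, 1, 2))
  expect_equal(cal$slope, 1)
  expect_equal(cal$intercept, 0)
  expect_equal(cal$residual, 0)
  expect_equal(predict(cal, c(0.5, 3)), c(0.5, 3))
  expect_error(fit_gauge_calibration(1, 1), "at least 2")
  expect_error(fit_gauge_calibration(c(1, 2), c(3, 3)), "distinct")
})

test_that("gauge calibration slope is within 2 se on noisy data", {
  set.seed(42)
  v <- seq(0, 5, by = 0.1)
  f <- 2.5 * v + 0.3 + rnorm(length(v), 0, 0.05)
  cal <- fit_gauge_calibration(f, v)
  se <- summary(cal$fit)$coefficients["voltage", "Std. Error"]
  expect_lt(abs(cal$slope - 2.5), 2 * se)
})

test_that("model force bounds bracket and scale with the modulus ratio", {
  p <- probe_spec(60)
  d <- seq(0, 25, by = 5)
  b <- model_force_bounds(p, d, 1.6, 4, 0.45)
  expect_equal(b$f_high, b$f_low * (4 / 1.6), tolerance = 1e-12)
  expect_equal(b$f_low[1], 0)
  expect_equal(b$f_high[1], 0)
  at20 <- b[b$depth == 20, ]
  expect_equal(at20$f_low, 1.31, tolerance = 5e-3)
  expect_equal(at20$f_high, 3.28, tolerance = 5e-3)
  expect_error(model_force_bounds(p, d, 4, 1.6, 0.45), "smaller")
})

test_that("smaller probes trade contact area for pressure at fixed force", {
  f <- 0.5  # mN; small enough that d < r holds for every probe
  Estar <- 3.26
  vals <- lapply(c(30, 60, 100), function(dia) {
    p <- probe_spec(dia)
    d <- ((f * 1000) / (4 / 3 * Estar * sqrt(p$radius)))^(2 / 3)
    a <- contact_radius(p, d)
    list(P0 = central_pressure(f, a), Ac = contact_area(p, d))
  })
  P0s <- sapply(vals, `[[`, "P0")
  Acs <- sapply(vals, `[[`, "Ac")
  expect_true(all(diff(P0s) < 0))  # pressure drops as the probe grows
  expect_true(all(diff(Acs) > 0))  # contact area grows with the probe
})
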