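test_that("total length sums segment lengths", {
  one <- arbor(data.frame(id = 1:2, x = c(0, 0), y = c(0, 100),
                          parent = c(-1L, 1L)))
  expect_equal(total_length(one), 100)
  expect_equal(total_length(make_cross_arbor(300, 5)), 1200)
  # independent per-edge oracle on a random tree
  set.seed(1)
  n <- 60
  nodes <- data.frame(id = 1:n, x = runif(n, -50, 50), y = runif(n, -50, 50),
                      parent = c(-1L, sapply(2:n, function(i) sample(i - 1, 1))))
  arb <- arbor(nodes)
  manual <- sum(sapply(2:n, function(i) {
    j <- nodes$parent[i]
    sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2)
  }))
  expect_equal(total_length(arb), manual)
})

test_that("SWC round trip preserves coordinates and topology", {
  arb <- generate_arbor("c4da_wt", seed = 2, total_length = 3000,
                        territory_radius = 90)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(arb, path)
  back <- read_swc(path, class_label = "c4da_wt", territory_radius = 90)
  expect_equal(back$nodes$x, arb$nodes$x, tolerance = 1e-6)
  expect_equal(back$nodes$y, arb$nodes$y, tolerance = 1e-6)
  expect_identical(back$nodes$parent, arb$nodes$parent)
})

test_that("malformed SWC inputs are rejected, 3D input is flattened", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 5 0 0 1 99"), path)
  expect_error(read_swc(path), "parent")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 5 0 0 1 1", "3 1 9 9 0 1 -1"), path)
  expect_error(read_swc(path), "root")
  writeLines(c("1 1 0 0 2.5 1 -1", "2 3 5 0 2.5 1 1"), path)
  expect_warning(arb <- read_swc(path), "3D")
  expect_equal(arb$nodes$x, c(0, 5))
})

test_that("Sholl crossings of a radial cross follow 4/(2 pi r)", {
  arb <- make_cross_arbor(300, 5)
  sh <- sholl(arb, dr = 10, r_max = 400)
  inside <- sh$radius < 300
  expect_true(all(sh$intersections[inside] == 4L))
  expect_equal(sh$density[inside], 4 / (2 * pi * sh$radius[inside]))
  expect_true(all(sh$intersections[sh$radius > 300] == 0L))
  # density x circumference returns the counts exactly, at every ring
  expect_equal(sh$density * 2 * pi * sh$radius, as.numeric(sh$intersections))
})

test_that("a segment tangent to a Sholl ring counts once", {
  nodes <- data.frame(id = 1:3,
                      x = c(0, -5, 5), y = c(0, 10, 10),
                      parent = c(-1L, 1L, 2L))
  arb <- arbor(nodes)
  sh <- sholl(arb, dr = 10, r_max = 10)
  # one crossing on the way out plus one tangent touch at (0, 10)
  expect_identical(sh$intersections, 2L)
})

test_that("distance maps agree with the exact point-to-segment oracle", {
  arb <- generate_arbor("c4da_wt", seed = 1, total_length = 4000,
                        territory_radius = 100)
  dm <- distance_map(arb, pixel_size = 2)
  set.seed(7)
  i <- sample(length(dm$x), 100, replace = TRUE)
  j <- sample(length(dm$y), 100, replace = TRUE)
  pts <- cbind(dm$x[i], dm$y[j])
  exact <- dist_to_arbor(pts, arb)
  expect_lt(max(abs(dm$values[cbind(i, j)] - exact)), 2)  # one pixel
  expect_error(distance_map(arb, pixel_size = 0), "positive")
})

test_that("exact distances handle on-segment and perpendicular points", {
  arb <- arbor(data.frame(id = 1:2, x = c(0, 0), y = c(-50, 50),
                          parent = c(-1L, 1L)))
  expect_equal(dist_to_arbor(cbind(20, 0), arb), 20)
  expect_equal(dist_to_arbor(cbind(0, 10), arb), 0)
  expect_equal(dist_to_arbor(cbind(3, 70), arb), sqrt(3^2 + 20^2))
})

test_that("stimulus position sampling honours mode and seed", {
  arb <- generate_arbor("c4da_wt", seed = 4)
  u1 <- sample_stimulus_positions(arb, 50, "uniform", seed = 3)
  u2 <- sample_stimulus_positions(arb, 50, "uniform", seed = 3)
  expect_identical(u1, u2)
  rho <- sqrt(rowSums(sweep(u1, 2, arb$soma)^2))
  expect_true(all(rho <= arb$territory_radius))

  pr <- sample_stimulus_positions(arb, 20, "proximal", seed = 5)
  rr <- sqrt(rowSums(sweep(pr, 2, arb$soma)^2))
  expect_true(all(abs(rr - 100) <= 10))
  expect_true(all(dist_to_arbor(pr, arb) < 1e-6))  # on the dendrite

  di <- sample_stimulus_positions(arb, 20, "distal", seed = 5)
  rr <- sqrt(rowSums(sweep(di, 2, arb$soma)^2))
  expect_true(all(abs(rr - 200) <= 10))

  # dendrite-off placements 20 um from a dendrite exist in the sparse
  # distal field of a cut-knockdown arbor
  cti <- generate_arbor("c4da_cti", seed = 4)
  off <- sample_stimulus_positions(cti, 15, "d_off", seed = 6, distance = 20)
  expect_true(all(abs(dist_to_arbor(off, cti) - 20) <= 2))
  # but a dense wild-type arbor leaves no point that far from a dendrite
  expect_error(
    sample_stimulus_positions(arb, 5, "d_off", seed = 6, distance = 80),
    "could not sample")
})

test_that("arbors reject cycles and multiple roots", {
  expect_error(arbor(data.frame(id = 1:2, x = 0:1, y = 0:1,
                                parent = c(-1L, -1L))), "root")
  expect_error(arbor(data.frame(id = 1:3, x = 0:2, y = 0:2,
                                parent = c(-1L, 3L, 2L))), "cycle")
})
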