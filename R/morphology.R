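#' Planar dendritic arbor
#'
#' A dendritic tree rooted at the soma, stored as SWC-style nodes: each
#' node has an id, planar coordinates (um) and a parent id (-1 for the
#' root). Dendritic arborization neurons tile a two-dimensional epidermal
#' sheet, so arbors are planar (z = 0).
#'
#' @param nodes Data frame with columns `id`, `x`, `y`, `parent`.
#' @param class_label One of `"c4da_wt"`, `"c4da_cti"`, `"c3da"`,
#'   `"custom"`.
#' @param territory_radius Radius (um) of the disc around the soma taken
#'   as the dendritic territory; defaults to 220 um (just beyond the
#'   200 um ring used for distal stimuli).
#' @return An object of class `arbor`.
#' @export
arbor <- function(nodes, class_label = "custom", territory_radius = 220) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "x", "y", "parent") %in% names(nodes)))
  root <- which(nodes$parent == -1)
  if (length(root) != 1L) {
    stop("arbor must have exactly one root (parent = -1); found ",
         length(root))
  }
  idx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1 & is.na(idx))
  if (length(bad)) {
    stop("malformed arbor: parent id of node ", nodes$id[bad[1]],
         " does not exist")
  }
  # cycle check by repeated parent contraction
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    frontier <- which(idx %in% frontier & is.na(depth))
    depth[frontier] <- 1L
  }
  if (anyNA(depth)) stop("malformed arbor: cycle or disconnected nodes")
  structure(list(nodes = nodes,
                 soma = c(x = nodes$x[root], y = nodes$y[root]),
                 class_label = class_label,
                 territory_radius = territory_radius),
            class = "arbor")
}

# Segment table of an arbor: one row per (parent -> child) edge, columns
# x0, y0, x1, y1, len. Cached on the object by the constructor's callers.
arbor_segments <- function(arb) {
  nd <- arb$nodes
  child <- which(nd$parent != -1)
  pidx <- match(nd$parent[child], nd$id)
  seg <- cbind(x0 = nd$x[pidx], y0 = nd$y[pidx],
               x1 = nd$x[child], y1 = nd$y[child])
  len <- sqrt((seg[, "x1"] - seg[, "x0"])^2 + (seg[, "y1"] - seg[, "y0"])^2)
  cbind(seg, len = len)
}

#' @export
print.arbor <- function(x, ...) {
  cat(sprintf("dendritic arbor (%s): %d nodes, total length %.0f um, territory radius %g um\n",
              x$class_label, nrow(x$nodes), total_length(x),
              x$territory_radius))
  invisible(x)
}

#' @export
plot.arbor <- function(x, col = "grey25", add = FALSE, ...) {
  seg <- arbor_segments(x)
  if (!add) {
    lim <- x$territory_radius * c(-1, 1)
    graphics::plot(NA, xlim = x$soma[1] + lim, ylim = x$soma[2] + lim,
                   asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  }
  graphics::segments(seg[, "x0"], seg[, "y0"], seg[, "x1"], seg[, "y1"],
                     col = col)
  graphics::points(x$soma[1], x$soma[2], pch = 16, col = "firebrick")
  invisible(x)
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`). Arbors are
#' planar; nonzero z coordinates are dropped with a warning.
#'
#' @param path Path to an SWC file.
#' @param class_label,territory_radius Passed to [arbor()].
#' @return An [arbor()].
#' @export
read_swc <- function(path, class_label = "custom", territory_radius = 220) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (any(abs(tab$z) > 1e-9)) {
    warning("3D SWC input: z coordinates dropped (arbors are planar)")
  }
  arbor(data.frame(id = tab$id, x = tab$x, y = tab$y, parent = tab$parent),
        class_label = class_label, territory_radius = territory_radius)
}

#' Write a morphology to an SWC file
#'
#' Coordinates are written with 6 decimal places, so a read/write round
#' trip preserves them to 1e-6 um.
#'
#' @param arb An [arbor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(arb, path) {
  nd <- arb$nodes
  type <- ifelse(nd$parent == -1, 1L, 3L)  # soma point, then dendrite
  lines <- sprintf("%d %d %.6f %.6f %.6f %.3f %d",
                   nd$id, type, nd$x, nd$y, 0, 0.5, nd$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' Total dendritic length
#'
#' @param arb An [arbor()].
#' @return Sum of segment Euclidean lengths (um).
#' @export
total_length <- function(arb) {
  seg <- arbor_segments(arb)
  if (nrow(seg) == 0L) {
    warning("arbor has no segments")
    return(0)
  }
  sum(seg[, "len"])
}

#' Modified Sholl analysis
#'
#' Counts intersections of the arbor with concentric circles centred on
#' the soma and reports the density of intersections, defined as the
#' number of intersections divided by the circumference of the
#' corresponding circle. Crossings are counted as quadratic-root crossings
#' of each straight segment with each circle, with segment parameters in
#' the half-open interval `[0, 1)` so a shared endpoint of two chained
#' segments is counted once; a tangent touch also counts once.
#'
#' @param arb An [arbor()].
#' @param dr Ring spacing (um), default 10.
#' @param r_max Largest ring radius (um); defaults to the territory
#'   radius.
#' @return A data frame of class `sholl_profile` with columns `radius`,
#'   `intersections`, `density` (um^-1).
#' @export
sholl <- function(arb, dr = 10, r_max = NULL) {
  stopifnot(dr > 0)
  if (is.null(r_max)) r_max <- arb$territory_radius
  seg <- arbor_segments(arb)
  bbox_ok <- arb$soma[1] >= min(c(seg[, "x0"], seg[, "x1"])) &&
    arb$soma[1] <= max(c(seg[, "x0"], seg[, "x1"])) &&
    arb$soma[2] >= min(c(seg[, "y0"], seg[, "y1"])) &&
    arb$soma[2] <= max(c(seg[, "y0"], seg[, "y1"]))
  if (!bbox_ok) warning("soma lies outside the arbor bounding box")
  px <- seg[, "x0"] - arb$soma[1]
  py <- seg[, "y0"] - arb$soma[2]
  vx <- seg[, "x1"] - seg[, "x0"]
  vy <- seg[, "y1"] - seg[, "y0"]
  aa <- vx^2 + vy^2
  bb <- 2 * (px * vx + py * vy)
  d0sq <- px^2 + py^2
  radii <- seq(dr, r_max, by = dr)
  counts <- integer(length(radii))
  eps <- 1e-12
  for (k in seq_along(radii)) {
    cc <- d0sq - radii[k]^2
    disc <- bb^2 - 4 * aa * cc
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-bb - sq) / (2 * aa)
    t2 <- (-bb + sq) / (2 * aa)
    tangent <- disc > -eps & disc < eps
    n <- ifelse(disc <= -eps, 0L,
                ifelse(tangent,
                       as.integer(t1 >= 0 & t1 < 1),
                       (t1 >= 0 & t1 < 1) + (t2 >= 0 & t2 < 1)))
    counts[k] <- as.integer(round(sum(n)))
  }
  out <- data.frame(radius = radii, intersections = counts,
                    density = counts / (2 * pi * radii))
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::plot(x$radius, x$density, type = "b", pch = 16,
                 xlab = "distance to soma (um)",
                 ylab = "intersection density (1/um)", ...)
  invisible(x)
}

#' Exact distance from points to the nearest dendritic segment
#'
#' Brute-force minimum over all segments of the point-to-segment Euclidean
#' distance. Exact but O(points x segments); used for stimulus-position
#' sampling and as the oracle for [distance_map()].
#'
#' @param points An n x 2 matrix of coordinates (um).
#' @param arb An [arbor()].
#' @return A vector of n distances (um).
#' @export
dist_to_arbor <- function(points, arb) {
  points <- rbind(points)
  seg <- arbor_segments(arb)
  dmin <- rep(Inf, nrow(points))
  px <- points[, 1]
  py <- points[, 2]
  for (s in seq_len(nrow(seg))) {
    vx <- seg[s, "x1"] - seg[s, "x0"]
    vy <- seg[s, "y1"] - seg[s, "y0"]
    l2 <- vx^2 + vy^2
    t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - seg[s, "x0"]) * vx +
                                                (py - seg[s, "y0"]) * vy) / l2))
    dx <- px - (seg[s, "x0"] + t * vx)
    dy <- py - (seg[s, "y0"] + t * vy)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Distance-to-nearest-dendrite map
#'
#' Pixel map of the Euclidean distance to the nearest dendritic segment,
#' computed by rasterizing the arbor at quarter-pixel resolution and
#' applying a Euclidean distance transform; accurate to about one pixel.
#'
#' @param arb An [arbor()].
#' @param pixel_size Pixel size (um).
#' @param extent Half-width of the square map around the soma (um);
#'   defaults to the territory radius.
#' @return An object of class `distance_map`: list with pixel-centre
#'   coordinates `x`, `y`, `pixel_size` and the distance matrix `values`
#'   (um, rows indexed by `x`).
#' @export
distance_map <- function(arb, pixel_size = 2, extent = NULL) {
  if (pixel_size <= 0) stop("pixel size must be positive")
  if (is.null(extent)) extent <- arb$territory_radius
  n <- floor(extent / pixel_size)
  x <- arb$soma[1] + (-n:n) * pixel_size
  y <- arb$soma[2] + (-n:n) * pixel_size
  seg <- arbor_segments(arb)
  # rasterize: sample along each segment at quarter-pixel spacing
  step <- pixel_size / 4
  pts <- lapply(seq_len(nrow(seg)), function(s) {
    m <- max(2L, ceiling(seg[s, "len"] / step) + 1L)
    t <- seq(0, 1, length.out = m)
    cbind(seg[s, "x0"] + t * (seg[s, "x1"] - seg[s, "x0"]),
          seg[s, "y0"] + t * (seg[s, "y1"] - seg[s, "y0"]))
  })
  pts <- do.call(rbind, pts)
  i <- round((pts[, 1] - x[1]) / pixel_size) + 1
  j <- round((pts[, 2] - y[1]) / pixel_size) + 1
  ok <- i >= 1 & i <= length(x) & j >= 1 & j <= length(y)
  img <- matrix(1, length(x), length(y))
  img[cbind(i[ok], j[ok])] <- 0  # dendrite pixels are background
  dm <- EBImage::distmap(img, metric = "euclidean")
  structure(list(x = x, y = y, pixel_size = pixel_size,
                 values = as.matrix(dm) * pixel_size),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("distance map: %d x %d pixels of %g um, max distance %.1f um\n",
              length(x$x), length(x$y), x$pixel_size, max(x$values)))
  invisible(x)
}

#' Sample stimulus positions on or around an arbor
#'
#' Draws probe-placement positions mimicking the stimulation protocols:
#' `"proximal"` and `"distal"` pick points on the dendrite near 100 um and
#' 200 um from the soma respectively; `"d_off"` picks dendrite-off
#' positions at a prescribed distance to the nearest dendrite (rejection
#' sampling, tolerance `tol`); `"uniform"` samples uniformly over the
#' territory disc.
#'
#' @param arb An [arbor()].
#' @param n Number of positions.
#' @param mode One of `"proximal"`, `"distal"`, `"d_off"`, `"uniform"`.
#' @param seed RNG seed; the result is reproducible given `(arguments,
#'   seed)`.
#' @param distance Target distance to the nearest dendrite (um), `d_off`
#'   mode only.
#' @param tol Acceptance tolerance for `d_off` (um) and half-width of the
#'   radial band for `proximal`/`distal` (um; defaults 2 and 10).
#' @return An n x 2 matrix of positions (um).
#' @export
sample_stimulus_positions <- function(arb, n, mode = c("uniform", "proximal",
                                                       "distal", "d_off"),
                                      seed = 1L, distance = 20, tol = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  with_seed(seed, {
    if (mode == "uniform") {
      rho <- arb$territory_radius * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      return(cbind(x = arb$soma[1] + rho * cos(th),
                   y = arb$soma[2] + rho * sin(th)))
    }
    if (mode %in% c("proximal", "distal")) {
      ring <- if (mode == "proximal") 100 else 200
      band <- if (is.null(tol)) 10 else tol
      seg <- arbor_segments(arb)
      pts <- lapply(seq_len(nrow(seg)), function(s) {
        m <- max(2L, ceiling(seg[s, "len"]) + 1L)
        t <- seq(0, 1, length.out = m)
        cbind(seg[s, "x0"] + t * (seg[s, "x1"] - seg[s, "x0"]),
              seg[s, "y0"] + t * (seg[s, "y1"] - seg[s, "y0"]))
      })
      pts <- do.call(rbind, pts)
      rr <- sqrt((pts[, 1] - arb$soma[1])^2 + (pts[, 2] - arb$soma[2])^2)
      cand <- which(abs(rr - ring) <= band)
      if (!length(cand)) {
        stop("no dendrite found within ", band, " um of the ", ring,
             " um ring")
      }
      pick <- cand[sample.int(length(cand), n, replace = n > length(cand))]
      return(cbind(x = pts[pick, 1], y = pts[pick, 2]))
    }
    # d_off: uniform proposals accepted at the requested distance
    if (is.null(tol)) tol <- 2
    out <- matrix(NA_real_, n, 2)
    got <- 0L
    m <- 500L
    for (chunk in seq_len(max(20L, ceiling(600 * n / m)))) {
      rho <- arb$territory_radius * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      p <- cbind(arb$soma[1] + rho * cos(th), arb$soma[2] + rho * sin(th))
      d <- dist_to_arbor(p, arb)
      ok <- which(abs(d - distance) <= tol)
      take <- utils::head(ok, n - got)
      if (length(take)) {
        out[(got + 1):(got + length(take)), ] <- p[take, , drop = FALSE]
        got <- got + length(take)
      }
      if (got == n) break
    }
    if (got < n) {
      stop("could not sample positions at distance ", distance,
           " +/- ", tol, " um from a dendrite (found ", got, " of ", n, ")")
    }
    colnames(out) <- c("x", "y")
    out
  })
}
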