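# Shared fixtures built in code.

# Four straight radial arms of length `arm`, subdivided into `step`-um
# nodes -- the geometry has closed-form Sholl and coverage answers.
make_cross_arbor <- function(arm = 300, step = 5) {
  dirs <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  nodes <- data.frame(id = 1L, x = 0, y = 0, parent = -1L)
  nid <- 1L
  for (d in dirs) {
    prev <- 1L
    for (s in seq(step, arm, by = step)) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, x = d[1] * s, y = d[2] * s,
                                       parent = prev))
      prev <- nid
    }
  }
  arbor(nodes, class_label = "custom", territory_radius = arm + 20)
}

# Length of the part of segment p0 -> p1 lying inside the disc of radius R
# centred at c (closed form; independent oracle for activated_length).
segment_chord_in_disc <- function(p0, p1, c, R) {
  v <- p1 - p0
  l2 <- sum(v^2)
  w <- p0 - c
  A <- l2
  B <- 2 * sum(w * v)
  C <- sum(w^2) - R^2
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(0)
  t1 <- max(0, (-B - sqrt(disc)) / (2 * A))
  t2 <- min(1, (-B + sqrt(disc)) / (2 * A))
  if (t2 <= t1) return(0)
  (t2 - t1) * sqrt(l2)
}

cross_tophat_length <- function(arb, centre, R) {
  seg <- nocimech:::arbor_segments(arb)
  sum(vapply(seq_len(nrow(seg)), function(s) {
    segment_chord_in_disc(c(seg[s, "x0"], seg[s, "y0"]),
                          c(seg[s, "x1"], seg[s, "y1"]), centre, R)
  }, numeric(1)))
}
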