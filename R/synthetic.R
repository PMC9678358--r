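#' Generate a synthetic dendritic arbor
#'
#' Stochastic space-filling growth model for planar dendritic arbors:
#' tips elongate in fixed steps with angular wobble and a radially outward
#' bias, branch when local space permits, and die when they leave the
#' territory or come closer than a self-avoidance distance to an existing
#' branch. The self-avoidance distance is derived from the target total
#' length, so the realized arbor statistics are calibrated:
#'
#' * `c4da_wt` (default): territory radius 220 um, target total length
#'   19560 um, near-uniform Sholl intersection density between 20 and
#'   180 um from the soma, and at least 95 percent of the territory within
#'   20 um of a dendrite.
#' * `c4da_cti`: same proximal behaviour, but branching stops and tips can
#'   die beyond `decay_radius` (100 um), giving the distally decaying
#'   density of cut-knockdown cells.
#' * `c3da`: a sparse gentle-touch-receptor-like arbor (short target
#'   length, early decay), provided as a qualitative comparator.
#'
#' @param class_label Arbor class; sets the defaults below.
#' @param seed RNG seed. The generator is a pure function of
#'   `(parameters, seed)`.
#' @param total_length Target mean total dendritic length (um).
#' @param territory_radius Territory disc radius (um).
#' @param step Elongation step (um).
#' @param n_primary Number of primary branches leaving the soma.
#' @param branch_prob Per-step branching attempt probability.
#' @param branch_angle Branch half-opening angle (degrees).
#' @param wobble_sd Sd of the per-step heading noise (degrees).
#' @param radial_bias Weight pulling the heading back outward (0-1).
#' @param avoid_factor Branch-gating distance as a fraction of the mean
#'   inter-branch spacing implied by `total_length`: a new branch is only
#'   created where it has at least this much clearance, which is what
#'   regulates the filled density.
#' @param elong_factor Hard self-avoidance distance for tip elongation,
#'   as a fraction of the mean spacing (smaller than `avoid_factor`, so
#'   fresh sibling branches can diverge).
#' @param decay_radius Radius (um) beyond which branching stops and tips
#'   may die (`Inf` for wild type).
#' @param death_prob Per-step tip death probability beyond `decay_radius`.
#' @return An [arbor()].
#' @examples
#' arb <- generate_arbor("c4da_wt", seed = 1)
#' total_length(arb)
#' @export
generate_arbor <- function(class_label = c("c4da_wt", "c4da_cti", "c3da",
                                           "custom"),
                           seed = 1L,
                           total_length = NULL, territory_radius = NULL,
                           step = 4, n_primary = NULL,
                           branch_prob = NULL, branch_angle = 28,
                           wobble_sd = 10, radial_bias = 0.35,
                           avoid_factor = NULL, elong_factor = 0.6,
                           decay_radius = NULL, death_prob = NULL) {
  class_label <- match.arg(class_label)
  def <- switch(class_label,
    c4da_wt = list(L = 19560, R = 220, m0 = 6, pb = 0.8, av = 1.25,
                   dec = Inf, dth = 0),
    c4da_cti = list(L = 19560, R = 220, m0 = 6, pb = 0.8, av = 1.25,
                    dec = 100, dth = 0.03),
    c3da = list(L = 6000, R = 200, m0 = 4, pb = 0.6, av = 1.25,
                dec = 80, dth = 0.04),
    custom = list(L = 19560, R = 220, m0 = 6, pb = 0.8, av = 1.25,
                  dec = Inf, dth = 0))
  L_target <- if (is.null(total_length)) def$L else total_length
  R <- if (is.null(territory_radius)) def$R else territory_radius
  m0 <- if (is.null(n_primary)) def$m0 else n_primary
  pb <- if (is.null(branch_prob)) def$pb else branch_prob
  av <- if (is.null(avoid_factor)) def$av else avoid_factor
  dec <- if (is.null(decay_radius)) def$dec else decay_radius
  dth <- if (is.null(death_prob)) def$dth else death_prob
  stopifnot(L_target > 0, R > 0, step > 0, m0 >= 1)

  # mean inter-branch spacing for a uniform-density arbor of the target
  # length, and the avoidance distances derived from it
  spacing <- pi * R^2 / L_target
  s_branch <- av * spacing
  s_elong <- elong_factor * spacing
  wob <- wobble_sd * pi / 180
  bang <- branch_angle * pi / 180
  max_nodes <- ceiling(4 * L_target / step)

  with_seed(seed, {
    nx <- numeric(max_nodes)
    ny <- numeric(max_nodes)
    par <- integer(max_nodes)
    nx[1] <- 0; ny[1] <- 0; par[1] <- -1L
    nn <- 1L

    # each tip: node index, heading, and a short list of recently related
    # nodes (own recent path and the sibling at a branch point) excluded
    # from the self-avoidance test
    th0 <- stats::runif(1, 0, 2 * pi) + 2 * pi * (seq_len(m0) - 1) / m0 +
      stats::rnorm(m0, 0, wob)
    tips <- lapply(seq_len(m0), function(k) {
      list(node = 1L, angle = th0[k], recent = c(1L, 1L, 1L, 1L))
    })

    min_dist_ok <- function(p, excl, need) {
      use <- seq_len(nn)
      d2 <- (nx[use] - p[1])^2 + (ny[use] - p[2])^2
      d2[excl[excl <= nn]] <- Inf
      all(d2 >= need^2)
    }

    while (length(tips) && nn < max_nodes) {
      new_tips <- list()
      for (tp in tips) {
        pos <- c(nx[tp$node], ny[tp$node])
        rho <- sqrt(sum(pos^2))
        if (rho > dec && stats::runif(1) < dth) next
        rad_ang <- if (rho > 1e-9) atan2(pos[2], pos[1]) else tp$angle
        dd <- atan2(sin(rad_ang - tp$angle), cos(rad_ang - tp$angle))
        base <- tp$angle + radial_bias * dd + stats::rnorm(1, 0, wob)
        placed <- FALSE
        for (turn in c(0, 0.45, -0.45, 0.9, -0.9)) {
          ang <- base + turn
          p <- pos + step * c(cos(ang), sin(ang))
          if (sqrt(sum(p^2)) > R) next
          if (!min_dist_ok(p, tp$recent, s_elong)) next
          nn <- nn + 1L
          nx[nn] <- p[1]; ny[nn] <- p[2]; par[nn] <- tp$node
          np <- nn
          new_tips[[length(new_tips) + 1L]] <-
            list(node = np, angle = ang,
                 recent = c(np, tp$node, tp$recent[1:2]))
          placed <- TRUE
          break
        }
        if (!placed) next
        # branching attempt from the same point
        if (rho <= dec && stats::runif(1) < pb && nn < max_nodes) {
          side <- sample(c(-1, 1), 1)
          bang_i <- bang * (1 + stats::rnorm(1, 0, 0.2))
          angb <- base + side * bang_i
          q <- pos + step * c(cos(angb), sin(angb))
          if (sqrt(sum(q^2)) <= R &&
              min_dist_ok(q, c(tp$recent, np), s_branch)) {
            nn <- nn + 1L
            nx[nn] <- q[1]; ny[nn] <- q[2]; par[nn] <- tp$node
            new_tips[[length(new_tips) + 1L]] <-
              list(node = nn, angle = angb,
                   recent = c(nn, np, tp$node, tp$recent[1]))
            # let the sibling know about this branch too
            k <- length(new_tips) - 1L
            new_tips[[k]]$recent <- c(new_tips[[k]]$recent[1:3], nn)
          }
        }
      }
      tips <- new_tips
    }

    nodes <- data.frame(id = seq_len(nn), x = nx[seq_len(nn)],
                        y = ny[seq_len(nn)], parent = par[seq_len(nn)])
    arbor(nodes, class_label = class_label, territory_radius = R)
  })
}

#' Force-response presets
#'
#' Boltzmann parameter presets used to simulate calcium force-response
#' experiments. The wild-type presets carry the reported half- and
#' full-activation forces: `wt_60um` (60 um probe) f50 = 3 mN, f90 = 4 mN;
#' `wt_30um` (30 um probe) f50 = 0.7 mN, f90 = 1.5 mN, with a larger
#' plateau reflecting the stronger responses to small probes. Mutant-like
#' presets (`piezo_30um` small-probe attenuation, `ppk26_60um` global
#' attenuation, `double_60um` near-silent) are qualitative fixtures only.
#'
#' @param label Preset name.
#' @return A list of class `response_preset` with fields `label`, `A`
#'   (plateau, dimensionless dF/F0), `f50`, `f90`, `w` (mN), `noise_sd`
#'   (fraction of `A`), `n_cells` and `forces` (mN grid).
#' @export
response_preset <- function(label = c("wt_60um", "wt_30um", "piezo_30um",
                                      "ppk26_60um", "double_60um")) {
  label <- match.arg(label)
  p <- switch(label,
    wt_60um = list(A = 1, f50 = 3, f90 = 4, forces = seq(0, 5, by = 0.5)),
    wt_30um = list(A = 1.5, f50 = 0.7, f90 = 1.5,
                   forces = seq(0, 2, by = 0.2)),
    piezo_30um = list(A = 0.5, f50 = 1.1, f90 = 1.9,
                      forces = seq(0, 2, by = 0.2)),
    ppk26_60um = list(A = 0.35, f50 = 3, f90 = 4.2,
                      forces = seq(0, 5, by = 0.5)),
    double_60um = list(A = 0.05, f50 = 3, f90 = 4,
                       forces = seq(0, 5, by = 0.5)))
  structure(list(label = label, A = p$A, f50 = p$f50, f90 = p$f90,
                 w = (p$f90 - p$f50) / log(9), noise_sd = 0.1,
                 n_cells = 12L, forces = p$forces),
            class = "response_preset")
}

#' @export
print.response_preset <- function(x, ...) {
  cat(sprintf(
    "response preset '%s': A = %g, f50 = %g mN, f90 = %g mN (w = %.3f), %d cells, noise sd %g A\n",
    x$label, x$A, x$f50, x$f90, x$w, x$n_cells, x$noise_sd))
  invisible(x)
}

#' Simulate force-response curves from a preset
#'
#' Per cell and per grid force, draws `R(f) + e` with
#' `R(f) = A / (1 + exp((f0 - f)/w))` and Gaussian noise of sd
#' `noise_sd * A`, truncated at 0 (dF/F0 is nonnegative).
#'
#' @param preset A [response_preset()] (or a list with the same fields).
#' @param seed RNG seed.
#' @return A data frame with columns `cell`, `force` (mN) and `response`
#'   (dF/F0), carrying the generating parameters as attribute `truth`.
#' @export
generate_response_curves <- function(preset, seed = 1L) {
  if (length(preset$forces) == 0L) stop("preset has an empty force grid")
  with_seed(seed, {
    n <- preset$n_cells
    f <- rep(preset$forces, times = n)
    cell <- rep(seq_len(n), each = length(preset$forces))
    mu <- preset$A / (1 + exp((preset$f50 - f) / preset$w))
    resp <- pmax(0, mu + stats::rnorm(length(f), 0, preset$noise_sd * preset$A))
    out <- data.frame(cell = cell, force = f, response = resp)
    attr(out, "truth") <- preset
    out
  })
}

#' Analytic toy field maps
#'
#' Small analytic [field_map] fixtures (both channels identical) used to
#' exercise the activation machinery against geometric oracles.
#'
#' @param kind `"tophat"` (value `peak` within `radius` of the origin),
#'   `"gaussian"` (peak at the origin, sd `sigma`), or `"zero"`.
#' @param peak Peak value.
#' @param radius Top-hat radius (um).
#' @param sigma Gaussian sd (um).
#' @param pixel_size,extent Map geometry (um).
#' @return A `field_map`.
#' @export
toy_field <- function(kind = c("tophat", "gaussian", "zero"), peak = 1,
                      radius = 50, sigma = 30, pixel_size = 1,
                      extent = 150) {
  kind <- match.arg(kind)
  n <- floor(extent / pixel_size)
  x <- (-n:n) * pixel_size
  rho <- sqrt(outer(x^2, x^2, "+"))
  M <- switch(kind,
              tophat = ifelse(rho <= radius, peak, 0),
              gaussian = peak * exp(-rho^2 / (2 * sigma^2)),
              zero = matrix(0, length(x), length(x)))
  structure(list(x = x, y = x, pixel_size = pixel_size, P_P = M, T_L = M),
            class = "field_map")
}
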