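#' Activation simulation configuration
#'
#' Settings for the Monte-Carlo receptive-field simulation. A dendritic
#' sub-segment counts as excited when the local field value reaches
#' `threshold_fraction` of that field's own global peak (default 10
#' percent); the cell counts as activated when the summed excited length
#' reaches the dendritic coverage threshold `C_d`.
#'
#' @param threshold_fraction Segment excitation threshold as a fraction of
#'   the field peak, in (0, 1).
#' @param C_d Dendritic coverage threshold(s) in um. The defaults 20, 200
#'   and 400 um are 0.1, 1 and 2 percent of the mean total dendritic
#'   length, rounded to one significant figure (see
#'   [coverage_thresholds()]).
#' @param n_positions Random probe positions per cell.
#' @param scenario Sensitivity scenario: `"P_only"`, `"T_only"` or
#'   `"both"`.
#' @param step Segment discretization step (um).
#' @param seed Base RNG seed for position sampling.
#' @return A list of class `activation_config`.
#' @export
activation_config <- function(threshold_fraction = 0.1,
                              C_d = c(20, 200, 400),
                              n_positions = 100,
                              scenario = c("both", "P_only", "T_only"),
                              step = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            all(C_d >= 0), n_positions >= 1, step > 0)
  structure(list(threshold_fraction = threshold_fraction, C_d = C_d,
                 n_positions = n_positions, scenario = scenario,
                 step = step, seed = seed),
            class = "activation_config")
}

#' Coverage thresholds from the total dendritic length
#'
#' The low/intermediate/high dendritic coverage thresholds are 0.1, 1 and
#' 2 percent of the mean total dendritic length, rounded to one
#' significant figure; for the reported mean of 19560 um these are 20, 200
#' and 400 um.
#'
#' @param total_length Mean total dendritic length (um).
#' @param fractions Fractions of the total length.
#' @return Named vector of thresholds (um).
#' @examples
#' coverage_thresholds(19560)  # c(low = 20, intermediate = 200, high = 400)
#' @export
coverage_thresholds <- function(total_length = 19560,
                                fractions = c(low = 0.001,
                                              intermediate = 0.01,
                                              high = 0.02)) {
  signif(fractions * total_length, 1)
}

# Discretize an arbor into sub-segment midpoints of ~`step` um; each
# segment is split into equal pieces so lengths sum exactly to the total.
discretize_arbor <- function(arb, step = 1) {
  seg <- arbor_segments(arb)
  k <- pmax(1L, ceiling(seg[, "len"] / step))
  idx <- rep(seq_len(nrow(seg)), k)
  frac <- unlist(lapply(k, function(m) (seq_len(m) - 0.5) / m))
  list(mid = cbind(seg[idx, "x0"] + frac * (seg[idx, "x1"] - seg[idx, "x0"]),
                   seg[idx, "y0"] + frac * (seg[idx, "y1"] - seg[idx, "y0"])),
       len = seg[idx, "len"] / k[idx])
}

# Excited dendritic length for all three scenarios at once (internal
# workhorse; disc is a discretize_arbor() result).
activated_length_all <- function(disc, field, position, threshold_fraction) {
  peakP <- max(field$P_P)
  peakT <- max(field$T_L)
  if (peakP <= 0 && peakT <= 0) {
    warning("field has zero peak; no segment can be excited")
    return(c(P_only = 0, T_only = 0, both = 0))
  }
  rel <- cbind(disc$mid[, 1] - position[1], disc$mid[, 2] - position[2])
  hitP <- field_values(field, rel, "P_P") >= threshold_fraction * peakP
  hitT <- field_values(field, rel, "T_L") >= threshold_fraction * peakT
  c(P_only = sum(disc$len[hitP]),
    T_only = sum(disc$len[hitT]),
    both = sum(disc$len[hitP | hitT]))
}

#' Excited dendritic length under a mechanical field
#'
#' Overlays a field map (centred at `position`) on the arbor and sums the
#' lengths of dendritic sub-segments whose local field value reaches the
#' excitation threshold (a fraction of the field's global peak). Under the
#' `"both"` scenario a sub-segment excited by either channel counts once.
#'
#' @param arb An [arbor()].
#' @param field A `field_map` (see [radial_to_map()], [toy_field()]).
#' @param position Length-2 probe centre position (um, arbor frame).
#' @param config An [activation_config()]; its `scenario` selects the
#'   channel.
#' @return Excited dendritic length (um).
#' @export
activated_length <- function(arb, field, position,
                             config = activation_config()) {
  disc <- discretize_arbor(arb, config$step)
  unname(activated_length_all(disc, field, position,
                              config$threshold_fraction)[config$scenario])
}

#' Monte-Carlo activation probability
#'
#' For each arbor, draws probe positions (uniform over the territory disc
#' unless `positions` is supplied), computes the excited dendritic length
#' at each position for the three sensitivity scenarios, and reports per
#' cell the fraction of positions whose excited length reaches each
#' coverage threshold `C_d`.
#'
#' @param arbors A list of [arbor()] objects (or a single arbor).
#' @param field A `field_map`.
#' @param config An [activation_config()]. All three scenarios are always
#'   reported.
#' @param positions Optional n x 2 matrix of probe positions used for
#'   every arbor (overrides random sampling; used e.g. for exhaustive-grid
#'   checks).
#' @return A data frame of class `activation_result` with columns `cell`,
#'   `scenario`, `C_d`, `probability`, plus a `summary` attribute with
#'   mean and sd across cells.
#' @export
activation_probability <- function(arbors, field,
                                   config = activation_config(),
                                   positions = NULL) {
  if (inherits(arbors, "arbor")) arbors <- list(arbors)
  stopifnot(length(arbors) >= 1L)
  rows <- list()
  for (ci in seq_along(arbors)) {
    arb <- arbors[[ci]]
    disc <- discretize_arbor(arb, config$step)
    pos <- if (is.null(positions)) {
      sample_stimulus_positions(arb, config$n_positions, "uniform",
                                seed = config$seed + ci)
    } else {
      positions
    }
    lens <- t(apply(pos, 1, function(p) {
      activated_length_all(disc, field, p, config$threshold_fraction)
    }))
    for (sc in c("P_only", "T_only", "both")) {
      for (cd in config$C_d) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = ci, scenario = sc, C_d = cd,
          probability = mean(lens[, sc] >= cd))
      }
    }
  }
  out <- do.call(rbind, rows)
  agg_m <- stats::aggregate(probability ~ scenario + C_d, out, mean)
  agg_s <- stats::aggregate(probability ~ scenario + C_d, out, stats::sd)
  names(agg_m)[3] <- "mean"
  agg_m$sd <- agg_s$probability
  class(out) <- c("activation_result", "data.frame")
  attr(out, "summary") <- agg_m
  out
}

#' @export
print.activation_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("activation probability over %d cell(s):\n",
              length(unique(x$cell))))
  s <- s[order(s$C_d, s$scenario), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  C_d = %4g um  %-7s  %.2f +/- %.2f\n",
                s$C_d[i], s$scenario[i], s$mean[i],
                ifelse(is.na(s$sd[i]), 0, s$sd[i])))
  }
  invisible(x)
}
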