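#' Track distribution shape along an ordered condition sequence
#'
#' Classifies each distribution in an ordered sequence and records the shape
#' parameters `d` and `o` where the verdict is bimodal (`h` is not tracked:
#' it depends on the sampled fraction of cells and hence on procedure, not
#' state).  Non-bimodal conditions are kept as gaps (`NA`), preserving order.
#'
#' @param distributions list of `snapshot_distribution`s (or numeric
#'   vectors), in condition order.
#' @param labels condition labels; default taken from the distributions.
#' @param direction tag stored with the path (e.g. `"forward"`,
#'   `"backward"`, or a generation index).
#' @param kind analysis kind for the classifier.
#' @return An object of class `hysteresis_path`: data.frame with columns
#'   `condition`, `phase`, `verdict`, `d`, `o`.
#' @export
track_path <- function(distributions, labels = NULL, direction = "forward",
                       kind = NULL) {
  if (!is.list(distributions) || length(distributions) < 2)
    stop("need an ordered sequence of at least 2 distributions", call. = FALSE)
  if (is.null(labels))
    labels <- vapply(seq_along(distributions), function(i) {
      x <- distributions[[i]]
      if (is.data.frame(x)) as.character(x$condition[1]) else paste0("c", i)
    }, "")
  rows <- lapply(seq_along(distributions), function(i) {
    x <- distributions[[i]]
    call <- classify_modality(x, kind = kind)
    if (call$verdict == "bimodal") {
      sp <- shape_params(call, x)
      data.frame(condition = labels[i], phase = i, verdict = "bimodal",
                 d = sp$d, o = sp$o)
    } else {
      data.frame(condition = labels[i], phase = i, verdict = "unimodal",
                 d = NA_real_, o = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "direction") <- direction
  class(out) <- c("hysteresis_path", "data.frame")
  out
}

#' @export
print.hysteresis_path <- function(x, ...) {
  cat("Hysteresis path (", attr(x, "direction"), "), ", nrow(x),
      " conditions\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' Loop gap between forward and backward shape paths
#'
#' Quantifies non-closure of a hysteresis loop as the mean Euclidean distance
#' in the `(d, o)` plane between direction-matched conditions.  Conditions
#' that are not bimodal on both paths are excluded (not imputed); with no
#' matched bimodal condition the gap is undefined and an error is raised.
#' The gap is symmetric, non-negative, and zero iff the matched path points
#' coincide.
#'
#' @param forward,backward `hysteresis_path`s with matching condition labels.
#' @return The gap (a single non-negative number).
#' @export
loop_gap <- function(forward, backward) {
  stopifnot(inherits(forward, "hysteresis_path"),
            inherits(backward, "hysteresis_path"))
  m <- merge(as.data.frame(forward), as.data.frame(backward),
             by = "condition", suffixes = c("_f", "_b"))
  m <- m[!is.na(m$d_f) & !is.na(m$d_b), , drop = FALSE]
  if (!nrow(m))
    stop("no condition is bimodal on both paths; gap undefined", call. = FALSE)
  mean(sqrt((m$d_f - m$d_b)^2 + (m$o_f - m$o_b)^2))
}

#' Simulated parameter ramp cycle for hysteresis experiments
#'
#' Ramps a rate-set field up through `factors` and back down, carrying the
#' simulated cell ensemble from step to step: after each change of the rate
#' the ensemble evolves for `dwell` minutes before the snapshot is taken.
#' With `dwell` much shorter than the protein relaxation time the ensemble
#' lags the conditions and forward/backward paths differ (hysteresis); with
#' `dwell` much longer each snapshot is stationary and history is erased.
#'
#' @param base_rates reference `rate_set`.
#' @param param rate field(s) to ramp; the default ramps the protein decay
#'   rate downward, the parameter with the strongest stationary effect on
#'   the relative peak distance d (decay rates control the means and hence,
#'   through counting noise, the relative mode widths).
#' @param factors ramp factors, starting at the base condition
#'   (default `c(1, 0.46, 0.215, 0.1)`); the cycle visits them up then down.
#' @param dwell minutes the ensemble evolves at each step before snapshot;
#'   compare with the slowest protein relaxation time along the ramp
#'   (about 500 min at the default turning point); the default dwell is
#'   equilibrating, pass a short dwell (e.g. 100) for a lagged cycle.
#' @param n_cells ensemble size.
#' @param seed master seed.
#' @param t_burn burn-in at the base condition; default 20 protein lifetimes.
#' @return List with `forward` and `backward` `hysteresis_path`s and the
#'   per-step snapshots.
#' @export
run_ramp_cycle <- function(base_rates = reference_rates(),
                           param = "kd_prot",
                           factors = c(1, 0.46, 0.215, 0.1), dwell = 2500,
                           n_cells = 6000, seed = 1, t_burn = NULL) {
  stopifnot(all(param %in% rate_fields))
  if (is.null(t_burn)) t_burn <- 20 / base_rates$kd_prot
  sys0 <- build_reduced_model(base_rates)
  st <- sample_states(sys0, times = t_burn, n_cells = n_cells,
                      seed = derive_seed(seed, 1))[[1]]
  seq_factors <- c(factors, rev(factors)[-1])
  direction <- c(rep("forward", length(factors)),
                 rep("backward", length(factors) - 1))
  snaps <- vector("list", length(seq_factors))
  for (i in seq_along(seq_factors)) {
    f <- seq_factors[i]
    rates <- apply_scenario(base_rates,
                            perturbation_scenario("ramp",
                                                  setNames(rep(f, length(param)),
                                                           param)))
    sys <- build_reduced_model(rates)
    st <- sample_states(sys, times = dwell, n_cells = n_cells,
                        seed = derive_seed(seed, i + 1), init = st)[[1]]
    snaps[[i]] <- snapshot_distribution(st[, "Protein"],
                                        condition = sprintf("factor=%gx", f),
                                        kind = "count")
  }
  fwd_idx <- seq_len(length(factors))
  # backward path revisits the same factors in reverse order; the turning
  # point snapshot is shared by both directions
  bwd_positions <- c(length(factors),
                     length(factors) + seq_len(length(factors) - 1))
  fwd <- track_path(snaps[fwd_idx],
                    labels = sprintf("factor=%gx", factors),
                    direction = "forward")
  bwd <- track_path(snaps[bwd_positions],
                    labels = sprintf("factor=%gx", rev(factors)),
                    direction = "backward")
  list(forward = fwd, backward = bwd, snapshots = snaps,
       factors = seq_factors)
}

#' Resampling null for the loop gap
#'
#' Distribution of the gap expected with no hysteresis: pairs of independent
#' equilibrated cycles (long dwell) are generated at the same conditions with
#' different seeds, and the gap between the members of each pair is computed.
#' An observed gap inside this distribution's upper quantile is consistent
#' with sampling noise alone.
#'
#' @inheritParams run_ramp_cycle
#' @param n_pairs number of independent cycle pairs.
#' @return Numeric vector of `n_pairs` null gaps.
#' @export
loop_gap_null <- function(base_rates = reference_rates(),
                          param = "kd_prot",
                          factors = c(1, 0.46, 0.215, 0.1), dwell = 2500,
                          n_cells = 6000, seed = 1, n_pairs = 8) {
  vapply(seq_len(n_pairs), function(k) {
    a <- run_ramp_cycle(base_rates, param, factors, dwell, n_cells,
                        seed = derive_seed(seed, 2 * k))
    b <- run_ramp_cycle(base_rates, param, factors, dwell, n_cells,
                        seed = derive_seed(seed, 2 * k + 1))
    loop_gap(a$forward, b$forward)
  }, numeric(1))
}
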