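#' Default multiplicative sweep grid
#'
#' Seven log-spaced factors spanning one order of magnitude either side of
#' the reference value.
#'
#' @return Numeric vector `{0.1, 0.215, 0.464, 1, 2.15, 4.64, 10}`.
#' @export
default_grid <- function() round(10^seq(-1, 1, length.out = 7), 3)

#' Specification of a single-parameter perturbation sweep
#'
#' @param base_rates the reference `rate_set`.
#' @param param rate field to sweep, or a character vector of coupled fields
#'   swept by the same factor (e.g. `c("k_L", "k_H")` keeps their ratio
#'   fixed).
#' @param factors positive multiplicative grid; default [default_grid()].
#' @param n_cells cells per grid point.
#' @param t_snap snapshot time (min); default 20 protein lifetimes of the
#'   base rates.
#' @param seed master seed; each grid point gets a derived seed.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(base_rates, param, factors = default_grid(),
                       n_cells = 5000, t_snap = NULL, seed = 1) {
  stopifnot(inherits(base_rates, "rate_set"))
  bad <- setdiff(param, rate_fields)
  if (length(bad)) stop("unknown rate field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(factors <= 0)) stop("grid factors must be > 0", call. = FALSE)
  if (is.null(t_snap)) t_snap <- 20 / base_rates$kd_prot
  structure(list(base_rates = base_rates, param = param,
                 factors = as.numeric(factors), n_cells = n_cells,
                 t_snap = t_snap, seed = seed),
            class = "sweep_spec")
}

#' Run a single-parameter perturbation sweep
#'
#' For every factor in the grid, multiplies the swept field(s) of the base
#' rate set, rebuilds the reduced model, samples a stationary snapshot of
#' `n_cells` cells, classifies its modality, and computes shape parameters
#' when the verdict is bimodal.  Deterministic under the master seed (grid
#' point `i` uses `derive_seed(seed, i)`).
#'
#' @param spec a `sweep_spec`.
#' @param classify_kind analysis kind passed to the classifier
#'   (`"count"` for raw simulated protein numbers).
#' @return An object of class `sweep_result`: list of per-point records
#'   (`factor`, `rates`, `snapshot`, `call`, `shape`, `moments`) plus the
#'   spec; `summary()` returns a data.frame.
#' @export
run_sweep <- function(spec, classify_kind = "count") {
  stopifnot(inherits(spec, "sweep_spec"))
  records <- lapply(seq_along(spec$factors), function(i) {
    f <- spec$factors[i]
    sc <- perturbation_scenario(sprintf("%s x %g",
                                        paste(spec$param, collapse = "+"), f),
                                setNames(rep(f, length(spec$param)),
                                         spec$param))
    rates <- apply_scenario(spec$base_rates, sc)
    sweep_point(rates, spec$t_snap, spec$n_cells,
                derive_seed(spec$seed, i), f, classify_kind,
                condition = sc$name)
  })
  structure(list(records = records, spec = spec, type = "single_parameter"),
            class = "sweep_result")
}

sweep_point <- function(rates, t_snap, n_cells, seed, f, classify_kind,
                        condition, system = NULL, init = NULL) {
  if (is.null(system)) system <- build_reduced_model(rates)
  snap <- sample_snapshot(system, t_snap = t_snap, n_cells = n_cells,
                          seed = seed, init = init, condition = condition)
  call <- classify_modality(snap, kind = classify_kind)
  shp <- if (call$verdict == "bimodal") shape_params(call, snap) else NULL
  list(factor = f, rates = rates, snapshot = snap, call = call, shape = shp,
       moments = snapshot_moments(snap))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep result (", x$type, "): ", length(x$records), " grid points\n",
      sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
summary.sweep_result <- function(object, ...) {
  do.call(rbind, lapply(object$records, function(r) {
    data.frame(factor = r$factor,
               verdict = r$call$verdict,
               bic = unname(r$call$criteria["bic"]),
               peaks = unname(r$call$criteria["peaks"]),
               mean = r$moments$mean, cv2 = r$moments$cv2,
               d = if (!is.null(r$shape)) r$shape$d else NA_real_,
               h = if (!is.null(r$shape)) r$shape$h else NA_real_,
               o = if (!is.null(r$shape)) r$shape$o else NA_real_)
  }))
}

#' Extended sweep of the L-state initiation rates toward the H-state values
#'
#' Raises the L-state binding and escape rates jointly from their reference
#' values to exact equality with the H-state values, on a geometric path
#' parameterised by `alpha` in [0, 1] (`alpha = 0`: reference; `alpha = 1`:
#' L rates equal H rates, i.e. the two states have identical dynamics).
#' Both rate-limiting steps move together, so at `alpha = 1` the model
#' collapses to the high state and the distribution becomes unimodal around
#' the H-locked mean.
#'
#' @param base_rates reference `rate_set`.
#' @param alphas grid in [0, 1].
#' @inheritParams sweep_spec
#' @return A `sweep_result` (the `factor` field holds `alpha`).
#' @export
run_extended_L_sweep <- function(base_rates = reference_rates(),
                                 alphas = seq(0, 1, by = 0.25),
                                 n_cells = 5000, t_snap = NULL, seed = 1) {
  stopifnot(inherits(base_rates, "rate_set"))
  if (any(alphas < 0 | alphas > 1)) stop("alphas must be in [0,1]",
                                         call. = FALSE)
  if (is.null(t_snap)) t_snap <- 20 / base_rates$kd_prot
  records <- lapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    rates <- base_rates
    rates$k_bind_L <- base_rates$k_bind_L^(1 - a) * base_rates$k_bind_H^a
    rates$k_esc_L <- base_rates$k_esc_L^(1 - a) * base_rates$k_esc_H^a
    sweep_point(rates, t_snap, n_cells, derive_seed(seed, i), a, "count",
                condition = sprintf("L_rates alpha=%g", a))
  })
  structure(list(records = records,
                 spec = list(base_rates = base_rates, alphas = alphas,
                             n_cells = n_cells, t_snap = t_snap, seed = seed),
                 type = "extended_L"),
            class = "sweep_result")
}

#' Gradual exponential-to-stationary growth transition
#'
#' Sweeps the transition progress fraction `f` over a grid, interpolating all
#' rates between the exponential-phase and stationary-phase conditions with
#' [interpolate_condition()], and records distribution, modality and shape at
#' each point.  Whether bimodality is preserved along the path is recorded,
#' not enforced.
#'
#' @param f_grid fractions in [0, 1].
#' @param rates_exp,rates_stat endpoint `rate_set`s.
#' @inheritParams sweep_spec
#' @return A `sweep_result` (the `factor` field holds `f`).
#' @export
run_stationary_transition <- function(f_grid = seq(0, 1, by = 0.25),
                                      rates_exp = reference_rates(),
                                      rates_stat = stationary_phase_rates(),
                                      n_cells = 5000, t_snap = NULL, seed = 1) {
  if (any(f_grid < 0 | f_grid > 1)) stop("f_grid must lie in [0,1]",
                                         call. = FALSE)
  records <- lapply(seq_along(f_grid), function(i) {
    f <- f_grid[i]
    rates <- interpolate_condition(rates_exp, rates_stat, f)
    ts <- if (is.null(t_snap)) 20 / rates$kd_prot else t_snap
    sweep_point(rates, ts, n_cells, derive_seed(seed, i), f, "count",
                condition = sprintf("stationary f=%g", f))
  })
  structure(list(records = records,
                 spec = list(rates_exp = rates_exp, rates_stat = rates_stat,
                             f_grid = f_grid, n_cells = n_cells, seed = seed),
                 type = "stationary_transition"),
            class = "sweep_result")
}

#' Bimodal-to-unimodal transient after collapsing to one state
#'
#' Starts an ensemble from the stationary snapshot of the parent two-state
#' model, switches the reactions to a single-state variant
#' ([build_unimodal_variant()]), and follows the distribution as it relaxes:
#' at each requested time the protein snapshot is classified and recorded.
#' The reported relaxation time is the first snapshot time from which the
#' verdict is unimodal at every later recorded time.
#'
#' @param variant `"low"`, `"average"` or `"high"`.
#' @param parent_rates the two-state `rate_set`.
#' @param times increasing snapshot times (min) after the switch; time 0
#'   records the initial (still bimodal) ensemble.
#' @param n_cells ensemble size.
#' @param seed master seed (burn-in and relaxation use derived streams).
#' @param t_burn parent burn-in time; default 20 protein lifetimes.
#' @return An object of class `shift_result`: per-time records plus
#'   `relaxation_time`.
#' @export
run_unimodal_shift <- function(variant, parent_rates = reference_rates(),
                               times = c(0, 50, 100, 200, 400, 800),
                               n_cells = 5000, seed = 1, t_burn = NULL) {
  parent <- build_reduced_model(parent_rates)
  if (is.null(t_burn)) t_burn <- 20 / parent_rates$kd_prot
  st0 <- sample_states(parent, times = t_burn, n_cells = n_cells,
                       seed = derive_seed(seed, 1))[[1]]
  vsys <- build_unimodal_variant(parent_rates, variant)
  # carry RNA and Protein; promoter restarts free in the collapsed state
  init <- matrix(0, nrow = n_cells, ncol = length(vsys$species),
                 dimnames = list(NULL, vsys$species))
  init[, "Pr_free"] <- 1
  init[, "RNA"] <- st0[, "RNA"]
  init[, "Protein"] <- st0[, "Protein"]
  times <- sort(unique(times))
  pos_times <- times[times > 0]
  states <- if (length(pos_times))
    sample_states(vsys, times = pos_times, n_cells = n_cells,
                  seed = derive_seed(seed, 2), init = init)
  else list()
  records <- vector("list", length(times))
  for (i in seq_along(times)) {
    tm <- times[i]
    vals <- if (tm == 0) st0[, "Protein"]
            else states[[as.character(tm)]][, "Protein"]
    snap <- snapshot_distribution(vals,
                                  condition = sprintf("%s t=%g", variant, tm),
                                  kind = "count")
    call <- classify_modality(snap)
    records[[i]] <- list(time = tm, snapshot = snap, call = call,
                         shape = if (call$verdict == "bimodal")
                           shape_params(call, snap) else NULL,
                         moments = snapshot_moments(snap))
  }
  verdicts <- vapply(records, function(r) r$call$verdict, "")
  relax <- NA_real_
  uni <- verdicts == "unimodal"
  for (i in seq_along(times))
    if (all(uni[i:length(uni)])) { relax <- times[i]; break }
  structure(list(variant = variant, times = times, records = records,
                 relaxation_time = relax),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat("Unimodal-shift experiment (variant '", x$variant, "')\n", sep = "")
  for (r in x$records)
    cat(sprintf("  t = %6g min: %s (mean %.4g)\n", r$time, r$call$verdict,
                r$moments$mean))
  cat("relaxation time:", x$relaxation_time, "min\n")
  invisible(x)
}
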