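#' Exact stochastic simulation of a reaction system
#'
#' Generates one statistically exact sample path of the continuous-time
#' Markov jump process defined by the system's mass-action propensities
#' (Gillespie direct method).  If all propensities vanish before `t_end` the
#' trajectory ends early with the final (absorbing) state recorded; this is
#' not an error.
#'
#' @param system a `reaction_system`.
#' @param init named (or ordered) non-negative integer initial state; default
#'   [default_init()].
#' @param t_end end time (min), > 0.
#' @param seed integer master seed; the same seed and inputs give an
#'   identical trajectory.
#' @param stream stream index, letting several independent trajectories share
#'   one master seed.
#' @param max_events hard cap on recorded events.
#' @return An object of class `ssa_trajectory`: list with `times` (event
#'   times, starting at 0), `states` (matrix, one row per event, columns the
#'   species), `seed`, `label`, and `ended_early`.
#' @examples
#' sys <- build_reduced_model(reference_rates())
#' tr <- simulate_ssa(sys, t_end = 100, seed = 1)
#' tail(tr$states[, "Protein"], 3)
#' @export
simulate_ssa <- function(system, init = default_init(system), t_end, seed,
                         stream = 1, max_events = 5e6) {
  stopifnot(inherits(system, "reaction_system"))
  init <- align_init(system, init)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  res <- cpp_ssa_trajectory(system$rates, lapply(system$reactants, function(i) i - 1L),
                            system$stoich, unname(init), t_end,
                            as.double(seed), as.double(stream),
                            as.integer(max_events))
  colnames(res$states) <- system$species
  structure(list(times = as.numeric(res$times), states = res$states,
                 seed = seed, label = system$label,
                 ended_early = res$ended_early),
            class = "ssa_trajectory")
}

align_init <- function(system, init) {
  if (!is.null(names(init))) {
    x <- setNames(numeric(length(system$species)), system$species)
    bad <- setdiff(names(init), system$species)
    if (length(bad)) stop("unknown species in init: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    x[names(init)] <- init
    init <- x
  }
  if (length(init) != length(system$species))
    stop("init has wrong length", call. = FALSE)
  if (any(init < 0) || any(init != round(init)))
    stop("init must be non-negative integers", call. = FALSE)
  init
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory '", x$label, "': ", length(x$times), " events to t = ",
      signif(max(x$times), 4), " min (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.ssa_trajectory <- function(x, species = "Protein", ...) {
  species <- match.arg(species, colnames(x$states))
  graphics::plot(x$times, x$states[, species], type = "s",
                 xlab = "time (min)", ylab = paste(species, "copies"),
                 main = x$label, ...)
  invisible(x)
}

#' Ensemble of independent cells recorded at snapshot times
#'
#' Runs `n_cells` independent exact simulations and records the full species
#' state of every cell at each requested time.  Per-cell random streams are
#' derived from the master seed by a counter, so results are reproducible and
#' independent of evaluation order.  This is the workhorse behind
#' [sample_snapshot()] and the time-resolved experiments.
#'
#' @inheritParams simulate_ssa
#' @param times increasing vector of snapshot times (min).
#' @param n_cells number of cells (ignored when `init` is a matrix).
#' @param init a single state vector applied to every cell, or a matrix with
#'   one row per cell (carrying an ensemble across conditions).
#' @return List of `n_cells x n_species` matrices, one per snapshot time,
#'   with the times as names.
#' @export
sample_states <- function(system, times, n_cells, seed,
                          init = default_init(system)) {
  stopifnot(inherits(system, "reaction_system"))
  times <- as.numeric(times)
  if (any(diff(times) < 0) || any(times < 0))
    stop("times must be non-negative and non-decreasing", call. = FALSE)
  if (is.matrix(init)) {
    if (!is.null(colnames(init))) init <- init[, system$species, drop = FALSE]
    im <- init
  } else {
    init <- align_init(system, init)
    if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
    im <- matrix(rep(unname(init), each = n_cells), nrow = n_cells)
  }
  out <- cpp_ssa_ensemble(system$rates,
                          lapply(system$reactants, function(i) i - 1L),
                          system$stoich, im, times, as.double(seed))
  out <- lapply(out, function(m) { colnames(m) <- system$species; m })
  names(out) <- as.character(times)
  out
}

#' Snapshot distribution of single-cell protein numbers
#'
#' Simulates `n_cells` independent cells to `t_snap` and records each cell's
#' protein copy number, the model analogue of a flow-cytometry snapshot.  The
#' default snapshot time is 20 protein lifetimes (`20 / kd_prot`).  For the
#' reduced two-state model the default initial ensemble draws each cell's
#' promoter state from the stationary switching distribution
#' (H with probability `k_H / (k_H + k_L)`, free, RNA = Protein = 0), the
#' model analogue of sampling an asynchronous culture: a snapshot of cells
#' all started in the L state would otherwise carry a mode-weight bias
#' whenever the promoter relaxation time `1/(k_H + k_L)` is not far below
#' `t_snap`.  Pass `init` explicitly to override.
#'
#' @inheritParams sample_states
#' @param t_snap snapshot time (min); default 20 protein lifetimes when the
#'   system carries a `rate_set` attribute.
#' @param condition condition label stored with the values.
#' @param replicate replicate id stored with the values.
#' @param species species whose copy number is recorded.
#' @return A `snapshot_distribution`: data.frame with columns `cell_id`,
#'   `replicate`, `condition`, `value`, plus attributes `kind = "count"` and
#'   `states` (the full final state matrix, for carrying ensembles).
#' @export
sample_snapshot <- function(system, t_snap = NULL, n_cells, seed,
                            init = NULL,
                            condition = system$label, replicate = 1L,
                            species = "Protein") {
  if (is.null(t_snap)) {
    r <- attr(system, "rates")
    kd <- if (!is.null(r)) r$kd_prot else attr(system, "params")$kd_prot
    if (is.null(kd) || kd <= 0)
      stop("t_snap must be given for this system", call. = FALSE)
    t_snap <- 20 / kd
  }
  if (is.null(init)) {
    init <- if (all(c("Pr_L_free", "Pr_H_free") %in% system$species) &&
                !is.null(attr(system, "rates")))
      stationary_promoter_init(system, n_cells, seed)
    else default_init(system)
  }
  st <- sample_states(system, times = t_snap, n_cells = n_cells, seed = seed,
                      init = init)[[1]]
  snapshot_distribution(st[, species], condition = condition,
                        replicate = replicate, kind = "count", states = st)
}

#' Stationary-promoter initial ensemble for the two-state model
#'
#' Builds an initial state matrix in which each cell starts with zero RNA and
#' protein and a free promoter whose state (L or H) is drawn from the
#' stationary switching distribution `pi_H = k_H / (k_H + k_L)`.  The draw is
#' deterministic given the seed (a stream derived from it, so it does not
#' collide with the simulation streams).
#'
#' @param system a reduced two-state `reaction_system`.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return An `n_cells x n_species` matrix.
#' @export
stationary_promoter_init <- function(system, n_cells, seed) {
  r <- attr(system, "rates")
  if (is.null(r) || !all(c("Pr_L_free", "Pr_H_free") %in% system$species))
    stop("stationary promoter init needs the reduced two-state model",
         call. = FALSE)
  pi_H <- if (r$k_H + r$k_L > 0) r$k_H / (r$k_H + r$k_L) else 0
  u <- lcg_unif(derive_seed(seed, 104729L), n_cells)
  m <- matrix(0, nrow = n_cells, ncol = length(system$species),
              dimnames = list(NULL, system$species))
  high <- u < pi_H
  m[high, "Pr_H_free"] <- 1
  m[!high, "Pr_L_free"] <- 1
  m
}

#' Construct a snapshot distribution
#'
#' @param values non-negative per-cell scalar values (protein copy numbers or
#'   fluorescence intensities).
#' @param condition condition label (recycled).
#' @param replicate replicate id per cell (recycled).
#' @param kind `"count"` (analysed on the raw scale) or `"intensity"`
#'   (analysed on the log10 scale).
#' @param states optional full state matrix attribute.
#' @return A data.frame of class `snapshot_distribution`.
#' @export
snapshot_distribution <- function(values, condition = "condition",
                                  replicate = 1L,
                                  kind = c("count", "intensity"),
                                  states = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (any(is.na(values)) || any(values < 0))
    stop("values must be non-negative", call. = FALSE)
  out <- data.frame(cell_id = seq_along(values),
                    replicate = rep_len(replicate, length(values)),
                    condition = rep_len(condition, length(values)),
                    value = values)
  class(out) <- c("snapshot_distribution", "data.frame")
  attr(out, "kind") <- kind
  if (!is.null(states)) attr(out, "states") <- states
  out
}

#' @export
print.snapshot_distribution <- function(x, ...) {
  cat("Snapshot distribution (", attr(x, "kind"), "): ", nrow(x),
      " cells, condition '", as.character(x$condition[1]), "'\n", sep = "")
  cat(sprintf("  mean %.4g, CV^2 %.4g\n", mean(x$value),
              stats::var(x$value) / mean(x$value)^2))
  invisible(x)
}

# value kind of a snapshot or bare numeric vector
value_kind <- function(x, default = "count") {
  k <- attr(x, "kind")
  if (is.null(k)) default else k
}

values_of <- function(x) {
  if (is.data.frame(x)) x$value else as.numeric(x)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based derivation keeping seeds in the 32-bit integer
#' range, used to give every stochastic sub-task (cells, sweep points, ramp
#' steps) an independent reproducible stream.
#'
#' @param master integer master seed.
#' @param index non-negative counter.
#' @return An integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 1000003) %%
               2147483629)
}

# evaluate fun with a temporary RNG state seeded by `seed`
with_seed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}
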