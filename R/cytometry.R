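#' Specification of a synthetic flow-cytometry population
#'
#' Describes the statistical structure of a cytometry-like single-cell
#' dataset: a log10-normal mixture for the reporter intensity channel
#' (FITC-H), a multiplicative log-normal extrinsic-noise factor shared by
#' all intensity components, an additive autofluorescence floor present in
#' every cell (the wild-type background), per-replicate mean shifts on the
#' log10 scale, and unimodal log-normal size channels (SSC-H, FSC-H, Width)
#' correlated with log-intensity through a Gaussian copula.
#'
#' @param weights mixture component weights (non-negative, summing to 1).
#' @param log_means,log_sds component means and SDs of log10 signal.
#' @param extrinsic_sd SD of the multiplicative extrinsic-noise factor on the
#'   log10 scale.
#' @param af_log_mean,af_log_sd log10 mean and SD of the autofluorescence
#'   floor added to every cell.
#' @param replicate_sd SD of per-replicate mean shifts (log10 scale).
#' @param n_per_replicate cells per biological replicate.
#' @param n_replicates number of biological replicates.
#' @param size_correlation Pearson correlation between log10 intensity and
#'   the log10 size channels (|rho| < 1).
#' @param condition condition label.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(weights = c(0.4, 0.6),
                            log_means = c(2, 3.5),
                            log_sds = c(0.2, 0.25),
                            extrinsic_sd = 0.05,
                            af_log_mean = 1.3, af_log_sd = 0.15,
                            replicate_sd = 0.02,
                            n_per_replicate = 10000,
                            n_replicates = 3,
                            size_correlation = 0.3,
                            condition = "synthetic") {
  weights <- as.numeric(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (length(log_means) != length(weights) ||
      length(log_sds) != length(weights))
    stop("weights, log_means and log_sds must have equal length", call. = FALSE)
  if (any(log_sds < 0) || extrinsic_sd < 0 || af_log_sd < 0 || replicate_sd < 0)
    stop("SDs must be >= 0", call. = FALSE)
  if (abs(size_correlation) >= 1)
    stop("|size_correlation| must be < 1", call. = FALSE)
  if (n_per_replicate < 1 || n_replicates < 1)
    stop("need at least one cell and one replicate", call. = FALSE)
  structure(list(weights = weights, log_means = log_means, log_sds = log_sds,
                 extrinsic_sd = extrinsic_sd,
                 af_log_mean = af_log_mean, af_log_sd = af_log_sd,
                 replicate_sd = replicate_sd,
                 n_per_replicate = n_per_replicate,
                 n_replicates = n_replicates,
                 size_correlation = size_correlation,
                 condition = condition),
            class = "population_spec")
}

# size-channel log10 location/scale (shared by all shipped populations)
size_channel_pars <- list(`SSC-H` = c(4.0, 0.18),
                          `FSC-H` = c(4.3, 0.15),
                          Width = c(2.0, 0.08))

#' Generate a synthetic cytometry table
#'
#' Draws a cytometry-like dataset from a [population_spec()]: per cell,
#' intensity = autofluorescence + mixture signal x extrinsic noise factor,
#' with replicate-level mean shifts; size channels are unimodal log-normal
#' with the specified correlation to log-intensity (Gaussian copula).
#' Reproducible by seed; the global RNG state is left untouched.
#'
#' @param spec a `population_spec`.
#' @param seed integer seed.
#' @return A `cytometry_table`: data.frame with columns `FITC-H`, `SSC-H`,
#'   `FSC-H`, `Width`, `replicate`, `condition` (check.names = FALSE).
#' @export
generate_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, function() {
    reps <- lapply(seq_len(spec$n_replicates), function(r) {
      n <- spec$n_per_replicate
      shift <- stats::rnorm(1, 0, spec$replicate_sd)
      comp <- sample.int(length(spec$weights), n, replace = TRUE,
                         prob = spec$weights)
      log_signal <- stats::rnorm(n, spec$log_means[comp] + shift,
                                 spec$log_sds[comp]) +
        stats::rnorm(n, 0, spec$extrinsic_sd)
      af <- 10^stats::rnorm(n, spec$af_log_mean, spec$af_log_sd)
      fitc <- af + 10^log_signal
      z <- scale(log10(fitc))[, 1]
      rho <- spec$size_correlation
      size <- lapply(size_channel_pars, function(p) {
        zi <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
        10^(p[1] + p[2] * zi)
      })
      out <- data.frame(fitc, size[["SSC-H"]], size[["FSC-H"]],
                        size[["Width"]],
                        replicate = r, condition = spec$condition,
                        check.names = FALSE)
      names(out)[1:4] <- c("FITC-H", "SSC-H", "FSC-H", "Width")
      out
    })
    tab <- do.call(rbind, reps)
    as_cytometry_table(tab)
  })
}

as_cytometry_table <- function(tab) {
  class(tab) <- c("cytometry_table", "data.frame")
  attr(tab, "kind") <- "intensity"
  tab
}

#' @export
print.cytometry_table <- function(x, ...) {
  cat("Cytometry table: ", nrow(x), " cells, ",
      length(unique(x$replicate)), " replicate(s), condition '",
      as.character(x$condition[1]), "'\n", sep = "")
  invisible(x)
}

#' Wild-type (non-expressing) background population
#'
#' Autofluorescence-only cells: the single-component background that a strain
#' carrying no fluorescent reporter produces.  Its intensity distribution is
#' unimodal and sits below the expressing modes of the shipped fixtures.
#'
#' @param n number of cells.
#' @param seed integer seed.
#' @param af_log_mean,af_log_sd autofluorescence log10 location and scale.
#' @return A `cytometry_table` with one replicate, condition `"WT"`.
#' @export
generate_wt_background <- function(n, seed, af_log_mean = 1.3,
                                   af_log_sd = 0.15) {
  spec <- population_spec(weights = 1, log_means = -10, log_sds = 0,
                          extrinsic_sd = 0, af_log_mean = af_log_mean,
                          af_log_sd = af_log_sd, replicate_sd = 0,
                          n_per_replicate = n, n_replicates = 1,
                          size_correlation = 0.3, condition = "WT")
  generate_population(spec, seed)
}

#' Merge biological replicates into one sample
#'
#' Row-concatenates cytometry tables (or snapshot distributions) of the same
#' condition, preserving replicate ids; downstream distribution fits operate
#' on the merged sample, mirroring the merging of biological repeats before
#' classification.
#'
#' @param tables list of `cytometry_table`s (or one table, returned as is).
#' @return A merged table of the same class.
#' @export
merge_replicates <- function(tables) {
  if (is.data.frame(tables)) return(tables)
  stopifnot(is.list(tables), length(tables) >= 1)
  conds <- vapply(tables, function(t) as.character(t$condition[1]), "")
  if (length(unique(conds)) != 1)
    stop("cannot merge replicates with different condition labels: ",
         paste(unique(conds), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(tables, as.data.frame))
  if (inherits(tables[[1]], "cytometry_table")) return(as_cytometry_table(out))
  class(out) <- class(tables[[1]])
  attr(out, "kind") <- attr(tables[[1]], "kind")
  out
}

#' Overlay measurement noise on simulated protein counts
#'
#' Bridges model output and cytometry-like data: each protein count becomes
#' `intensity = autofluorescence + gain * count * extrinsic factor`, where
#' the extrinsic factor is log-normal (SD `extrinsic_sd` on the log10 scale)
#' and the autofluorescence is drawn as in [generate_population()].  This
#' adds the cell-to-cell variability sources (shared-component differences,
#' measurement uncertainty, background) that the reaction model alone does
#' not contain.
#'
#' @param snapshot a `snapshot_distribution` of protein counts.
#' @param gain fluorescence units per protein copy (> 0).
#' @param extrinsic_sd log10-scale SD of the multiplicative extrinsic factor.
#' @param af_log_mean,af_log_sd autofluorescence parameters; set
#'   `af_log_sd = 0` and `af_log_mean = -Inf` for no background.
#' @param seed integer seed.
#' @return A `cytometry_table` (intensity kind) with the same replicate and
#'   condition labels.
#' @export
model_to_intensity <- function(snapshot, gain = 100, extrinsic_sd = 0.25,
                               af_log_mean = 1.3, af_log_sd = 0.15, seed = 1) {
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  v <- values_of(snapshot)
  n <- length(v)
  with_seed(seed, function() {
    extr <- 10^stats::rnorm(n, 0, extrinsic_sd)
    af <- if (is.finite(af_log_mean)) 10^stats::rnorm(n, af_log_mean, af_log_sd)
          else 0
    fitc <- af + gain * v * extr
    z <- if (stats::sd(log10(pmax(fitc, 1e-12))) > 0)
      scale(log10(pmax(fitc, 1e-12)))[, 1] else rep(0, n)
    size <- lapply(size_channel_pars, function(p) {
      zi <- 0.3 * z + sqrt(1 - 0.3^2) * stats::rnorm(n)
      10^(p[1] + p[2] * zi)
    })
    out <- data.frame(fitc, size[["SSC-H"]], size[["FSC-H"]], size[["Width"]],
                      replicate = if (is.data.frame(snapshot))
                        snapshot$replicate else 1L,
                      condition = if (is.data.frame(snapshot))
                        snapshot$condition else "model",
                      check.names = FALSE)
    names(out)[1:4] <- c("FITC-H", "SSC-H", "FSC-H", "Width")
    as_cytometry_table(out)
  })
}

#' Shipped synthetic population fixtures
#'
#' Seven named `population_spec`s spanning the qualitative variety of bimodal
#' single-cell distributions seen in flow cytometry: distant modes with
#' asymmetric weights, close symmetric modes, a dominant high mode, and so
#' on.  All are synthetic constructions for exercising the analysis stages;
#' none claims to match any real gene's numbers.
#'
#' @return Named list of `population_spec`s.
#' @export
cytometry_fixtures <- function() {
  mk <- function(cond, w, mu, sd) {
    population_spec(weights = w, log_means = mu, log_sds = sd,
                    condition = cond)
  }
  list(
    distant_asymmetric   = mk("distant_asymmetric", c(0.30, 0.70),
                              c(1.8, 3.6), c(0.18, 0.25)),
    distant_tall_low     = mk("distant_tall_low", c(0.60, 0.40),
                              c(1.9, 3.4), c(0.15, 0.30)),
    close_symmetric      = mk("close_symmetric", c(0.50, 0.50),
                              c(2.4, 3.1), c(0.18, 0.20)),
    close_asymmetric     = mk("close_asymmetric", c(0.35, 0.65),
                              c(2.5, 3.2), c(0.17, 0.22)),
    dominant_high        = mk("dominant_high", c(0.15, 0.85),
                              c(2.0, 3.3), c(0.20, 0.25)),
    weak_low_expression  = mk("weak_low_expression", c(0.45, 0.55),
                              c(1.6, 2.9), c(0.15, 0.25)),
    broad_high_mode      = mk("broad_high_mode", c(0.40, 0.60),
                              c(2.0, 3.5), c(0.18, 0.35))
  )
}
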