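#' Kernel density estimate of a single-cell expression distribution
#'
#' Gaussian KDE on a 512-point grid spanning the data range.  Intensity data
#' (flow-cytometry style, positive and right-skewed) are analysed on the
#' log10 scale; simulated protein counts on the raw scale.  The default
#' bandwidth is Silverman's rule on the analysis scale.  The curve is
#' renormalised to integrate to 1 on its grid, so that modes piled against a
#' boundary (e.g. counts at zero) keep their full weight.
#'
#' @param values a `snapshot_distribution` or numeric vector (>= 50 values).
#' @param bandwidth optional bandwidth on the analysis scale.
#' @param kind `"count"` or `"intensity"`; defaults to the `kind` attribute
#'   of `values`, else `"count"`.
#' @return An object of class `density_curve`: list with `grid` (analysis
#'   scale), `grid_original` (data scale), `y` (density on the analysis
#'   scale), `bw`, `kind`.
#' @export
estimate_density <- function(values, bandwidth = NULL, kind = NULL) {
  if (is.null(kind)) kind <- value_kind(values)
  kind <- match.arg(kind, c("count", "intensity"))
  v <- values_of(values)
  if (length(v) < 50) stop("need at least 50 values for a density estimate",
                           call. = FALSE)
  x <- if (kind == "intensity") {
    if (any(v <= 0)) stop("intensity values must be > 0 for log analysis",
                          call. = FALSE)
    log10(v)
  } else v
  if (stats::sd(x) == 0) stop("values are constant; density is degenerate",
                              call. = FALSE)
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  # integer count data live on a unit lattice: keep the kernel wide enough
  # that the lattice itself does not masquerade as modes
  if (is.null(bandwidth) && kind == "count" && all(x == round(x)))
    bw <- max(bw, 0.75)
  if (!is.numeric(bw) || bw <= 0) stop("bandwidth must be > 0", call. = FALSE)
  d <- stats::density(x, bw = bw, n = 512, from = min(x), to = max(x))
  dx <- d$x[2] - d$x[1]
  area <- sum(d$y) * dx
  y <- d$y / area
  structure(list(grid = d$x,
                 grid_original = if (kind == "intensity") 10^d$x else d$x,
                 y = y, bw = bw, kind = kind),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat("Density curve (", x$kind, " kind): 512-point grid, bandwidth ",
      signif(x$bw, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.density_curve <- function(x, ...) {
  graphics::plot(x$grid, x$y, type = "l",
                 xlab = if (x$kind == "intensity") "log10 intensity" else "count",
                 ylab = "density", ...)
  invisible(x)
}

#' Detect peaks of a density curve
#'
#' Finds local maxima of the density (grid endpoints are admitted, so a mode
#' piled at the low boundary counts), computes each candidate's topographic
#' prominence, and keeps peaks with prominence at least
#' `min_prominence_frac` of the maximum density that are separated by at
#' least `min_separation_frac` of the grid range (greedy by height).  At most
#' the two tallest peaks are returned, ordered by position, as used by the
#' downstream shape statistics.
#'
#' @param density a `density_curve`.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   maximum density.
#' @param min_separation_frac minimum peak separation as a fraction of the
#'   grid range.
#' @return data.frame with columns `position` (original data scale),
#'   `position_analysis`, and `height`, one row per retained peak.
#' @export
detect_peaks <- function(density, min_prominence_frac = 0.05,
                         min_separation_frac = 0.05) {
  stopifnot(inherits(density, "density_curve"))
  y <- density$y
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  cand <- which(y > left & y >= right)
  if (!length(cand)) return(peak_frame(density, integer(0)))

  # topographic prominence: on each side, the lowest point between the peak
  # and the nearest higher ground (or the grid edge); base = the higher of
  # the two side minima, one-sided for edge peaks
  prominence <- vapply(cand, function(i) {
    lbase <- rbase <- NA_real_
    if (i > 1) {
      seg <- (i - 1):1
      higher <- seg[y[seg] > y[i]]
      span <- if (length(higher)) (higher[1] + 1):(i - 1) else 1:(i - 1)
      lbase <- if (length(span)) min(y[span]) else y[i]
    }
    if (i < n) {
      seg <- (i + 1):n
      higher <- seg[y[seg] > y[i]]
      span <- if (length(higher)) (i + 1):(higher[1] - 1) else (i + 1):n
      rbase <- if (length(span)) min(y[span]) else y[i]
    }
    base <- if (is.na(lbase)) rbase else if (is.na(rbase)) lbase
            else max(lbase, rbase)
    y[i] - base
  }, numeric(1))

  # the global mode always qualifies; prominence filters secondary peaks
  keep <- cand[prominence >= min_prominence_frac * max(y) |
                 y[cand] == max(y[cand])]
  if (!length(keep)) return(peak_frame(density, integer(0)))
  # greedy separation filter, tallest first
  keep <- keep[order(y[keep], decreasing = TRUE)]
  min_sep <- min_separation_frac * diff(range(density$grid))
  sel <- integer(0)
  for (i in keep)
    if (!length(sel) || all(abs(density$grid[i] - density$grid[sel]) >= min_sep))
      sel <- c(sel, i)
  sel <- sel[seq_len(min(2L, length(sel)))]
  peak_frame(density, sort(sel))
}

peak_frame <- function(density, idx) {
  data.frame(position = density$grid_original[idx],
             position_analysis = density$grid[idx],
             height = density$y[idx])
}

# ---- 1-D Gaussian mixture via EM -------------------------------------------

# Deterministic order-statistic restarts: initial means are data quantiles at
# uniforms from a private LCG, so fits are reproducible, independent of the
# global RNG, and affine-equivariant.
lcg_unif <- function(seed, n) {
  s <- as.double(seed %% 2147483647)
  if (s <= 0) s <- s + 2147483646
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 16807) %% 2147483647
    out[i] <- s / 2147483647
  }
  out
}

gmm_fit <- function(x, k, n_restarts = 10, max_iter = 300, tol = 1e-8,
                    sd_floor = 0) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x); sd1 <- max(stats::sd(x) * sqrt((n - 1) / n), sd_floor)
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    return(list(weights = 1, means = mu, sds = sd1, loglik = ll,
                bic = -2 * ll + 2 * log(n), converged = TRUE))
  }
  xs <- sort(x)
  var_floor <- max(stats::var(x) * 1e-6, sd_floor^2, 1e-300)
  best <- NULL
  # first restarts use fixed quantile pairs that also cover minority
  # components in either tail; later ones straddle the median at random
  fixed_u <- list(c(0.05, 0.50), c(0.50, 0.95), c(0.10, 0.90),
                  c(0.25, 0.75), c(0.02, 0.60), c(0.40, 0.98))
  for (r in seq_len(n_restarts)) {
    u <- if (r <= length(fixed_u)) fixed_u[[r]]
         else { uu <- lcg_unif(1234 + r, 2); c(uu[1] / 2, 0.5 + uu[2] / 2) }
    mu <- xs[pmax(1L, ceiling(sort(u) * n))]
    if (mu[1] == mu[2]) mu <- stats::quantile(xs, c(0.25, 0.75), names = FALSE)
    sg0 <- max(stats::sd(x) / 4, sqrt(var_floor))
    fit <- cpp_gmm2_em(x, mu[1], mu[2], sg0, sg0, 0.5, var_floor,
                       max_iter, tol)
    if (is.finite(fit$loglik) &&
        (is.null(best) || fit$loglik > best$loglik)) {
      w <- c(fit$w1, 1 - fit$w1)
      mu2 <- c(fit$mu1, fit$mu2)
      sg <- c(fit$sg1, fit$sg2)
      ord <- order(mu2)
      best <- list(weights = w[ord], means = mu2[ord], sds = sg[ord],
                   loglik = fit$loglik,
                   bic = -2 * fit$loglik + 5 * log(n),
                   converged = fit$converged)
    }
  }
  best
}

#' BIC criterion for bimodality
#'
#' Fits 1- and 2-component Gaussian mixtures by EM on the analysis scale
#' (log10 for intensities, raw for counts) with deterministic restarts, and
#' applies the strong-evidence decision rule: the distribution is called
#' bimodal when `BIC2 <= BIC1 - delta_bic` AND the minor component weight is
#' at least `min_weight` AND the component means are separated by at least
#' `sep_mult * min(sd1, sd2)`.  BIC is on the `-2 logLik + p log n` scale
#' (smaller is better; 2 parameters for one component, 5 for two).
#'
#' @inheritParams estimate_density
#' @param delta_bic required BIC improvement of the 2-component fit.
#' @param min_weight minor-component weight floor.
#' @param sep_mult separation guard in units of the smaller component SD.
#' @param ashman_D minimum Ashman separation
#'   `D = sqrt(2) |mu2 - mu1| / sqrt(sd1^2 + sd2^2)`; `D >= 2` is the usual
#'   condition for a two-Gaussian mixture to be visibly bimodal, and guards
#'   against the BIC rewarding two components that merely absorb skewness.
#' @param n_restarts EM restarts for the 2-component fit.
#' @details For integer-valued count data the component SDs are floored at
#'   0.5 (half the unit lattice), so a point mass on a single count value
#'   cannot pose as an arbitrarily well-separated component.
#' @return List with `is_bimodal_bic`, `fit1`, `fit2`, `bic1`, `bic2`,
#'   `ashman_D`.
#' @export
classify_bic <- function(values, kind = NULL, delta_bic = 10,
                         min_weight = 0.05, sep_mult = 2, ashman_D = 2.2,
                         n_restarts = 10) {
  if (is.null(kind)) kind <- value_kind(values)
  kind <- match.arg(kind, c("count", "intensity"))
  v <- values_of(values)
  if (length(v) < 50) stop("need at least 50 values", call. = FALSE)
  x <- if (kind == "intensity") log10(v) else v
  if (stats::sd(x) == 0) stop("values are constant", call. = FALSE)
  sd_floor <- if (kind == "count" && all(x == round(x))) 0.5 else 0
  f1 <- gmm_fit(x, 1, sd_floor = sd_floor)
  f2 <- gmm_fit(x, 2, n_restarts = n_restarts, sd_floor = sd_floor)
  ok2 <- !is.null(f2) && is.finite(f2$loglik)
  if (!ok2 || !f2$converged)
    warning("2-component EM did not converge; BIC criterion set to FALSE")
  D <- if (ok2) sqrt(2) * abs(diff(f2$means)) / sqrt(sum(f2$sds^2))
       else NA_real_
  bim <- ok2 && f2$converged &&
    (f2$bic <= f1$bic - delta_bic) &&
    (min(f2$weights) >= min_weight) &&
    (abs(diff(f2$means)) >= sep_mult * min(f2$sds)) &&
    (D >= ashman_D)
  list(is_bimodal_bic = isTRUE(bim), fit1 = f1, fit2 = f2,
       bic1 = f1$bic, bic2 = if (ok2) f2$bic else NA_real_,
       ashman_D = D)
}

#' Classify a single-cell expression distribution as unimodal or bimodal
#'
#' The fit-like entry point of the package.  Combines two criteria on the
#' analysis scale: the mixture/BIC rule of [classify_bic()] and kernel-density
#' peak detection ([detect_peaks()]; two retained peaks make the criterion
#' true).  The verdict is `"bimodal"` iff at least one criterion is true.
#' For a bimodal verdict, the peak positions `pk1 < pk2` and heights
#' `PDF1`, `PDF2` are taken from the density curve when two peaks were
#' found, and otherwise from the 2-component mixture means (back-transformed)
#' with the density evaluated there.
#'
#' @inheritParams classify_bic
#' @inheritParams detect_peaks
#' @param bandwidth optional KDE bandwidth on the analysis scale.
#' @return An object of class `modality_call`: list with `verdict`,
#'   `criteria` (named logicals `bic`, `peaks`), `pk1`, `pk2`, `PDF1`,
#'   `PDF2` (NA when unimodal), `fit1`, `fit2`, `bic1`, `bic2`, `peaks`
#'   (data.frame), `density`, `n`, `kind`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 50, 5), rnorm(500, 200, 15))
#' call <- classify_modality(x, kind = "count")
#' call$verdict
#' @export
classify_modality <- function(values, kind = NULL, bandwidth = NULL,
                              delta_bic = 10, min_weight = 0.05, sep_mult = 2,
                              ashman_D = 2.2, n_restarts = 10,
                              min_prominence_frac = 0.05,
                              min_separation_frac = 0.05) {
  if (is.null(kind)) kind <- value_kind(values)
  kind <- match.arg(kind, c("count", "intensity"))
  v <- values_of(values)
  dc <- estimate_density(v, bandwidth = bandwidth, kind = kind)
  pk <- detect_peaks(dc, min_prominence_frac, min_separation_frac)
  bic <- classify_bic(v, kind = kind, delta_bic = delta_bic,
                      min_weight = min_weight, sep_mult = sep_mult,
                      ashman_D = ashman_D, n_restarts = n_restarts)
  crit <- c(bic = bic$is_bimodal_bic, peaks = nrow(pk) >= 2)
  verdict <- if (any(crit)) "bimodal" else "unimodal"

  pk1 <- pk2 <- PDF1 <- PDF2 <- NA_real_
  if (verdict == "bimodal") {
    if (nrow(pk) >= 2) {
      pk1 <- pk$position[1]; pk2 <- pk$position[2]
      PDF1 <- pk$height[1]; PDF2 <- pk$height[2]
    } else {
      mu <- sort(bic$fit2$means)
      pos <- if (kind == "intensity") 10^mu else mu
      h <- stats::approx(dc$grid, dc$y, xout = mu, rule = 2)$y
      pk1 <- pos[1]; pk2 <- pos[2]; PDF1 <- h[1]; PDF2 <- h[2]
    }
  }
  structure(list(verdict = verdict, criteria = crit,
                 pk1 = pk1, pk2 = pk2, PDF1 = PDF1, PDF2 = PDF2,
                 fit1 = bic$fit1, fit2 = bic$fit2,
                 bic1 = bic$bic1, bic2 = bic$bic2,
                 peaks = pk, density = dc, n = length(v), kind = kind),
            class = "modality_call")
}

#' @export
print.modality_call <- function(x, ...) {
  cat("Modality call: ", x$verdict, "  (BIC: ", x$criteria[["bic"]],
      ", peaks: ", x$criteria[["peaks"]], "; n = ", x$n, ")\n", sep = "")
  if (x$verdict == "bimodal")
    cat(sprintf("  pk1 = %.4g (PDF %.4g), pk2 = %.4g (PDF %.4g)\n",
                x$pk1, x$PDF1, x$pk2, x$PDF2))
  invisible(x)
}

#' @export
summary.modality_call <- function(object, ...) {
  f2 <- object$fit2
  cat("Modality classification (", object$kind, " scale analysis)\n", sep = "")
  print(object)
  cat(sprintf("  BIC1 = %.2f, BIC2 = %.2f (delta = %.2f)\n",
              object$bic1, object$bic2, object$bic1 - object$bic2))
  if (!is.null(f2))
    cat(sprintf("  2-comp fit: w = (%.3f, %.3f), mu = (%.4g, %.4g), sd = (%.4g, %.4g)\n",
                f2$weights[1], f2$weights[2], f2$means[1], f2$means[2],
                f2$sds[1], f2$sds[2]))
  invisible(object)
}

#' @export
coef.modality_call <- function(object, ...) {
  f2 <- object$fit2
  c(w1 = f2$weights[1], w2 = f2$weights[2],
    mu1 = f2$means[1], mu2 = f2$means[2],
    sd1 = f2$sds[1], sd2 = f2$sds[2])
}

#' @export
plot.modality_call <- function(x, ...) {
  plot(x$density, main = paste("verdict:", x$verdict), ...)
  if (x$verdict == "bimodal") {
    pos <- if (x$kind == "intensity") log10(c(x$pk1, x$pk2)) else c(x$pk1, x$pk2)
    graphics::abline(v = pos, lty = 2)
  }
  invisible(x)
}

#' Estimated weight of the high-expression mode
#'
#' Estimates the fraction of cells in the high mode of a bimodal call, for
#' comparison against the stationary promoter occupancy
#' `pi_H = k_H / (k_H + k_L)` in the slow-switching regime.  When the sample
#' values are supplied, the estimate is the fraction of cells above the
#' density antimode (the minimum of the KDE between the two peaks), which is
#' free of the slight weight bias a two-Gaussian fit incurs on right-skewed
#' components; without values, the 2-component mixture weight of the
#' higher-mean component is returned.
#'
#' @param call a `modality_call`.
#' @param values optionally, the values the call was fitted to.
#' @return Weight in [0, 1].
#' @export
high_mode_weight <- function(call, values = NULL) {
  stopifnot(inherits(call, "modality_call"))
  f2 <- call$fit2
  w_mix <- f2$weights[which.max(f2$means)]
  if (is.null(values)) return(w_mix)
  v <- values_of(values)
  lo <- call$pk1; hi <- call$pk2
  if (is.na(lo) || is.na(hi)) {
    mu <- sort(f2$means)
    pos <- if (call$kind == "intensity") 10^mu else mu
    lo <- pos[1]; hi <- pos[2]
  }
  g <- call$density$grid_original
  between <- g > lo & g < hi
  if (!any(between)) return(w_mix)
  antimode <- g[between][which.min(call$density$y[between])]
  mean(v > antimode)
}
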