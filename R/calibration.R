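#' Four-anchor sets for cross-fluorophore calibration
#'
#' An `anchor_set` holds the four calibration points of a bimodal single-cell
#' fluorescence distribution on one fluorophore's scale: the lowest cell
#' signal, the mean of the weak (low) mode, the mean of the high mode, and
#' the highest cell signal.  Anchors must be strictly increasing.
#'
#' @param values numeric vector of length 4, strictly increasing.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 4 || any(!is.finite(values)))
    stop("an anchor set is four finite numbers", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("anchors must be strictly increasing", call. = FALSE)
  structure(setNames(values, c("min", "weak_mode", "high_mode", "max")),
            class = "anchor_set")
}

#' Compute the four anchors of a bimodal sample
#'
#' Extracts (min, weak-mode mean, high-mode mean, max) from a sample and its
#' modality call.  Mode means are the 2-component mixture means on the
#' analysis scale, back-transformed to the data scale for intensity data.
#'
#' @param values the sample (a `snapshot_distribution` or numeric vector).
#' @param call the bimodal `modality_call` fitted to `values`.
#' @return An `anchor_set`.
#' @export
compute_anchors <- function(values, call) {
  stopifnot(inherits(call, "modality_call"))
  if (call$verdict != "bimodal")
    stop("anchors require a bimodal call", call. = FALSE)
  f2 <- call$fit2
  if (is.null(f2)) stop("call carries no 2-component mixture fit", call. = FALSE)
  mu <- sort(f2$means)
  if (diff(mu) == 0) stop("degenerate mixture fit: equal mode means",
                          call. = FALSE)
  modes <- if (call$kind == "intensity") 10^mu else mu
  v <- values_of(values)
  anchor_set(c(min(v), modes[1], modes[2], max(v)))
}

#' Piecewise-linear map between two fluorophore scales
#'
#' `fit_anchor_map()` builds the strictly increasing piecewise-linear
#' interpolant through the four source/target anchor pairs; outside the
#' source anchor span the terminal segments are continued linearly (the only
#' monotone choice without data).  `apply_map()` evaluates it elementwise.
#'
#' @param src,dst `anchor_set`s on the source and target scales.
#' @return `fit_anchor_map()` an object of class `anchor_map`;
#'   `apply_map()` a numeric vector (or `snapshot_distribution` if given one).
#' @examples
#' m <- fit_anchor_map(anchor_set(c(0, 1, 2, 3)), anchor_set(c(0, 10, 20, 30)))
#' apply_map(m, 1.5)  # 15
#' @export
fit_anchor_map <- function(src, dst) {
  if (!inherits(src, "anchor_set")) src <- anchor_set(src)
  if (!inherits(dst, "anchor_set")) dst <- anchor_set(dst)
  structure(list(src = src, dst = dst), class = "anchor_map")
}

#' @rdname fit_anchor_map
#' @param map an `anchor_map`.
#' @param values values on the source scale.
#' @export
apply_map <- function(map, values) {
  stopifnot(inherits(map, "anchor_map"))
  v <- values_of(values)
  s <- unclass(map$src); d <- unclass(map$dst)
  out <- stats::approx(s, d, xout = v, rule = 2)$y
  lo <- v < s[1]
  hi <- v > s[4]
  if (any(lo)) {
    sl <- (d[2] - d[1]) / (s[2] - s[1])
    out[lo] <- d[1] + sl * (v[lo] - s[1])
  }
  if (any(hi)) {
    sl <- (d[4] - d[3]) / (s[4] - s[3])
    out[hi] <- d[4] + sl * (v[hi] - s[4])
  }
  if (is.data.frame(values)) {
    res <- values
    res$value <- out
    return(res)
  }
  out
}

#' @export
print.anchor_map <- function(x, ...) {
  cat("Anchor map (piecewise linear through 4 anchor pairs)\n")
  print(rbind(source = unclass(x$src), target = unclass(x$dst)))
  invisible(x)
}

#' Ordinary least-squares fit with slope inference
#'
#' Regresses `y` on `x` and reports the slope, intercept, coefficient of
#' determination, the two-sided p-value of the t-test for slope = 0, and the
#' 95% confidence bounds of both coefficients, as used to relate paired
#' per-condition summary levels of two reporter libraries.
#'
#' @param x,y paired numeric vectors (>= 3 points; `x` not constant).
#' @return An object of class `linear_fit_stats`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `conf_low`, `conf_high` (length-2,
#'   intercept then slope), and the underlying `lm` fit.
#' @export
linear_fit_stats <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  p <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 conf_low = ci[, 1], conf_high = ci[, 2],
                 fit = fit),
            class = "linear_fit_stats")
}

#' @export
print.linear_fit_stats <- function(x, ...) {
  cat(sprintf("Linear fit: y = %.4g + %.4g x,  R^2 = %.4f,  p(slope) = %.3g\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
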