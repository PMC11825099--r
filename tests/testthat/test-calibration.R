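test_that("anchor sets must be strictly increasing", {
  expect_s3_class(anchor_set(c(1, 2, 3, 4)), "anchor_set")
  expect_error(anchor_set(c(1, 2, 2, 4)), "increasing")
  expect_error(anchor_set(c(1, 2, 3)), "four")
})

test_that("anchors recover the truth of a known mixture", {
  x <- bimodal_intensity(20000, seed = 1, mu = c(2, 3), sd = c(0.1, 0.12))
  call <- classify_modality(x, kind = "intensity")
  a <- compute_anchors(x, call)
  expect_equal(unname(a[["min"]]), min(x))
  expect_equal(unname(a[["max"]]), max(x))
  expect_equal(unname(a[["weak_mode"]]), 100, tolerance = 0.05 * 100)
  expect_equal(unname(a[["high_mode"]]), 1000, tolerance = 0.05 * 1000)
  expect_true(all(diff(unclass(a)) > 0))
  set.seed(2)
  uni <- 10^stats::rnorm(5000, 2.5, 0.2)
  ucall <- classify_modality(uni, kind = "intensity")
  expect_error(compute_anchors(uni, ucall), "bimodal")
})

test_that("anchor maps interpolate, extrapolate and invert as stated", {
  id <- fit_anchor_map(c(0, 1, 2, 3), c(0, 1, 2, 3))
  v <- c(0.2, 1.5, 2.9)
  expect_equal(apply_map(id, v), v)
  twice <- fit_anchor_map(c(0, 1, 2, 3), c(0, 2, 4, 6))
  expect_equal(apply_map(twice, v), 2 * v)
  seg <- fit_anchor_map(c(0, 1, 2, 3), c(0, 10, 20, 30))
  expect_equal(apply_map(seg, 1.5), 15)
  # terminal-segment extrapolation stays linear and monotone
  m <- fit_anchor_map(c(1, 2, 4, 8), c(10, 30, 40, 100))
  expect_equal(apply_map(m, 0), 10 + (30 - 10) / (2 - 1) * (0 - 1))
  expect_equal(apply_map(m, 10), 100 + (100 - 40) / (8 - 4) * (10 - 8))
  grid <- seq(-5, 20, by = 0.01)
  expect_true(all(diff(apply_map(m, grid)) > 0))
})

test_that("map round trip is exact on anchors and tight elsewhere", {
  a <- anchor_set(c(12, 110, 950, 4800))
  b <- anchor_set(c(30, 400, 2500, 20000))
  fwd <- fit_anchor_map(a, b)
  bwd <- fit_anchor_map(b, a)
  expect_equal(apply_map(bwd, apply_map(fwd, unname(unclass(a)))),
               unname(unclass(a)))
  v <- seq(12, 4800, length.out = 200)
  expect_equal(apply_map(bwd, apply_map(fwd, v)), v, tolerance = 1e-10)
})

test_that("monotone maps preserve ranks and modality", {
  x <- bimodal_intensity(8000, seed = 3)
  call <- classify_modality(x, kind = "intensity")
  src <- compute_anchors(x, call)
  dst <- anchor_set(unclass(src) * c(2.5, 2.8, 3.1, 3.0))
  m <- fit_anchor_map(src, dst)
  y <- apply_map(m, x)
  expect_equal(stats::cor(x, y, method = "spearman"), 1)
  expect_identical(classify_modality(y, kind = "intensity")$verdict, "bimodal")
})

test_that("linear fit statistics match known lines and degenerate cases", {
  f <- suppressWarnings(linear_fit_stats(1:5, 2 * (1:5)))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_true(is.finite(f$p_value) || f$p_value == 0)
  f3 <- suppressWarnings(linear_fit_stats(c(1, 2, 3), c(5, 7, 9)))
  expect_equal(f3$r_squared, 1)
  expect_false(is.na(f3$p_value))
  set.seed(4)
  fn <- linear_fit_stats(stats::rnorm(100), stats::rnorm(100))
  expect_true(fn$conf_low[2] < fn$slope && fn$slope < fn$conf_high[2])
  expect_error(linear_fit_stats(rep(1, 10), stats::rnorm(10)), "constant")
  expect_error(linear_fit_stats(1:2, 1:2), "3 paired")
})

test_that("slope p-values are calibrated under the null", {
  set.seed(5)
  p <- vapply(1:200, function(i)
    linear_fit_stats(stats::rnorm(40), stats::rnorm(40))$p_value, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})
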