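test_that("density estimation finds the mode and integrates to one", {
  set.seed(1)
  x <- stats::rnorm(10000, 100, 10)
  d <- estimate_density(x, kind = "count")
  expect_lt(abs(d$grid[which.max(d$y)] - 100), 2)
  dx <- diff(d$grid[1:2])
  expect_lt(abs(sum(d$y) * dx - 1), 0.01)
  # intensity kind: analysed on log10, integrates on its grid too
  di <- estimate_density(10^stats::rnorm(5000, 2, 0.2), kind = "intensity")
  expect_lt(abs(sum(di$y) * diff(di$grid[1:2]) - 1), 0.01)
  expect_error(estimate_density(rep(5, 100)), "constant")
  expect_error(estimate_density(stats::rnorm(20)), "at least 50")
  expect_error(estimate_density(c(-1, stats::rnorm(99, 5)), kind = "intensity"),
               "> 0")
})

test_that("peak detection resolves separated modes and merges coincident ones", {
  set.seed(2)
  x <- c(stats::rnorm(5000, 50, 5), stats::rnorm(5000, 200, 15))
  pk <- detect_peaks(estimate_density(x, kind = "count"))
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$position[1] - 50), 5)
  expect_lt(abs(pk$position[2] - 200), 10)
  expect_true(pk$position[1] < pk$position[2])

  single <- detect_peaks(estimate_density(stats::rnorm(5000, 100, 10),
                                          kind = "count"))
  expect_equal(nrow(single), 1)

  coincident <- c(stats::rnorm(5000, 100, 5), stats::rnorm(5000, 100, 20))
  expect_equal(nrow(detect_peaks(estimate_density(coincident, kind = "count"))),
               1)
})

test_that("a boundary-piled count distribution yields its edge mode", {
  set.seed(3)
  x <- stats::rpois(5000, 0.7)
  pk <- detect_peaks(estimate_density(x, kind = "count"))
  expect_equal(nrow(pk), 1)
  expect_lt(pk$position[1], 1)
})

test_that("BIC criterion detects separated mixtures and rejects weak ones", {
  x <- log10(bimodal_intensity(10000, seed = 4))  # already log scale
  res <- classify_bic(x, kind = "count")
  expect_true(res$is_bimodal_bic)
  expect_lt(res$bic2, res$bic1 - 10)
  # minor weight below the floor is rejected regardless of separation
  set.seed(5)
  y <- c(stats::rnorm(9900, 3, 0.1), stats::rnorm(100, 2, 0.1))
  res2 <- classify_bic(y, kind = "count")
  expect_false(res2$is_bimodal_bic)
  expect_lt(min(res2$fit2$weights), 0.05)
  # a single Gaussian is not split
  set.seed(6)
  res3 <- classify_bic(stats::rnorm(10000, 3, 0.1), kind = "count")
  expect_false(res3$is_bimodal_bic)
})

test_that("the in-package EM agrees with mclust on a clean mixture", {
  withr::local_package("mclust")
  x <- log10(bimodal_intensity(8000, seed = 7, w = 0.4))
  ours <- classify_bic(x, kind = "count")$fit2
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(ours$weights), sort(as.numeric(mc$parameters$pro)),
               tolerance = 0.03)
  # and mclust's BIC also prefers two components, like our delta-BIC rule
  expect_gt(mclustBIC(x, G = 2, modelNames = "V", verbose = FALSE)[1],
            mclustBIC(x, G = 1, modelNames = "X", verbose = FALSE)[1])
})

test_that("verdict is the OR of the two criteria", {
  cases <- list(bimodal_intensity(6000, seed = 8),
                10^stats::rnorm(6000, 2.5, 0.2),
                bimodal_intensity(6000, seed = 9, mu = c(2, 2.6)))
  set.seed(10)
  for (x in cases) {
    call <- suppressWarnings(classify_modality(x, kind = "intensity"))
    expect_identical(call$verdict == "bimodal", any(call$criteria))
    if (call$verdict == "bimodal") {
      expect_true(call$pk1 < call$pk2)
      expect_true(all(is.finite(c(call$PDF1, call$PDF2))))
    } else {
      expect_true(is.na(call$pk1))
    }
  }
})

test_that("high-mode weight recovers the true mixture fraction", {
  x <- bimodal_intensity(20000, seed = 11, w = 0.7)  # 30% in the high mode
  call <- classify_modality(x, kind = "intensity")
  expect_equal(high_mode_weight(call, x), 0.3, tolerance = 0.03)
  expect_equal(high_mode_weight(call), 0.3, tolerance = 0.05)
})

test_that("d, h, o are invariant under affine rescaling (continuous data)", {
  x <- c(stats::rnorm(4000, 30, 3), stats::rnorm(6000, 90, 6))
  set.seed(12); x <- x[x > 0]
  ref_call <- classify_modality(x, kind = "count")
  ref <- shape_params(ref_call, x)
  for (i in 1:3) {
    a <- stats::runif(1, 0.5, 20); b <- stats::runif(1, 0, 50)
    y <- a * x + b
    sp <- shape_params(classify_modality(y, kind = "count"), y)
    expect_equal(sp$d, ref$d, tolerance = 1e-6)
    expect_equal(sp$h, ref$h, tolerance = 1e-6)
    expect_equal(sp$o, ref$o, tolerance = 1e-6)
  }
})

test_that("estimated d does not decrease with true component separation", {
  set.seed(13)
  seps <- c(40, 70, 100, 130)
  ds <- vapply(seps, function(s) {
    x <- c(stats::rnorm(5000, 50, 6), stats::rnorm(5000, 50 + s, 6))
    shape_params(classify_modality(x, kind = "count"), x)$d
  }, numeric(1))
  expect_true(all(diff(ds) > -0.02))
})

test_that("classifier output is an S3 fit object with methods", {
  x <- bimodal_intensity(5000, seed = 14)
  call <- classify_modality(x, kind = "intensity")
  expect_s3_class(call, "modality_call")
  expect_output(print(call), "bimodal")
  expect_output(summary(call), "2-comp fit")
  expect_named(coef(call), c("w1", "w2", "mu1", "mu2", "sd1", "sd2"))
})
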