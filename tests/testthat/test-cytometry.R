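test_that("population generation is deterministic and structured", {
  spec <- population_spec(n_per_replicate = 500, n_replicates = 3)
  a <- generate_population(spec, seed = 1)
  b <- generate_population(spec, seed = 1)
  c <- generate_population(spec, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a[["FITC-H"]], c[["FITC-H"]]))
  expect_equal(nrow(a), 1500)
  expect_setequal(unique(a$replicate), 1:3)
  expect_true(all(a[["FITC-H"]] > 0))
  expect_true(all(a$Width > 0))
})

test_that("population_spec validates its structure", {
  expect_error(population_spec(weights = c(0.5, 0.6)), "sum to 1")
  expect_error(population_spec(weights = c(1), log_means = c(1, 2)),
               "equal length")
  expect_error(population_spec(size_correlation = 1), "< 1")
  expect_error(population_spec(extrinsic_sd = -1), ">= 0")
})

test_that("two-component populations are bimodal with recoverable weights", {
  # autofluorescence set far below the low mode so component locations are
  # recoverable on the log scale
  spec <- population_spec(weights = c(0.4, 0.6), log_means = c(2, 3.5),
                          log_sds = c(0.2, 0.25), af_log_mean = 0,
                          af_log_sd = 0.05)
  tab <- generate_population(spec, seed = 3)
  iv <- snapshot_distribution(tab[["FITC-H"]], kind = "intensity")
  call <- classify_modality(iv)
  expect_identical(call$verdict, "bimodal")
  expect_equal(sort(call$fit2$weights), c(0.4, 0.6), tolerance = 0.05)
  # component means recovered within 3 SE on the log scale
  ord <- order(call$fit2$means)
  mu <- call$fit2$means[ord]; sds <- call$fit2$sds[ord]
  n_eff <- nrow(tab) * sort(call$fit2$weights)
  expect_lt(abs(mu[1] - 2), 3 * sds[1] / sqrt(n_eff[1]) + 0.02)
  expect_lt(abs(mu[2] - 3.5), 3 * sds[2] / sqrt(n_eff[2]) + 0.02)
})

test_that("size channels are unimodal and correlated as requested", {
  spec <- population_spec(size_correlation = 0.5)
  tab <- generate_population(spec, seed = 4)
  expect_equal(stats::cor(log10(tab[["FITC-H"]]), log10(tab[["FSC-H"]])),
               0.5, tolerance = 0.05)
  for (ch in c("SSC-H", "FSC-H", "Width")) {
    call <- classify_modality(snapshot_distribution(tab[[ch]],
                                                    kind = "intensity"))
    expect_identical(call$verdict, "unimodal")
  }
})

test_that("all shipped fixtures are bimodal with unimodal scatter channels", {
  for (spec in cytometry_fixtures()) {
    small <- spec; small$n_per_replicate <- 4000; small$n_replicates <- 3
    class(small) <- "population_spec"
    tab <- generate_population(small, seed = 5)
    call <- suppressWarnings(
      classify_modality(snapshot_distribution(tab[["FITC-H"]],
                                              kind = "intensity")))
    expect_identical(call$verdict, "bimodal")
    sc <- suppressWarnings(
      classify_modality(snapshot_distribution(tab[["SSC-H"]],
                                              kind = "intensity")))
    expect_identical(sc$verdict, "unimodal")
  }
})

test_that("the WT background is unimodal and below expressing modes", {
  wt <- generate_wt_background(3000, seed = 6)
  call <- classify_modality(snapshot_distribution(wt[["FITC-H"]],
                                                  kind = "intensity"))
  expect_identical(call$verdict, "unimodal")
  expect_identical(generate_wt_background(3000, seed = 6), wt)
  # WT sits below the lowest expressing-mode mean of every shipped fixture
  wt_mean <- mean(log10(wt[["FITC-H"]]))
  low_modes <- vapply(cytometry_fixtures(), function(s) min(s$log_means),
                      numeric(1))
  expect_true(all(wt_mean < low_modes))
})

test_that("merging replicates concatenates and preserves labels", {
  spec <- population_spec(n_per_replicate = 100, n_replicates = 1,
                          condition = "g1")
  t1 <- generate_population(spec, seed = 1)
  t2 <- generate_population(spec, seed = 2); t2$replicate <- 2
  t3 <- generate_population(spec, seed = 3); t3$replicate <- 3
  m <- merge_replicates(list(t1, t2, t3))
  expect_equal(nrow(m), 300)
  expect_setequal(unique(m$replicate), 1:3)
  expect_identical(merge_replicates(list(t1))[["FITC-H"]], t1[["FITC-H"]])
  bad <- t2; bad$condition <- "g2"
  expect_error(merge_replicates(list(t1, bad)), "condition")
})

test_that("model counts map to intensities by the stated arithmetic", {
  snap <- snapshot_distribution(c(0, 1, 5, 10, 50), kind = "count")
  tab <- model_to_intensity(snap, gain = 1, extrinsic_sd = 0,
                            af_log_mean = -Inf, af_log_sd = 0, seed = 1)
  expect_equal(tab[["FITC-H"]], c(0, 1, 5, 10, 50))
  tab2 <- model_to_intensity(snap, gain = 100, extrinsic_sd = 0,
                             af_log_mean = 2, af_log_sd = 0, seed = 1)
  expect_equal(tab2[["FITC-H"]], 100 + 100 * c(0, 1, 5, 10, 50))
  expect_error(model_to_intensity(snap, gain = 0), "> 0")
})

test_that("extrinsic noise broadens modes: d falls and o rises", {
  sys <- build_reduced_model(reference_rates())
  snap <- sample_snapshot(sys, n_cells = 6000, seed = 13)
  res <- lapply(c(0.05, 0.25), function(esd) {
    tab <- model_to_intensity(snap, gain = 100, extrinsic_sd = esd, seed = 3)
    iv <- snapshot_distribution(tab[["FITC-H"]], kind = "intensity")
    call <- suppressWarnings(classify_modality(iv))
    expect_identical(call$verdict, "bimodal")
    shape_params(call, iv)
  })
  expect_gt(res[[1]]$d, res[[2]]$d)
  expect_lte(res[[1]]$o, res[[2]]$o + 0.02)
})
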