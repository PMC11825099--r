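test_that("a factor-1 sweep point reproduces the unswept run exactly", {
  r <- quick_rates()
  spec <- sweep_spec(r, "k_tr", factors = 1, n_cells = 300, seed = 9)
  sw <- run_sweep(spec)
  direct <- sample_snapshot(build_reduced_model(r), t_snap = spec$t_snap,
                            n_cells = 300, seed = derive_seed(9, 1))
  expect_identical(sw$records[[1]]$snapshot$value, direct$value)
  expect_equal(sw$records[[1]]$rates, r)
})

test_that("sweeps are deterministic and raising kd_prot lowers mean protein", {
  spec <- sweep_spec(quick_rates(), "kd_prot", factors = c(1, 3, 10),
                     n_cells = 1500, seed = 4)
  a <- suppressWarnings(run_sweep(spec))
  b <- suppressWarnings(run_sweep(spec))
  expect_identical(summary(a), summary(b))
  means <- summary(a)$mean
  expect_true(all(diff(means) < 0))
  # closed-form check of the trend: mean scales as 1/kd_prot
  expect_equal(means[1] / means[3], 10, tolerance = 0.2)
})

test_that("sweep_spec validates fields and factors", {
  expect_error(sweep_spec(quick_rates(), "k_nothing"), "unknown")
  expect_error(sweep_spec(quick_rates(), "k_tr", factors = c(1, -2)), "> 0")
  expect_equal(default_grid(), c(0.1, 0.215, 0.464, 1, 2.154, 4.642, 10),
               tolerance = 1e-3)
})

test_that("raising the L rates to the H values collapses onto the high state", {
  ext <- suppressWarnings(
    run_extended_L_sweep(alphas = c(0, 1), n_cells = 3000, seed = 5))
  s <- summary(ext)
  expect_identical(s$verdict, c("bimodal", "unimodal"))
  rec <- ext$records[[2]]
  mH <- stationary_moments_closed_form(reference_rates(), "H")$mean_protein
  se <- sqrt(rec$moments$var / 3000)
  expect_lt(abs(rec$moments$mean - mH), 3 * se)
  # at the endpoint the L rates equal the H rates exactly
  expect_equal(rec$rates$k_bind_L, reference_rates()$k_bind_H)
  expect_equal(rec$rates$k_esc_L, reference_rates()$k_esc_H)
})

test_that("unimodal shift starts bimodal and relaxes to the variant mean", {
  sh <- suppressWarnings(
    run_unimodal_shift("low", times = c(0, 100, 400, 800),
                       n_cells = 3000, seed = 6))
  verdicts <- vapply(sh$records, function(r) r$call$verdict, "")
  expect_identical(verdicts[1], "bimodal")
  expect_identical(verdicts[length(verdicts)], "unimodal")
  expect_false(is.na(sh$relaxation_time))
  final <- sh$records[[length(sh$records)]]
  mL <- stationary_moments_closed_form(reference_rates(), "L")$mean_protein
  expect_lt(abs(final$moments$mean - mL), 3 * sqrt(final$moments$var / 3000))
})

test_that("all three variants relax on comparable timescales", {
  times <- c(0, 75, 150, 300, 600)
  rt <- vapply(c("low", "average", "high"), function(v)
    suppressWarnings(run_unimodal_shift(v, times = times, n_cells = 2500,
                                        seed = 7))$relaxation_time,
    numeric(1))
  expect_true(all(is.finite(rt)))
  expect_lte(max(rt) / min(rt), 4)  # within a factor ~2 of each other on this grid
})

test_that("stationary transition endpoints behave as derived", {
  tr <- suppressWarnings(
    run_stationary_transition(f_grid = c(0, 1), n_cells = 3000, seed = 8))
  s <- summary(tr)
  expect_identical(s$verdict[1], "bimodal")
  expect_lt(s$mean[2], s$mean[1])
})
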