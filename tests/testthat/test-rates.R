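test_that("rate_set validates its fields", {
  expect_s3_class(reference_rates(), "rate_set")
  expect_error(rate_set(k_H = -1, k_L = 0.005, k_bind_L = 1e-4,
                        k_bind_H = 1e-3, k_esc_L = 0.1, k_esc_H = 1,
                        k_tr = 1, kd_rna = 0.5, kd_prot = 0.02,
                        n_rnap70 = 500),
               ">= 0")
  expect_error(rate_set(k_H = 0.001, k_L = 0.001, k_bind_L = 1e-4,
                        k_bind_H = 1e-3, k_esc_L = 0.1, k_esc_H = 1,
                        k_tr = 1, kd_rna = 0.5, kd_prot = 0.02,
                        n_rnap70 = 10.5),
               "integer")
  r <- reference_rates()
  # the regime the reference set must satisfy
  expect_equal(r$k_bind_H / r$k_bind_L, 10)
  expect_equal(r$k_esc_H / r$k_esc_L, 10)
  other <- unlist(r[c("k_bind_L", "k_bind_H", "k_esc_L", "k_esc_H",
                      "k_tr", "kd_rna", "kd_prot")])
  expect_true(all(c(r$k_H, r$k_L) < min(r$k_bind_L * r$n_rnap70, r$k_esc_L,
                                        r$k_tr, r$kd_rna, r$kd_prot)))
  expect_true(1 / r$kd_prot >= 10 && 1 / r$kd_prot <= 100)  # tens of minutes
})

test_that("apply_scenario modifies only the named fields and not its input", {
  r <- reference_rates()
  rif <- builtin_scenarios()$rifampicin
  out <- apply_scenario(r, rif)
  expect_equal(out$k_esc_L, r$k_esc_L * 0.1)
  expect_equal(out$k_esc_H, r$k_esc_H * 0.1)
  same <- setdiff(names(r), c("k_esc_L", "k_esc_H"))
  expect_identical(out[same], r[same])
  expect_identical(r, reference_rates())  # input untouched

  strep <- builtin_scenarios()$streptomycin
  out2 <- apply_scenario(r, strep)
  expect_equal(out2$k_tr, r$k_tr * 0.1)
  expect_identical(out2[setdiff(names(r), "k_tr")], r[setdiff(names(r), "k_tr")])

  ident <- perturbation_scenario("identity",
                                 setNames(rep(1, 9),
                                          c("k_H", "k_L", "k_bind_L",
                                            "k_bind_H", "k_esc_L", "k_esc_H",
                                            "k_tr", "kd_rna", "kd_prot")))
  expect_equal(apply_scenario(r, ident), r)
  expect_error(perturbation_scenario("bad", c(nope = 2)), "unknown")
  expect_error(perturbation_scenario("bad", c(k_tr = 0)), "> 0")
})

test_that("scenario factors compose multiplicatively", {
  r <- reference_rates()
  for (f in c("k_tr", "k_esc_H", "kd_rna")) {
    for (ab in list(c(2, 3), c(0.5, 0.2), c(10, 0.1))) {
      s1 <- perturbation_scenario("a", setNames(ab[1], f))
      s2 <- perturbation_scenario("b", setNames(ab[2], f))
      s12 <- perturbation_scenario("ab", setNames(prod(ab), f))
      expect_equal(apply_scenario(apply_scenario(r, s1), s2),
                   apply_scenario(r, s12))
    }
  }
})

test_that("interpolate_condition is geometric in rates, exact at endpoints, monotone", {
  a <- reference_rates()
  b <- stationary_phase_rates(a)
  expect_equal(interpolate_condition(a, b, 0), a)
  expect_equal(interpolate_condition(a, b, 1), b)
  # geometric midpoint of a 100-fold spread
  a2 <- a; a2$k_tr <- 0.1
  b2 <- a; b2$k_tr <- 10
  expect_equal(interpolate_condition(a2, b2, 0.5)$k_tr, 1.0)
  # per-field monotonicity along the path
  fs <- seq(0, 1, by = 0.2)
  for (fn in c("k_tr", "kd_rna", "kd_prot")) {
    path <- vapply(fs, function(f) interpolate_condition(a, b, f)[[fn]],
                   numeric(1))
    expect_true(all(diff(path) < 0 | diff(path) > 0) ||
                  all(abs(diff(path)) < 1e-12))
    if (a[[fn]] < b[[fn]]) expect_true(all(diff(path) > 0))
    if (a[[fn]] > b[[fn]]) expect_true(all(diff(path) < 0))
  }
  # holoenzyme counts move linearly (rounded) and stay integers
  mid <- interpolate_condition(a, b, 0.5)
  expect_equal(mid$n_rnap38, round((a$n_rnap38 + b$n_rnap38) / 2))
  expect_error(interpolate_condition(a, b, 1.2), "\\[0,1\\]")
})

test_that("stationary-phase rates encode the documented physiological changes", {
  r <- reference_rates()
  s <- stationary_phase_rates(r)
  expect_equal(s$kd_rna, 1 / 7.8)
  expect_equal(s$k_tr, r$k_tr / 40)
  expect_lt(s$kd_prot, r$kd_prot)   # dilution loss dominates
  expect_gt(s$n_rnap38, r$n_rnap38) # sigma38 pool grows
  expect_equal(s$n_rnap70 + s$n_rnap38, r$n_rnap70 + r$n_rnap38)
  # the stationary(f) scenario routes through the interpolation
  st <- builtin_scenarios(f = 0.5)$stationary
  expect_equal(apply_scenario(r, st),
               interpolate_condition(r, stationary_phase_rates(r), 0.5))
})

test_that("effective two-step rate is the harmonic composition", {
  expect_equal(effective_rate(1, 1, 1), 0.5)
  expect_equal(effective_rate(1e-3, 500, 1), 1 / (1 / 0.5 + 1 / 1))
  expect_equal(effective_rate(0, 500, 1), 0)   # silent promoter is legal
  expect_error(effective_rate(0, 0, 0), "zero")
})
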