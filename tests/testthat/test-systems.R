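test_that("reduced model has the expected species and reactions", {
  sys <- build_reduced_model(reference_rates())
  expect_setequal(sys$species,
                  c("Pr_L_free", "Pr_L_occ", "Pr_H_free", "Pr_H_occ",
                    "RNA", "Protein"))
  expect_length(sys$rates, 9)
  sys2 <- build_reduced_model(reference_rates(), switch_occupied = TRUE)
  expect_length(sys2$rates, 11)
  # binding propensities carry the holoenzyme copy number
  r <- reference_rates()
  expect_equal(sys$rates[sys$reaction_names == "bind_H"],
               r$k_bind_H * r$n_rnap70)
  # sigma38-preference promoter sees the sigma38 pool (here empty -> silent)
  sys38 <- build_reduced_model(r, sigma_preference = "s38")
  expect_equal(sys38$rates[sys38$reaction_names == "bind_H"], 0)
})

test_that("k_tr = 0 never produces protein", {
  r <- quick_rates(); r$k_tr <- 0
  sys <- build_reduced_model(r)
  tr <- simulate_ssa(sys, t_end = 200, seed = 3)
  expect_true(all(tr$states[, "Protein"] == 0))
  # and an initial protein stock decays monotonically to zero
  init <- default_init(sys); init["Protein"] <- 5
  tr2 <- simulate_ssa(sys, init = init, t_end = 500, seed = 4)
  p <- tr2$states[, "Protein"]
  expect_true(all(diff(p) <= 0))
  expect_equal(p[length(p)], 0)
})

test_that("locked two-state model equals the single-state variant", {
  r <- quick_rates(); r$k_H <- 0; r$k_L <- 0
  locked <- build_reduced_model(r)
  low <- build_unimodal_variant(r, "low")
  # the locked model's reachable (L) reactions match the variant reaction
  # list up to labels: same rates on binding/escape/translation/decays
  lr <- setNames(locked$rates, locked$reaction_names)
  vr <- setNames(low$rates, low$reaction_names)
  expect_equal(unname(lr[c("bind_L", "escape_L", "translate",
                           "rna_decay", "protein_decay")]),
               unname(vr[c("bind", "escape", "translate",
                           "rna_decay", "protein_decay")]))
})

test_that("unimodal variants reproduce the prescribed effective rates", {
  r <- reference_rates()
  n <- r$n_rnap70
  r_L <- effective_rate(r$k_bind_L, n, r$k_esc_L)
  r_H <- effective_rate(r$k_bind_H, n, r$k_esc_H)
  for (v in c("low", "average", "high")) {
    sys <- build_unimodal_variant(r, v)
    kb <- sys$rates[sys$reaction_names == "bind"]
    ke <- sys$rates[sys$reaction_names == "escape"]
    eff <- 1 / (1 / kb + 1 / ke)
    target <- switch(v, low = r_L, average = (r_L + r_H) / 2, high = r_H)
    expect_equal(eff, target, tolerance = 1e-12)
  }
  expect_error(build_unimodal_variant(r, "middling"))
})

test_that("promoter indicator conservation holds along trajectories", {
  for (seed in 1:5) {
    sys <- build_reduced_model(quick_rates(),
                               switch_occupied = seed %% 2 == 0)
    tr <- simulate_ssa(sys, t_end = 300, seed = seed)
    prom <- tr$states[, c("Pr_L_free", "Pr_L_occ", "Pr_H_free", "Pr_H_occ")]
    expect_true(all(rowSums(prom) == 1))
    expect_true(all(tr$states >= 0))
  }
})

test_that("feedback model switches configurations only through protein", {
  # no activation: basal-only low expression
  p0 <- feedback_params(k_act = 0)
  sys0 <- build_feedback_model(p0)
  tr <- simulate_ssa(sys0, t_end = 1000, seed = 5)
  expect_true(all(tr$states[, "Pr_act_free"] == 0))
  expect_true(all(tr$states[, "Pr_act_occ"] == 0))
  # no deactivation with protein present: active configuration absorbs
  p1 <- feedback_params(k_deact = 0)
  sys1 <- build_feedback_model(p1)
  init <- default_init(sys1); init["Protein"] <- 20
  tr1 <- simulate_ssa(sys1, init = init, t_end = 2000, seed = 6)
  basal <- tr1$states[, "Pr_basal_free"] + tr1$states[, "Pr_basal_occ"]
  i_act <- which(basal == 0)[1]
  expect_false(is.na(i_act))
  expect_true(all(basal[i_act:length(basal)] == 0))
})
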