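# shared fixtures: all synthetic, generated in code

# fast-relaxing small system for cheap SSA/CME checks (protein lifetime 10 min)
quick_rates <- function() {
  rate_set(k_H = 0.002, k_L = 0.002,
           k_bind_L = 1e-4, k_bind_H = 1e-3,
           k_esc_L = 0.1, k_esc_H = 1,
           k_tr = 1, kd_rna = 0.5, kd_prot = 0.1,
           n_rnap70 = 500, n_rnap38 = 0)
}

# pure birth process 0 -> X at a constant rate (Poisson event count oracle)
birth_system <- function(rate = 1) {
  reaction_system("X",
                  list(list(name = "birth", rate = rate, reactants = character(),
                            changes = c(X = 1))),
                  label = "pure_birth")
}

# well-separated two-component log-normal sample (intensity scale)
bimodal_intensity <- function(n = 10000, seed = 1, w = 0.5,
                              mu = c(2, 3), sd = c(0.1, 0.1)) {
  set.seed(seed)
  k <- stats::rbinom(n, 1, 1 - w) + 1
  10^stats::rnorm(n, mu[k], sd[k])
}

# manual hysteresis path for arithmetic tests
manual_path <- function(d, o, labels = paste0("c", seq_along(d)),
                        direction = "forward") {
  out <- data.frame(condition = labels, phase = seq_along(d),
                    verdict = ifelse(is.na(d), "unimodal", "bimodal"),
                    d = d, o = o)
  attr(out, "direction") <- direction
  class(out) <- c("hysteresis_path", "data.frame")
  out
}
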