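#' Rate constants of the reduced two-state expression model
#'
#' A `rate_set` collects every rate constant and holoenzyme copy number of the
#' reduced stochastic model of bimodal gene expression: a promoter that
#' switches between a low- (L) and a high-activity (H) transcription state,
#' with transcription initiation in each state modelled as two rate-limiting
#' steps (RNAP-holoenzyme binding, then promoter escape), followed by
#' state-independent translation and first-order RNA/protein decay
#' (degradation plus dilution).  All rates are per minute; binding rates are
#' second order (per molecule per minute) and are multiplied by the available
#' holoenzyme copy number when propensities are formed.
#'
#' @param k_H rate of L to H promoter-state switching (1/min).
#' @param k_L rate of H to L promoter-state switching (1/min).
#' @param k_bind_L,k_bind_H RNAP-holoenzyme binding rate constants in each
#'   promoter state (1/(molecule x min)).
#' @param k_esc_L,k_esc_H promoter escape rates in each state (1/min).
#' @param k_tr translation rate per RNA (1/min).
#' @param kd_rna RNA decay rate, degradation plus dilution (1/min).
#' @param kd_prot protein decay rate, degradation plus dilution (1/min).
#' @param n_rnap70,n_rnap38 available RNAP.sigma70 and RNAP.sigma38
#'   holoenzyme copy numbers (non-negative integers).
#' @return An object of class `rate_set` (a named list of the fields above).
#' @examples
#' r <- reference_rates()
#' r$k_esc_H / r$k_esc_L  # H-state escape is one order of magnitude faster
#' @export
rate_set <- function(k_H, k_L, k_bind_L, k_bind_H, k_esc_L, k_esc_H,
                     k_tr, kd_rna, kd_prot, n_rnap70, n_rnap38 = 0) {
  x <- list(k_H = k_H, k_L = k_L,
            k_bind_L = k_bind_L, k_bind_H = k_bind_H,
            k_esc_L = k_esc_L, k_esc_H = k_esc_H,
            k_tr = k_tr, kd_rna = kd_rna, kd_prot = kd_prot,
            n_rnap70 = n_rnap70, n_rnap38 = n_rnap38)
  validate_rate_set(x)
  structure(x, class = "rate_set")
}

rate_fields <- c("k_H", "k_L", "k_bind_L", "k_bind_H", "k_esc_L", "k_esc_H",
                 "k_tr", "kd_rna", "kd_prot")
count_fields <- c("n_rnap70", "n_rnap38")

validate_rate_set <- function(x) {
  for (f in c(rate_fields, count_fields)) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("rate_set field '", f, "' must be a single number", call. = FALSE)
    if (v < 0) stop("rate_set field '", f, "' must be >= 0", call. = FALSE)
  }
  for (f in count_fields)
    if (abs(x[[f]] - round(x[[f]])) > 1e-8)
      stop("holoenzyme count '", f, "' must be an integer", call. = FALSE)
  invisible(x)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Rate set (1/min; binding per molecule/min; counts in molecules)\n")
  v <- unlist(x[c(rate_fields, count_fields)])
  print(signif(v, 4))
  invisible(x)
}

#' Reference rate set for the reduced model
#'
#' The documented default parameterisation used throughout this package for
#' the exponential-phase "reference" condition.  It satisfies the orderings
#' that define the regime of interest: the L-state binding and escape rates
#' are one order of magnitude below the H-state ones, the switching rates
#' `k_H`, `k_L` are smaller than every other rate, and the protein decay
#' timescale is of the order of tens of minutes.  Under these values the
#' stationary single-cell protein distribution is bimodal with the taller
#' peak in the first (low-expression) mode; locked-state mean proteins are
#' about 3.3 (L) and 33 (H) copies.
#'
#' @return A `rate_set`.
#' @export
reference_rates <- function() {
  rate_set(k_H = 0.001, k_L = 0.001,
           k_bind_L = 1e-4, k_bind_H = 1e-3,
           k_esc_L = 0.1, k_esc_H = 1,
           k_tr = 1, kd_rna = 0.5, kd_prot = 0.02,
           n_rnap70 = 500, n_rnap38 = 0)
}

#' Stationary growth-phase rate set derived from the reference
#'
#' Builds the stationary-phase target condition from the exponential-phase
#' reference by applying the documented physiological changes: the mean RNA
#' lifetime becomes `rna_lifetime` minutes (so `kd_rna = 1/rna_lifetime`);
#' protein dilution (assumed `log(2)/doubling_time` of the reference
#' `kd_prot`) is reduced by `dilution_drop` while the degradation remainder
#' increases by `deg_increase`; translation is reduced by
#' `translation_factor`; and the holoenzyme pool shifts from RNAP.sigma70
#' toward RNAP.sigma38 with `sigma38_fraction` of the total ending up as
#' sigma38 holoenzyme.
#'
#' @param ref reference `rate_set` (exponential phase).
#' @param sigma38_fraction fraction of the holoenzyme pool recruited by
#'   sigma38 in stationary phase.
#' @param rna_lifetime stationary-phase mean RNA lifetime (min).
#' @param dilution_drop fractional reduction of the dilution component of
#'   protein decay (cells stop dividing).
#' @param deg_increase fractional increase of the degradation component.
#' @param translation_factor multiplicative change of `k_tr`.
#' @param doubling_time exponential-phase doubling time (min), used to split
#'   the reference `kd_prot` into dilution and degradation.
#' @return A `rate_set`.
#' @export
stationary_phase_rates <- function(ref = reference_rates(),
                                   sigma38_fraction = 0.5,
                                   rna_lifetime = 7.8,
                                   dilution_drop = 0.915,
                                   deg_increase = 0.08,
                                   translation_factor = 1 / 40,
                                   doubling_time = 40) {
  stopifnot(inherits(ref, "rate_set"))
  dilution <- log(2) / doubling_time
  if (dilution > ref$kd_prot) dilution <- ref$kd_prot
  degradation <- ref$kd_prot - dilution
  kd_prot <- dilution * (1 - dilution_drop) + degradation * (1 + deg_increase)
  n_total <- ref$n_rnap70 + ref$n_rnap38
  out <- ref
  out$kd_rna <- 1 / rna_lifetime
  out$kd_prot <- kd_prot
  out$k_tr <- ref$k_tr * translation_factor
  out$n_rnap38 <- round(n_total * sigma38_fraction)
  out$n_rnap70 <- n_total - out$n_rnap38
  validate_rate_set(out)
  out
}

#' Perturbation scenarios acting on a rate set
#'
#' A `perturbation_scenario` is a named set of multiplicative factors applied
#' to `rate_set` fields, optionally with replacement holoenzyme counts.
#' `apply_scenario()` returns a modified copy; the input is never changed.
#' `builtin_scenarios()` returns the named scenarios used to emulate the
#' stresses studied with the reduced model: rifampicin (promoter escape
#' reduced in both states), novobiocin acting on the state-switching rates,
#' streptomycin (translation reduced), and the stationary growth-phase
#' transition at a given progress fraction.
#'
#' @param name scenario label.
#' @param factors named numeric vector of positive multiplicative factors;
#'   names must be rate fields of `rate_set`.
#' @param counts optional named vector replacing `n_rnap70`/`n_rnap38`.
#' @return `perturbation_scenario()` an object of class
#'   `perturbation_scenario`; `apply_scenario()` a new `rate_set`.
#' @examples
#' rif <- perturbation_scenario("rifampicin", c(k_esc_L = 0.1, k_esc_H = 0.1))
#' apply_scenario(reference_rates(), rif)
#' @export
perturbation_scenario <- function(name, factors = numeric(), counts = NULL) {
  factors <- unlist(factors)
  if (length(factors)) {
    if (is.null(names(factors)) || any(!nzchar(names(factors))))
      stop("scenario factors must be named", call. = FALSE)
    bad <- setdiff(names(factors), rate_fields)
    if (length(bad))
      stop("unknown rate_set field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(factors <= 0)) stop("scenario factors must be > 0", call. = FALSE)
  }
  if (!is.null(counts)) {
    bad <- setdiff(names(counts), count_fields)
    if (length(bad))
      stop("unknown count field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  }
  structure(list(name = name, factors = factors, counts = counts),
            class = "perturbation_scenario")
}

#' @rdname perturbation_scenario
#' @param rates a `rate_set`.
#' @param scenario a `perturbation_scenario`.
#' @export
apply_scenario <- function(rates, scenario) {
  stopifnot(inherits(rates, "rate_set"),
            inherits(scenario, "perturbation_scenario"))
  if (inherits(scenario, "stationary_scenario"))
    return(interpolate_condition(rates, stationary_phase_rates(rates),
                                 scenario$f))
  out <- rates
  for (f in names(scenario$factors)) out[[f]] <- out[[f]] * scenario$factors[[f]]
  for (f in names(scenario$counts)) out[[f]] <- scenario$counts[[f]]
  validate_rate_set(out)
  out
}

#' @rdname perturbation_scenario
#' @param f for the `stationary` scenario, the transition progress in [0,1].
#' @export
builtin_scenarios <- function(f = 1) {
  list(
    rifampicin = perturbation_scenario("rifampicin",
                                       c(k_esc_L = 0.1, k_esc_H = 0.1)),
    novobiocin_L = perturbation_scenario("novobiocin_L", c(k_L = 10)),
    novobiocin_H = perturbation_scenario("novobiocin_H", c(k_H = 0.1)),
    streptomycin = perturbation_scenario("streptomycin", c(k_tr = 0.1)),
    stationary = structure(list(name = sprintf("stationary(f=%g)", f), f = f),
                           class = c("stationary_scenario",
                                     "perturbation_scenario"))
  )
}

#' Interpolate between two growth conditions
#'
#' Produces the rate set at fractional progress `f` along the transition from
#' an exponential-phase condition (`f = 0`) to a stationary-phase condition
#' (`f = 1`).  Rates are interpolated geometrically,
#' `rate(f) = rate_exp^(1-f) * rate_stat^f`, because they change
#' multiplicatively over orders of magnitude and must stay positive;
#' holoenzyme counts are interpolated linearly and rounded to the nearest
#' integer.  A rate that is zero at either endpoint is interpolated linearly
#' instead (the geometric path is degenerate there).
#'
#' @param rates_exp,rates_stat endpoint `rate_set`s.
#' @param f fraction in [0,1].
#' @return A `rate_set`.
#' @export
interpolate_condition <- function(rates_exp, rates_stat, f) {
  stopifnot(inherits(rates_exp, "rate_set"), inherits(rates_stat, "rate_set"))
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("f must be a single number in [0,1]", call. = FALSE)
  out <- rates_exp
  for (fn in rate_fields) {
    a <- rates_exp[[fn]]; b <- rates_stat[[fn]]
    out[[fn]] <- if (a > 0 && b > 0) a^(1 - f) * b^f else (1 - f) * a + f * b
  }
  for (fn in count_fields)
    out[[fn]] <- round((1 - f) * rates_exp[[fn]] + f * rates_stat[[fn]])
  validate_rate_set(out)
  out
}

#' Effective one-step transcription rate of a two-step initiation cycle
#'
#' For a promoter locked in state X, initiation is a cycle of holoenzyme
#' binding (pseudo-first-order rate `k_bind * n_holo`) followed by promoter
#' escape (`k_esc`); the promoter is unavailable for new binding while
#' occupied.  The long-run RNA production rate is the inverse of the mean
#' cycle time: `r_X = 1 / (1/(k_bind*n_holo) + 1/k_esc)`.
#'
#' @param k_bind second-order binding rate constant.
#' @param n_holo available holoenzyme copy number.
#' @param k_esc escape rate.
#' @return Effective transcription rate (1/min).
#' @export
effective_rate <- function(k_bind, n_holo, k_esc) {
  kb <- k_bind * n_holo
  if (kb <= 0 && k_esc <= 0)
    stop("both initiation steps have rate zero", call. = FALSE)
  if (kb <= 0 || k_esc <= 0) return(0)
  1 / (1 / kb + 1 / k_esc)
}

# holoenzyme count seen by the promoter given its sigma-factor preference
holo_count <- function(rates, sigma_preference = c("s70", "s38")) {
  sigma_preference <- match.arg(sigma_preference)
  if (sigma_preference == "s70") rates$n_rnap70 else rates$n_rnap38
}
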