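#' Closed-form stationary moments of the locked-state model
#'
#' With the promoter locked in state X, transcription is a two-step cycle
#' with effective rate `r_X = 1/(1/(k_bind_X * n_holo) + 1/k_esc_X)` and the
#' RNA/protein counts form a linear birth-death cascade, so the stationary
#' means are exact: `mean RNA = r_X / kd_rna` and
#' `mean Protein = r_X * k_tr / (kd_rna * kd_prot)`.  With
#' `locked_state = "none"` the switching-weighted mean is returned, with
#' promoter-state weights `pi_H = k_H / (k_H + k_L)`; this is exact in the
#' slow-switching regime when the free-promoter fraction is equal in the two
#' states (as it is whenever the L rates are a common multiple of the H
#' rates) and is reported as the mean only.
#'
#' @param rates a `rate_set`.
#' @param locked_state `"L"`, `"H"`, or `"none"`.
#' @inheritParams build_reduced_model
#' @return List with `r_eff`, `mean_rna`, `mean_protein` (and `pi_H` when
#'   `locked_state = "none"`).
#' @examples
#' stationary_moments_closed_form(reference_rates(), "H")$mean_protein
#' @export
stationary_moments_closed_form <- function(rates,
                                           locked_state = c("L", "H", "none"),
                                           sigma_preference = c("s70", "s38")) {
  stopifnot(inherits(rates, "rate_set"))
  locked_state <- match.arg(locked_state)
  n_holo <- holo_count(rates, match.arg(sigma_preference))
  r_L <- effective_rate(rates$k_bind_L, n_holo, rates$k_esc_L)
  r_H <- effective_rate(rates$k_bind_H, n_holo, rates$k_esc_H)
  if (rates$kd_rna <= 0 || rates$kd_prot <= 0)
    stop("decay rates must be > 0 for stationary moments", call. = FALSE)
  if (locked_state == "none") {
    if (rates$k_H + rates$k_L <= 0)
      stop("k_H + k_L must be > 0 when locked_state = 'none'", call. = FALSE)
    pi_H <- rates$k_H / (rates$k_H + rates$k_L)
    r <- pi_H * r_H + (1 - pi_H) * r_L
    return(list(r_eff = r, pi_H = pi_H,
                mean_rna = r / rates$kd_rna,
                mean_protein = r * rates$k_tr / (rates$kd_rna * rates$kd_prot)))
  }
  r <- if (locked_state == "L") r_L else r_H
  list(r_eff = r,
       mean_rna = r / rates$kd_rna,
       mean_protein = r * rates$k_tr / (rates$kd_rna * rates$kd_prot))
}

#' Empirical moments of a snapshot
#'
#' @param x a `snapshot_distribution` or numeric vector.
#' @return List with `mean`, `var`, and `cv2` (variance/mean^2; `NA` when the
#'   mean is 0).
#' @export
snapshot_moments <- function(x) {
  v <- values_of(x)
  m <- mean(v)
  list(mean = m, var = stats::var(v),
       cv2 = if (m > 0) stats::var(v) / m^2 else NA_real_)
}

#' Stationary solution of the truncated chemical master equation
#'
#' Brute-force oracle for snapshot distributions: enumerates all states with
#' one active promoter configuration, RNA in `0..max_rna` and protein in
#' `0..max_protein`, builds the sparse generator of the Markov jump process,
#' and solves the stationary linear system (one balance equation replaced by
#' the normalisation constraint).  Transitions that would leave the truncated
#' box are dropped; the probability mass on the truncation boundary is
#' reported and the box is expanded by 1.5x per dimension until it falls
#' below `boundary_tol` (a warning is raised if the expansion budget is
#' exhausted first).
#'
#' @param system a `reaction_system` whose species are promoter indicators
#'   plus `RNA` and `Protein`.
#' @param max_rna,max_protein initial truncation bounds; by default derived
#'   from closed-form moments (mean + 10 SD, with a burst-size inflation for
#'   the protein).
#' @param boundary_tol target boundary mass.
#' @param max_expand maximum number of 1.5x expansions.
#' @return An object of class `cme_result`: list with `protein_marginal` and
#'   `rna_marginal` (named probability vectors over `0:max`), `mean_protein`,
#'   `mean_rna`, `boundary_mass`, and the bounds used.
#' @export
cme_stationary <- function(system, max_rna = NULL, max_protein = NULL,
                           boundary_tol = 1e-6, max_expand = 8) {
  stopifnot(inherits(system, "reaction_system"))
  if (is.null(max_rna) || is.null(max_protein)) {
    g <- cme_default_bounds(system)
    if (is.null(max_rna)) max_rna <- g$max_rna
    if (is.null(max_protein)) max_protein <- g$max_protein
  }
  for (k in 0:max_expand) {
    res <- cme_solve(system, max_rna, max_protein)
    if (res$boundary_mass < boundary_tol) return(res)
    max_rna <- ceiling(max_rna * 1.5)
    max_protein <- ceiling(max_protein * 1.5)
  }
  warning(sprintf("CME truncation boundary mass %.2e exceeds tol %.2e",
                  res$boundary_mass, boundary_tol))
  res
}

cme_default_bounds <- function(system) {
  r <- attr(system, "rates")
  p <- attr(system, "params")
  if (!is.null(r)) {
    mh <- stationary_moments_closed_form(r, "H")
    ml <- stationary_moments_closed_form(r, "L")
    b <- if (r$kd_rna > 0) r$k_tr / r$kd_rna else 1
    mr <- max(mh$mean_rna, ml$mean_rna, 0.5)
    mp <- max(mh$mean_protein, ml$mean_protein, 0.5)
  } else if (!is.null(p)) {
    r_act <- effective_rate(p$k_bind_act, 1, p$k_esc_act)
    b <- if (p$kd_rna > 0) p$k_tr / p$kd_rna else 1
    mr <- max(r_act / p$kd_rna, 0.5)
    mp <- max(r_act * p$k_tr / (p$kd_rna * p$kd_prot), 0.5)
  } else stop("give max_rna and max_protein explicitly for this system",
              call. = FALSE)
  list(max_rna = ceiling(mr + 10 * sqrt(mr)),
       max_protein = ceiling(mp + 10 * sqrt(mp * (1 + b))))
}

cme_solve <- function(system, max_rna, max_protein) {
  prom <- attr(system, "promoter_species")
  if (is.null(prom)) stop("system has no promoter species", call. = FALSE)
  sp <- system$species
  if (!all(c("RNA", "Protein") %in% sp))
    stop("system must contain RNA and Protein species", call. = FALSE)
  P <- length(prom)
  R1 <- max_rna + 1L
  Pm1 <- max_protein + 1L
  n <- P * R1 * Pm1
  c_vec <- rep(seq_len(P), times = R1 * Pm1)
  r_vec <- rep(rep(0:max_rna, each = P), times = Pm1)
  p_vec <- rep(0:max_protein, each = P * R1)
  idx_of <- function(cc, rr, pp) cc + P * (rr + R1 * pp)

  count_of <- function(sname) {
    if (sname == "RNA") return(r_vec)
    if (sname == "Protein") return(p_vec)
    k <- match(sname, prom)
    if (is.na(k)) stop("unexpected species ", sname, call. = FALSE)
    as.numeric(c_vec == k)
  }

  ii <- list(); jj <- list(); xx <- list()
  m <- 0L
  for (j in seq_along(system$rates)) {
    prop <- rep(system$rates[j], n)
    for (ri in system$reactants[[j]]) prop <- prop * count_of(sp[ri])
    d <- system$stoich[j, ]
    dprom <- d[prom]
    new_c <- if (any(dprom > 0)) rep(which(dprom > 0)[1], n) else c_vec
    new_r <- r_vec + d[["RNA"]]
    new_p <- p_vec + d[["Protein"]]
    ok <- prop > 0 & new_r >= 0 & new_r <= max_rna &
      new_p >= 0 & new_p <= max_protein
    if (!any(ok)) next
    m <- m + 1L
    ii[[m]] <- idx_of(new_c[ok], new_r[ok], new_p[ok])
    jj[[m]] <- which(ok)
    xx[[m]] <- prop[ok]
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  # generator: Q[to, from] = rate; Q[from, from] = -outflow
  out_flow <- vapply(split(xx, jj), sum, numeric(1))
  jd <- as.integer(names(out_flow))
  Q <- Matrix::sparseMatrix(i = c(ii, jd), j = c(jj, jd),
                            x = c(xx, -out_flow), dims = c(n, n))
  # stationary: Q pi = 0 with sum(pi) = 1 (replace last balance equation)
  Q[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- as.numeric(Matrix::solve(Q, b))
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)

  boundary <- sum(pi[r_vec == max_rna | p_vec == max_protein])
  pm <- as.numeric(rowsum(pi, p_vec))
  rm_ <- as.numeric(rowsum(pi, r_vec))
  structure(list(protein_marginal = setNames(pm, 0:max_protein),
                 rna_marginal = setNames(rm_, 0:max_rna),
                 promoter_marginal = setNames(as.numeric(rowsum(pi, c_vec)),
                                              prom),
                 mean_protein = sum(pm * (0:max_protein)),
                 mean_rna = sum(rm_ * (0:max_rna)),
                 boundary_mass = boundary,
                 max_rna = max_rna, max_protein = max_protein,
                 label = system$label),
            class = "cme_result")
}

#' @export
print.cme_result <- function(x, ...) {
  cat("CME stationary solution '", x$label, "' (RNA <= ", x$max_rna,
      ", Protein <= ", x$max_protein, ")\n", sep = "")
  cat(sprintf("  mean RNA %.4g, mean Protein %.4g, boundary mass %.2e\n",
              x$mean_rna, x$mean_protein, x$boundary_mass))
  invisible(x)
}

#' Total variation distance between a snapshot and a CME marginal
#'
#' Compares the empirical probability mass function of integer-valued
#' snapshot values with the CME stationary protein marginal:
#' `TV = 0.5 * sum |p_emp - p_cme|`, with empirical mass beyond the
#' truncation bound counted in full.
#'
#' @param x a `snapshot_distribution` or integer vector of counts.
#' @param cme a `cme_result`.
#' @return Total variation distance in [0, 1].
#' @export
total_variation <- function(x, cme) {
  stopifnot(inherits(cme, "cme_result"))
  v <- values_of(x)
  q <- cme$protein_marginal
  kmax <- length(q) - 1L
  emp <- tabulate(pmin(v, kmax + 1L) + 1L, nbins = kmax + 2L) / length(v)
  0.5 * (sum(abs(emp[seq_len(kmax + 1L)] - q)) + emp[kmax + 2L])
}
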