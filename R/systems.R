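#' Mass-action reaction systems
#'
#' A `reaction_system` is a list of species and mass-action reactions.  Each
#' reaction has a rate constant (with any fixed concentration factors, such
#' as holoenzyme copy numbers, already folded in), a vector of reactant
#' species indices (with multiplicity) defining the propensity
#' `rate * prod(x[reactants])`, and an integer stoichiometry vector.
#'
#' @param species character vector of species names.
#' @param reactions list of reactions; each a list with `name`, `rate`,
#'   `reactants` (character vector of species names, possibly empty), and
#'   `changes` (named integer vector of copy-number changes).
#' @param label system label used in downstream records.
#' @return An object of class `reaction_system`.
#' @export
reaction_system <- function(species, reactions, label = "system") {
  stopifnot(is.character(species), length(species) > 0, !anyDuplicated(species))
  n_s <- length(species)
  rates <- numeric(length(reactions))
  reac_idx <- vector("list", length(reactions))
  stoich <- matrix(0L, nrow = length(reactions), ncol = n_s,
                   dimnames = list(NULL, species))
  nm <- character(length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    if (!is.numeric(r$rate) || length(r$rate) != 1L || is.na(r$rate) || r$rate < 0)
      stop("reaction rate must be a single non-negative number", call. = FALSE)
    rates[j] <- r$rate
    nm[j] <- if (is.null(r$name)) paste0("r", j) else r$name
    if (length(r$reactants)) {
      idx <- match(r$reactants, species)
      if (anyNA(idx)) stop("unknown reactant species in reaction ", nm[j],
                           call. = FALSE)
      reac_idx[[j]] <- as.integer(idx)
    } else reac_idx[[j]] <- integer(0)
    ch <- r$changes
    idx <- match(names(ch), species)
    if (anyNA(idx)) stop("unknown species in changes of reaction ", nm[j],
                         call. = FALSE)
    if (any(ch != round(ch))) stop("stoichiometries must be integers",
                                   call. = FALSE)
    stoich[j, idx] <- as.integer(ch)
  }
  structure(list(species = species, rates = rates, reactants = reac_idx,
                 stoich = stoich, reaction_names = nm, label = label),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("Reaction system '", x$label, "': ", length(x$species), " species, ",
      length(x$rates), " reactions\n", sep = "")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (j in seq_along(x$rates)) {
    lhs <- if (length(x$reactants[[j]]))
      paste(x$species[x$reactants[[j]]], collapse = " + ") else "0"
    d <- x$stoich[j, ]
    cat(sprintf("  %-22s rate %-10.4g  %s : %s\n", x$reaction_names[j],
                x$rates[j], lhs,
                paste(sprintf("%+d %s", d[d != 0], x$species[d != 0]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Build the reduced two-state stochastic expression model
#'
#' Constructs the reaction system for a promoter switching between a
#' low-activity (L) and a high-activity (H) transcription state.  In each
#' state, transcription initiation is a two-step cycle: a free promoter binds
#' an RNAP holoenzyme (propensity `k_bind_X * n_holo`; the holoenzyme pool is
#' treated as a fixed concentration parameter, not a consumed species) and
#' the occupied promoter then escapes, releasing one RNA.  While occupied the
#' promoter is unavailable for new binding, and state switching is only
#' possible from the free promoter.  RNAs are translated at `k_tr` per RNA
#' and RNA/protein decay first-order.
#'
#' Species are `Pr_L_free`, `Pr_L_occ`, `Pr_H_free`, `Pr_H_occ`, `RNA`,
#' `Protein`; exactly one promoter indicator is 1 in any reachable state.
#' The convention for the switching constants is that the subscript names the
#' destination state: `k_H` drives L_free -> H_free and `k_L` drives
#' H_free -> L_free.
#'
#' @param rates a `rate_set`.
#' @param sigma_preference which holoenzyme pool the promoter recognises
#'   (`"s70"` or `"s38"`); its copy number scales the binding propensities.
#' @param switch_occupied if `TRUE`, state switching is also allowed while
#'   the promoter is occupied (default `FALSE`: an engaged RNAP blocks the
#'   state change).
#' @return A `reaction_system` with 9 reactions (11 with
#'   `switch_occupied = TRUE`).
#' @examples
#' sys <- build_reduced_model(reference_rates())
#' sys
#' @export
build_reduced_model <- function(rates, sigma_preference = c("s70", "s38"),
                                switch_occupied = FALSE) {
  stopifnot(inherits(rates, "rate_set"))
  validate_rate_set(rates)
  n_holo <- holo_count(rates, match.arg(sigma_preference))
  species <- c("Pr_L_free", "Pr_L_occ", "Pr_H_free", "Pr_H_occ",
               "RNA", "Protein")
  rx <- list(
    list(name = "switch_L_to_H", rate = rates$k_H,
         reactants = "Pr_L_free",
         changes = c(Pr_L_free = -1, Pr_H_free = 1)),
    list(name = "switch_H_to_L", rate = rates$k_L,
         reactants = "Pr_H_free",
         changes = c(Pr_H_free = -1, Pr_L_free = 1)),
    list(name = "bind_L", rate = rates$k_bind_L * n_holo,
         reactants = "Pr_L_free",
         changes = c(Pr_L_free = -1, Pr_L_occ = 1)),
    list(name = "escape_L", rate = rates$k_esc_L,
         reactants = "Pr_L_occ",
         changes = c(Pr_L_occ = -1, Pr_L_free = 1, RNA = 1)),
    list(name = "bind_H", rate = rates$k_bind_H * n_holo,
         reactants = "Pr_H_free",
         changes = c(Pr_H_free = -1, Pr_H_occ = 1)),
    list(name = "escape_H", rate = rates$k_esc_H,
         reactants = "Pr_H_occ",
         changes = c(Pr_H_occ = -1, Pr_H_free = 1, RNA = 1)),
    list(name = "translate", rate = rates$k_tr,
         reactants = "RNA", changes = c(Protein = 1)),
    list(name = "rna_decay", rate = rates$kd_rna,
         reactants = "RNA", changes = c(RNA = -1)),
    list(name = "protein_decay", rate = rates$kd_prot,
         reactants = "Protein", changes = c(Protein = -1))
  )
  if (switch_occupied) {
    rx <- c(rx, list(
      list(name = "switch_L_to_H_occ", rate = rates$k_H,
           reactants = "Pr_L_occ",
           changes = c(Pr_L_occ = -1, Pr_H_occ = 1)),
      list(name = "switch_H_to_L_occ", rate = rates$k_L,
           reactants = "Pr_H_occ",
           changes = c(Pr_H_occ = -1, Pr_L_occ = 1))))
  }
  sys <- reaction_system(species, rx, label = "reduced_two_state")
  attr(sys, "rates") <- rates
  attr(sys, "promoter_species") <- species[1:4]
  sys
}

#' Single-state (unimodal) variants of the reduced model
#'
#' Collapses the two-state model into a one-state model whose effective
#' transcription rate equals (i) the L state's (`"low"`), (ii) the average of
#' the two states' (`"average"`), or (iii) the H state's (`"high"`) effective
#' two-step rate.  The two-step initiation structure (and hence its occupancy
#' noise) is retained: the `"low"` and `"high"` variants keep the
#' corresponding state's binding/escape rates, while the `"average"` variant
#' scales the H-state binding and escape rates by a common factor `c` chosen
#' so the effective rate `c * r_H` equals `(r_L + r_H)/2`.
#'
#' @param rates a `rate_set` (the parent two-state parameterisation).
#' @param variant `"low"`, `"average"` or `"high"`.
#' @inheritParams build_reduced_model
#' @return A `reaction_system` with species `Pr_free`, `Pr_occ`, `RNA`,
#'   `Protein`.
#' @export
build_unimodal_variant <- function(rates, variant = c("low", "average", "high"),
                                   sigma_preference = c("s70", "s38")) {
  stopifnot(inherits(rates, "rate_set"))
  variant <- match.arg(variant)
  n_holo <- holo_count(rates, match.arg(sigma_preference))
  r_L <- effective_rate(rates$k_bind_L, n_holo, rates$k_esc_L)
  r_H <- effective_rate(rates$k_bind_H, n_holo, rates$k_esc_H)
  if (variant == "low") {
    kb <- rates$k_bind_L * n_holo; ke <- rates$k_esc_L
  } else if (variant == "high") {
    kb <- rates$k_bind_H * n_holo; ke <- rates$k_esc_H
  } else {
    if (r_H <= 0) stop("average variant undefined: H-state rate is zero",
                       call. = FALSE)
    cc <- ((r_L + r_H) / 2) / r_H
    kb <- cc * rates$k_bind_H * n_holo; ke <- cc * rates$k_esc_H
  }
  species <- c("Pr_free", "Pr_occ", "RNA", "Protein")
  rx <- list(
    list(name = "bind", rate = kb, reactants = "Pr_free",
         changes = c(Pr_free = -1, Pr_occ = 1)),
    list(name = "escape", rate = ke, reactants = "Pr_occ",
         changes = c(Pr_occ = -1, Pr_free = 1, RNA = 1)),
    list(name = "translate", rate = rates$k_tr,
         reactants = "RNA", changes = c(Protein = 1)),
    list(name = "rna_decay", rate = rates$kd_rna,
         reactants = "RNA", changes = c(RNA = -1)),
    list(name = "protein_decay", rate = rates$kd_prot,
         reactants = "Protein", changes = c(Protein = -1))
  )
  sys <- reaction_system(species, rx,
                         label = paste0("unimodal_", variant))
  attr(sys, "rates") <- rates
  attr(sys, "promoter_species") <- species[1:2]
  attr(sys, "effective_rate") <- switch(variant, low = r_L, high = r_H,
                                        average = (r_L + r_H) / 2)
  sys
}

#' Parameters of the positive-feedback model
#'
#' In the positive-feedback variant the expressed protein itself activates
#' the promoter: a basal-configuration promoter switches to the active
#' configuration with propensity `k_act * Protein` (the protein acts
#' catalytically and is not sequestered), and the active configuration
#' reverts at `k_deact`.  Transcription in each configuration is the same
#' two-step scheme as the reduced model, with the basal configuration using
#' the low-state rates and the active configuration the high-state rates.
#' The defaults are anchored to [reference_rates()] and produce a bimodal
#' stationary protein distribution.
#'
#' @param k_act promoter activation rate per protein molecule
#'   (1/(molecule x min)).
#' @param k_deact deactivation (protein unbinding) rate (1/min).
#' @param k_bind_basal,k_esc_basal two-step rates of the basal configuration
#'   (binding already includes the holoenzyme factor; 1/min).
#' @param k_bind_act,k_esc_act two-step rates of the active configuration
#'   (1/min).
#' @param k_tr,kd_rna,kd_prot as in [rate_set()].
#' @return An object of class `feedback_params`.
#' @export
feedback_params <- function(k_act = 0.001, k_deact = 0.005,
                            k_bind_basal = 0.05, k_esc_basal = 0.1,
                            k_bind_act = 0.5, k_esc_act = 1,
                            k_tr = 1, kd_rna = 0.5, kd_prot = 0.02) {
  x <- list(k_act = k_act, k_deact = k_deact,
            k_bind_basal = k_bind_basal, k_esc_basal = k_esc_basal,
            k_bind_act = k_bind_act, k_esc_act = k_esc_act,
            k_tr = k_tr, kd_rna = kd_rna, kd_prot = kd_prot)
  for (f in names(x))
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || is.na(x[[f]]) || x[[f]] < 0)
      stop("feedback parameter '", f, "' must be a single non-negative number",
           call. = FALSE)
  structure(x, class = "feedback_params")
}

#' Build the positive-feedback-loop model
#'
#' @param params a `feedback_params` object.
#' @return A `reaction_system` with species `Pr_basal_free`, `Pr_basal_occ`,
#'   `Pr_act_free`, `Pr_act_occ`, `RNA`, `Protein`.
#' @seealso [feedback_params()]
#' @export
build_feedback_model <- function(params = feedback_params()) {
  stopifnot(inherits(params, "feedback_params"))
  species <- c("Pr_basal_free", "Pr_basal_occ", "Pr_act_free", "Pr_act_occ",
               "RNA", "Protein")
  rx <- list(
    list(name = "activate", rate = params$k_act,
         reactants = c("Pr_basal_free", "Protein"),
         changes = c(Pr_basal_free = -1, Pr_act_free = 1)),
    list(name = "deactivate", rate = params$k_deact,
         reactants = "Pr_act_free",
         changes = c(Pr_act_free = -1, Pr_basal_free = 1)),
    list(name = "bind_basal", rate = params$k_bind_basal,
         reactants = "Pr_basal_free",
         changes = c(Pr_basal_free = -1, Pr_basal_occ = 1)),
    list(name = "escape_basal", rate = params$k_esc_basal,
         reactants = "Pr_basal_occ",
         changes = c(Pr_basal_occ = -1, Pr_basal_free = 1, RNA = 1)),
    list(name = "bind_act", rate = params$k_bind_act,
         reactants = "Pr_act_free",
         changes = c(Pr_act_free = -1, Pr_act_occ = 1)),
    list(name = "escape_act", rate = params$k_esc_act,
         reactants = "Pr_act_occ",
         changes = c(Pr_act_occ = -1, Pr_act_free = 1, RNA = 1)),
    list(name = "translate", rate = params$k_tr,
         reactants = "RNA", changes = c(Protein = 1)),
    list(name = "rna_decay", rate = params$kd_rna,
         reactants = "RNA", changes = c(RNA = -1)),
    list(name = "protein_decay", rate = params$kd_prot,
         reactants = "Protein", changes = c(Protein = -1))
  )
  sys <- reaction_system(species, rx, label = "positive_feedback")
  attr(sys, "params") <- params
  attr(sys, "promoter_species") <- species[1:4]
  sys
}

#' Default initial state of a system
#'
#' Returns the standard initial state: the first promoter species set to 1
#' (L/basal free configuration), all other species 0.
#'
#' @param system a `reaction_system`.
#' @return Named numeric vector over the system's species.
#' @export
default_init <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  x <- setNames(numeric(length(system$species)), system$species)
  prom <- attr(system, "promoter_species")
  x[if (length(prom)) prom[1] else system$species[1]] <- 1
  x
}
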