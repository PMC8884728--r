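#' Sample a consumption-rate vector uniformly from the unit simplex
#'
#' Every strain has a fixed "enzyme budget": its resource consumption rates
#' are non-negative and sum to 1. Uniform sampling uses the standard
#' exponential-spacings construction.
#'
#' @param dim Number of resources (>= 2).
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return Numeric vector on the unit simplex.
#' @export
sample_simplex <- function(dim, seed = NULL) {
  if (dim < 2) stop("dim must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  e <- stats::rexp(dim)
  e / sum(e)
}

#' Place a conspecific consumption vector at Euclidean distance D
#'
#' Draws a random direction in the simplex's tangent space (components
#' summing to zero, unit Euclidean norm) and moves `D` along it, rejecting
#' directions that leave the simplex. Near-maximal distances admit very few
#' feasible directions, so when rejection sampling fails the step is taken
#' toward the farthest vertex of the simplex (the resource on which the
#' original vector spends least), which is the least constrained feasible
#' direction. Errors if even that is infeasible.
#'
#' @param c0 Consumption vector on the simplex.
#' @param D Required Euclidean distance (>= 0).
#' @param seed Optional integer seed.
#' @param max_retries Rejection-sampling attempts before the directed
#'   fallback.
#' @return A vector `c1` on the simplex with `||c0 - c1|| = D` (to 1e-9).
#' @export
conspecific_at_distance <- function(c0, D, seed = NULL, max_retries = 200) {
  if (!is.null(seed)) set.seed(seed)
  if (D < 0) stop("D must be >= 0")
  if (D == 0) return(c0)
  n <- length(c0)
  for (try in seq_len(max_retries)) {
    v <- stats::rnorm(n)
    v <- v - mean(v)            # project onto the tangent space (sum 0)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    c1 <- c0 + D * v / nv
    if (all(c1 >= 0)) return(c1)
  }
  # directed fallback: toward the vertex of the least-used resource
  k <- which.min(c0)
  ek <- rep(0, n)
  ek[k] <- 1
  v <- ek - c0
  nv <- sqrt(sum(v^2))
  if (nv >= D) {
    c1 <- c0 + D * v / nv
    c1[c1 < 0] <- 0  # numerical dust only
    return(c1 / sum(c1) * sum(c0))
  }
  stop("distance D = ", D, " infeasible from this simplex position; ",
       "use a smaller D")
}

#' Integrate one batch growth cycle of the consumer-resource model
#'
#' Solves `dN_a/dt = N_a * sum_i C_ai R_i` and
#' `dR_i/dt = -R_i * sum_a C_ai N_a` (unit biomass yield) until the total
#' remaining resource concentration drops below `epsilon` or `t_max` is
#' reached. Total biomass plus resources is conserved by construction and
#' checked to 1e-6 relative.
#'
#' @param N0,R0 Initial strain biomasses and resource concentrations.
#' @param C Consumption matrix, strains x resources.
#' @param epsilon Resource-depletion stopping threshold (default 1e-6).
#' @param t_max Integration horizon safeguard.
#' @return List with `N`, `R` at the end of the cycle and `t_end`.
#' @export
integrate_cycle <- function(N0, R0, C, epsilon = 1e-6, t_max = 1e4) {
  if (any(N0 < 0) || any(R0 < 0)) stop("state must be non-negative")
  nN <- length(N0)
  out <- deSolve::lsodar(c(N0, R0), times = c(0, t_max),
                         func = "crm_derivs", dllname = "straindyn",
                         initfunc = "crm_initmod", rootfunc = "crm_root",
                         nroot = 1L,
                         parms = c(nN, length(R0), epsilon, as.vector(C)),
                         rtol = 1e-6, atol = 1e-9)
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE integration failed; state: ",
         paste(signif(out[nrow(out), -1L], 4), collapse = ", "))
  }
  final <- out[nrow(out), -1L]
  N <- pmax(final[seq_len(nN)], 0)
  R <- pmax(final[-seq_len(nN)], 0)
  drift <- abs((sum(N) + sum(R)) - (sum(N0) + sum(R0))) /
    (sum(N0) + sum(R0))
  if (drift > 1e-6) {
    stop(sprintf("mass conservation violated (relative drift %.2e)", drift))
  }
  list(N = unname(N), R = unname(R), t_end = out[nrow(out), 1L])
}

#' Neutral drift specification for species-identical strains
#'
#' Per generation, the within-species frequency of a strain receives a
#' Gaussian increment with mean zero and variance `v * N` (`mode = "vN"`,
#' the default: fluctuations grow with the species' relative abundance
#' `N`) or `v / N` (`mode = "v_over_N"`, the population-genetic scaling
#' where drift is stronger in small populations). Frequencies are clipped
#' to \[0,1\].
#'
#' The default `v = 0.03` is calibrated so that, in the default scenario,
#' the simulated within-species frequency of a still-polymorphic strain
#' pair fluctuates by roughly 0.1 per metagenomic sampling interval — the
#' scale of the strain-frequency changes observed between successive
#' samples in serially passaged communities, which is how the coefficient
#' is meant to be fit.
#'
#' @param v Drift variance coefficient per generation (>= 0).
#' @param mode Variance scaling with species relative abundance.
#' @return A `drift_spec` list.
#' @export
drift_spec <- function(v = 0.03, mode = c("vN", "v_over_N")) {
  if (v < 0) stop("v must be >= 0")
  structure(list(v = v, mode = match.arg(mode)), class = "drift_spec")
}

#' Apply neutral drift to within-species strain frequencies
#'
#' The cumulative increment over `n_generations` is drawn in one Gaussian
#' step with variance `n_generations` times the per-generation variance
#' (the sum of independent Gaussian steps), then clipped to \[0,1\].
#'
#' @param freqs Strain frequencies in \[0,1\] (one per species).
#' @param species_abundance Relative abundance of each species (same
#'   length), the `N` in the variance scaling.
#' @param spec A [drift_spec()].
#' @param n_generations Generations elapsed (e.g. `log2(dilution)` per
#'   cycle).
#' @param seed Optional integer seed.
#' @return Drifted frequencies.
#' @export
apply_drift <- function(freqs, species_abundance, spec = drift_spec(),
                        n_generations = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$v == 0) return(freqs)
  var1 <- switch(spec$mode,
                 vN = spec$v * species_abundance,
                 v_over_N = spec$v / pmax(species_abundance, 1e-12))
  inc <- stats::rnorm(length(freqs), 0, sqrt(pmax(var1, 0) * n_generations))
  pmin(1, pmax(0, freqs + inc))
}

#' Consumer-resource scenario
#'
#' Defaults reproduce the standard in-silico experiment: 10 communities of
#' 50 species (two strains each, 100 strains) competing for 30 resources
#' supplied in equal mean proportions (total 1 biomass unit) with minor
#' Gaussian supply noise (dispersion 0.05 per resource proportion), serial
#' 1:100 dilution, and conspecific competitive distances `D` drawn as 15%
#' at 0.01, 20% at 0.1, 50% at 0.3 and 15% at 1.0. Under
#' `hypothesis = "species_identical"` all conspecific pairs have `D = 0`
#' and within-species frequencies change only by neutral drift.
#'
#' @param n_species,n_resources,n_communities Community dimensions.
#' @param dilution Serial dilution factor (> 1).
#' @param supply_noise_sd Standard deviation of the Gaussian noise on each
#'   supplied resource proportion (default 0.05). The mean proportion with
#'   30 resources is 1/30, so the default perturbs each proportion by a
#'   "minor" amount while occasionally zeroing a resource for a transfer.
#' @param supply_noise_mode How the noise perturbs the mean proportions:
#'   `"additive"` (default) adds the Gaussian deviate to each supplied
#'   proportion directly; `"relative"` applies it to the relative
#'   (multiplicative) deviation from the mean proportion. In both modes
#'   negatives are clipped to zero and the supply is renormalized to
#'   total 1 biomass unit.
#' @param hypothesis `"strain_specific"` or `"species_identical"`.
#' @param D_values,D_probs Discrete competitive-distance mixture.
#' @param drift A [drift_spec()] (used by the species-identical model).
#' @param max_cycles Burn-in cycles before recording (communities are
#'   passaged to (noisy) steady state; a warning is raised if the
#'   composition is still changing by more than `eq_tol` in L1 per cycle).
#' @param eq_tol,eq_consecutive Equilibrium rule: L1 change of end-of-cycle
#'   composition below `eq_tol` for `eq_consecutive` consecutive cycles.
#' @param n_recorded Post-equilibrium samples recorded (default 8).
#' @param record_every Spacing, in cycles, between recorded samples
#'   (default 5): the in-silico analogue of metagenomic sampling every
#'   5-6 transfers, as in an experiment with 8 samples across ~46
#'   transfers.
#' @param extinction Biomass threshold below which a strain is set to 0 at
#'   the end of a cycle.
#' @param seed Integer seed.
#' @return A `crm_scenario` list.
#' @export
crm_scenario <- function(n_species = 50, n_resources = 30,
                         n_communities = 10, dilution = 100,
                         supply_noise_sd = 0.05,
                         supply_noise_mode = c("additive", "relative"),
                         hypothesis = c("strain_specific",
                                        "species_identical"),
                         D_values = c(0.01, 0.1, 0.3, 1.0),
                         D_probs = c(0.15, 0.20, 0.50, 0.15),
                         drift = drift_spec(), max_cycles = 400,
                         eq_tol = 1e-3, eq_consecutive = 5,
                         n_recorded = 8, record_every = 5,
                         extinction = 1e-12, seed = 1) {
  hypothesis <- match.arg(hypothesis)
  supply_noise_mode <- match.arg(supply_noise_mode)
  if (dilution <= 1) stop("dilution must be > 1")
  if (any(D_values < 0)) stop("D must be >= 0")
  if (abs(sum(D_probs) - 1) > 1e-9) stop("D_probs must sum to 1")
  structure(list(n_species = n_species, n_resources = n_resources,
                 n_communities = n_communities, dilution = dilution,
                 supply_noise_sd = supply_noise_sd,
                 supply_noise_mode = supply_noise_mode,
                 hypothesis = hypothesis, D_values = D_values,
                 D_probs = D_probs, drift = drift, max_cycles = max_cycles,
                 eq_tol = eq_tol, eq_consecutive = eq_consecutive,
                 n_recorded = n_recorded, record_every = record_every,
                 extinction = extinction, seed = seed),
            class = "crm_scenario")
}

# build the strains x resources consumption matrix for one community
build_consumption <- function(scenario) {
  n_sp <- scenario$n_species
  C <- matrix(0, 2L * n_sp, scenario$n_resources)
  D_of <- numeric(n_sp)
  for (s in seq_len(n_sp)) {
    c1 <- sample_simplex(scenario$n_resources)
    if (scenario$hypothesis == "strain_specific") {
      D <- sample(scenario$D_values, 1L, prob = scenario$D_probs)
      c2 <- conspecific_at_distance(c1, D)
    } else {
      D <- 0
      c2 <- c1
    }
    D_of[s] <- D
    C[2L * s - 1L, ] <- c1
    C[2L * s, ] <- c2
  }
  list(C = C, D = D_of)
}

#' Simulate serial passage of consumer-resource communities
#'
#' Each cycle: the fresh medium supplies resources at the mean proportions
#' plus Gaussian noise (negatives clipped, renormalized to total 1), the
#' community biomass is diluted by the dilution factor, and the batch
#' dynamics are integrated to resource depletion. Communities are passaged
#' through `max_cycles` burn-in cycles (stopping early once the
#' end-of-cycle composition is stable under the equilibrium rule), then
#' `n_recorded` further cycles are recorded. Under the species-identical
#' hypothesis, conspecific frequencies additionally drift by
#' [apply_drift()] each cycle with `log2(dilution)` generations.
#'
#' @param scenario A [crm_scenario()].
#' @return A `crm_run`: list of per-community results, each with
#'   `abundance` (strains x recorded cycles, relative), `species_of`
#'   (species index per strain), `D` (per species), plus the scenario.
#' @export
serial_passage <- function(scenario = crm_scenario()) {
  set.seed(scenario$seed)
  n_sp <- scenario$n_species
  n_strains <- 2L * n_sp
  gens <- log2(scenario$dilution)
  supply_mean <- rep(1 / scenario$n_resources, scenario$n_resources)
  communities <- vector("list", scenario$n_communities)
  for (com in seq_len(scenario$n_communities)) {
    cm <- build_consumption(scenario)
    N <- rep(1 / n_strains, n_strains)
    rel_prev <- N / sum(N)
    stable <- 0L
    converged <- FALSE
    one_cycle <- function(N) {
      eps <- stats::rnorm(scenario$n_resources, 0, scenario$supply_noise_sd)
      supply <- if (scenario$supply_noise_mode == "additive") {
        supply_mean + eps
      } else {
        supply_mean * (1 + eps)
      }
      supply[supply < 0] <- 0
      supply <- supply / sum(supply)
      res <- integrate_cycle(N / scenario$dilution, supply, cm$C)
      N <- res$N
      N[N < scenario$extinction] <- 0
      if (scenario$hypothesis == "species_identical" &&
          scenario$drift$v > 0) {
        tot <- sum(N)
        for (s in seq_len(n_sp)) {
          i1 <- 2L * s - 1L
          i2 <- 2L * s
          pair <- N[i1] + N[i2]
          # drift acts only while both lineages persist: once a strain is
          # lost the within-species frequency is fixed (absorbing state)
          if (pair <= 0 || N[i1] <= 0 || N[i2] <= 0) next
          f <- apply_drift(N[i1] / pair, pair / tot, scenario$drift,
                           n_generations = gens)
          N[i1] <- pair * f
          N[i2] <- pair * (1 - f)
          N[N < scenario$extinction] <- 0
        }
      }
      N
    }
    for (cycle in seq_len(scenario$max_cycles)) {
      N <- one_cycle(N)
      rel <- N / sum(N)
      stable <- if (sum(abs(rel - rel_prev)) < scenario$eq_tol) {
        stable + 1L
      } else 0L
      rel_prev <- rel
      if (stable >= scenario$eq_consecutive) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning(sprintf(
        "community %d: composition still fluctuating after %d cycles; recording from the last state",
        com, scenario$max_cycles))
    }
    rec <- matrix(0, n_strains, scenario$n_recorded)
    for (t in seq_len(scenario$n_recorded)) {
      for (j in seq_len(scenario$record_every)) N <- one_cycle(N)
      rec[, t] <- N / sum(N)
    }
    rownames(rec) <- sprintf("sp%03d_s%d", rep(seq_len(n_sp), each = 2L),
                             rep(1:2, n_sp))
    communities[[com]] <- list(abundance = rec,
                               species_of = rep(seq_len(n_sp), each = 2L),
                               D = cm$D, converged = converged)
  }
  structure(list(communities = communities, scenario = scenario),
            class = "crm_run")
}

#' @export
print.crm_run <- function(x, ...) {
  cat(sprintf(
    "crm_run (%s): %d communities, %d species x 2 strains, %d resources, %d recorded cycles\n",
    x$scenario$hypothesis, length(x$communities), x$scenario$n_species,
    x$scenario$n_resources, x$scenario$n_recorded))
  invisible(x)
}

#' Fraction of species pairs whose strain correlation exceeds the species
#' correlation
#'
#' For every pair of surviving species in every simulated community, the
#' species-level correlation magnitude and the maximum interspecific
#' strain-pair correlation magnitude are computed from the recorded
#' trajectories (as for observed communities), and the fraction of pairs
#' where the strain correlation is strictly greater is returned, pooled
#' over communities.
#'
#' @param run A `crm_run` from [serial_passage()].
#' @param min_abundance A species must stay above this relative abundance
#'   at every recorded cycle to count as surviving.
#' @return List with `fraction`, `n_pairs`.
#' @export
fraction_strain_exceeds_species <- function(run, min_abundance = 1e-6) {
  wins <- 0L
  n <- 0L
  for (com in run$communities) {
    ab <- com$abundance
    sp <- com$species_of
    species_traj <- rowsum(ab, sp)
    surviving <- which(apply(species_traj > min_abundance, 1L, all))
    if (length(surviving) < 2L) next
    for (ii in seq_along(surviving)[-length(surviving)]) {
      for (jj in seq((ii + 1L), length(surviving))) {
        a <- surviving[ii]
        b <- surviving[jj]
        res <- interspecies_correlations(
          species_traj[a, ], species_traj[b, ],
          ab[sp == a, , drop = FALSE], ab[sp == b, , drop = FALSE])
        if (is.na(res$species_r) || is.na(res$strain_r)) next
        n <- n + 1L
        if (res$strain_r > res$species_r) wins <- wins + 1L
      }
    }
  }
  if (n == 0L) stop("fewer than two surviving species in every community")
  list(fraction = wins / n, n_pairs = n)
}

#' Conspecific strain coupling by competitive distance
#'
#' Computes the coupling (|Pearson r|) of every conspecific strain pair in
#' a strain-specific run and summarizes it by the pair's competitive
#' distance D — the in-silico analogue of the coupling-versus-genetic-
#' distance curve.
#'
#' @param run A `crm_run`.
#' @return Data frame `D`, `coupling` (one row per surviving conspecific
#'   pair).
#' @export
conspecific_coupling_by_D <- function(run) {
  out <- list()
  for (com in run$communities) {
    ab <- com$abundance
    for (s in unique(com$species_of)) {
      idx <- which(com$species_of == s)
      r <- abs_cor(ab[idx[1L], ], ab[idx[2L], ])
      if (is.na(r)) next
      out[[length(out) + 1L]] <- data.frame(D = com$D[s], coupling = r)
    }
  }
  do.call(rbind, out)
}
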