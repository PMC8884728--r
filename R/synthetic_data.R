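#' Serial-passage schedule
#'
#' @param n_transfers Number of growth-dilution cycles.
#' @param dilution_factor Fold dilution at each transfer (> 1). Each cycle
#'   the community regrows by this factor, so `log2(dilution_factor)`
#'   generations elapse per transfer.
#' @return An object of class `passage_schedule`.
#' @export
passage_schedule <- function(n_transfers, dilution_factor = 100) {
  if (any(dilution_factor <= 1)) stop("dilution_factor must be > 1")
  if (n_transfers < 1) stop("n_transfers must be >= 1")
  structure(list(n_transfers = as.integer(n_transfers),
                 dilution_factor = dilution_factor,
                 generations_per_transfer = log2(dilution_factor)),
            class = "passage_schedule")
}

#' Cumulative generations elapsed under one or more passage schedules
#'
#' Each transfer at dilution factor D contributes log2(D) generations (the
#' number of doublings needed to regrow the diluted biomass). For the
#' standard regime of 46 weekly transfers at 1:100 this gives
#' 46 * log2(100) = 305.6 generations.
#'
#' @param schedule A [passage_schedule()] or a list of them (e.g. an initial
#'   low-dilution regime followed by a high-dilution one).
#' @return Total generations (numeric scalar).
#' @export
generations_elapsed <- function(schedule) {
  if (inherits(schedule, "passage_schedule")) schedule <- list(schedule)
  sum(vapply(schedule, function(s) {
    stopifnot(inherits(s, "passage_schedule"))
    s$n_transfers * log2(s$dilution_factor)
  }, numeric(1)))
}

#' Default configuration for the synthetic community generator
#'
#' The defaults mirror the scale of the laboratory system the package
#' targets: 10 replicate communities of ~10 species, metagenomically sampled
#' at 8 time points, each species carrying two strains differentiated by a
#' linked SNP cluster plus a set of shared near-fixed SNPs. Species
#' abundances fluctuate around their mean following a gamma distribution
#' with a coefficient of variation of 0.31 (the median temporal CV observed
#' for species in such communities).
#'
#' @param n_times Number of sampled time points.
#' @param mean_abundance Per-species mean relative abundances (recycled /
#'   normalized); default equal means.
#' @param cv Coefficient of variation of the gamma abundance fluctuations.
#' @param freq_process Strain-frequency process: `"constant"`,
#'   `"random-walk"` (Gaussian steps, sd `walk_sd`, clipped to \[0,1\]) or
#'   `"driven"` (logistic sweep at rate `sweep_rate` per time step).
#' @param walk_sd Per-step standard deviation of the random walk.
#' @param sweep_rate Logistic growth rate of the driven sweep.
#' @param f_bounds Interval to which the strain frequency is clipped
#'   (default \[0,1\]). Validation fixtures narrow this (e.g. to
#'   \[0.1, 0.85\]) so that the truth stays identifiable: a strain whose
#'   frequency reaches the fixed band is indistinguishable from a shared
#'   SNP cluster, as it should be.
#' @param n_diff_snps Differentiating SNPs per two-strain species.
#' @param n_shared_snps Shared (near-fixed) SNPs per species.
#' @param shared_freq True major-allele frequency of shared SNPs (close to,
#'   but below, 1 to emulate residual mapping noise).
#' @return A list of generator settings.
#' @export
truth_config <- function(n_times = 8, mean_abundance = NULL, cv = 0.31,
                         freq_process = c("random-walk", "constant", "driven"),
                         walk_sd = 0.05, sweep_rate = 1.0,
                         f_bounds = c(0, 1),
                         n_diff_snps = 30, n_shared_snps = 20,
                         shared_freq = 0.98) {
  freq_process <- match.arg(freq_process)
  stopifnot(length(f_bounds) == 2, f_bounds[1] < f_bounds[2])
  list(n_times = n_times, mean_abundance = mean_abundance, cv = cv,
       freq_process = freq_process, walk_sd = walk_sd,
       sweep_rate = sweep_rate, f_bounds = f_bounds,
       n_diff_snps = n_diff_snps,
       n_shared_snps = n_shared_snps, shared_freq = shared_freq)
}

#' Generate ground-truth communities for pipeline validation
#'
#' Species relative abundances at each time point are independent gamma
#' draws with the configured mean and variance (shape = mean^2/var),
#' renormalized to sum to 1 — the same stochastic structure the
#' interaction-detection null model assumes. Each species carries two
#' strains whose true strain-1 frequency f(t) follows the configured
#' process, clipped to \[0,1\].
#'
#' @param n_communities,n_species Community count and species per community.
#' @param seed Integer seed; output is reproducible given the seed.
#' @param config A [truth_config()].
#' @return List of `truth_community` objects, each with `abundance`
#'   (species x time matrix, columns summing to 1), `strain_freq`
#'   (species x time matrix of true strain-1 frequencies), `n_diff_snps`,
#'   `n_shared_snps`, `species_ids`, `times`.
#' @export
generate_truth <- function(n_communities = 10, n_species = 10, seed = 1,
                           config = truth_config()) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (config$cv <= 0) stop("abundance variance must be > 0")
  set.seed(seed)
  means <- config$mean_abundance
  if (is.null(means)) means <- rep(1 / n_species, n_species)
  means <- rep_len(means, n_species)
  means <- means / sum(means)
  shape <- 1 / config$cv^2              # shape = mean^2 / var, var = (cv*mean)^2
  Tn <- config$n_times
  lapply(seq_len(n_communities), function(ci) {
    if (config$cv < 1e-12) {
      ab <- matrix(means, n_species, Tn)
    } else {
      ab <- matrix(stats::rgamma(n_species * Tn, shape = shape,
                                 rate = shape / rep(means, Tn)),
                   n_species, Tn)
    }
    ab <- sweep(ab, 2L, colSums(ab), "/")
    lo <- config$f_bounds[1L]
    hi <- config$f_bounds[2L]
    f0 <- stats::runif(n_species, max(0.2, lo), min(0.8, hi))
    f <- matrix(NA_real_, n_species, Tn)
    f[, 1L] <- f0
    for (t in seq_len(Tn)[-1L]) {
      f[, t] <- switch(config$freq_process,
        "constant" = f[, t - 1L],
        "random-walk" = pmin(hi, pmax(lo, f[, t - 1L] +
          stats::rnorm(n_species, 0, config$walk_sd))),
        "driven" = {
          x <- pmin(1 - 1e-9, pmax(1e-9, f[, t - 1L]))
          pmin(hi, pmax(lo,
            1 / (1 + exp(-(log(x / (1 - x)) + config$sweep_rate)))))
        })
    }
    sp <- sprintf("C%02d_sp%02d", ci, seq_len(n_species))
    rownames(ab) <- rownames(f) <- sp
    structure(list(abundance = ab, strain_freq = f,
                   n_diff_snps = rep(config$n_diff_snps, n_species),
                   n_shared_snps = rep(config$n_shared_snps, n_species),
                   shared_freq = config$shared_freq,
                   species_ids = sp, times = seq_len(Tn) - 1),
              class = "truth_community")
  })
}

#' Read-depth model for synthetic SNP observations
#'
#' Depths are drawn per SNP per time point from a Poisson distribution
#' around `mean_depth`; the `dispersion` slot is reserved for an
#' overdispersed variant and currently unused.
#'
#' @param mean_depth Mean local read depth (>= 1).
#' @param dispersion Reserved.
#' @return A `depth_model` list.
#' @export
depth_model <- function(mean_depth = 50, dispersion = NULL) {
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  structure(list(mean_depth = mean_depth, dispersion = dispersion),
            class = "depth_model")
}

#' Simulate metagenomic SNP observations from a ground-truth community
#'
#' For every differentiating SNP of every species, the observed major-allele
#' frequency at time t is `Binomial(depth, f(t)) / depth` — binomial read
#' sampling at the locally drawn depth. Shared SNPs are observed around
#' their near-fixed true frequency the same way. Zero-depth draws are
#' recorded as depth 0 with frequency `NA`.
#'
#' @param truth A `truth_community` from [generate_truth()].
#' @param depth A [depth_model()].
#' @param seed Integer seed.
#' @return A `snp_trajectories` object: list with `freq` and `depth`
#'   matrices (SNPs x time) and a `meta` data frame (`snp_id`, `species`,
#'   `kind` in \{"differentiating","shared"\}).
#' @export
observe_snps <- function(truth, depth = depth_model(), seed = 1) {
  stopifnot(inherits(truth, "truth_community"))
  set.seed(seed)
  Tn <- ncol(truth$strain_freq)
  rows <- list()
  meta <- list()
  for (si in seq_along(truth$species_ids)) {
    sp <- truth$species_ids[si]
    n_d <- truth$n_diff_snps[si]
    n_s <- truth$n_shared_snps[si]
    if (n_d < 1) stop("each two-strain species needs >= 1 differentiating SNP")
    p <- c(rep(list(truth$strain_freq[si, ]), n_d),
           rep(list(rep(truth$shared_freq, Tn)), n_s))
    kind <- c(rep("differentiating", n_d), rep("shared", n_s))
    for (k in seq_along(p)) {
      d <- stats::rpois(Tn, depth$mean_depth)
      obs <- ifelse(d > 0, stats::rbinom(Tn, d, p[[k]]) / pmax(d, 1L),
                    NA_real_)
      rows[[length(rows) + 1L]] <- list(freq = obs, depth = d)
      meta[[length(meta) + 1L]] <- data.frame(
        snp_id = sprintf("%s_snp%04d", sp, k), species = sp,
        kind = kind[k], stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  freq <- do.call(rbind, lapply(rows, `[[`, "freq"))
  dep <- do.call(rbind, lapply(rows, `[[`, "depth"))
  rownames(freq) <- rownames(dep) <- meta$snp_id
  structure(list(freq = freq, depth = dep, meta = meta),
            class = "snp_trajectories")
}

#' @export
print.snp_trajectories <- function(x, ...) {
  cat(sprintf("snp_trajectories: %d SNPs x %d time points (%d species)\n",
              nrow(x$freq), ncol(x$freq), length(unique(x$meta$species))))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate synthetic open reading frames and a gene table
#'
#' Each gene is a complete ORF: start codon ATG, `length_codons - 2` random
#' sense codons (no internal stop), and a terminal stop codon. Genes are
#' laid head-to-tail on a synthetic genome with fixed 50 bp intergenic
#' spacers; strands alternate so both orientations are exercised. Category
#' labels are drawn from `categories`.
#'
#' @param n_genes Number of genes.
#' @param length_codons Codons per gene including start and stop (>= 2).
#' @param seed Integer seed.
#' @param genome_id Identifier of the synthetic genome/contig.
#' @param categories Character palette of functional category labels.
#' @return List with `genes` (data frame: `gene_id`, `genome_id`, `start`,
#'   `end`, `strand`, `frame`, `complete`, `category`) and `genome`
#'   (a named [Biostrings::DNAStringSet] of length 1).
#' @export
generate_genes <- function(n_genes = 10, length_codons = 100, seed = 1,
                           genome_id = "synth_genome",
                           categories = c("transporters", "two-component",
                                          "transcription_factors",
                                          "carbon_metabolism", "motility",
                                          "phage", "other")) {
  if (length_codons < 2) stop("length_codons must be >= 2")
  set.seed(seed)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste0,
                  collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  spacer_len <- 50L
  pos <- 1L
  seqs <- character(0)
  genes <- list()
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  for (g in seq_len(n_genes)) {
    body <- paste(sample(sense, length_codons - 2L, replace = TRUE),
                  collapse = "")
    orf <- paste0("ATG", body, sample(STOP_CODONS, 1L))
    strand <- if (g %% 2L == 1L) "+" else "-"
    placed <- if (strand == "+") orf else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
    gap <- spacer(spacer_len)
    seqs <- c(seqs, gap, placed)
    start <- pos + spacer_len
    end <- start + nchar(orf) - 1L
    pos <- end + 1L
    genes[[g]] <- data.frame(
      gene_id = sprintf("%s_g%03d", genome_id, g), genome_id = genome_id,
      start = start, end = end, strand = strand, frame = 0L,
      complete = TRUE, category = sample(categories, 1L),
      stringsAsFactors = FALSE)
  }
  seqs <- c(seqs, spacer(spacer_len))
  genome <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(genome) <- genome_id
  list(genes = do.call(rbind, genes), genome = genome)
}
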