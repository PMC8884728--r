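#' SNP filtering configuration
#'
#' Defaults follow the standard post-calling filters for pooled haploid
#' metagenomic variant calls: Phred quality >= 20 and local read depth >= 10
#' (an allele-frequency least count of 10%), biallelic sites only, and the
#' persistence rule: once detected, a SNP must be re-detected at every later
#' time point, or until the time point at which its species drops to zero
#' relative abundance.
#'
#' @param min_qual Minimum Phred quality at detection.
#' @param min_depth Minimum local read depth at detection.
#' @param require_biallelic Drop sites with more than one alternate allele.
#' @param require_persistence Enforce the persistence rule.
#' @return A `snp_filter_config` list.
#' @export
snp_filter_config <- function(min_qual = 20, min_depth = 10,
                              require_biallelic = TRUE,
                              require_persistence = TRUE) {
  if (min_qual < 0) stop("min_qual must be >= 0")
  if (min_depth < 1) stop("min_depth must be >= 1")
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 require_biallelic = require_biallelic,
                 require_persistence = require_persistence),
            class = "snp_filter_config")
}

#' Filter SNP records and assemble major-allele frequency trajectories
#'
#' Records for the same site across time points are grouped; each site is
#' tested against the configured rules and either converted into a
#' major-allele frequency trajectory or rejected with a reason. A SNP is
#' "detected" at a time point when its alternate allele has at least one
#' supporting read. The major allele (reference or alternate, whichever has
#' the higher frequency) is fixed at the first detection and tracked
#' thereafter, so trajectories do not flip at frequency 0.5.
#'
#' @param records Long data frame of SNP records as produced by
#'   [read_snp_vcf()] over all time points (rows for every site at every
#'   time, including zero-alternate observations, as emitted by a caller
#'   run with monomorphic reporting).
#' @param config A [snp_filter_config()].
#' @param species_abundance Numeric matrix of relative abundances, genomes
#'   in rows (rownames = genome ids), time points in columns; used by the
#'   persistence rule. A SNP whose species has reached abundance 0 is not
#'   required to persist past that point.
#' @return List with `trajectories` (a `snp_trajectories` object: `freq`,
#'   `depth`, `meta` with the site coordinates and major allele) and
#'   `rejections` (data frame `snp_id`, `reason` in
#'   \{"indel","biallelic","qual","depth","persistence","undetected"\}).
#' @export
filter_snps <- function(records, config = snp_filter_config(),
                        species_abundance) {
  n_times <- ncol(species_abundance)
  # every genome must be observed at every time point
  for (g in unique(records$genome_id)) {
    seen <- sort(unique(records$time_index[records$genome_id == g]))
    missing <- setdiff(seq_len(n_times) - 1L, seen)
    if (length(missing)) {
      stop("genome ", g, " has no records at time point(s): ",
           paste(missing, collapse = ", "))
    }
  }
  key <- paste(records$genome_id, records$position, records$ref,
               records$alt, sep = ":")
  groups <- split(seq_len(nrow(records)), key)

  reject <- list()
  keep_meta <- list()
  keep_freq <- list()
  keep_depth <- list()
  for (k in names(groups)) {
    r <- records[groups[[k]], , drop = FALSE]
    r <- r[order(r$time_index), , drop = FALSE]
    snp_id <- k
    if (any(r$is_indel)) {
      reject[[snp_id]] <- "indel"; next
    }
    if (config$require_biallelic && any(r$n_alts_at_site > 1L)) {
      reject[[snp_id]] <- "biallelic"; next
    }
    full <- rep(NA_integer_, n_times)
    ti <- r$time_index + 1L
    alt_c <- full; alt_c[ti] <- r$alt_count
    ref_c <- full; ref_c[ti] <- r$ref_count
    dep <- full; dep[ti] <- r$depth
    qual <- rep(NA_real_, n_times); qual[ti] <- r$qual
    detected <- !is.na(alt_c) & alt_c > 0L
    if (!any(detected)) {
      reject[[snp_id]] <- "undetected"; next
    }
    t0 <- which(detected)[1L]
    if (!is.na(qual[t0]) && qual[t0] < config$min_qual) {
      reject[[snp_id]] <- "qual"; next
    }
    if (!is.na(dep[t0]) && dep[t0] < config$min_depth) {
      reject[[snp_id]] <- "depth"; next
    }
    genome <- r$genome_id[1L]
    present <- if (genome %in% rownames(species_abundance)) {
      species_abundance[genome, ] > 0
    } else {
      rep(TRUE, n_times)
    }
    if (config$require_persistence && t0 < n_times) {
      later <- seq(t0 + 1L, n_times)
      required <- later[present[later]]
      # presence is only required until the species first vanishes
      gone <- which(!present[later])
      if (length(gone)) required <- later[later < later[gone[1L]]]
      if (any(!detected[required])) {
        reject[[snp_id]] <- "persistence"; next
      }
    }
    alt_freq <- alt_c / pmax(dep, 1L)
    major <- if (alt_freq[t0] >= 0.5) "alt" else "ref"
    freq <- if (major == "alt") alt_freq else ref_c / pmax(dep, 1L)
    freq[is.na(dep) | dep == 0L] <- NA_real_
    keep_meta[[snp_id]] <- data.frame(
      snp_id = snp_id, species = genome, genome_id = genome,
      position = r$position[1L], ref = r$ref[1L], alt = r$alt[1L],
      major_allele = major, first_detected = t0 - 1L, kind = NA_character_,
      stringsAsFactors = FALSE)
    keep_freq[[snp_id]] <- freq
    keep_depth[[snp_id]] <- ifelse(is.na(dep), 0L, dep)
  }
  rejections <- data.frame(snp_id = names(reject),
                           reason = unlist(reject, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (length(keep_meta)) {
    meta <- do.call(rbind, keep_meta)
    freq <- do.call(rbind, keep_freq)
    depth <- do.call(rbind, keep_depth)
    rownames(meta) <- rownames(freq) <- rownames(depth) <- meta$snp_id
    traj <- structure(list(freq = freq, depth = depth, meta = meta),
                      class = "snp_trajectories")
  } else {
    traj <- structure(list(freq = matrix(numeric(), 0, n_times),
                           depth = matrix(integer(), 0, n_times),
                           meta = data.frame()),
                      class = "snp_trajectories")
  }
  list(trajectories = traj, rejections = rejections)
}

#' Flag genes with anomalous coverage
#'
#' A gene is flagged when its coverage is less than half the median gene
#' coverage in a sample, or greater than three times the median in any
#' sample (strict inequalities). SNPs in flagged genes should be excluded
#' upstream as likely read-stealing artifacts.
#'
#' @param coverage Numeric matrix, genes x samples, with gene rownames.
#' @return Data frame `gene`, `flagged`, `reason` ("low", "high",
#'   "low+high" or "").
#' @export
flag_anomalous_genes <- function(coverage) {
  coverage <- as.matrix(coverage)
  if (any(coverage < 0)) stop("coverage must be non-negative")
  med <- apply(coverage, 2L, stats::median)
  if (any(med == 0)) {
    stop("sample(s) with all-zero median coverage: ",
         paste(which(med == 0), collapse = ", "))
  }
  low <- sweep(coverage, 2L, 0.5 * med, "<")
  high <- sweep(coverage, 2L, 3 * med, ">")
  reason <- paste0(ifelse(rowSums(low) > 0, "low", ""),
                   ifelse(rowSums(low) > 0 & rowSums(high) > 0, "+", ""),
                   ifelse(rowSums(high) > 0, "high", ""))
  data.frame(gene = rownames(coverage) %||% seq_len(nrow(coverage)),
             flagged = reason != "", reason = reason,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Species relative abundances from mapped metagenomic read counts
#'
#' The fraction of reads mapped to each reference genome, normalized by
#' genome length: `abundance_i = (reads_i / length_i) / sum_j (reads_j /
#' length_j)`.
#'
#' @param reads Mapped read counts per genome (named numeric).
#' @param lengths Genome lengths in bp (> 0), same order.
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
metagenome_species_abundance <- function(reads, lengths) {
  if (any(lengths <= 0)) stop("genome lengths must be > 0")
  dens <- reads / lengths
  total <- sum(dens)
  if (total == 0) stop("no mapped reads")
  dens / total
}

#' Classify the coding effect of a SNP
#'
#' Locates the SNP in the gene table; SNPs outside annotated genes are
#' intergenic. For genic SNPs the affected codon is evaluated on the coding
#' strand (minus-strand genes are reverse-complemented before lookup) under
#' the standard genetic code. A substitution that leaves the amino acid
#' unchanged is synonymous; one that introduces a stop codon is nonsense;
#' any other amino-acid change is nonsynonymous.
#'
#' @param snp A one-row data frame or list with `genome_id`, `position`,
#'   `ref`, `alt` (plus-strand alleles, as in a VCF).
#' @param genes Gene table as in [generate_genes()]: `gene_id`, `genome_id`,
#'   `start`, `end`, `strand`, `complete`.
#' @param genome Named [Biostrings::DNAStringSet] holding the genome
#'   sequence(s).
#' @return A one-row data frame (`effect_call`): `snp_id`, `gene_id`,
#'   `class` in \{"synonymous","nonsynonymous","nonsense","intergenic",
#'   "unclassified"\}, `codon_before`, `codon_after`, `aa_before`,
#'   `aa_after`, `codon_index`, `n_codons`.
#' @export
classify_snp_effect <- function(snp, genes, genome) {
  snp <- as.list(snp)
  pos <- as.integer(snp$position)
  snp_id <- snp$snp_id %||%
    paste(snp$genome_id, pos, snp$ref, snp$alt, sep = ":")
  blank <- data.frame(snp_id = snp_id, gene_id = NA_character_,
                      class = "intergenic", codon_before = NA_character_,
                      codon_after = NA_character_, aa_before = NA_character_,
                      aa_after = NA_character_, codon_index = NA_integer_,
                      n_codons = NA_integer_, stringsAsFactors = FALSE)
  hit <- which(genes$genome_id == snp$genome_id & genes$start <= pos &
                 genes$end >= pos)
  if (!length(hit)) return(blank)
  g <- genes[hit[1L], ]
  if (!isTRUE(g$complete)) {
    blank$gene_id <- g$gene_id
    blank$class <- "unclassified"
    return(blank)
  }
  seq <- genome[[g$genome_id]]
  if (g$strand == "+") {
    offset <- pos - g$start
    ref_coding <- snp$ref
    alt_coding <- snp$alt
  } else {
    offset <- g$end - pos
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_coding <- unname(comp[snp$ref])
    alt_coding <- unname(comp[snp$alt])
  }
  codon_index <- offset %/% 3L + 1L
  within <- offset %% 3L + 1L
  n_codons <- (g$end - g$start + 1L) %/% 3L
  if (g$strand == "+") {
    cstart <- g$start + 3L * (codon_index - 1L)
    codon <- as.character(Biostrings::subseq(seq, cstart, cstart + 2L))
  } else {
    cend <- g$end - 3L * (codon_index - 1L)
    codon <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(seq, cend - 2L, cend)))
  }
  if (substr(codon, within, within) != ref_coding) {
    warning("reference allele of ", snp_id,
            " does not match the genome sequence")
  }
  codon_after <- codon
  substr(codon_after, within, within) <- alt_coding
  code <- Biostrings::GENETIC_CODE
  aa_before <- unname(code[codon])
  aa_after <- unname(code[codon_after])
  class <- if (aa_before == aa_after) "synonymous"
  else if (aa_after == "*") "nonsense"
  else "nonsynonymous"
  data.frame(snp_id = snp_id, gene_id = g$gene_id, class = class,
             codon_before = codon, codon_after = codon_after,
             aa_before = aa_before, aa_after = aa_after,
             codon_index = codon_index, n_codons = n_codons,
             stringsAsFactors = FALSE)
}

#' Classify the effects of a set of SNPs
#'
#' @param snps Data frame with one SNP per row (see [classify_snp_effect()]).
#' @inheritParams classify_snp_effect
#' @return Data frame of effect calls, one row per SNP.
#' @export
classify_snp_effects <- function(snps, genes, genome) {
  do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    classify_snp_effect(snps[i, ], genes, genome)
  }))
}

#' Detect pseudogenes from nonsense effect calls
#'
#' A pseudogene call is a gene in which a SNP introduces a premature stop
#' codon that satisfies the persistence rule: detected at every time point
#' after its first detection (while the species is present). Stops created
#' in the gene's final codon are not premature and are excluded.
#'
#' @param effects Effect-call data frame from [classify_snp_effects()].
#' @param detected Logical matrix, SNPs x time points (rownames = `snp_id`),
#'   TRUE where the SNP was detected.
#' @param species_present Optional logical matrix or vector giving, per time
#'   point, whether the species carrying the SNPs was present; persistence
#'   is only required while present. Default: always present.
#' @return Data frame `gene_id`, `snp_id`, `first_detected` (0-based time
#'   index), one row per persistent premature-stop SNP.
#' @export
detect_pseudogenes <- function(effects, detected, species_present = NULL) {
  n_times <- ncol(detected)
  if (is.null(species_present)) species_present <- rep(TRUE, n_times)
  calls <- list()
  nonsense <- effects[effects$class == "nonsense", , drop = FALSE]
  for (i in seq_len(nrow(nonsense))) {
    e <- nonsense[i, ]
    # the last codon before the terminal stop is not premature
    if (e$codon_index >= e$n_codons - 1L) next
    det <- detected[e$snp_id, ]
    if (!any(det)) next
    t0 <- which(det)[1L]
    if (t0 < n_times) {
      later <- seq(t0 + 1L, n_times)
      gone <- which(!species_present[later])
      required <- if (length(gone)) later[later < later[gone[1L]]] else later
      if (any(!det[required])) next
    }
    calls[[length(calls) + 1L]] <- data.frame(
      gene_id = e$gene_id, snp_id = e$snp_id, first_detected = t0 - 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) {
    return(data.frame(gene_id = character(), snp_id = character(),
                      first_detected = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

#' Assign a pseudogene (loss-of-function SNP) to a strain
#'
#' The causal SNP's allele-frequency trajectory is compared with the
#' frequency trajectories of the two strains; the pseudogene is assigned to
#' the unique strain whose frequency it matches within `tol` at every time
#' point where the SNP is detected. If it is consistent with both strains,
#' or with neither, it stays unassigned.
#'
#' @param snp_freq Allele-frequency trajectory of the stop-causing SNP.
#' @param model A two-strain `strain_model` (see [select_strain_model()]).
#' @param tol Allele-frequency consistency tolerance (default 0.1, the
#'   frequency least count implied by a minimum read depth of 10).
#' @param detected Optional logical vector marking time points where the
#'   SNP was detected (default: where `snp_freq` is finite).
#' @return One of `"strain_1"`, `"strain_2"`, `"unassigned"`.
#' @export
assign_pseudogene_to_strain <- function(snp_freq, model, tol = 0.1,
                                        detected = NULL) {
  if (model$n_strains != 2L) {
    stop("pseudogene assignment requires a two-strain model")
  }
  if (is.null(detected)) detected <- is.finite(snp_freq)
  if (!any(detected)) return("unassigned")
  f1 <- model$f
  f2 <- 1 - model$f
  ok1 <- all(abs(snp_freq[detected] - f1[detected]) <= tol, na.rm = TRUE)
  ok2 <- all(abs(snp_freq[detected] - f2[detected]) <= tol, na.rm = TRUE)
  if (ok1 && !ok2) "strain_1" else if (ok2 && !ok1) "strain_2"
  else "unassigned"
}

# Nei-Gojobori fractional site counts for one sense codon: for each of the
# three positions, the fraction of the three possible substitutions that
# are synonymous contributes to S-sites; the rest (including stop-gains)
# to N-sites. Sites per codon always sum to 3.
codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[codon]
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(nts, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (identical(unname(code[mut]), unname(aa))) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

#' Expected synonymous and nonsynonymous site counts for genes
#'
#' Nei-Gojobori counting over the sense codons of each gene (the terminal
#' stop codon is excluded): each codon position contributes the fraction of
#' its three possible substitutions that are synonymous to the S-site
#' count, and the remainder to the N-site count, so N + S = 3 per codon.
#'
#' @param genes Gene table (rows restricted to the genes of interest).
#' @param genome Named [Biostrings::DNAStringSet].
#' @return List with totals `N_sites`, `S_sites` and per-gene data frame.
#' @export
ng_site_counts <- function(genes, genome) {
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    seq <- Biostrings::subseq(genome[[g$genome_id]], g$start, g$end)
    if (g$strand == "-") seq <- Biostrings::reverseComplement(seq)
    cds <- as.character(seq)
    n_codons <- nchar(cds) %/% 3L
    codons <- substring(cds, 3L * seq_len(n_codons) - 2L,
                        3L * seq_len(n_codons))
    codons <- codons[codons %in% names(Biostrings::GENETIC_CODE)]
    # drop the terminal stop codon from site counting
    if (length(codons) &&
        Biostrings::GENETIC_CODE[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    sites <- rowSums(vapply(codons, codon_sites, numeric(2)))
    data.frame(gene_id = g$gene_id, S_sites = sites[["S"]],
               N_sites = sites[["N"]], n_codons = length(codons),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, per_gene)
  list(N_sites = sum(per_gene$N_sites), S_sites = sum(per_gene$S_sites),
       per_gene = per_gene)
}

#' Compute pN/pS for a set of SNP effect calls
#'
#' pN is the count of observed nonsynonymous changes (including nonsense)
#' per expected nonsynonymous site; pS the count of synonymous changes per
#' expected synonymous site; sites are counted with the Nei-Gojobori
#' fractional scheme over the genes in `gene_subset`. No multiple-hit
#' (Jukes-Cantor) correction is applied: the statistic is a polymorphism
#' ratio, not a divergence rate.
#'
#' @param effects Effect-call data frame (genic calls only are used).
#' @param genes Gene table.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param gene_subset Character vector of gene ids defining the set
#'   (default: all genes with at least one effect call).
#' @return List (`pnps_result`): `N_sites`, `S_sites`, `N_obs`, `S_obs`,
#'   `pN`, `pS`, `pnps`, `undefined` (TRUE when `S_obs` is 0).
#' @export
compute_pnps <- function(effects, genes, genome, gene_subset = NULL) {
  genic <- effects[effects$class %in%
                     c("synonymous", "nonsynonymous", "nonsense"), ,
                   drop = FALSE]
  if (is.null(gene_subset)) gene_subset <- unique(genic$gene_id)
  genic <- genic[genic$gene_id %in% gene_subset, , drop = FALSE]
  if (!nrow(genic)) stop("no SNP effect calls in the requested gene subset")
  sites <- ng_site_counts(genes[genes$gene_id %in% gene_subset, ,
                                drop = FALSE], genome)
  N_obs <- sum(genic$class %in% c("nonsynonymous", "nonsense"))
  S_obs <- sum(genic$class == "synonymous")
  pN <- N_obs / sites$N_sites
  pS <- S_obs / sites$S_sites
  structure(list(N_sites = sites$N_sites, S_sites = sites$S_sites,
                 N_obs = N_obs, S_obs = S_obs, pN = pN, pS = pS,
                 pnps = if (S_obs > 0) pN / pS else NA_real_,
                 undefined = S_obs == 0),
            class = "pnps_result")
}

#' Genome fraction of each functional category
#'
#' The success rate for the enrichment binomial: summed coding length of a
#' category's genes divided by the total annotated coding length, which
#' accounts for both the number and the length of genes per category.
#'
#' @param genes Gene table with a `category` column.
#' @return Named numeric vector of fractions summing to 1.
#' @export
category_fractions <- function(genes) {
  len <- genes$end - genes$start + 1L
  fr <- tapply(len, genes$category, sum) / sum(len)
  fr[order(names(fr))]
}

#' Binomial enrichment of SNPs in functional categories
#'
#' For each category, the observed SNP count is compared against a binomial
#' with success rate equal to the fraction of the annotated genome covered
#' by that category: `p = P(X >= observed)` with
#' `X ~ Binomial(total, fraction)` (one-sided upper tail), and the
#' enrichment score is `1/p`. No multiple-testing correction is applied
#' here; scores are descriptive ranks.
#'
#' @param counts Named integer vector of SNP counts per category.
#' @param fractions Named numeric vector of genome fractions per category
#'   (e.g. [category_fractions()]); names must cover those of `counts`.
#' @param total Total number of categorized SNPs (default `sum(counts)`).
#' @return Data frame `category`, `observed`, `expected`, `p_value`,
#'   `enrichment_score`, sorted by decreasing score.
#' @export
category_enrichment <- function(counts, fractions, total = sum(counts)) {
  if (!all(names(counts) %in% names(fractions))) {
    stop("missing genome fraction for: ",
         paste(setdiff(names(counts), names(fractions)), collapse = ", "))
  }
  fr <- fractions[names(counts)]
  if (any(fr <= 0 & counts > 0)) {
    stop("category with zero genome fraction but nonzero SNP count")
  }
  if (any(counts > total)) stop("category count exceeds total SNPs")
  p <- stats::pbinom(counts - 1L, size = total, prob = fr,
                     lower.tail = FALSE)
  out <- data.frame(category = names(counts), observed = as.integer(counts),
                    expected = total * fr, p_value = p,
                    enrichment_score = 1 / p, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$enrichment_score), ]
}

#' Divergence-time parameters
#'
#' Defaults follow literature estimates for wild soil bacteria: a mutation
#' rate of 1e-8 per nucleotide per generation, a genome size of ~1e6 bp of
#' reliably alignable core genome, and ~100 generations per year.
#'
#' @param mu Mutations per nucleotide per generation.
#' @param L Genome size in bp.
#' @param g Generations per year.
#' @return A `divergence_params` list.
#' @export
divergence_params <- function(mu = 1e-8, L = 1e6, g = 100) {
  if (mu <= 0 || L <= 0 || g <= 0) stop("all parameters must be > 0")
  structure(list(mu = mu, L = L, g = g), class = "divergence_params")
}

#' Neutral divergence time implied by a SNP count
#'
#' Under the molecular-clock argument, the neutral divergence rate of a
#' population equals the per-individual mutation rate, independent of
#' population size; one SNP then accumulates every `1/(mu * L)` generations
#' (100 generations, or about 1 year, at the defaults).
#'
#' @param n_snps Number of SNPs separating two strains.
#' @param params A [divergence_params()].
#' @return List with `generations` and `years`.
#' @export
divergence_time <- function(n_snps, params = divergence_params()) {
  gens_per_snp <- 1 / (params$mu * params$L)
  generations <- n_snps * gens_per_snp
  list(generations = generations, years = generations / params$g)
}
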