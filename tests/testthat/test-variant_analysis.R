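abund2 <- function(genomes, n_times = 4,
                   values = matrix(0.5, length(genomes), n_times)) {
  rownames(values) <- genomes
  values
}

test_that("filter_snps applies quality, depth, biallelic and persistence rules", {
  ab <- abund2(c("g1"), 5)
  clean <- make_site_records("g1", 100, "A", "G",
                             alt_counts = c(10, 12, 9, 11, 10),
                             depths = rep(20, 5))
  low_qual <- make_site_records("g1", 200, "C", "T",
                                alt_counts = rep(5, 5), depths = rep(20, 5),
                                qual = 19)
  low_depth <- make_site_records("g1", 300, "G", "A",
                                 alt_counts = rep(4, 5), depths = rep(8, 5))
  triallelic <- make_site_records("g1", 400, "T", "C",
                                  alt_counts = rep(6, 5), depths = rep(20, 5),
                                  n_alts = 2L)
  vanishing <- make_site_records("g1", 500, "A", "C",
                                 alt_counts = c(0, 0, 8, 0, 0),
                                 depths = rep(20, 5))
  clean2 <- make_site_records("g1", 600, "A", "T",
                              alt_counts = c(15, 14, 16, 15, 15),
                              depths = rep(20, 5))
  records <- rbind(clean, low_qual, low_depth, triallelic, vanishing, clean2)
  res <- filter_snps(records, snp_filter_config(), ab)
  expect_equal(nrow(res$trajectories$freq), 2L)
  reasons <- setNames(res$rejections$reason, res$rejections$snp_id)
  expect_equal(unname(reasons["g1:200:C:T"]), "qual")
  expect_equal(unname(reasons["g1:300:G:A"]), "depth")
  expect_equal(unname(reasons["g1:400:T:C"]), "biallelic")
  expect_equal(unname(reasons["g1:500:A:C"]), "persistence")
})

test_that("persistence is only required while the species is present", {
  ab <- abund2("g1", 5)
  ab["g1", 4:5] <- 0  # species vanishes from time index 3 on
  rec <- make_site_records("g1", 10, "A", "G",
                           alt_counts = c(0, 8, 9, 0, 0),
                           depths = rep(20, 5))
  res <- filter_snps(rec, snp_filter_config(), ab)
  expect_equal(nrow(res$trajectories$freq), 1L)
})

test_that("the major allele is fixed at first detection", {
  ab <- abund2("g1", 4)
  # alt frequency 0.8 at detection -> alt is major; stays major even when
  # its frequency later crosses 0.5
  rec <- make_site_records("g1", 10, "A", "G",
                           alt_counts = c(16, 12, 8, 4),
                           depths = rep(20, 4))
  res <- filter_snps(rec, snp_filter_config(), ab)
  expect_equal(res$trajectories$meta$major_allele, "alt")
  expect_equal(unname(res$trajectories$freq[1, ]), c(0.8, 0.6, 0.4, 0.2))
  # alt frequency 0.2 at detection -> ref is major
  rec2 <- make_site_records("g1", 20, "C", "T",
                            alt_counts = c(4, 4, 4, 4), depths = rep(20, 4))
  res2 <- filter_snps(rec2, snp_filter_config(), ab)
  expect_equal(res2$trajectories$meta$major_allele, "ref")
  expect_equal(unname(res2$trajectories$freq[1, ]), rep(0.8, 4))
})

test_that("filters give the same retained set in any order", {
  ab <- abund2("g1", 4)
  set.seed(42)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    make_site_records("g1", i * 10, "A", "G",
                      alt_counts = sample(0:10, 4, TRUE),
                      depths = sample(c(5, 15, 30), 4, TRUE),
                      qual = sample(c(10, 30), 1),
                      n_alts = sample(c(1L, 2L), 1, prob = c(0.8, 0.2)))
  }))
  full <- filter_snps(recs, snp_filter_config(), ab)
  # disabling one rule then applying it manually yields the same set:
  # here biallelic off, then drop multi-allelic ids afterwards
  relaxed <- filter_snps(recs, snp_filter_config(require_biallelic = FALSE),
                         ab)
  multi <- unique(with(recs[recs$n_alts_at_site > 1L, ],
                       paste(genome_id, position, ref, alt, sep = ":")))
  expect_setequal(setdiff(rownames(relaxed$trajectories$freq), multi),
                  rownames(full$trajectories$freq))
})

test_that("missing time points are reported", {
  ab <- abund2("g1", 5)
  rec <- make_site_records("g1", 10, "A", "G", alt_counts = rep(5, 3),
                           depths = rep(20, 3))  # only times 0..2
  expect_error(filter_snps(rec, snp_filter_config(), ab), "3, 4")
})

test_that("coverage anomalies use strict half/thrice median bounds", {
  cov <- rbind(gA = c(4, 10), gB = c(31, 10), gC = c(5, 10),
               gD = c(10, 10), gE = c(10, 12))
  flags <- flag_anomalous_genes(cov)
  expect_true(flags$flagged[flags$gene == "gA"])    # 4 < 0.5 * 10
  expect_equal(flags$reason[flags$gene == "gB"], "high")  # 31 > 3 * 10
  expect_false(flags$flagged[flags$gene == "gC"])   # exactly 0.5x: kept
  expect_false(flags$flagged[flags$gene == "gD"])
  expect_error(flag_anomalous_genes(rbind(a = c(0, 1), b = c(0, 2))),
               "zero")
})

test_that("species abundance normalizes read counts by genome length", {
  expect_equal(unname(metagenome_species_abundance(c(100, 200),
                                                   c(1e6, 2e6))),
               c(0.5, 0.5))
  expect_equal(unname(metagenome_species_abundance(c(300, 100),
                                                   c(1e6, 1e6))),
               c(0.75, 0.25))
  expect_equal(unname(metagenome_species_abundance(50, 1e6)), 1)
  expect_error(metagenome_species_abundance(c(0, 0), c(1e6, 1e6)), "reads")
})

test_that("SNP effects are classified on the coding strand", {
  # one + gene and one - gene with known codons
  plus_orf <- "ATGGAATACAAATAA"        # M E Y K *
  minus_orf <- plus_orf
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome_seq <- paste0("CCCCC", plus_orf, "CCCCC", rc(minus_orf), "CCCCC")
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "g1"
  genes <- data.frame(
    gene_id = c("gp", "gm"), genome_id = "g1",
    start = c(6L, 26L), end = c(20L, 40L), strand = c("+", "-"),
    frame = 0L, complete = TRUE, category = "other",
    stringsAsFactors = FALSE)
  # + strand: GAA -> GAG at codon position 3 (genome pos 11) = synonymous
  eff <- classify_snp_effect(
    list(genome_id = "g1", position = 11L, ref = "A", alt = "G"),
    genes, genome)
  expect_equal(eff$class, "synonymous")
  expect_equal(eff$aa_before, "E")
  # + strand: TAC -> TAA (genome pos 14, C->A) = nonsense
  eff <- classify_snp_effect(
    list(genome_id = "g1", position = 14L, ref = "C", alt = "A"),
    genes, genome)
  expect_equal(eff$class, "nonsense")
  expect_equal(eff$aa_after, "*")
  # - strand gene: same TAC codon sits reverse-complemented; the genome
  # (plus-strand) allele G->T corresponds to C->A on the coding strand
  pos_minus <- 40L - (6L + 2L)  # codon 3, coding position 3
  eff <- classify_snp_effect(
    list(genome_id = "g1", position = pos_minus, ref = "G", alt = "T"),
    genes, genome)
  expect_equal(eff$class, "nonsense")
  # outside any gene
  eff <- classify_snp_effect(
    list(genome_id = "g1", position = 2L, ref = "C", alt = "A"),
    genes, genome)
  expect_equal(eff$class, "intergenic")
  # incomplete frame is flagged, not classified
  genes2 <- genes
  genes2$complete <- FALSE
  eff <- classify_snp_effect(
    list(genome_id = "g1", position = 11L, ref = "A", alt = "G"),
    genes2, genome)
  expect_equal(eff$class, "unclassified")
})

test_that("pseudogene calls require persistence and a premature stop", {
  effects <- data.frame(
    snp_id = c("s1", "s2", "s3"), gene_id = c("gA", "gA", "gB"),
    class = "nonsense", codon_index = c(5L, 5L, 9L),
    n_codons = c(10L, 10L, 10L), stringsAsFactors = FALSE)
  detected <- rbind(
    s1 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),   # persistent from t3
    s2 = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE), # transient
    s3 = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  calls <- detect_pseudogenes(effects[1:2, ], detected)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$snp_id, "s1")
  expect_equal(calls$first_detected, 3L)
  # stop in the final sense codon is not premature
  expect_equal(nrow(detect_pseudogenes(effects[3, ], detected)), 0L)
})

test_that("pseudogenes are assigned to the consistent strain", {
  model <- structure(list(species = "sp", n_strains = 2L,
                          f = c(0.7, 0.6, 0.5, 0.4)),
                     class = "strain_model")
  expect_equal(assign_pseudogene_to_strain(c(0.72, 0.58, 0.52, 0.38),
                                           model), "strain_1")
  expect_equal(assign_pseudogene_to_strain(c(0.28, 0.42, 0.48, 0.62),
                                           model), "strain_2")
  # consistent with both strains (f = 0.5 everywhere)
  model5 <- structure(list(n_strains = 2L, f = rep(0.5, 4)),
                      class = "strain_model")
  expect_equal(assign_pseudogene_to_strain(rep(0.5, 4), model5),
               "unassigned")
  # consistent with neither
  expect_equal(assign_pseudogene_to_strain(rep(1, 4), model), "unassigned")
  one <- structure(list(n_strains = 1L), class = "strain_model")
  expect_error(assign_pseudogene_to_strain(rep(1, 4), one), "two-strain")
})

test_that("Nei-Gojobori sites sum to 3 per sense codon", {
  gg <- generate_genes(n_genes = 4, length_codons = 25, seed = 13)
  sites <- ng_site_counts(gg$genes, gg$genome)
  # 24 sense codons per gene (terminal stop excluded)
  expect_equal(sites$per_gene$n_codons, rep(24L, 4))
  expect_equal(sites$per_gene$N_sites + sites$per_gene$S_sites,
               rep(3 * 24, 4), tolerance = 1e-9)
  # TTT has exactly one third of a synonymous site (position 3 -> TTC)
  genome <- Biostrings::DNAStringSet("ATGTTTTAA")
  names(genome) <- "gx"
  g1 <- data.frame(gene_id = "g", genome_id = "gx", start = 1L, end = 9L,
                   strand = "+", complete = TRUE, stringsAsFactors = FALSE)
  s <- ng_site_counts(g1, genome)
  # codons ATG (0 syn) + TTT (1/3 syn)
  expect_equal(s$S_sites, 1 / 3, tolerance = 1e-9)
  expect_equal(s$N_sites + s$S_sites, 6)
})

test_that("pN/pS is ~1 under neutral substitution and 0 for all-synonymous", {
  gg <- generate_genes(n_genes = 20, length_codons = 60, seed = 21)
  genes <- gg$genes
  genome <- gg$genome
  # neutral oracle: uniform random single-nucleotide substitutions at
  # uniformly random coding positions
  set.seed(31)
  n_sub <- 6000
  gi <- sample(nrow(genes), n_sub, replace = TRUE)
  snps <- do.call(rbind, lapply(seq_len(n_sub), function(k) {
    g <- genes[gi[k], ]
    pos <- sample(seq(g$start, g$end - 3L), 1L)  # skip terminal stop
    ref <- as.character(Biostrings::subseq(genome[[g$genome_id]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    data.frame(snp_id = paste0("n", k), genome_id = g$genome_id,
               position = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }))
  effects <- classify_snp_effects(snps, genes, genome)
  res <- compute_pnps(effects, genes, genome)
  expect_false(res$undefined)
  expect_gt(res$pnps, 0.9)
  expect_lt(res$pnps, 1.1)
  # an all-synonymous observed set has pN/pS = 0
  syn_only <- effects[effects$class == "synonymous", ]
  res0 <- compute_pnps(syn_only, genes, genome)
  expect_equal(res0$pnps, 0)
  expect_error(compute_pnps(effects[0, ], genes, genome), "no SNP")
})

test_that("category enrichment uses the exact binomial upper tail", {
  fr <- c(catA = 0.1, catB = 0.9)
  res <- category_enrichment(c(catA = 5L, catB = 5L), fr, total = 10L)
  pA <- res$p_value[res$category == "catA"]
  expect_equal(pA, 0.001634937, tolerance = 1e-6)
  expect_equal(res$enrichment_score[res$category == "catA"], 1 / pA)
  # zero observed -> p = 1, score 1
  res0 <- category_enrichment(c(catA = 0L), fr["catA"], total = 10L)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$enrichment_score, 1)
  # observed equal to expectation at large n -> p near 0.5
  resm <- category_enrichment(c(catA = 100L), fr["catA"], total = 1000L)
  expect_equal(resm$p_value, 0.5154177, tolerance = 1e-6)
  expect_error(category_enrichment(c(z = 1L), c(z = 0), total = 10L),
               "zero genome fraction")
})

test_that("enrichment p-values are uniform under random SNP placement", {
  gg <- generate_genes(n_genes = 12, length_codons = 40, seed = 5)
  fr <- category_fractions(gg$genes)
  set.seed(6)
  ps <- replicate(400, {
    # place SNPs uniformly over the coding genome, count per category
    lens <- gg$genes$end - gg$genes$start + 1L
    cat_draw <- sample(gg$genes$category, 60, replace = TRUE,
                       prob = lens / sum(lens))
    cnt <- table(factor(cat_draw, levels = names(fr)))
    res <- category_enrichment(
      setNames(as.integer(cnt), names(fr)), fr, total = 60L)
    res$p_value[res$category == names(fr)[1]]
  })
  # discrete uniformity: P(p <= x) <= x for the valid test, and the mean
  # of a uniform-ish p should be near 0.5 (binomial discreteness shifts
  # it slightly above)
  expect_gt(mean(ps < 0.25), 0.10)
  expect_lt(mean(ps < 0.25), 0.40)
  expect_gt(mean(ps), 0.45)
})

test_that("divergence time follows the molecular clock constants", {
  res <- divergence_time(1, divergence_params(mu = 1e-8, L = 1e6, g = 100))
  expect_equal(res$generations, 100)
  expect_equal(res$years, 1)
  expect_equal(divergence_time(0)$generations, 0)
  expect_equal(divergence_time(186)$years, 186)  # ~100s of years
  expect_error(divergence_params(mu = 0), "parameters")
})
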