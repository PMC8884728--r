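# Small fixtures shared across test files; everything is built in code.

# a minimal FreeBayes-style VCF with the given data lines
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"ref obs\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(header, lines), path)
  path
}

# long-format SNP records for filter_snps: one site observed at all time
# points, with per-time alternate counts and quality/depth
make_site_records <- function(genome, pos, ref, alt, alt_counts, depths,
                              qual = 50, n_alts = 1L) {
  n <- length(alt_counts)
  data.frame(
    genome_id = genome, position = pos, ref = ref, alt = alt,
    time_index = seq_len(n) - 1L, qual = qual, depth = depths,
    alt_count = alt_counts, ref_count = depths - alt_counts,
    n_alts_at_site = n_alts,
    is_indel = nchar(ref) != 1L | nchar(alt) != 1L,
    stringsAsFactors = FALSE
  )
}

# an identifiable two-strain synthetic community and its observations
make_recovery_fixture <- function(seed = 11, depth = 100, n_species = 5,
                                  n_diff = 20, n_shared = 15) {
  cfg <- truth_config(n_diff_snps = n_diff, n_shared_snps = n_shared,
                      f_bounds = c(0.1, 0.85))
  truth <- generate_truth(1, n_species, seed = seed, config = cfg)[[1]]
  obs <- observe_snps(truth, depth_model(depth), seed = seed + 1000)
  list(truth = truth, obs = obs)
}

subset_species <- function(obs, sp) {
  sel <- obs$meta$species == sp
  structure(list(freq = obs$freq[sel, , drop = FALSE],
                 depth = obs$depth[sel, , drop = FALSE],
                 meta = obs$meta[sel, , drop = FALSE]),
            class = "snp_trajectories")
}
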