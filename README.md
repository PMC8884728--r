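# straindyn

Strain-resolved eco-evolutionary analysis of serially passaged microbial
communities.

When a natural microbial community is propagated in the laboratory for
hundreds of generations and deep-sequenced along the way, the allele
frequencies of the SNPs inside each reference genome trace the hidden
dynamics of coexisting *strains* — genotypes a handful to thousands of
SNPs apart. `straindyn` turns those SNP trajectories into strain models
and then asks the central ecological question: do community interactions
act at the level of species, or of strains?

The package provides:

* **Variant QC** — FreeBayes-style VCF parsing, biallelic/quality/depth
  filters, the detection-persistence rule, and coverage-anomaly flags for
  read-stealing suspects.
* **Strain inference** — dynamic-time-warping k-means clustering of
  major-allele frequency trajectories, cluster acceptance rules
  (merge distance 0.15, fixation threshold 0.9), depth-weighted strain
  frequency estimation, and strain-level abundance tables. At most two
  strains per species are claimed, which is what eight noisy time points
  can support.
* **Dynamical statistics** — strain–strain coupling (|Pearson r|, with a
  decoupling threshold at 0.4), species-vs-strain correlation comparison,
  a gamma-sampling null for interaction detection, a strain-label
  permutation null, co-occurrence variability across taxonomic levels,
  eco-evolutionary influence, and coupling-versus-genetic-distance
  curves.
* **Genomics of strain differentiation** — codon-level SNP effect calls,
  pseudogene (premature stop) detection with strain assignment,
  Nei–Gojobori pN/pS, binomial category enrichment, and molecular-clock
  divergence times (1 SNP ≈ 100 generations ≈ 1 year for wild soil
  bacteria).
* **Consumer-resource models** — two minimal serial-dilution models with
  growth `dN_a/dt = N_a Σ_i C_ai R_i` and depletion
  `dR_i/dt = −R_i Σ_a C_ai N_a`, consumption vectors on the unit simplex,
  in which conspecific strains either differ by a competitive distance D
  (strain-specific interactions) or are identical with neutral drift
  (species-specific interactions). A single statistic — the fraction of
  species pairs whose best interspecific *strain* correlation beats the
  *species* correlation — cleanly separates the two hypotheses.
* **A synthetic-data generator** for every stage, so the whole pipeline
  is testable without any sequencing data.

## Worked example

Simulate a ground-truth community, observe its SNPs through binomial
read sampling, and recover the strains:

```r
library(straindyn)

cfg   <- truth_config(n_diff_snps = 20, n_shared_snps = 15,
                      f_bounds = c(0.1, 0.85))
truth <- generate_truth(n_communities = 1, n_species = 5, seed = 11,
                        config = cfg)[[1]]
obs   <- observe_snps(truth, depth_model(mean_depth = 100), seed = 1011)

sel <- obs$meta$species == "C01_sp01"
sub <- list(freq = obs$freq[sel, ], depth = obs$depth[sel, ],
            meta = obs$meta[sel, ])
model <- select_strain_model(sub, seed = 3)
model
#> strain_model for C01_sp01: 2 strain(s); 20 differentiating, 15 shared, 0 unassigned SNPs

round(model$f, 3)
#> [1] 0.539 0.559 0.543 0.539 0.547 0.602 0.566 0.629
round(truth$strain_freq[1, ], 3)
#> [1] 0.538 0.584 0.537 0.540 0.564 0.600 0.568 0.605
```

The model found both strains, the 20 differentiating SNPs (the genetic
distance between the strains), the 15 shared fixed SNPs, and a strain-1
frequency trajectory within ~0.01 of the truth. A strain pair 186 SNPs
apart corresponds to roughly 186 years of divergence:

```r
divergence_time(186)
#> $generations
#> [1] 18600
#> $years
#> [1] 186
```

And the two consumer-resource worlds are told apart by one number (a
desk-scale version; the full default scenario uses 50 species, 30
resources and 400 burn-in cycles):

```r
sc  <- crm_scenario(n_species = 12, n_resources = 15, n_communities = 6,
                    max_cycles = 150, seed = 38)
fraction_strain_exceeds_species(serial_passage(sc))$fraction
#> [1] 0.9119318

sc2 <- crm_scenario(n_species = 12, n_resources = 15, n_communities = 6,
                    max_cycles = 150, hypothesis = "species_identical",
                    seed = 38)
fraction_strain_exceeds_species(serial_passage(sc2))$fraction
#> [1] 0.2122186
```

With strain-specific consumption rates, the best strain pair beats the
species pair in most comparisons; with ecologically identical strains and
neutral drift it rarely does — most strain pairs have fixed by sampling
time, and a fixed pair's best strain correlation can never strictly
exceed its species correlation. (This desk-scale version runs in
seconds; at the full default scenario the fractions settle near 0.8 and
0.2.)

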