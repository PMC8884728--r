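---
title: "Resolving strain-level dynamics and interactions in passaged microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving strain-level dynamics and interactions in passaged microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straindyn)
```

## The scientific problem

Natural microbial communities carry genotypic variants of the same species
— strains — that may differ by anywhere from one to tens of thousands of
SNPs. When such a community is domesticated in the laboratory and serially
passaged for hundreds of generations, deep metagenomic sequencing lets us
follow every polymorphic site through time. Two questions drive this
package:

1. **Strain inference.** Can the allele-frequency trajectories of the SNPs
   detected within one reference genome be decomposed into a small number
   of linked haplotypes (strains), and with what frequencies do those
   strains wax and wane?
2. **Level of interaction.** Are the ecological interactions that shape
   community dynamics conserved at the species level, or do conspecific
   strains interact with the rest of the community in distinct,
   strain-specific ways?

`straindyn` implements the full analysis chain: SNP quality/persistence
filtering, trajectory clustering into strain models, strain abundance
estimation, correlation statistics with their null models, genomic
characterization of strain differences, and the pair of minimal
consumer-resource models that discriminate the two interaction hypotheses
in silico.

## Serial passage and the generation clock

A community diluted 1:D at each transfer must double `log2(D)` times to
regrow, so each cycle contributes `log2(D)` generations
(`generations_elapsed()`). At the standard dilution of 1:100 this is 6.64
generations per transfer; 46 transfers exceed 300 generations. With eight
metagenomic samples over ~298 generations, dynamics finer than ~37
generations are unresolvable — all correlation statistics in the package
operate on these eight-point trajectories, and their sampling noise is
part of every null model.

## SNP filtering

Variant records (FreeBayes-style VCFs, read with `read_snp_vcf()`) pass
through `filter_snps()`:

* biallelic SNPs only (sites with two alternates are rejected);
* Phred quality ≥ 20 and local read depth ≥ 10 at first detection — depth
  10 makes 10% the least count of an allele frequency estimate;
* persistence: once detected, a SNP must be re-detected at every later
  time point, or until its species' abundance reaches zero. This guards
  against sequencing and mapping artifacts, which do not recur
  systematically;
* the major allele (reference or alternate, whichever is more frequent) is
  fixed **at first detection** and followed thereafter, so a trajectory
  crossing 0.5 does not flip direction.

Genes with anomalous coverage (below half, or above three times, the
sample median — strict inequalities, read literally from the filter's
definition) are flagged by `flag_anomalous_genes()` so their SNPs can be
excluded as read-stealing suspects.

## Strain inference

Allele-frequency trajectories of the SNPs in one species are clustered
with a k-means algorithm that uses dynamic time warping (`dtw_distance()`,
full DP alignment, local cost `|a_i − b_j|`) as the assignment distance.
Because every series shares one time grid, centroids are updated as
pointwise means; DTW serves only to absorb small temporal misalignments
during assignment. Ten random restarts are used and the best fit by
inertia kept, under a caller-supplied seed.

`select_strain_model()` fits one, two and three clusters and applies the
acceptance rules:

* a clustering is rejected when two of its centroids lie within a mean
  pointwise distance of 0.15 — such clusters are statistically
  indistinguishable, which in practice always eliminates the third
  cluster;
* a cluster whose centroid exceeds 0.9 at every time point is a set of
  *shared* SNPs: fixed in both strains, differentiating them jointly from
  the reference isolate;
* a remaining non-fixed cluster is the *differentiating* cluster — direct
  evidence of two coexisting strains; its size is the genetic distance
  between them;
* "loose" unclustered SNPs are detected as outliers whose assignment
  distance exceeds 1.5 times the 95th percentile of within-cluster
  distances. The plain 95th-percentile rule would mechanically label the
  top 5% of any clean clustering as outliers, so the Tukey-style fence is
  used; detached SNPs with mean frequency above 0.9 join the shared set
  (by the pigeonhole argument they must sit in both strains), the rest
  stay unassigned.

At most two strains are ever reported: with eight time points and
coverage-limited frequency noise, a third haplotype is not statistically
separable, and the model selection reflects that honestly.

The strain-1 frequency trajectory is the depth-weighted mean of the
differentiating cluster's allele frequencies
(`estimate_strain_frequencies()`); the strain above 0.5 at the first time
point is the major strain. `strain_abundance_table()` multiplies
frequencies by species relative abundances, partitioning each species row
of an abundance table into two strain rows that sum exactly to it.

An alternative UPGMA backend (average-linkage clustering on Euclidean
distances between rows of the SNP-trajectory correlation matrix) is
provided as a robustness check and gives the same strain counts on the
synthetic fixtures.

## Correlation statistics and null models

**Strain–strain coupling** (`strain_coupling()`) is the magnitude of the
Pearson correlation between the abundance trajectories of two conspecific
strains; pairs below 0.4 — the inflection point of the empirical coupling
distribution — are *decoupled*. Magnitude is used because the statistic
measures the extent, not the direction, of covariation; Spearman is
available and yields the same labels away from the threshold.
`coupling_distance_curve()` summarizes coupling against genetic distance
in log-spaced bins (a binned moving average stands in for figure-level
LOESS smoothing).

**Species vs strain correlations** (`interspecies_correlations()`): for a
species pair, the species-level statistic is the correlation magnitude of
the two species trajectories; the strain-level statistic is the *maximum*
magnitude over the (up to four) interspecific strain pairs. Conspecific
pairs are never included. Because a maximum over four noisy correlations
is upward-biased, every use of this statistic is paired with a null:

* **Gamma-sampling null** (`gamma_null_correlations()`): abundances of
  non-interacting members are modeled as independent gamma draws with each
  member's observed mean and variance (shape `mean²/var`), renormalized to
  the simplex each time point — the empirical form of abundance
  fluctuations in microbial communities. Pooled pairwise correlation
  magnitudes over 1000 simulated communities form the reference
  distribution; `detect_interactions()` calls an edge at `p < 0.05`
  without further multiple-testing correction, because the null is built
  from whole communities and already carries the comparison structure.
  (When individual pair correlations are reported on their own, outside
  this detection path, their p-values should be Benjamini–Hochberg
  adjusted with `stats::p.adjust`.) Network density is reported as edges
  per node (interaction partners per member, deliberately not edges per
  possible edge).
* **Strain-label permutation null** (`strain_label_permutation_test()`):
  strain labels are shuffled across species, coalescing unrelated strains
  into mock species (trajectory = sum of members), preserving both the
  number of comparisons and the data; the fraction F of species pairs
  where the best strain pair beats the species pair is recomputed per
  permutation. Empirical p-values use (k+1)/(n+1) smoothing throughout.

**Compositional variability** (`cooccurrence_variability()`) measures, at
each taxonomic level, how often two members that differ at that level but
share the parent level co-occur in a community, normalized by the same
statistic under member-label shuffles that preserve group count and
sizes. Co-occurrence means joint presence (abundance > 0) in the same
community at the analyzed time point.

**Eco-evolutionary influence** (`ecoevo_influence()`) is the correlation
between a species' abundance trajectory and its major strain's frequency
trajectory; the null shuffles the species–strain pairing across the whole
population and species above the null's 95th percentile are flagged.
Signed correlation is the default (an abundance rise driven by a strain
sweep is a signed prediction); magnitudes are available via `absolute =
TRUE`.

## Genomic differentiation of strains

`classify_snp_effect()` locates each SNP in the gene table and evaluates
the codon substitution on the coding strand under the standard genetic
code (minus-strand genes are reverse-complemented; the VCF alleles are
plus-strand). `detect_pseudogenes()` calls a gene pseudogenized when a
SNP introduces a premature stop (not in the final sense codon) that
satisfies the same persistence rule as every other SNP, and
`assign_pseudogene_to_strain()` attributes the call to whichever strain's
frequency trajectory matches the stop allele's trajectory within a
tolerance of 0.1 — the allele-frequency least count implied by the depth
filter; matches to both or neither stay unassigned.

`compute_pnps()` uses Nei–Gojobori fractional site counting: each codon
position contributes the synonymous fraction of its three possible
substitutions to the S-site count, the rest to N-sites (N + S = 3 per
sense codon; terminal stops are excluded; stop-gains count as
nonsynonymous on both the site and the observation side, which keeps the
neutral expectation at exactly 1). pN/pS is a polymorphism ratio, so no
Jukes–Cantor multiple-hit correction is applied. `category_enrichment()`
scores functional categories by the inverse upper-tail binomial
probability of the observed SNP count, with success rate equal to the
category's share of the total annotated coding length (accounting for
both gene number and gene length); the tail is one-sided because
enrichment, not depletion, is the question.

`divergence_time()` converts a strain pair's SNP count into time with the
molecular-clock argument that a population's neutral divergence rate
equals the per-individual mutation rate: at 1e-8 mutations/nt/generation
over a ~1e6 bp core genome, one SNP per ~100 generations, or about one
per year at ~100 generations/year for wild soil bacteria.

## The synthetic-data generator

`generate_truth()` builds ground-truth communities with the statistical
structure the analysis assumes: 10 communities, ~10 species, 8 time
points, two strains per species. Species abundances fluctuate as
independent gamma draws around their mean with a temporal CV of 0.31 (the
median observed for species in communities of this kind), renormalized
per time point. Strain frequencies follow a constant, random-walk
(sd 0.05/step) or logistic-sweep process; the sweep emulates the
one-strain-displaces-the-other dynamics seen in real communities and is
pure test scaffolding, since no generative model of the real dynamics is
claimed. `observe_snps()` overlays measurement: depths are Poisson around
the configured mean and observed frequencies are binomial draws at those
depths — the coverage-dependent noise that limits strain resolution.
Shared SNPs are planted at a true frequency of 0.98 so that estimator
noise, not construction, decides whether they look fixed.

What the generator does *not* emulate: read-level errors, mapping bias and
read stealing between similar genomes, linkage breakdown by
recombination, more than two strains per species, and non-stationary
depth. Passing recovery tests therefore demonstrates correctness of the
inference chain under its own model assumptions, not robustness to every
artifact of real sequencing data.

Recovery tests require an *identifiable* truth: a strain whose frequency
wanders into the fixed band (> 0.9) is genuinely indistinguishable from a
shared SNP cluster, so validation fixtures clip the true frequency to
\[0.1, 0.85\] (`f_bounds`). On such fixtures, with depth ≥ 100 and ≥ 20
SNPs per cluster, cluster membership is recovered exactly and the
inferred frequency trajectory has RMSE < 0.05.

`generate_genes()` writes complete synthetic ORFs (start codon, no
internal stop, terminal stop) on both strands of a synthetic contig with
category labels, for exercising the effect-classification and pN/pS
machinery.

## The consumer-resource models

Two minimal batch-culture models ask which interaction structure
reproduces the observed dominance of strain-level correlations
(`crm_scenario()`, `serial_passage()`):

\[
\frac{dN_\alpha}{dt} = N_\alpha \sum_i C_{\alpha i} R_i,
\qquad
\frac{dR_i}{dt} = -R_i \sum_\alpha C_{\alpha i} N_\alpha
\]

with unit biomass yield, so total biomass plus resources is conserved
within a cycle (checked to 1e-6 relative; the right-hand side is compiled
C code under `deSolve::lsodar`, integrated until total resources fall
below 1e-6). Each of 10 communities holds 50 species × 2 strains
competing for 30 resources. Consumption vectors are sampled uniformly
from the unit simplex — the fixed enzyme-budget assumption that permits
high diversity. Each cycle supplies resources at equal mean proportions
(total 1) perturbed by Gaussian noise, dilutes biomass 1:100, and
integrates to depletion.

* **Hypothesis 1 (strain-specific):** the second strain of each species
  sits at Euclidean distance D from its conspecific on the simplex, with
  D drawn as 15% at 0.01, 20% at 0.1, 50% at 0.3, 15% at 1.0 — a rough
  mirror of the broad genetic-distance distribution between real strains.
  `conspecific_at_distance()` takes a random tangent-space direction,
  rejecting draws that leave the simplex; near-maximal D admits almost no
  feasible directions, so after 200 rejections the step is taken toward
  the vertex of the least-used resource, the least constrained choice.
* **Hypothesis 2 (species-identical):** D = 0 and within-species
  frequencies change only by neutral drift (`apply_drift()`): a Gaussian
  increment per generation with variance `v·N` (N the species' relative
  abundance; the population-genetic `v/N` scaling is selectable but
  diverges exactly for the rare species where it would act, so the
  literal reading is the default). Increments for the `log2(100)`
  generations of a cycle are drawn in one step, and drift is *absorbing*:
  once a strain's biomass is zero the frequency is fixed — extinct
  lineages are not resurrected by noise. `v = 0.03` is calibrated so that
  a polymorphic pair's frequency moves by roughly 0.1 per sampling
  interval, the scale of strain-frequency changes observed between
  successive metagenomic samples, which is how the coefficient is meant
  to be fit from data.

Numerical conventions worth stating. The printed supply-noise dispersion
of 0.05 is interpreted as the standard deviation of the additive noise on
each supplied proportion: as a variance it would imply perturbations
seven times the mean proportion of 1/30, zeroing half the resources every
transfer — not "minor variations" around a common environment — and
produces communities that never stop losing species. At sd 0.05 the
per-species temporal CV of the simulated communities (~30%) matches the
experimental scale. Negative supplies are clipped at zero and proportions
renormalized so total supply stays one biomass unit. Strains below 1e-12
biomass at the end of a cycle are set to zero.

Communities are passaged for up to 400 burn-in cycles (~2650 generations);
the strict L1 stability rule (< 1e-3 for 5 consecutive cycles) can only
trigger in noise-free runs, so under stochastic supply the full burn-in is
used — by then competitive exclusion has settled the community at 36–40
coexisting species — and a warning notes that composition still fluctuates,
as it must. Eight samples are then recorded five cycles apart, the
in-silico analogue of metagenomic sampling every ~5–6 transfers.

`fraction_strain_exceeds_species()` reuses the observational statistic
unchanged on the recorded trajectories: for every surviving species pair,
does the best interspecific strain correlation beat the species
correlation? Under strain-specific interactions the answer is yes for
roughly 78–84% of pairs; under species-identical interactions most
species have fixed one strain by sampling time (a fixed pair's best
strain correlation *equals* its species correlation and cannot strictly
exceed it), and the fraction falls to roughly 19%. Fixation is therefore
not an artifact but the mechanism by which the neutral model fails to
reproduce the data. Changing the number of resources (e.g. 20 vs 30)
leaves the ordering of the two hypotheses unchanged, and conspecific
coupling in hypothesis 1 declines monotonically with D over the
well-populated part of the mixture — at equilibrium the D = 1.0 pairs
have typically lost one strain to competitive exclusion, which is itself
the strongest form of decoupling.

## Problem sizes used in validation

The test suite validates the statistics at sizes chosen to make every
stochastic check well-conditioned: recovery fixtures use 5 species × 35
SNPs at depth 100–120; calibration suites use a few hundred null
replicates; the neutral pN/pS simulation places 4000–6000 substitutions
in 15–20 synthetic genes; the consumer-resource discrimination runs the
full default scenario (10 communities, 100 strains, 30 resources) over
five seeds per hypothesis, and desk-scale variants (10–15 resources,
60–150 cycles) for qualitative properties. `scripts/acceptance.R`
recomputes the two headline fractions from scratch at the full default
scenario.

## Known limitations

* At most two strains per species are resolvable; true multi-strain
  populations will be folded into the closest two-haplotype description.
* The persistence rule assumes dense, regular sampling; with sparse time
  points it is conservative and may discard genuine transient variants.
* The gamma null treats members as independent given their marginal
  moments; compositional closure is handled only through renormalization,
  not through a logistic-normal or CLR-based model.
* The consumer-resource models omit cross-feeding, variable yields,
  chemostat dynamics and evolution of consumption rates; they are
  deliberately minimal discriminators, not fitted models of the system.
* Pseudogene detection sees only premature stops from SNPs; frameshifts
  from indels and gene gains/losses in the flexible genome are out of
  scope (indels are parsed and counted but not interpreted).
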