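#' Coupling configuration
#'
#' @param threshold Coupling below this is "decoupled" (default 0.4, the
#'   inflection point of the empirical coupling distribution).
#' @param kind Correlation flavour: `"pearson"` (default) or `"spearman"`.
#' @return A `coupling_config` list.
#' @export
coupling_config <- function(threshold = 0.4,
                            kind = c("pearson", "spearman")) {
  stopifnot(threshold > 0, threshold < 1)
  structure(list(threshold = threshold, kind = match.arg(kind)),
            class = "coupling_config")
}

#' Estimate the decoupling threshold from a coupling distribution
#'
#' The empirical distribution of conspecific couplings is bimodal: a mode
#' of coupled pairs near 1 and a mode of decoupled pairs at low values.
#' This helper smooths the distribution with a Gaussian kernel density
#' estimate and returns the location of its minimum between the two
#' largest modes — the inflection point used to classify pairs. Falls
#' back to `default` when the distribution has no interior minimum (e.g.
#' unimodal null data).
#'
#' @param couplings Coupling values in \[0,1\] (NAs dropped).
#' @param default Threshold returned when no interior minimum exists.
#' @return Estimated threshold in (0,1).
#' @export
estimate_coupling_threshold <- function(couplings, default = 0.4) {
  x <- couplings[is.finite(couplings)]
  if (length(x) < 10) return(default)
  d <- stats::density(x, from = 0, to = 1)
  y <- d$y
  n <- length(y)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] &
                y[2:(n - 1)] < y[3:n], FALSE)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] > y[3:n], FALSE)
  modes <- which(is_max)
  # only count modes with real mass (>= 10% of the tallest peak)
  modes <- modes[y[modes] >= 0.1 * max(y[modes])]
  if (length(modes) < 2) return(default)
  top2 <- sort(modes[order(-y[modes])][1:2])
  valley <- which(is_min)
  valley <- valley[valley > top2[1] & valley < top2[2]]
  if (!length(valley)) return(default)
  v <- valley[which.min(y[valley])]
  # the dip must be pronounced, not a kernel wiggle
  if (y[v] > 0.8 * min(y[top2])) return(default)
  d$x[v]
}

abs_cor <- function(a, b, kind = "pearson") {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  abs(stats::cor(a[ok], b[ok], method = kind))
}

#' Strain-strain coupling of a conspecific pair
#'
#' Coupling is the magnitude (absolute value) of the correlation between
#' the two strains' abundance trajectories; the sign is ignored because the
#' statistic measures the extent of covariance, not its direction. Pairs
#' with coupling below the threshold are "decoupled". Constant
#' trajectories give an undefined (NA) coupling, flagged in the label.
#'
#' @param strain_a,strain_b Abundance trajectories of the two conspecific
#'   strains (>= 3 finite shared time points).
#' @param config A [coupling_config()].
#' @return List with `coupling` (in \[0,1\] or NA) and `label`
#'   (`"coupled"`, `"decoupled"`, `"undefined"`).
#' @export
strain_coupling <- function(strain_a, strain_b, config = coupling_config()) {
  r <- abs_cor(strain_a, strain_b, config$kind)
  label <- if (is.na(r)) "undefined"
  else if (r < config$threshold) "decoupled" else "coupled"
  list(coupling = r, label = label)
}

#' Species-level vs strain-level correlation for a species pair
#'
#' The species correlation is the magnitude of the correlation between the
#' two species' abundance trajectories. The strain correlation is the
#' highest magnitude among all interspecific strain pairs (up to four when
#' both species carry two strains); conspecific pairs are never compared.
#'
#' @param species_a,species_b Species abundance trajectories.
#' @param strains_a,strains_b Lists (or matrices, strains in rows) of the
#'   strain abundance trajectories of each species.
#' @param kind Correlation flavour.
#' @return List with `species_r`, `strain_r` (max interspecific magnitude),
#'   `strain_exceeds` flag.
#' @export
interspecies_correlations <- function(species_a, species_b, strains_a,
                                      strains_b, kind = "pearson") {
  as_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else
      if (is.list(x)) x else list(x)
  }
  sa <- as_list(strains_a)
  sb <- as_list(strains_b)
  if (!length(sa) || !length(sb)) stop("missing strain trajectories")
  species_r <- abs_cor(species_a, species_b, kind)
  strain_r <- max(unlist(lapply(sa, function(x) {
    lapply(sb, function(y) abs_cor(x, y, kind))
  })), na.rm = TRUE)
  if (!is.finite(strain_r)) strain_r <- NA_real_
  list(species_r = species_r, strain_r = strain_r,
       strain_exceeds = isTRUE(strain_r > species_r))
}

#' Gamma-sampling null distribution of pairwise correlations
#'
#' Simulates communities in which member abundances fluctuate independently
#' (no interactions): at each time point every member's abundance is drawn
#' from a gamma distribution with its observed mean and variance (shape
#' `beta_i = mean_i^2 / var_i`, rate `beta_i / mean_i`), the draws are
#' renormalized to relative abundances, and all pairwise correlation
#' magnitudes are pooled across `n_sims` simulated communities into one
#' null distribution.
#'
#' @param means,vars Observed mean and variance of each member's relative
#'   abundance (> 0).
#' @param n_times Number of time points per simulated trajectory.
#' @param n_sims Number of simulated communities (default 1000).
#' @param seed Integer seed.
#' @param kind Correlation flavour.
#' @return A `null_distribution`: list with `values` (pooled |r|),
#'   `n_sims`.
#' @export
gamma_null_correlations <- function(means, vars, n_times = 8,
                                    n_sims = 1000, seed = 1,
                                    kind = "pearson") {
  if (any(means <= 0) || any(vars <= 0)) {
    stop("means and variances must be > 0")
  }
  n <- length(means)
  stopifnot(length(vars) == n, n >= 2)
  set.seed(seed)
  shape <- means^2 / vars
  rate <- shape / means
  vals <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    x <- matrix(stats::rgamma(n * n_times, shape = shape, rate = rate),
                nrow = n)
    x <- sweep(x, 2L, colSums(x), "/")
    cm <- abs(suppressWarnings(stats::cor(t(x), method = kind)))
    vals[[s]] <- cm[upper.tri(cm)]
  }
  structure(list(values = unlist(vals), n_sims = n_sims),
            class = "null_distribution")
}

#' Empirical p-value against a null distribution
#'
#' `(1 + # null >= observed) / (1 + n_null)`: add-one smoothing so p is
#' never exactly zero.
#'
#' @param observed Observed statistic(s).
#' @param null A `null_distribution` or numeric vector of null samples.
#' @return p-value(s).
#' @export
null_p_value <- function(observed, null) {
  values <- if (inherits(null, "null_distribution")) null$values else null
  if (!length(values)) stop("empty null distribution")
  vapply(observed, function(o) {
    (1 + sum(values >= o)) / (1 + length(values))
  }, numeric(1))
}

#' Detect interactions from observed correlations and a null
#'
#' An interaction is called "present" when the empirical p-value of the
#' observed correlation magnitude against the null is below `alpha`. No
#' additional multiple-testing correction is applied: the null distribution
#' is built from whole simulated communities and already reflects the
#' number of comparisons. Network density is reported as edges per node.
#'
#' @param pairs Data frame with columns `a`, `b` (node ids) and `r`
#'   (observed correlation magnitude; NA rows are excluded and counted in
#'   `n_undefined`).
#' @param null A `null_distribution` (e.g. [gamma_null_correlations()]).
#' @param alpha Significance level (default 0.05).
#' @param nodes Node set (default: all ids appearing in `pairs`).
#' @param level `"species"` or `"strain"` (annotation only).
#' @return An `interaction_network`: list with `edges` (data frame with
#'   `p`), `nodes`, `density`, `level`, `n_undefined`.
#' @export
detect_interactions <- function(pairs, null, alpha = 0.05, nodes = NULL,
                                level = c("species", "strain")) {
  level <- match.arg(level)
  if (is.null(nodes)) nodes <- unique(c(pairs$a, pairs$b))
  undefined <- !is.finite(pairs$r)
  ok <- pairs[!undefined, , drop = FALSE]
  ok$p <- null_p_value(ok$r, null)
  edges <- ok[ok$p < alpha, , drop = FALSE]
  structure(list(edges = edges, nodes = nodes,
                 density = nrow(edges) / length(nodes), level = level,
                 n_undefined = sum(undefined)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("%s-level interaction network: %d edges / %d nodes (density %.2f)\n",
              x$level, nrow(x$edges), length(x$nodes), x$density))
  invisible(x)
}

# F statistic: fraction of species pairs whose best interspecific strain
# correlation beats the species correlation. strains: matrix with rows =
# strain trajectories; species_of: species label per row.
fraction_strain_dominant <- function(strains, species_of, kind = "pearson") {
  sp <- unique(species_of)
  species_traj <- do.call(rbind, lapply(sp, function(s) {
    colSums(strains[species_of == s, , drop = FALSE])
  }))
  rownames(species_traj) <- sp
  wins <- 0L
  n <- 0L
  for (i in seq_along(sp)[-length(sp)]) {
    for (j in seq((i + 1L), length(sp))) {
      res <- interspecies_correlations(
        species_traj[i, ], species_traj[j, ],
        strains[species_of == sp[i], , drop = FALSE],
        strains[species_of == sp[j], , drop = FALSE], kind = kind)
      if (is.na(res$species_r) || is.na(res$strain_r)) next
      n <- n + 1L
      if (res$strain_r > res$species_r) wins <- wins + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  wins / n
}

#' Permutation test for the strain-dominance fraction
#'
#' The observed statistic F is the fraction of species pairs in which the
#' best interspecific strain correlation exceeds the species correlation.
#' The null shuffles strain labels across species (coalescing unrelated
#' strains into mock species, whose trajectory is the sum of the two
#' member strains), preserving the number of comparisons and the abundance
#' data, and recomputes F for each permutation.
#'
#' @param strains Matrix of strain abundance trajectories (strains in
#'   rows).
#' @param species_of Species label per strain (each species must have
#'   exactly two strains; >= 2 species).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param kind Correlation flavour.
#' @return List with `F_obs`, `null_mean`, `null_sd`, `p`, `null_F`.
#' @export
strain_label_permutation_test <- function(strains, species_of,
                                          n_perm = 1000, seed = 1,
                                          kind = "pearson") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  tab <- table(species_of)
  if (length(tab) < 2 || any(tab != 2)) {
    stop("need >= 2 species with exactly 2 strains each")
  }
  F_obs <- fraction_strain_dominant(strains, species_of, kind)
  set.seed(seed)
  null_F <- vapply(seq_len(n_perm), function(p) {
    fraction_strain_dominant(strains, sample(species_of), kind)
  }, numeric(1))
  null_F <- null_F[is.finite(null_F)]
  list(F_obs = F_obs, null_mean = mean(null_F), null_sd = stats::sd(null_F),
       p = (1 + sum(null_F >= F_obs)) / (1 + length(null_F)),
       null_F = null_F)
}

#' Compositional variability at one taxonomic level
#'
#' Members are partitioned into groups that differ at the requested level
#' but share the parent taxon one level above (e.g. at the species level:
#' groups of congeneric species). The observed statistic is the fraction
#' of within-group member pairs that co-occur (are both present) in at
#' least one community; it is normalized by the same statistic after
#' shuffling member labels across groups (preserving group count and
#' sizes), so 1 means "no more structured than random".
#'
#' @param presence Logical/0-1 matrix, communities x members (member ids as
#'   colnames).
#' @param lineage Data frame, one row per member, with the taxonomy columns
#'   (e.g. `family`, `genus`, `species`, `strain`).
#' @param level Column of `lineage` at which members differ.
#' @param parent Column one level above `level` that group members share.
#' @param n_shuffles Label shuffles for the null (default 1000).
#' @param seed Integer seed.
#' @return List with `observed`, `null_mean`, `normalized`.
#' @export
cooccurrence_variability <- function(presence, lineage, level, parent,
                                     n_shuffles = 1000, seed = 1) {
  presence <- as.matrix(presence) > 0
  groups <- split(seq_len(nrow(lineage)), lineage[[parent]])
  groups <- Filter(function(g) length(g) >= 2, groups)
  if (!length(groups)) stop("no groups of size >= 2 at level ", level)
  cooccur_frac <- function(members_idx) {
    tot <- 0L
    co <- 0L
    for (g in members_idx) {
      pr <- utils::combn(g, 2L)
      for (k in seq_len(ncol(pr))) {
        tot <- tot + 1L
        if (any(presence[, pr[1L, k]] & presence[, pr[2L, k]])) co <- co + 1L
      }
    }
    co / tot
  }
  observed <- cooccur_frac(groups)
  set.seed(seed)
  all_members <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  null <- vapply(seq_len(n_shuffles), function(s) {
    shuffled <- sample(all_members)
    regrouped <- split(shuffled, rep(seq_along(sizes), sizes))
    cooccur_frac(regrouped)
  }, numeric(1))
  null_mean <- mean(null)
  list(observed = observed, null_mean = null_mean,
       normalized = observed / null_mean)
}

#' Eco-evolutionary influence of strains on species
#'
#' For each species, the statistic is the correlation between its relative
#' abundance trajectory and the within-species frequency trajectory of its
#' major strain; a species is flagged "influential" when its statistic
#' exceeds the 95th percentile of a null built by shuffling the pairing
#' between species trajectories and major-strain trajectories across all
#' species (and communities). Signed correlation is the default; set
#' `absolute = TRUE` to use magnitudes.
#'
#' @param species_traj Matrix of species abundance trajectories (rows).
#' @param strain_freq Matrix of matched major-strain frequency trajectories
#'   (same row order).
#' @param n_shuffles Pairing shuffles (default 1000).
#' @param seed Integer seed.
#' @param absolute Use |r| instead of signed r.
#' @return List with `r` (per species), `null` (shuffled correlations),
#'   `cutoff` (95th percentile), `influential` (logical per species),
#'   `fraction_influential`.
#' @export
ecoevo_influence <- function(species_traj, strain_freq, n_shuffles = 1000,
                             seed = 1, absolute = FALSE) {
  species_traj <- as.matrix(species_traj)
  strain_freq <- as.matrix(strain_freq)
  stopifnot(nrow(species_traj) == nrow(strain_freq))
  if (nrow(species_traj) < 2L) {
    stop("need more than one species to build the pairing null")
  }
  stat <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(NA_real_)
    }
    r <- stats::cor(a[ok], b[ok])
    if (absolute) abs(r) else r
  }
  r <- vapply(seq_len(nrow(species_traj)), function(i) {
    stat(species_traj[i, ], strain_freq[i, ])
  }, numeric(1))
  set.seed(seed)
  n <- nrow(species_traj)
  null <- unlist(lapply(seq_len(n_shuffles), function(s) {
    perm <- sample(n)
    vapply(seq_len(n), function(i) {
      stat(species_traj[i, ], strain_freq[perm[i], ])
    }, numeric(1))
  }))
  null <- null[is.finite(null)]
  cutoff <- stats::quantile(null, 0.95, names = FALSE)
  influential <- !is.na(r) & r > cutoff
  list(r = r, null = null, cutoff = cutoff, influential = influential,
       fraction_influential = mean(influential[!is.na(r)]))
}

#' Binned moving average of coupling against genetic distance
#'
#' Log-spaced bins over the genetic-distance range; per-bin mean coupling
#' and pair count. Empty bins are omitted.
#'
#' @param distance Genetic distances (SNP counts, > 0) per strain pair.
#' @param coupling Coupling values per pair.
#' @param n_bins Number of log-spaced bins (default 10).
#' @return Data frame `bin_lo`, `bin_hi`, `mid`, `mean_coupling`, `n`.
#' @export
coupling_distance_curve <- function(distance, coupling, n_bins = 10) {
  stopifnot(length(distance) == length(coupling), length(distance) >= 1)
  ok <- is.finite(distance) & is.finite(coupling) & distance > 0
  distance <- distance[ok]
  coupling <- coupling[ok]
  lo <- min(distance)
  hi <- max(distance)
  if (lo == hi) {
    return(data.frame(bin_lo = lo, bin_hi = hi, mid = lo,
                      mean_coupling = mean(coupling),
                      n = length(coupling)))
  }
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  edges[1L] <- lo * (1 - 1e-12)
  edges[length(edges)] <- hi * (1 + 1e-12)
  bin <- findInterval(distance, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               mid = sqrt(edges[b] * edges[b + 1L]),
               mean_coupling = mean(coupling[sel]), n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}
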