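#' Dynamic time warping distance between two series
#'
#' Full dynamic-programming alignment with local cost `|a_i - b_j|`, steps
#' (i-1,j), (i,j-1), (i-1,j-1), and no warping window.
#'
#' @param a,b Numeric series (length >= 1, finite).
#' @return Non-negative accumulated alignment cost.
#' @export
dtw_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("series must have length >= 1")
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("series must be finite")
  }
  n <- length(a)
  m <- length(b)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  cost <- abs(outer(a, b, "-"))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- cost[i, j] +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Cluster allele-frequency trajectories with DTW k-means
#'
#' k-means-style alternation where assignment uses [dtw_distance()] to the
#' centroids and the centroid update is the pointwise mean of the member
#' trajectories (all series share one time grid, so no barycenter averaging
#' is needed). The best of `n_init` random restarts by inertia (sum of
#' squared assignment distances) is returned.
#'
#' @param trajectories Numeric matrix, series in rows. `NA`s are imputed to
#'   the row mean for clustering purposes.
#' @param k Number of clusters (1 <= k <= rows).
#' @param seed Integer seed controlling the restarts.
#' @param n_init Number of random restarts.
#' @param max_iter Iteration cap per restart.
#' @return List with `assignment` (integer vector), `centroids` (k x T
#'   matrix), `inertia`.
#' @export
cluster_trajectories <- function(trajectories, k, seed = 1, n_init = 10,
                                 max_iter = 50) {
  X <- as.matrix(trajectories)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(X)) stop("k exceeds the number of trajectories")
  # impute missing points with the row mean so DTW sees finite series
  for (i in seq_len(nrow(X))) {
    bad <- !is.finite(X[i, ])
    if (any(bad)) X[i, bad] <- mean(X[i, ], na.rm = TRUE)
  }
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    centroids <- X[sample(nrow(X), k), , drop = FALSE]
    assignment <- rep(0L, nrow(X))
    for (iter in seq_len(max_iter)) {
      d <- vapply(seq_len(k), function(j) {
        vapply(seq_len(nrow(X)), function(i) {
          dtw_distance(X[i, ], centroids[j, ])
        }, numeric(1))
      }, numeric(nrow(X)))
      d <- matrix(d, nrow = nrow(X))
      new_assign <- max.col(-d, ties.method = "first")
      if (identical(new_assign, assignment)) break
      assignment <- new_assign
      for (j in seq_len(k)) {
        members <- which(assignment == j)
        if (length(members)) {
          centroids[j, ] <- colMeans(X[members, , drop = FALSE])
        }
      }
    }
    inertia <- sum(vapply(seq_len(nrow(X)), function(i) {
      d[i, assignment[i]]^2
    }, numeric(1)))
    if (is.null(best) || inertia < best$inertia) {
      best <- list(assignment = assignment, centroids = centroids,
                   inertia = inertia)
    }
  }
  best
}

# UPGMA backend: average-linkage hierarchical clustering on the Euclidean
# distance between rows of the SNP-trajectory correlation matrix, cut at k.
upgma_cluster <- function(X, k) {
  if (nrow(X) <= k) {
    return(list(assignment = seq_len(nrow(X)), centroids = X,
                inertia = 0))
  }
  cors <- suppressWarnings(stats::cor(t(X)))
  cors[!is.finite(cors)] <- 0
  hc <- stats::hclust(stats::dist(cors), method = "average")
  assignment <- stats::cutree(hc, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(X[assignment == j, , drop = FALSE])
  }))
  list(assignment = assignment, centroids = centroids, inertia = NA_real_)
}

#' Strain-model selection configuration
#'
#' @param max_clusters Largest k tried (default 3).
#' @param merge_distance Centroid pairs closer than this (mean pointwise
#'   distance) are considered indistinguishable and merged (default 0.15).
#' @param fixed_threshold Centroids above this at every time point are
#'   "nearly fixed" and represent SNPs shared by both strains
#'   (default 0.9).
#' @param min_cluster_coverage Warn when the top two clusters hold less
#'   than this fraction of the species' SNPs (default 0.8).
#' @param backend `"dtw-kmeans"` (default) or `"upgma"`.
#' @param n_init Restarts for the k-means backend.
#' @return A `strain_model_config` list.
#' @export
strain_model_config <- function(max_clusters = 3, merge_distance = 0.15,
                                fixed_threshold = 0.9,
                                min_cluster_coverage = 0.8,
                                backend = c("dtw-kmeans", "upgma"),
                                n_init = 10) {
  stopifnot(fixed_threshold > 0, fixed_threshold < 1, merge_distance > 0)
  structure(list(max_clusters = max_clusters,
                 merge_distance = merge_distance,
                 fixed_threshold = fixed_threshold,
                 min_cluster_coverage = min_cluster_coverage,
                 backend = match.arg(backend), n_init = n_init),
            class = "strain_model_config")
}

# mean pointwise distance between two centroids on the shared time grid
centroid_distance <- function(a, b) mean(abs(a - b))

#' Select a strain model for one species from its SNP trajectories
#'
#' Clusters the major-allele frequency trajectories for k = 1..3 and
#' applies the acceptance rules: a k is rejected whenever two of its
#' centroids are closer than `merge_distance` (visually indistinguishable
#' clusters). In the accepted clustering, clusters whose centroid exceeds
#' `fixed_threshold` at every time point are "shared" SNPs (fixed in both
#' strains, differentiating them from the reference genome); a remaining
#' non-fixed cluster is the strain-differentiating cluster, and its
#' presence implies two coexisting strains. Outlier SNPs (assignment
#' distance above the 95th percentile of within-cluster distances) are
#' appended to the shared set when their mean frequency is above
#' `fixed_threshold` and left unassigned otherwise. At most two strains are
#' ever reported.
#'
#' @param trajectories A `snp_trajectories` object (or a list with `freq`
#'   and `depth` matrices) for one species.
#' @param config A [strain_model_config()].
#' @param seed Integer seed for the clustering restarts.
#' @return A `strain_model`: list with `species`, `n_strains`,
#'   `differentiating`, `shared`, `unassigned` (SNP id vectors), `f`
#'   (strain-1 frequency trajectory, `NULL` for one-strain models),
#'   `major_strain`, `genetic_distance` (count of differentiating SNPs).
#' @export
select_strain_model <- function(trajectories, config = strain_model_config(),
                                seed = 1) {
  freq <- trajectories$freq
  depth <- trajectories$depth
  species <- if (!is.null(trajectories$meta) &&
                 nrow(trajectories$meta)) {
    trajectories$meta$species[1L]
  } else {
    NA_character_
  }
  ids <- rownames(freq) %||% sprintf("snp_%d", seq_len(nrow(freq)))
  rownames(freq) <- rownames(depth) <- ids
  one_strain <- function(shared = character(0), unassigned = character(0)) {
    structure(list(species = species, n_strains = 1L,
                   differentiating = character(0), shared = shared,
                   unassigned = unassigned, f = NULL,
                   major_strain = NA_character_, genetic_distance = 0L),
              class = "strain_model")
  }
  if (nrow(freq) == 0L) return(one_strain())
  X <- freq
  for (i in seq_len(nrow(X))) {
    bad <- !is.finite(X[i, ])
    if (any(bad)) X[i, bad] <- mean(X[i, ], na.rm = TRUE)
  }
  run <- function(k) {
    if (config$backend == "upgma") upgma_cluster(X, k)
    else cluster_trajectories(X, k, seed = seed, n_init = config$n_init)
  }
  # accept the largest k (up to max_clusters) whose centroids are mutually
  # distinguishable; k = 3 collapses whenever two centroids nearly coincide
  fit <- run(1L)
  k_used <- 1L
  k_max <- min(config$max_clusters, nrow(X))
  for (k in if (k_max >= 2L) 2L:k_max else integer(0)) {
    cand <- run(k)
    pairs <- utils::combn(k, 2L)
    dmin <- min(apply(pairs, 2L, function(p) {
      centroid_distance(cand$centroids[p[1L], ], cand$centroids[p[2L], ])
    }))
    if (dmin < config$merge_distance) break
    fit <- cand
    k_used <- k
  }
  assignment <- fit$assignment
  centroids <- fit$centroids[seq_len(k_used), , drop = FALSE]

  # outliers ("loose SNPs"): assignment distance well beyond the bulk of
  # within-cluster distances. A plain 95th-percentile rule would flag the
  # top 5% of any clean clustering, so the fence is the larger of 1.5x the
  # 95th percentile and a median + 5 MAD robust bound; ordinary noise
  # stays inside, while genuinely detached trajectories (several-fold
  # larger distances) are still caught.
  dist_to_own <- vapply(seq_len(nrow(X)), function(i) {
    dtw_distance(X[i, ], centroids[assignment[i], ])
  }, numeric(1))
  cutoff <- max(1.5 * stats::quantile(dist_to_own, 0.95, names = FALSE),
                stats::median(dist_to_own) + 5 * stats::mad(dist_to_own))
  outlier <- dist_to_own > cutoff & dist_to_own > 0
  mean_freq <- rowMeans(X)
  shared <- ids[outlier & mean_freq > config$fixed_threshold]
  unassigned <- ids[outlier & mean_freq <= config$fixed_threshold]

  cluster_fixed <- apply(centroids > config$fixed_threshold, 1L, all)
  diff_ids <- character(0)
  diff_cluster <- NA_integer_
  sizes <- tabulate(assignment[!outlier], nbins = k_used)
  nonfixed <- which(!cluster_fixed)
  if (length(nonfixed) > 1L) {
    # keep the largest non-fixed cluster as the differentiating set;
    # the rest cannot be phased into a third strain and stay unassigned
    keep <- nonfixed[which.max(sizes[nonfixed])]
    drop <- setdiff(nonfixed, keep)
    warning("more than one non-fixed cluster; keeping the largest, ",
            "leaving ", sum(sizes[drop]), " SNPs unassigned")
    unassigned <- c(unassigned, ids[!outlier & assignment %in% drop])
    nonfixed <- keep
  }
  for (j in which(cluster_fixed)) {
    shared <- c(shared, ids[!outlier & assignment == j])
  }
  if (length(nonfixed) == 1L) {
    diff_cluster <- nonfixed
    diff_ids <- ids[!outlier & assignment == diff_cluster]
  }
  top2 <- sum(sort(sizes, decreasing = TRUE)[seq_len(min(2L, k_used))])
  if (top2 < config$min_cluster_coverage * nrow(X)) {
    warning(sprintf(
      "top two clusters hold only %.0f%% of SNPs (< %.0f%%)",
      100 * top2 / nrow(X), 100 * config$min_cluster_coverage))
  }
  if (!length(diff_ids)) {
    return(one_strain(shared = shared, unassigned = unassigned))
  }
  est <- estimate_strain_frequencies(
    freq[diff_ids, , drop = FALSE], depth[diff_ids, , drop = FALSE])
  structure(list(species = species, n_strains = 2L,
                 differentiating = diff_ids, shared = shared,
                 unassigned = unassigned, f = est$f,
                 major_strain = est$major_strain,
                 genetic_distance = length(diff_ids)),
            class = "strain_model")
}

#' @export
print.strain_model <- function(x, ...) {
  cat(sprintf(
    "strain_model for %s: %d strain(s); %d differentiating, %d shared, %d unassigned SNPs\n",
    x$species, x$n_strains, length(x$differentiating), length(x$shared),
    length(x$unassigned)))
  invisible(x)
}

#' Estimate the strain frequency trajectory from a differentiating cluster
#'
#' The frequency of the strain carrying the cluster alleles is the average
#' major-allele frequency of the cluster's SNPs, weighted by local read
#' depth: `f(t) = sum_s depth_s(t) freq_s(t) / sum_s depth_s(t)`. The
#' cluster strain is labelled "strain_1"; it is the major strain when
#' `f >= 0.5` at the first time point. Time points where every SNP has zero
#' depth yield `NA` (missing, not imputed).
#'
#' @param freq SNPs x time matrix of major-allele frequencies.
#' @param depth SNPs x time matrix of read depths.
#' @return List with `f` (strain-1 frequency per time point) and
#'   `major_strain` (`"strain_1"` or `"strain_2"`).
#' @export
estimate_strain_frequencies <- function(freq, depth) {
  freq <- as.matrix(freq)
  depth <- as.matrix(depth)
  if (nrow(freq) < 1L) stop("need at least one differentiating SNP")
  w <- depth
  w[!is.finite(freq)] <- 0
  fz <- freq
  fz[!is.finite(freq)] <- 0
  denom <- colSums(w)
  f <- ifelse(denom > 0, colSums(fz * w) / denom, NA_real_)
  first <- which(is.finite(f))[1L]
  major <- if (is.na(first)) NA_character_
  else if (f[first] >= 0.5) "strain_1" else "strain_2"
  list(f = f, major_strain = major)
}

#' Expand a species abundance table to strain level
#'
#' For each two-strain species, strain abundances are `f * A` and
#' `(1 - f) * A`, where `f` is the strain-1 frequency and `A` the species'
#' relative abundance; one-strain species pass through unchanged. Lineage
#' is extended with strain labels, and column sums are preserved.
#'
#' @param models List of `strain_model`s (one per species).
#' @param species_table An [abundance_table()] whose taxa include every
#'   model's species.
#' @return An [abundance_table()] at strain level.
#' @export
strain_abundance_table <- function(models, species_table) {
  stopifnot(inherits(species_table, "abundance_table"))
  by_species <- stats::setNames(models, vapply(models, `[[`, character(1),
                                               "species"))
  missing <- setdiff(names(by_species), species_table$taxa$taxon_id)
  if (length(missing)) {
    stop("species absent from abundance table: ",
         paste(missing, collapse = ", "))
  }
  rows <- list()
  taxa <- list()
  for (i in seq_len(nrow(species_table$values))) {
    id <- species_table$taxa$taxon_id[i]
    A <- species_table$values[i, ]
    tx <- species_table$taxa[i, , drop = FALSE]
    m <- by_species[[id]]
    if (!is.null(m) && m$n_strains == 2L) {
      for (s in 1:2) {
        f <- if (s == 1L) m$f else 1 - m$f
        tx_s <- tx
        tx_s$taxon_id <- paste0(id, "_strain", s)
        tx_s$strain <- paste0("strain_", s)
        taxa[[length(taxa) + 1L]] <- tx_s
        rows[[length(rows) + 1L]] <- f * A
      }
    } else {
      tx$strain <- if ("strain" %in% names(tx)) tx$strain else NA_character_
      taxa[[length(taxa) + 1L]] <- tx
      rows[[length(rows) + 1L]] <- A
    }
  }
  taxa <- do.call(rbind, taxa)
  if (!"strain" %in% names(species_table$taxa)) {
    taxa$strain[is.na(taxa$strain)] <- "strain_1"
  }
  abundance_table(do.call(rbind, rows), taxa, times = species_table$times)
}
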