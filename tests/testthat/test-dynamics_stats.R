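test_that("strain coupling is the correlation magnitude", {
  set.seed(1)
  species <- rgamma(8, 4, 40)
  # constant strain frequency: both strains proportional to the species
  s1 <- 0.6 * species
  s2 <- 0.4 * species
  res <- strain_coupling(s1, s2)
  expect_equal(res$coupling, 1)
  expect_equal(res$label, "coupled")
  # constant species, varying frequency: perfectly anti-correlated
  # abundances still have coupling 1 (magnitude convention)
  f <- seq(0.2, 0.8, length.out = 8)
  res2 <- strain_coupling(f * 0.3, (1 - f) * 0.3)
  expect_equal(res2$coupling, 1)
  # constant trajectory is flagged undefined
  res3 <- strain_coupling(rep(0.2, 8), species)
  expect_true(is.na(res3$coupling))
  expect_equal(res3$label, "undefined")
})

test_that("independent gamma trajectories are predominantly decoupled", {
  set.seed(2)
  res <- replicate(500, {
    strain_coupling(rgamma(8, 1, 10), rgamma(8, 1, 10))$coupling
  })
  # E|r| for independent series at n = 8 is ~0.32; most pairs sit below
  # the 0.4 decoupling threshold
  expect_equal(mean(res), 0.33, tolerance = 0.15)
  expect_gt(mean(res < 0.4), 0.6)
})

test_that("spearman and pearson coupling agree away from the threshold", {
  set.seed(3)
  res <- replicate(150, {
    a <- rgamma(8, 2, 10)
    b <- if (runif(1) < 0.5) a * runif(1, 0.5, 2) else rgamma(8, 2, 10)
    p <- strain_coupling(a, b)
    s <- strain_coupling(a, b, coupling_config(kind = "spearman"))
    c(p$coupling, p$label == s$label)
  })
  clear <- abs(res[1, ] - 0.4) > 0.1   # pairs not sitting on the boundary
  expect_gt(mean(res[2, clear]), 0.9)
})

test_that("interspecies correlations enumerate only interspecific pairs", {
  set.seed(4)
  spA <- rgamma(8, 2, 10)
  spB <- 2 * spA
  # perfectly proportional species: species |r| = 1, no strain can exceed
  res <- interspecies_correlations(spA, spB, rbind(spA), rbind(spB))
  expect_equal(res$species_r, 1)
  expect_equal(res$strain_r, 1)
  expect_false(res$strain_exceeds)
  # hidden interaction: minor strains are copies, species independent
  spA <- rgamma(8, 5, 10)
  spB <- rgamma(8, 5, 10)
  minor <- rgamma(8, 1, 20)
  res2 <- interspecies_correlations(
    spA, spB,
    rbind(spA - minor, minor), rbind(spB - minor, minor))
  expect_equal(res2$strain_r, 1)
  expect_true(res2$strain_exceeds)
})

test_that("gamma null sampler has the requested moments", {
  means <- c(0.3, 0.1, 0.05, 0.2)
  vars <- c(0.02, 0.01, 0.001, 0.01)
  # beta = mean^2/var; check raw draws directly against the stated gamma
  set.seed(5)
  n <- 2e4
  for (i in seq_along(means)) {
    shape <- means[i]^2 / vars[i]
    draws <- rgamma(n, shape = shape, rate = shape / means[i])
    se_mean <- sqrt(vars[i] / n)
    expect_lt(abs(mean(draws) - means[i]), 3 * se_mean)
  }
  # beta = 1 is the exponential special case
  expect_equal(0.1^2 / 0.01, 1)
  null <- gamma_null_correlations(means, vars, n_times = 8, n_sims = 50,
                                  seed = 6)
  # 4 members -> 6 pairs per simulated community
  expect_equal(length(null$values), 50 * 6)
  expect_true(all(null$values >= 0 & null$values <= 1))
})

test_that("renormalized gamma-null abundances sum to one", {
  set.seed(7)
  means <- rep(0.1, 10)
  shape <- 1
  x <- matrix(rgamma(10 * 8, shape, rate = shape / 0.1), 10)
  x <- sweep(x, 2, colSums(x), "/")
  expect_equal(colSums(x), rep(1, 8))
})

test_that("interaction detection calls extremes and calibrates to alpha", {
  set.seed(8)
  null <- gamma_null_correlations(rep(0.1, 10), rep(0.005, 10),
                                  n_times = 8, n_sims = 100, seed = 9)
  # a perfect correlation is always called
  pairs <- data.frame(a = "x", b = "y", r = 1)
  net <- detect_interactions(pairs, null, level = "strain")
  expect_equal(nrow(net$edges), 1L)
  expect_lt(net$edges$p, 0.05)
  # null data tested against its own null: edge rate ~ alpha
  obs <- matrix(rgamma(10 * 8, 2, rate = 2 / 0.1), 10)
  obs <- sweep(obs, 2, colSums(obs), "/")
  null2 <- gamma_null_correlations(rowMeans(obs), apply(obs, 1, var),
                                   n_times = 8, n_sims = 200, seed = 10)
  cm <- abs(cor(t(obs)))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs2 <- data.frame(a = idx[, 1], b = idx[, 2], r = cm[upper.tri(cm)])
  net2 <- detect_interactions(pairs2, null2, alpha = 0.05)
  expect_lt(nrow(net2$edges) / nrow(pairs2), 0.25)
  # undefined correlations are excluded but counted
  pairs3 <- data.frame(a = c("x", "z"), b = c("y", "w"), r = c(0.5, NA))
  net3 <- detect_interactions(pairs3, null, level = "species")
  expect_equal(net3$n_undefined, 1L)
})

test_that("network density is edges per node", {
  null <- structure(list(values = runif(500), n_sims = 1), # nolint
                    class = "null_distribution")
  strain_net <- detect_interactions(
    data.frame(a = 1, b = 2, r = 2), null, nodes = 1:24, level = "strain")
  expect_equal(strain_net$density, 1 / 24)
  # the worked density comparison: 38 edges over 24 nodes is 90% denser
  # than 10 edges over 12 nodes
  expect_equal((38 / 24) / (10 / 12) - 1, 0.9, tolerance = 1e-12)
})

test_that("permutation test F matches a brute-force oracle on a toy set", {
  set.seed(11)
  strains <- matrix(rgamma(6 * 8, 2, 20), 6)
  species_of <- rep(c("A", "B", "C"), each = 2)
  # brute force: enumerate all species pairs explicitly
  species <- rbind(A = colSums(strains[1:2, ]), B = colSums(strains[3:4, ]),
                   C = colSums(strains[5:6, ]))
  combos <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  wins <- vapply(combos, function(pr) {
    sr <- max(abs(cor(t(strains[species_of == pr[1], ]),
                      t(strains[species_of == pr[2], ]))))
    sp_r <- abs(cor(species[pr[1], ], species[pr[2], ]))
    sr > sp_r
  }, logical(1))
  oracle_F <- mean(wins)
  res <- strain_label_permutation_test(strains, species_of, n_perm = 50,
                                       seed = 12)
  expect_equal(res$F_obs, oracle_F)
  expect_true(res$p > 0 && res$p <= 1)
  expect_error(strain_label_permutation_test(strains, species_of,
                                             n_perm = 0), "n_perm")
  expect_error(strain_label_permutation_test(strains[1:2, ],
                                             rep("A", 2)), "2 species")
})

test_that("permutations preserve the multiset of strain labels", {
  set.seed(13)
  species_of <- rep(letters[1:4], each = 2)
  perm <- sample(species_of)
  expect_equal(sort(perm), sort(species_of))
})

test_that("co-occurrence variability normalizes against label shuffles", {
  # two congeneric pairs that always co-occur vs singleton genera
  lineage <- data.frame(
    member = paste0("m", 1:6),
    genus = c("g1", "g1", "g2", "g2", "g3", "g4"),
    stringsAsFactors = FALSE)
  presence <- rbind(
    c(1, 1, 0, 0, 1, 0),
    c(0, 0, 1, 1, 0, 1))
  colnames(presence) <- lineage$member
  res <- cooccurrence_variability(presence, lineage, level = "species",
                                  parent = "genus", n_shuffles = 300,
                                  seed = 14)
  expect_equal(res$observed, 1)
  expect_gt(res$normalized, 1)  # more structured than random labels
  # a single community containing everything: ratio is exactly 1
  all_present <- matrix(1, 1, 6, dimnames = list(NULL, lineage$member))
  res2 <- cooccurrence_variability(all_present, lineage, level = "species",
                                   parent = "genus", n_shuffles = 20,
                                   seed = 15)
  expect_equal(res2$normalized, 1)
  expect_error(cooccurrence_variability(
    presence, data.frame(member = "m", genus = "g"), "species", "genus"),
    "size")
})

test_that("eco-evolutionary influence flags driven species", {
  set.seed(16)
  n <- 20
  strain_freq <- t(replicate(n, cumsum(rnorm(8, 0, 0.05)) + 0.5))
  species <- t(replicate(n, rgamma(8, 2, 20)))
  # species 1 tracks its strain frequency exactly
  species[1, ] <- strain_freq[1, ] * 0.2
  res <- ecoevo_influence(species, strain_freq, n_shuffles = 200,
                          seed = 17)
  expect_equal(res$r[1], 1)
  expect_true(res$influential[1])
  # constant strain frequency gives an undefined statistic, never flagged
  strain_freq[2, ] <- 0.5
  res2 <- ecoevo_influence(species, strain_freq, n_shuffles = 100,
                           seed = 18)
  expect_true(is.na(res2$r[2]))
  expect_false(res2$influential[2])
  expect_error(ecoevo_influence(species[1, , drop = FALSE],
                                strain_freq[1, , drop = FALSE]),
               "more than one")
})

test_that("fully shuffled populations are flagged at ~5%", {
  set.seed(19)
  n <- 150
  species <- t(replicate(n, rgamma(8, 2, 20)))
  strain_freq <- t(replicate(n, runif(1) + rnorm(8, 0, 0.05)))
  res <- ecoevo_influence(species, strain_freq, n_shuffles = 100,
                          seed = 20)
  expect_lt(abs(res$fraction_influential - 0.05), 0.05)
})

test_that("the coupling threshold tracks the valley of a bimodal mix", {
  set.seed(22)
  x <- c(rbeta(300, 12, 1.5), rbeta(120, 2, 8))  # coupled + decoupled
  thr <- estimate_coupling_threshold(x)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.7)
  # unimodal data falls back to the default
  expect_equal(estimate_coupling_threshold(rbeta(300, 12, 1.5)), 0.4)
  expect_equal(estimate_coupling_threshold(c(0.5, 0.6)), 0.4)
})

test_that("coupling-distance curve bins log-spaced and averages", {
  # all pairs at one distance: single bin equal to the plain mean
  res <- coupling_distance_curve(rep(50, 5), c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(nrow(res), 1L)
  expect_equal(res$mean_coupling, 0.6)
  # constructed drop at the ~100-SNP decoupling scale
  set.seed(21)
  d <- c(runif(200, 5, 90), runif(200, 120, 5000))
  cpl <- ifelse(d < 100, 1, 0.2)
  curve <- coupling_distance_curve(d, cpl, n_bins = 8)
  expect_equal(curve$mean_coupling[1], 1)
  expect_equal(curve$mean_coupling[nrow(curve)], 0.2)
  expect_lt(min(diff(curve$mean_coupling)), -0.5)  # a sharp drop exists
  # monotone inputs give non-increasing binned means
  d2 <- sort(runif(100, 1, 1000))
  c2 <- seq(1, 0, length.out = 100)
  curve2 <- coupling_distance_curve(d2, c2, n_bins = 6)
  expect_true(all(diff(curve2$mean_coupling) <= 1e-12))
})
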