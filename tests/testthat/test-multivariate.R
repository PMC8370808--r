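test_that("PCA preserves variance and distances, orders axes", {
  set.seed(1)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(sprintf("s%02d", 1:20), NULL))
  p <- pca(x)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$sdev) <= 1e-12))
  ## all axes kept: pairwise distances are reproduced
  expect_equal(as.matrix(dist(p$scores)), as.matrix(dist(scale(x, scale = FALSE))),
               tolerance = 1e-9, ignore_attr = TRUE)

  ## collinear data: one axis carries everything
  line <- cbind(1:10, 2 * (1:10))
  rownames(line) <- paste0("s", 1:10)
  expect_equal(pca(line)$explained[1], 1, tolerance = 1e-12)

  expect_error(pca(x, n_axes = 50), class = "phylosym_argument_error")
})

test_that("sequential PERMANOVA agrees with vegan and decomposes exactly", {
  skip_if_not_installed("vegan")
  set.seed(2)
  n <- 30
  meta <- sample_metadata(data.frame(
    sample_id = sprintf("s%02d", 1:n),
    host_species = sample(letters[1:5], n, TRUE),
    host_order = sample(c("o1", "o2"), n, TRUE),
    host_class = "c",
    sample_type = sample(c("t1", "t2", "t3"), n, TRUE),
    tissue_storage = sample(c("frozen", "etoh"), n, TRUE),
    extraction_kit = "k", stringsAsFactors = FALSE))
  d <- as_distance_matrix(as.matrix(dist(matrix(rnorm(n * 8), n,
                                                dimnames = list(meta$sample_id, NULL)))))
  terms <- c("sample_type", "tissue_storage", "host_order", "host_species")
  mine <- permanova_sequential(d, meta, terms, n_perm = 99, seed = 1)
  va <- vegan::adonis2(as.dist(d) ~ sample_type + tissue_storage + host_order +
                         host_species, data = as.data.frame(meta),
                       permutations = 99, by = "terms")
  expect_equal(mine$sum_sq[1:5], va$SumOfSqs[1:5], tolerance = 1e-9)
  expect_equal(mine$pseudo_f[1:4], va$F[1:4], tolerance = 1e-9)
  expect_equal(mine$df[1:5], va$Df[1:5])
  expect_equal(sum(mine$r_squared[seq_len(5)]), 1, tolerance = 1e-12)

  ## single two-level factor reduces to the classical SS decomposition
  g <- rep(c("A", "B"), each = 6)
  x <- c(rnorm(6), rnorm(6) + 3)
  meta2 <- sample_metadata(data.frame(
    sample_id = sprintf("u%02d", 1:12), host_species = g, host_order = "o",
    host_class = "c", sample_type = "t", tissue_storage = "s",
    extraction_kit = "k", stringsAsFactors = FALSE))
  d2 <- as_distance_matrix(as.matrix(dist(cbind(x))), meta2$sample_id)
  pm2 <- permanova_sequential(d2, meta2, "host_species", n_perm = 999, seed = 2)
  ss_direct <- sum((tapply(x, g, mean) - mean(x))^2 * 6)
  expect_equal(pm2$sum_sq[1], ss_direct, tolerance = 1e-9)
  expect_equal(pm2$sum_sq[2], sum((x - ave(x, g))^2), tolerance = 1e-9)

  expect_error(permanova_sequential(d2, meta2, "sample_type", 9, seed = 1),
               "single level", class = "phylosym_argument_error")
  meta3 <- meta2; meta3$host_order <- meta3$host_species
  expect_error(permanova_sequential(d2, meta3, c("host_species", "host_order"),
                                    9, seed = 1),
               "host_order", class = "phylosym_argument_error")
})

test_that("random-permutation p converges to the exact enumerated p", {
  set.seed(3)
  g <- rep(c("A", "B"), each = 3)
  x <- matrix(rnorm(12, sd = 0.8), 6, 2) + cbind(rep(c(0, 4), each = 3), 0)
  rownames(x) <- paste0("s", 1:6)
  d <- as_distance_matrix(as.matrix(dist(x)))
  p_exact <- permanova_exact_p(d, g)
  meta <- sample_metadata(data.frame(
    sample_id = rownames(x), host_species = g, host_order = "o",
    host_class = "c", sample_type = "t", tissue_storage = "s",
    extraction_kit = "k", stringsAsFactors = FALSE))
  n_perm <- 999
  p_mc <- permanova_sequential(d, meta, "host_species", n_perm, seed = 4)$p_value[1]
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_mc - p_exact), 2 * mc_se + 2 / n_perm)
  ## with 3v3 labels the attainable minimum is 72/720 = 0.1
  expect_lte(p_mc, 0.15)
  expect_equal(p_exact, 0.1, tolerance = 1e-12)
  r2 <- permanova_sequential(d, meta, "host_species", 99, seed = 1)$r_squared[1]
  expect_gt(r2, 0.5)
})

test_that("Procrustes correlation: exact fit, invariances, vegan agreement", {
  skip_if_not_installed("vegan")
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Y <- X %*% R * 2
  rownames(Y) <- rownames(X)
  expect_equal(procrustes_correlation(X, Y)$correlation, 1, tolerance = 1e-9)

  ## invariant to rigid motion + scaling of either input
  Y2 <- (X + 5) %*% R * 0.3
  rownames(Y2) <- rownames(X)
  noise <- matrix(rnorm(40), 20, 2, dimnames = dimnames(X))
  r_a <- procrustes_correlation(X, noise)$correlation
  r_b <- procrustes_correlation(Y2, noise)$correlation
  expect_equal(r_a, r_b, tolerance = 1e-9)

  ## row order of Y is irrelevant (ids realign)
  perm <- sample(20)
  expect_equal(procrustes_correlation(X, noise[perm, ])$correlation, r_a,
               tolerance = 1e-12)

  vg <- vegan::protest(X, noise, permutations = 19)
  expect_equal(r_a, vg$t0, tolerance = 1e-9)
})

test_that("PROTEST: minimum p on self-comparison, determinism, null behaviour", {
  set.seed(5)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  self <- protest(X, X, n_perm = 99, seed = 1)
  expect_equal(self$p, 1 / 100)
  expect_identical(protest(X, X, n_perm = 99, seed = 1)$p, self$p)

  Y <- matrix(rnorm(200), 100, 2,
              dimnames = list(paste0("t", 1:100), NULL))
  X2 <- matrix(rnorm(200), 100, 2, dimnames = dimnames(Y))
  ind <- protest(X2, Y, n_perm = 199, seed = 2)
  expect_lt(ind$correlation, quantile(ind$null, 0.95) + 0.05)
  expect_gt(ind$p, 0.05)
})

test_that("Mantel: identity, symmetry, vegan agreement", {
  skip_if_not_installed("vegan")
  set.seed(6)
  x <- matrix(rnorm(100), 20, 5, dimnames = list(paste0("s", 1:20), NULL))
  d1 <- as_distance_matrix(as.matrix(dist(x)))
  d2 <- as_distance_matrix(2 * as.matrix(dist(x)))
  expect_equal(mantel(d1, d2, n_perm = 9, seed = 1)$r, 1, tolerance = 1e-12)

  y <- matrix(rnorm(100), 20, 5, dimnames = list(paste0("s", 1:20), NULL))
  d3 <- as_distance_matrix(as.matrix(dist(y)))
  r12 <- mantel(d1, d3, n_perm = 9, seed = 1)$r
  expect_equal(mantel(d3, d1, n_perm = 9, seed = 1)$r, r12, tolerance = 1e-12)
  expect_equal(r12, vegan::mantel(as.dist(d1), as.dist(d3),
                                  permutations = 9)$statistic,
               tolerance = 1e-12)
  ## spearman variant agrees too
  expect_equal(mantel(d1, d3, method = "spearman", n_perm = 9, seed = 1)$r,
               vegan::mantel(as.dist(d1), as.dist(d3), method = "spearman",
                             permutations = 9)$statistic, tolerance = 1e-12)

  bad <- d3; rownames(bad)[1] <- colnames(bad)[1] <- "zz"
  expect_error(mantel(d1, bad, n_perm = 9, seed = 1),
               class = "phylosym_validation_error")
})

test_that("bootstrap Procrustes: degenerate frac, shrinking intervals", {
  ds <- sim_dataset(seed = 12, coupling = 0.8, phylo_strength = 1.5)
  sw <- bootstrap_procrustes(ds$fungi, ds$bacteria, ds$taxonomy_fungi,
                             ds$taxonomy_bacteria, rank_levels = c("asv"),
                             frac = 1.0, n_boot = 10, seed = 1)
  expect_true(all(abs(sw$asv$replicates - sw$asv$correlation) < 1e-12))

  ## interval endpoints inside the replicate range; width shrinks with n
  width <- function(n_sp, seed) {
    ds2 <- sim_dataset(seed = seed, n_species = n_sp, samples_per_species = 5,
                       coupling = 0.8, phylo_strength = 1.5)
    sw2 <- bootstrap_procrustes(ds2$fungi, ds2$bacteria, ds2$taxonomy_fungi,
                                ds2$taxonomy_bacteria, rank_levels = "asv",
                                frac = 0.9, n_boot = 99, seed = seed)
    expect_gte(sw2$asv$interval[1], min(sw2$asv$replicates))
    expect_lte(sw2$asv$interval[2], max(sw2$asv$replicates))
    diff(sw2$asv$interval)
  }
  w_small <- mean(vapply(1:5, function(s) width(6, s), numeric(1)))
  w_big <- mean(vapply(1:5, function(s) width(24, s), numeric(1)))
  expect_lt(w_big, w_small)
})

test_that("phylosymbiosis test recovers tree signal and stays null without it", {
  ds_sig <- sim_dataset(seed = 13, phylo_strength = 2, sigma_within = 0.3,
                        samples_per_species = 3)
  sw <- suppressWarnings(phylosymbiosis_test(
    ds_sig$fungi, ds_sig$taxonomy_fungi, ds_sig$metadata, ds_sig$tree,
    rank_levels = "asv", n_boot = 49, seed = 1))
  ## null band from species-label permutation of the same data
  clr <- clr_transform(ds_sig$fungi)
  ids <- sample_ids(ds_sig$fungi)
  s2s <- setNames(ds_sig$metadata$host_species[
    match(ids, ds_sig$metadata$sample_id)], ids)
  null_cor <- vapply(1:99, function(k) {
    set.seed(k)
    perm_map <- setNames(s2s[sample(length(s2s))], names(s2s))
    g <- graft_samples(ds_sig$tree, perm_map)
    suppressWarnings(procrustes_correlation(
      phylosym:::pcoa_embed(aitchison_distance(clr)[ids, ids]),
      phylosym:::pcoa_embed(patristic_distance(g)[ids, ids]))$correlation)
  }, numeric(1))
  expect_gt(sw$asv$correlation, quantile(null_cor, 0.975))

  ds_null <- sim_dataset(seed = 14, phylo_strength = 0, coupling = 0,
                         samples_per_species = 3)
  sw0 <- suppressWarnings(phylosymbiosis_test(
    ds_null$fungi, ds_null$taxonomy_fungi, ds_null$metadata, ds_null$tree,
    rank_levels = "asv", n_boot = 49, seed = 2))
  null_cor0 <- vapply(1:99, function(k) {
    set.seed(k + 1000)
    clr0 <- clr_transform(ds_null$fungi)
    ids0 <- sample_ids(ds_null$fungi)
    s2s0 <- setNames(ds_null$metadata$host_species[
      match(ids0, ds_null$metadata$sample_id)], ids0)
    perm_map <- setNames(s2s0[sample(length(s2s0))], names(s2s0))
    g <- graft_samples(ds_null$tree, perm_map)
    suppressWarnings(procrustes_correlation(
      phylosym:::pcoa_embed(aitchison_distance(clr0)[ids0, ids0]),
      phylosym:::pcoa_embed(patristic_distance(g)[ids0, ids0]))$correlation)
  }, numeric(1))
  ## a calibration pilot shows this rank statistic is uniform under the
  ## null; a fixed seed can land anywhere, so only extreme ranks fail
  rank_p <- (sum(null_cor0 >= sw0$asv$correlation) + 1) / (length(null_cor0) + 1)
  expect_gt(rank_p, 0.01)
})

test_that("diet analysis: mirror-image diets, dropped species, slope recovery", {
  ## two mirror-image diet profiles: PC1 explains everything
  ds <- sim_dataset(seed = 15, diet_signal = 1, phylo_strength = 1.5)
  da <- diet_analysis(ds$fungi, ds$bacteria, ds$metadata, ds$diet,
                      n_perm = 99, n_boot = 49, seed = 1)
  expect_s3_class(da, "diet_analysis")
  expect_equal(nrow(da$pca$scores), 10)

  prop <- matrix(0, 4, 10, dimnames = list(paste0("sp", 1:4),
                                           phylosym:::DIET_CATEGORIES))
  prop[c(1, 3), 1] <- 100; prop[c(2, 4), 2] <- 100
  dt <- diet_table(data.frame(species = rownames(prop), prop,
                              check.names = FALSE))
  keep <- apply(prop, 2, sd) > 0
  pc <- prcomp(prop[, keep], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  expect_equal(expl[1], 1, tolerance = 1e-12)

  ## species without diet rows are dropped with a report
  diet_sub <- ds$diet[ds$diet$species != "sp001", ]
  expect_message(
    da2 <- diet_analysis(ds$fungi, ds$bacteria, ds$metadata,
                         diet_table(diet_sub), n_perm = 49, n_boot = 49,
                         seed = 2),
    "sp001")
  expect_false("sp001" %in% da2$species)
  expect_error(diet_analysis(ds$fungi, ds$bacteria, ds$metadata,
                             diet_table(ds$diet[1:3, ]), n_perm = 9,
                             n_boot = 9, seed = 3),
               class = "phylosym_argument_error")
})
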