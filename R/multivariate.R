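## Ordination and inference: PCA, sequential PERMANOVA,
## Procrustes/PROTEST, bootstrap rank sweeps, Mantel, phylosymbiosis
## and diet analyses.

#' Principal component analysis of a CLR matrix
#'
#' Centred (not scaled) PCA.  Axes are ordered by decreasing variance;
#' each axis is flipped so its largest-magnitude loading is positive.
#'
#' @param clr a `clr_matrix` or plain numeric matrix (samples x
#'   features).
#' @param n_axes number of axes to keep, or `"all"` (default).
#' @return a `pca_result` list: `scores` (samples x axes), `explained`
#'   (proportion of variance per axis), `sdev`, `totvar`.
#' @export
pca <- function(clr, n_axes = "all") {
  x <- unclass(as.matrix(clr))
  if (nrow(x) < 2L || ncol(x) < 2L) abort("need >= 2 samples and >= 2 features")
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (!identical(n_axes, "all")) {
    n_axes <- check_scalar_int(n_axes, "n_axes", 1L)
    if (n_axes > kmax) abort(sprintf("n_axes > min(n - 1, p) = %d", kmax),
                             class = "phylosym_argument_error")
  } else n_axes <- kmax
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_axes, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) sign(rot[which.max(abs(rot[, j])), j]),
                 numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  totvar <- sum(pc$sdev^2)
  structure(list(scores = scores,
                 explained = pc$sdev[seq_len(k)]^2 / totvar,
                 sdev = pc$sdev[seq_len(k)], totvar = totvar),
            class = "pca_result")
}

# ---------------------------------------------------------------------------
# Sequential PERMANOVA

## Gower-centred inner-product matrix of a distance matrix.
gower_matrix <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  j <- diag(n) - 1 / n
  -0.5 * j %*% d2 %*% j
}

## Hat matrix of a design, via thin QR.
hat_matrix <- function(X) {
  qr_ <- qr(X)
  q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  tcrossprod(q)
}

#' Sequential (Type-I) PERMANOVA
#'
#' Partitions the total sum of squared distances across terms added in
#' the given order, marginalizing earlier terms before later ones (the
#' strategy used to strip sample-processing effects before host
#' taxonomy).  Pseudo-F tests each term against the residual;
#' p-values come from unrestricted permutations of sample identities,
#' recomputing the full sequential decomposition each time.
#'
#' @param dist a `distance_matrix` (samples x samples).
#' @param metadata a `sample_metadata` covering the samples.
#' @param term_order character vector of metadata columns, in the order
#'   they should absorb variance.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a `permanova_table` data frame: one row per term plus
#'   `residual` and `total`, with `df`, `sum_sq`, `r_squared`,
#'   `pseudo_f`, `p_value`.
#' @export
permanova_sequential <- function(dist, metadata, term_order, n_perm = 999L, seed) {
  n_perm <- check_scalar_int(n_perm, "n_perm", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  d <- as.matrix(dist)
  ids <- rownames(d)
  meta_idx <- match(ids, metadata$sample_id)
  if (anyNA(meta_idx)) abort("distance matrix samples missing from metadata")
  if (!length(term_order)) abort("term_order must be non-empty")
  bad <- setdiff(term_order, names(metadata))
  if (length(bad)) abort("unknown metadata term(s): ", paste(bad, collapse = ", "))

  n <- nrow(d)
  G <- gower_matrix(d)
  total_ss <- sum(diag(G))

  ## cumulative designs and their hat matrices
  X <- matrix(1, n, 1)
  hats <- vector("list", length(term_order))
  dfs <- numeric(length(term_order))
  rank_prev <- 1L
  for (k in seq_along(term_order)) {
    f <- factor(metadata[[term_order[k]]][meta_idx])
    if (nlevels(f) < 2L) {
      abort(sprintf("term '%s' has a single level", term_order[k]),
            class = "phylosym_argument_error")
    }
    X <- cbind(X, stats::model.matrix(~ f)[, -1, drop = FALSE])
    qr_rank <- qr(X)$rank
    if (qr_rank == rank_prev) {
      abort(sprintf("term '%s' is aliased with earlier terms", term_order[k]),
            class = "phylosym_argument_error")
    }
    dfs[k] <- qr_rank - rank_prev
    rank_prev <- qr_rank
    hats[[k]] <- hat_matrix(X)
  }
  df_res <- n - 1L - sum(dfs)
  if (df_res < 1L) abort("no residual degrees of freedom")

  decompose <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    f_stat <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f_stat)
  }
  obs <- decompose(G)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  exceed <- numeric(length(term_order))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    f_perm <- decompose(G[p, p])$f
    exceed <- exceed + (f_perm >= obs$f)
  }
  pvals <- (exceed + 1) / (n_perm + 1)

  out <- data.frame(
    term = c(term_order, "residual", "total"),
    df = c(dfs, df_res, n - 1L),
    sum_sq = c(obs$ss, obs$ss_res, total_ss),
    r_squared = c(obs$ss, obs$ss_res, total_ss) / total_ss,
    pseudo_f = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("permanova_table", "data.frame")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

# ---------------------------------------------------------------------------
# Procrustes / PROTEST

prepare_procrustes <- function(X, Y, symmetric = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(rownames(X)) || is.null(rownames(Y))) {
    abort("score matrices must carry sample ids as rownames")
  }
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < 3L) abort("need >= 3 shared rows",
                                 class = "phylosym_argument_error")
  X <- X[shared, , drop = FALSE]; Y <- Y[shared, , drop = FALSE]
  k <- max(ncol(X), ncol(Y))
  pad <- function(M) cbind(M, matrix(0, nrow(M), k - ncol(M)))
  X <- pad(X); Y <- pad(Y)
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  if (symmetric) {
    X <- X / sqrt(sum(X^2))
    Y <- Y / sqrt(sum(Y^2))
  }
  list(X = X, Y = Y, shared = shared)
}

procrustes_m12sq <- function(X, Y, symmetric = TRUE) {
  d <- svd(crossprod(X, Y))$d
  if (symmetric) 1 - sum(d)^2 else 1 - sum(d)^2 / (sum(X^2) * sum(Y^2))
}

#' Procrustes correlation between two ordinations
#'
#' Finds the optimal translation, rotation and scaling of `Y` onto `X`
#' (the symmetric variant normalizes both configurations first) and
#' reports `m12^2`, the residual fraction of the total sum of squares,
#' together with the Procrustes correlation `sqrt(1 - m12^2)`.  Rows
#' are aligned by id; the intersection is used.
#'
#' @param X,Y score matrices (e.g. `$scores` of [pca()]) with sample
#'   ids as rownames.
#' @param symmetric use the symmetric variant (default `TRUE`).
#' @return a `procrustes_result` list: `correlation`, `m12_squared`,
#'   `n_shared`, `symmetric`.
#' @export
procrustes_correlation <- function(X, Y, symmetric = TRUE) {
  pr <- prepare_procrustes(X, Y, symmetric)
  m12 <- procrustes_m12sq(pr$X, pr$Y, symmetric)
  m12 <- min(max(m12, 0), 1)
  structure(list(correlation = sqrt(1 - m12), m12_squared = m12,
                 n_shared = length(pr$shared), symmetric = symmetric),
            class = "procrustes_result")
}

#' PROTEST: permutation test of Procrustes concordance
#'
#' Permutes the rows of `Y` and recomputes the Procrustes correlation;
#' `p = (b + 1) / (n_perm + 1)`, upper tail.
#'
#' @inheritParams procrustes_correlation
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return a `procrustes_result` with `p`, `n_perm`, `seed` added.
#' @export
protest <- function(X, Y, n_perm = 999L, seed, symmetric = TRUE) {
  n_perm <- check_scalar_int(n_perm, "n_perm", 99L)
  seed <- check_scalar_int(seed, "seed", 0L)
  pr <- prepare_procrustes(X, Y, symmetric)
  obs <- sqrt(1 - min(max(procrustes_m12sq(pr$X, pr$Y, symmetric), 0), 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  n <- nrow(pr$X)
  null <- vapply(seq_len(n_perm), function(b) {
    Yp <- pr$Y[sample.int(n), , drop = FALSE]
    sqrt(1 - min(max(procrustes_m12sq(pr$X, Yp, symmetric), 0), 1))
  }, numeric(1))
  structure(list(correlation = obs, m12_squared = 1 - obs^2,
                 p = perm_pvalue(null, obs, "upper"),
                 n_perm = n_perm, seed = seed, null = null,
                 n_shared = length(pr$shared), symmetric = symmetric),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes> correlation = %.4f (m12^2 = %.4f, n = %d)%s\n",
              x$correlation, x$m12_squared, x$n_shared,
              if (!is.null(x$p)) sprintf(", p = %.4g [%d perms]", x$p, x$n_perm) else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Bootstrap sweep across taxonomic ranks

agglomerate_or_asv <- function(table, taxonomy, rank) {
  if (identical(rank, "asv")) table else agglomerate(table, taxonomy, rank)
}

boot_interval <- function(cors) {
  stats::quantile(cors, c(0.025, 0.975), names = FALSE, type = 7)
}

#' Cross-kingdom Procrustes correlation with bootstrap, per rank
#'
#' For each taxonomic rank level: agglomerate both kingdom tables, CLR
#' transform, run PCA, compute the full-data symmetric Procrustes
#' correlation, then resample `ceiling(frac * n)` paired samples
#' without replacement `n_boot` times (the same subsample for both
#' kingdoms), each replicate yielding one correlation.  The paired
#' sample set is computed once and reused across ranks so replicates
#' are comparable.
#'
#' @param fungi,bacteria `feature_table`s sharing samples.
#' @param taxonomy_fungi,taxonomy_bacteria matching taxonomies.
#' @param rank_levels subset of `c("asv", "genus", "family", "order")`.
#' @param frac subsample fraction in (0, 1\]; default 0.9.
#' @param n_boot bootstrap replicates; default 999.
#' @param seed integer seed.
#' @param pseudocount_rule passed to [clr_transform()].
#' @return a `bootstrap_sweep`: list per rank of
#'   `bootstrap_distribution` objects (`rank`, `correlation`,
#'   `replicates`, `interval`, `frac`, `n_boot`).
#' @export
bootstrap_procrustes <- function(fungi, bacteria, taxonomy_fungi, taxonomy_bacteria,
                                 rank_levels = c("asv", "genus", "family", "order"),
                                 frac = 0.9, n_boot = 999L, seed,
                                 pseudocount_rule = "unit") {
  frac <- check_scalar_num(frac, "frac", min = 1e-12, max = 1)
  n_boot <- check_scalar_int(n_boot, "n_boot", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  shared <- intersect(sample_ids(fungi), sample_ids(bacteria))
  if (length(shared) < 10L) abort("need >= 10 paired samples",
                                  class = "phylosym_argument_error")
  fungi <- subset_samples(fungi, shared)
  bacteria <- subset_samples(bacteria, shared)
  n <- length(shared)
  m <- ceiling(frac * n)

  out <- lapply(rank_levels, function(rank) {
    sf <- pca(clr_transform(agglomerate_or_asv(fungi, taxonomy_fungi, rank),
                            pseudocount_rule))$scores
    sb <- pca(clr_transform(agglomerate_or_asv(bacteria, taxonomy_bacteria, rank),
                            pseudocount_rule))$scores
    full <- procrustes_correlation(sf, sb)$correlation
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    seed_rng(seed)    # same subsample sequence at every rank
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- shared[sample.int(n, m)]
      procrustes_correlation(sf[idx, , drop = FALSE],
                             sb[idx, , drop = FALSE])$correlation
    }, numeric(1))
    structure(list(rank = rank, correlation = full, replicates = reps,
                   interval = boot_interval(reps), frac = frac, n_boot = n_boot),
              class = "bootstrap_distribution")
  })
  names(out) <- rank_levels
  structure(out, class = "bootstrap_sweep")
}

## Classical PCoA embedding of a distance matrix; axes with negative
## eigenvalues are dropped with a warning.
pcoa_embed <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  keep <- which(fit$eig > max(fit$eig) * 1e-9)
  if (any(fit$eig < -max(fit$eig) * 1e-6)) {
    warning("negative eigenvalues in principal-coordinates embedding; dropping those axes")
  }
  scores <- fit$points[, seq_len(min(length(keep), ncol(fit$points))), drop = FALSE]
  rownames(scores) <- rownames(d)
  scores
}

#' Phylosymbiosis test: community distance vs host patristic distance
#'
#' Grafts sample tips onto the host tree, builds the sample-level
#' patristic matrix, computes the per-rank Aitchison community
#' distance, embeds both distance matrices by classical principal
#' coordinates and reports the symmetric Procrustes correlation with a
#' bootstrap interval (subsampling paired samples, as in
#' [bootstrap_procrustes()]).
#'
#' @param table a `feature_table`.
#' @param taxonomy its `taxonomy_table`.
#' @param metadata a `sample_metadata` (supplies `host_species`).
#' @param tree host species phylogeny.
#' @param rank_levels subset of `c("asv", "genus", "family", "order")`.
#' @param n_boot,frac,seed bootstrap controls.
#' @param pseudocount_rule passed to [clr_transform()].
#' @param epsilon grafting branch length; see [graft_samples()].
#' @return a `bootstrap_sweep` over ranks.
#' @export
phylosymbiosis_test <- function(table, taxonomy, metadata, tree,
                                rank_levels = c("asv", "genus", "family", "order"),
                                n_boot = 999L, frac = 0.9, seed,
                                pseudocount_rule = "unit", epsilon = NULL) {
  frac <- check_scalar_num(frac, "frac", 1e-12, 1)
  n_boot <- check_scalar_int(n_boot, "n_boot", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  validate_alignment(table, metadata = metadata)
  ids <- sample_ids(table)
  s2s <- stats::setNames(metadata$host_species[match(ids, metadata$sample_id)], ids)
  grafted <- graft_samples(tree, s2s, epsilon)
  host_scores <- pcoa_embed(patristic_distance(grafted)[ids, ids])
  n <- length(ids)
  m <- ceiling(frac * n)
  out <- lapply(rank_levels, function(rank) {
    dmic <- aitchison_distance(clr_transform(
      agglomerate_or_asv(table, taxonomy, rank), pseudocount_rule))
    mic_scores <- pcoa_embed(dmic[ids, ids])
    full <- procrustes_correlation(mic_scores, host_scores)$correlation
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    seed_rng(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- ids[sample.int(n, m)]
      procrustes_correlation(mic_scores[idx, , drop = FALSE],
                             host_scores[idx, , drop = FALSE])$correlation
    }, numeric(1))
    structure(list(rank = rank, correlation = full, replicates = reps,
                   interval = boot_interval(reps), frac = frac, n_boot = n_boot),
              class = "bootstrap_distribution")
  })
  names(out) <- rank_levels
  structure(out, class = "bootstrap_sweep")
}

# ---------------------------------------------------------------------------
# Mantel

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries and permutes the rows/columns
#' of `d2` jointly for the null; upper-tail
#' `p = (b + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 `distance_matrix` objects with matching labels.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return a list: `r`, `p`, `method`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, method = c("pearson", "spearman"), n_perm = 999L, seed) {
  method <- match.arg(method)
  n_perm <- check_scalar_int(n_perm, "n_perm", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (nrow(m1) < 4L) abort("need >= 4 objects", class = "phylosym_argument_error")
  if (!setequal(rownames(m1), rownames(m2))) {
    abort("distance matrices have mismatched labels",
          class = "phylosym_validation_error")
  }
  m2 <- m2[rownames(m1), rownames(m1)]
  r_obs <- stats::cor(upper_tri_vec(m1), upper_tri_vec(m2), method = method)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  n <- nrow(m1)
  null <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(upper_tri_vec(m1), upper_tri_vec(m2[p, p]), method = method)
  }, numeric(1))
  list(r = r_obs, p = perm_pvalue(null, r_obs, "upper"),
       method = method, n_perm = n_perm, seed = seed)
}

# ---------------------------------------------------------------------------
# Diet analysis

#' Diet-composition analysis
#'
#' Merges each kingdom's table to host-species level, relates the
#' species-level Aitchison community distances to Euclidean distances
#' over diet proportions via Mantel tests, and regresses species-level
#' Shannon diversity on the first two axes of a centred, scaled diet
#' PCA (ordinary least squares with species-resampling bootstrap CIs).
#' Species missing from the diet table are dropped with a report.
#'
#' @param fungi,bacteria `feature_table`s.
#' @param metadata a `sample_metadata`.
#' @param diet a `diet_table`.
#' @param n_perm Mantel permutations.
#' @param n_boot bootstrap replicates for slope CIs.
#' @param seed integer seed.
#' @param mantel_method passed to [mantel()].
#' @param pseudocount_rule passed to [clr_transform()].
#' @return a `diet_analysis` list: `pca` (scores + explained), `mantel`
#'   (per kingdom), `slopes` (per kingdom x axis with 95% CI),
#'   `species`, `dropped_species`.
#' @export
diet_analysis <- function(fungi, bacteria, metadata, diet, n_perm = 999L,
                          n_boot = 999L, seed, mantel_method = "pearson",
                          pseudocount_rule = "unit") {
  seed <- check_scalar_int(seed, "seed", 0L)
  mf <- merge_by_species(fungi, metadata)
  mb <- merge_by_species(bacteria, metadata)
  species <- intersect(intersect(sample_ids(mf), sample_ids(mb)), diet$species)
  dropped <- setdiff(union(sample_ids(mf), sample_ids(mb)), species)
  if (length(species) < 4L) abort("fewer than 4 species with diet data",
                                  class = "phylosym_argument_error")
  if (length(dropped)) {
    message("diet_analysis: dropped species without diet or paired data: ",
            paste(dropped, collapse = ", "))
  }
  mf <- subset_samples(mf, species)
  mb <- subset_samples(mb, species)
  prop <- as.matrix(diet[match(species, diet$species), DIET_CATEGORIES])
  rownames(prop) <- species
  keep_cols <- apply(prop, 2, stats::sd) > 0
  pc <- stats::prcomp(prop[, keep_cols, drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  explained <- pc$sdev^2 / sum(pc$sdev^2)

  d_diet <- as_distance_matrix(as.matrix(stats::dist(prop)))
  mant <- list(
    fungi = mantel(aitchison_distance(clr_transform(mf, pseudocount_rule)),
                   d_diet, method = mantel_method, n_perm = n_perm, seed = seed),
    bacteria = mantel(aitchison_distance(clr_transform(mb, pseudocount_rule)),
                      d_diet, method = mantel_method, n_perm = n_perm, seed = seed + 1L)
  )

  slope_fit <- function(sh, sc) {
    df <- as.data.frame(sc)
    names(df) <- paste0("PC", seq_len(ncol(df)))
    df$sh <- sh
    stats::coef(stats::lm(sh ~ ., data = df))[-1]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed + 2L)
  slopes <- do.call(rbind, lapply(c("fungi", "bacteria"), function(kg) {
    tab <- if (kg == "fungi") mf else mb
    sh <- alpha_diversity(tab)$shannon
    est <- slope_fit(sh, scores)
    boots <- t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(sh), replace = TRUE)
      if (length(unique(idx)) < 3L) idx <- seq_along(sh)
      slope_fit(sh[idx], scores[idx, , drop = FALSE])
    }, numeric(length(est))))
    ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(kingdom = kg, axis = paste0("PC", seq_along(est)),
               slope = unname(est), ci_lower = ci[1, ], ci_upper = ci[2, ],
               stringsAsFactors = FALSE)
  }))
  structure(list(pca = list(scores = scores, explained = explained),
                 mantel = mant, slopes = slopes, species = species,
                 dropped_species = dropped),
            class = "diet_analysis")
}
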