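## Compositional processing: rarefaction, CLR, Aitchison distances,
## taxonomic agglomeration, species-level merging and alpha diversity.

#' Rarefy a feature table to a fixed depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads.  Samples whose total is
#' below `depth` are dropped and reported via the `"dropped_samples"`
#' attribute and a message, matching the convention of excluding
#' sub-depth libraries rather than keeping them unrarefied.
#'
#' @param table a `feature_table`.
#' @param depth target reads per sample (default 500).
#' @param seed integer seed; the draw is deterministic given it.
#' @return a rarefied `feature_table`; attribute `dropped_samples`
#'   lists excluded samples.
#' @export
rarefy <- function(table, depth = 500L, seed) {
  stopifnot(inherits(table, "feature_table"))
  depth <- check_scalar_int(depth, "depth", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  totals <- colSums(table$counts)
  drop <- colnames(table$counts)[totals < depth]
  keep <- setdiff(colnames(table$counts), drop)
  if (!length(keep)) abort("no sample reaches the rarefaction depth")
  if (length(drop)) {
    message(sprintf("rarefy: dropped %d sample(s) below depth %d: %s",
                    length(drop), depth, paste(drop, collapse = ", ")))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  nf <- nrow(table$counts)
  out <- vapply(keep, function(s) {
    x <- table$counts[, s]
    picked <- sample.int(sum(x), depth)   # reads as 1..total, mapped to taxa
    tabulate(findInterval(picked - 1L, cumsum(x), left.open = FALSE) + 1L, nf)
  }, numeric(nf))
  rownames(out) <- rownames(table$counts)
  res <- feature_table(out, table$kingdom)
  attr(res, "dropped_samples") <- drop
  res
}

#' Centred log-ratio transform
#'
#' Per sample i with pseudocounted counts `x`, the CLR is
#' `ln(x_j) - mean_k ln(x_k)`; rows of the result (samples) sum to zero.
#'
#' @param table a `feature_table`.
#' @param pseudocount_rule `"unit"` adds 1 to every count (default);
#'   `"half_min_nonzero"` adds half the smallest non-zero count in the
#'   table; `"none"` adds nothing and errors on zeros.
#' @return a `clr_matrix`: samples x features real matrix with
#'   attributes `pseudocount` and `kingdom`.
#' @export
clr_transform <- function(table, pseudocount_rule = c("unit", "half_min_nonzero", "none")) {
  stopifnot(inherits(table, "feature_table"))
  pseudocount_rule <- match.arg(pseudocount_rule)
  counts <- t(table$counts)     # samples x features
  zero_samples <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero_samples)) {
    abort("all-zero sample(s), cannot form a composition: ",
          paste(zero_samples, collapse = ", "),
          class = "phylosym_validation_error")
  }
  delta <- switch(pseudocount_rule,
    unit = 1,
    half_min_nonzero = min(counts[counts > 0]) / 2,
    none = 0
  )
  if (delta == 0 && any(counts == 0)) {
    abort("pseudocount_rule 'none' requires strictly positive counts",
          class = "phylosym_argument_error")
  }
  lx <- log(counts + delta)
  out <- lx - rowMeans(lx)
  structure(out, class = c("clr_matrix", "matrix", "array"),
            pseudocount = delta, kingdom = table$kingdom)
}

#' Aitchison distance between samples
#'
#' Euclidean distance between rows of a CLR matrix.
#'
#' @param clr a `clr_matrix` (samples x features).
#' @return a symmetric, hollow `distance_matrix` over samples.
#' @export
aitchison_distance <- function(clr) {
  stopifnot(inherits(clr, "clr_matrix"))
  if (nrow(clr) < 2L) abort("need at least 2 samples")
  as_distance_matrix(as.matrix(stats::dist(unclass(clr))))
}

#' Agglomerate features to a higher taxonomic rank
#'
#' Features sharing the full lineage down to `rank` are summed.  Because
#' bins are keyed by the whole lineage prefix, an `"unassigned"` label
#' forms its own bin within each parent lineage rather than one global
#' pool.  Per-sample totals are conserved exactly.
#'
#' @param table a `feature_table`.
#' @param taxonomy a `taxonomy_table` covering every feature.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return a `feature_table` of binned counts; attribute `lineage` maps
#'   bin ids to their lineage strings.
#' @export
agglomerate <- function(table, taxonomy,
                        rank = c("genus", "family", "order", "class", "phylum")) {
  stopifnot(inherits(table, "feature_table"), inherits(taxonomy, "taxonomy_table"))
  rank <- match.arg(rank)
  validate_alignment(table, taxonomy = taxonomy)
  idx <- match(feature_ids(table), taxonomy$feature_id)
  upto <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
  lineage <- do.call(paste, c(lapply(upto, function(r) taxonomy[[r]][idx]), sep = ";"))
  merged <- rowsum(table$counts, group = lineage, reorder = TRUE)
  res <- feature_table(merged, table$kingdom)
  attr(res, "lineage") <- rownames(merged)
  attr(res, "rank") <- rank
  res
}

#' Merge samples by host species
#'
#' Sums counts over all samples of each host species, yielding one
#' column per species (species-level community profiles).
#'
#' @param table a `feature_table`.
#' @param metadata a `sample_metadata` covering every sample.
#' @return a `feature_table` with species as columns.
#' @export
merge_by_species <- function(table, metadata) {
  stopifnot(inherits(table, "feature_table"))
  validate_alignment(table, metadata = metadata)
  sp <- metadata$host_species[match(sample_ids(table), metadata$sample_id)]
  merged <- t(rowsum(t(table$counts), group = sp, reorder = TRUE))
  feature_table(merged, table$kingdom)
}

#' Alpha diversity per sample
#'
#' Observed richness (features with count > 0), Shannon entropy
#' (natural log) and the inverse Simpson index `1 / sum(p^2)`.
#'
#' @param table a `feature_table` with strictly positive sample totals.
#' @return a data frame with one row per sample.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$counts)
  empty <- colnames(table$counts)[totals == 0]
  if (length(empty)) abort("empty sample(s): ", paste(empty, collapse = ", "),
                           class = "phylosym_validation_error")
  p <- sweep(table$counts, 2, totals, "/")
  shannon <- apply(p, 2, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
  data.frame(
    sample_id = colnames(table$counts),
    observed_richness = as.integer(colSums(table$counts > 0)),
    shannon = unname(shannon),
    inverse_simpson = unname(1 / colSums(p^2)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Paired bacterial-vs-fungal richness summary
#'
#' For samples present in both kingdoms, reports per host class and
#' overall the proportion of individuals whose bacterial richness
#' exceeds their fungal richness, with an exact (Clopper-Pearson)
#' binomial 95% CI.  Ties are excluded from both numerator and
#' denominator and reported separately.
#'
#' @param fungi_alpha,bacteria_alpha outputs of [alpha_diversity()].
#' @param metadata a `sample_metadata`.
#' @return a data frame, one row per host class plus `"overall"`.
#' @export
paired_richness_summary <- function(fungi_alpha, bacteria_alpha, metadata) {
  shared <- intersect(fungi_alpha$sample_id, bacteria_alpha$sample_id)
  if (!length(shared)) abort("no shared samples between the two kingdoms")
  f <- fungi_alpha$observed_richness[match(shared, fungi_alpha$sample_id)]
  b <- bacteria_alpha$observed_richness[match(shared, bacteria_alpha$sample_id)]
  cls <- metadata$host_class[match(shared, metadata$sample_id)]
  one <- function(sel, label) {
    fb <- b[sel]; ff <- f[sel]
    ties <- sum(fb == ff)
    wins <- sum(fb > ff)
    m <- sum(sel) - ties
    if (m > 0) {
      bt <- stats::binom.test(wins, m)
      data.frame(group = label, n = sum(sel), n_ties = ties,
                 n_bacteria_higher = wins, proportion = wins / m,
                 ci_lower = bt$conf.int[1], ci_upper = bt$conf.int[2],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = label, n = sum(sel), n_ties = ties,
                 n_bacteria_higher = 0L, proportion = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(sort(unique(cls)), function(cl) one(cls == cl, cl))
  out <- rbind(do.call(rbind, rows), one(rep(TRUE, length(shared)), "overall"))
  rownames(out) <- NULL
  out
}
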