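## Host-tree computations: patristic distances, sample-tip grafting,
## Abouheif's Cmean phylogenetic-signal test, Benjamini-Hochberg.

#' Patristic distance matrix
#'
#' `d(i, j)` is the total branch length on the path between tips i and
#' j.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a symmetric `distance_matrix` over tips.
#' @export
patristic_distance <- function(tree) {
  validate_host_tree(tree)
  if (length(tree$tip.label) < 2L) abort("need at least 2 tips")
  as_distance_matrix(ape::cophenetic.phylo(tree))
}

#' Graft sample-level tips onto a species phylogeny
#'
#' Each species tip with k >= 2 samples is replaced by a polytomy of
#' its sample tips, each attached at branch length `epsilon`; species
#' with a single sample keep one tip, renamed to the sample id.  The
#' cross-species sample distance therefore equals the species patristic
#' distance plus `2 * epsilon` (or `epsilon` on a singleton side).
#'
#' @param tree species phylogeny.
#' @param sample_to_species named character vector: names are sample
#'   ids, values are species (tree tips).
#' @param epsilon attachment branch length; default `1e-6 *` tree depth.
#' @return a `phylo` whose tips are the samples.
#' @export
graft_samples <- function(tree, sample_to_species, epsilon = NULL) {
  validate_host_tree(tree)
  missing <- setdiff(unique(sample_to_species), tree$tip.label)
  if (length(missing)) {
    abort("species not in tree: ", paste(missing, collapse = ", "),
          class = "phylosym_validation_error")
  }
  if (is.null(epsilon)) epsilon <- 1e-6 * max(ape::node.depth.edgelength(tree))
  epsilon <- check_scalar_num(epsilon, "epsilon", min = .Machine$double.xmin)
  used <- unique(sample_to_species)
  pruned <- if (length(used) < length(tree$tip.label)) {
    ape::keep.tip(tree, used)
  } else tree
  ## Newick-level surgery: every tip label in a newick string is
  ## preceded by '(' or ',' and followed by ':' (branch lengths are
  ## guaranteed by validation), so anchored replacement is unambiguous.
  nwk <- ape::write.tree(pruned)
  eps_str <- sprintf("%.10g", epsilon)
  for (sp in used) {
    samples <- names(sample_to_species)[sample_to_species == sp]
    repl <- if (length(samples) == 1L) samples else {
      paste0("(", paste0(samples, ":", eps_str, collapse = ","), ")")
    }
    nwk <- sub(paste0("([(,])", sp, ":"), paste0("\\1", repl, ":"), nwk)
  }
  grafted <- ape::read.tree(text = nwk)
  validate_host_tree(grafted)
}

#' Abouheif proximity matrix
#'
#' The classic construction: `A_ij` is proportional to the reciprocal
#' of the product, over interior nodes on the path between tips i and
#' j, of the number of direct descendants of each node; the diagonal is
#' zero and each row is normalized to sum to 1.
#'
#' @param tree a `phylo` with >= 4 tips.
#' @return tips x tips proximity matrix with unit row sums.
#' @export
abouheif_proximity <- function(tree) {
  validate_host_tree(tree)
  n <- length(tree$tip.label)
  if (n < 4L) abort("need at least 4 tips", class = "phylosym_argument_error")
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)  # direct descendants
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      path <- ape::nodepath(tree, i, j)
      interior <- path[path > n]
      A[i, j] <- A[j, i] <- 1 / prod(dd[interior])
    }
  }
  A / rowSums(A)
}

#' Abouheif's Cmean statistic
#'
#' Moran-type autocorrelation `x' A x / x' x` of the centred, scaled
#' trait under the Abouheif proximity matrix.  Under no signal its
#' expectation is `-1 / (n - 1)`.
#'
#' @param trait named numeric vector over every tip, nonzero variance.
#' @param tree a `phylo`.
#' @return the Cmean value.
#' @export
abouheif_cmean <- function(trait, tree) {
  A <- abouheif_proximity(tree)
  x <- align_trait(trait, tree)
  drop(crossprod(x, A %*% x) / crossprod(x))
}

align_trait <- function(trait, tree) {
  tips <- tree$tip.label
  if (is.null(names(trait))) {
    if (length(trait) != length(tips)) abort("trait length must match tip count")
    names(trait) <- tips
  }
  missing <- setdiff(tips, names(trait))
  if (length(missing)) abort("trait missing for tip(s): ", paste(missing, collapse = ", "))
  x <- trait[tips]
  if (anyNA(x)) abort("trait contains NA")
  if (stats::sd(x) == 0) abort("trait has zero variance",
                               class = "phylosym_validation_error")
  as.numeric(scale(x))
}

#' Permutation test for Abouheif phylogenetic signal
#'
#' The null is built by permuting trait values across tips; by default
#' the test is one-tailed for positive autocorrelation (the direction
#' phylosymbiosis predicts).  P-values use `(b + 1) / (n_perm + 1)`.
#'
#' @param trait named per-tip trait vector.
#' @param tree a `phylo`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param tail `"upper"` (default) or `"two_sided"`.
#' @param trait_name label for the result row.
#' @return a one-row data frame: `trait`, `cmean`, `p_raw`, `n_perm`,
#'   `seed`; pass several through [bh_correct()] to add `p_bh`.
#' @export
abouheif_test <- function(trait, tree, n_perm = 999L, seed,
                          tail = c("upper", "two_sided"), trait_name = "trait") {
  tail <- match.arg(tail)
  n_perm <- check_scalar_int(n_perm, "n_perm", 99L)
  seed <- check_scalar_int(seed, "seed", 0L)
  A <- abouheif_proximity(tree)
  x <- align_trait(trait, tree)
  stat <- function(v) drop(crossprod(v, A %*% v) / crossprod(v))
  obs <- stat(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  null <- vapply(seq_len(n_perm), function(k) stat(sample(x)), numeric(1))
  centre <- -1 / (length(x) - 1)
  p <- if (tail == "upper") perm_pvalue(null, obs, "upper") else {
    perm_pvalue(null - centre, obs - centre, "two_sided")
  }
  data.frame(trait = trait_name, cmean = obs, p_raw = p,
             n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values, elementwise >= the input, capped at 1.
#' @export
bh_correct <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]", class = "phylosym_argument_error")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ## step-up: running minimum of p * m / rank from the largest down
  adj <- pmin(1, cummin(p_values[o] * m / seq(m, 1)))
  adj[order(o)]
}
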