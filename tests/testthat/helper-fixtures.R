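## Shared fixtures, all built in code.

## Tiny deterministic feature table: 4 features x 3 samples.
tiny_table <- function(kingdom = "fungi") {
  counts <- matrix(c(
    10, 0, 5,
    20, 8, 0,
    0, 2, 1,
    5, 5, 4
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  feature_table(counts, kingdom)
}

tiny_taxonomy <- function(ids = paste0("f", 1:4)) {
  k <- seq_along(ids)
  taxonomy_table(data.frame(
    feature_id = ids,
    kingdom = "fungi",
    phylum = c("pA", "pA", "pB", "pB")[k],
    class = c("cA", "cA", "cB", "cB")[k],
    order = c("oA", "oA", "oB", "oB")[k],
    family = c("famA", "famA", "famB", "famC")[k],
    genus = c("gA", "gA", "gB", "")[k],
    stringsAsFactors = FALSE
  ))
}

tiny_metadata <- function(ids = paste0("s", 1:3),
                          species = c("sp1", "sp1", "sp2")) {
  sample_metadata(data.frame(
    sample_id = ids,
    host_species = species,
    host_order = "ord1",
    host_class = rep(c("clsA", "clsB"), length.out = length(ids)),
    sample_type = "faecal",
    tissue_storage = "frozen",
    extraction_kit = "kitA",
    stringsAsFactors = FALSE
  ))
}

## Small simulated dataset shared across tests (memoised per options).
sim_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, n_species = 10, samples_per_species = 4,
           n_features = 60, depth = 1500, coupling = 0.5,
           phylo_strength = 1, sigma_within = 0.5,
           batch_effect_size = 0.4, diet_signal = 0.5) {
    key <- paste(seed, n_species, samples_per_species, n_features, depth,
                 coupling, phylo_strength, sigma_within, batch_effect_size,
                 diet_signal, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    tree <- simulate_host_tree(n_species, seed)
    ds <- simulate_paired_microbiome(tree, simulation_config(
      n_species = n_species, samples_per_species = samples_per_species,
      n_features_per_kingdom = n_features, depth = depth,
      phylo_strength = phylo_strength, coupling = coupling,
      sigma_within = sigma_within, batch_effect_size = batch_effect_size,
      diet_signal = diet_signal, seed = seed))
    cache[[key]] <- ds
    ds
  }
})

## Independent patristic oracle: undirected shortest path over the edge
## graph (never touches cophenetic).
patristic_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  d <- igraph::distances(g, weights = tree$edge.length)
  idx <- match(as.character(seq_len(n)), rownames(d))
  out <- d[idx, idx]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

## Independent Abouheif proximity oracle: path interior nodes found by
## comparing root-ward ancestor lists, not nodepath().
abouheif_proximity_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  ancestors <- function(v) {
    out <- integer(0)
    while (parent[v] != 0) { v <- parent[v]; out <- c(out, v) }
    out
  }
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ai <- ancestors(i); aj <- ancestors(j)
    mrca <- intersect(ai, aj)[1]
    path <- c(setdiff(ai, intersect(ai, aj)), setdiff(aj, intersect(ai, aj)), mrca)
    A[i, j] <- A[j, i] <- 1 / prod(dd[path])
  }
  A / rowSums(A)
}

## Exhaustive maximum-modularity partition of a small undirected graph.
best_partition_bruteforce <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  parts <- set_partitions(n)
  q <- vapply(parts, function(p) igraph::modularity(g, p), numeric(1))
  best <- which.max(q)
  list(modularity = q[best], membership = parts[[best]],
       n_communities = length(unique(parts[[best]])))
}

## All set partitions of n elements as membership vectors
## (restricted-growth strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

## Exact sequential-PERMANOVA p by full enumeration of label
## permutations (single grouping term, small n).
permanova_exact_p <- function(d, groups) {
  n <- length(groups)
  perms <- all_permutations(n)
  f_for <- function(g) {
    meta <- sample_metadata(data.frame(
      sample_id = rownames(as.matrix(d)), host_species = g, host_order = "o",
      host_class = "c", sample_type = "t", tissue_storage = "s",
      extraction_kit = "k", stringsAsFactors = FALSE))
    permanova_sequential(d, meta, "host_species", n_perm = 1, seed = 1)$pseudo_f[1]
  }
  f_obs <- f_for(groups)
  f_all <- vapply(perms, function(p) f_for(groups[p]), numeric(1))
  mean(f_all >= f_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1
    out[[k]] <- append(p, n, after = pos)
  }
  out
}
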