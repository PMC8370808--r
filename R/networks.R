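## Cross-kingdom co-occurrence networks: Spearman correlation matrices,
## thresholded graphs, structural traits, and label-permutation nulls
## for fungal betweenness and phylum-pair coupling.

#' Spearman correlation matrix over taxa of a merged two-kingdom table
#'
#' Stacks the (typically family-agglomerated) fungal and bacterial
#' tables over their shared samples, applies a prevalence filter, drops
#' constant taxa (whose Spearman coefficient is undefined) with a
#' report, and returns pairwise Spearman rho (average ranks for ties)
#' over samples for every within- and cross-kingdom taxon pair.
#'
#' @param fungi,bacteria `feature_table`s over shared samples (taxa in
#'   rows, usually agglomerated bins).
#' @param min_prevalence minimum fraction of samples in which a taxon
#'   must be present (count > 0); default 0.2.
#' @return a `cooccurrence_matrix`: the rho matrix with attributes
#'   `kingdom` (per taxon), `dropped` (filtered taxa) and `n_samples`.
#' @export
spearman_matrix <- function(fungi, bacteria, min_prevalence = 0.2) {
  min_prevalence <- check_scalar_num(min_prevalence, "min_prevalence", 0, 1)
  shared <- intersect(sample_ids(fungi), sample_ids(bacteria))
  if (length(shared) < 5L) abort("need >= 5 shared samples",
                                 class = "phylosym_argument_error")
  stack <- rbind(subset_samples(fungi, shared)$counts,
                 subset_samples(bacteria, shared)$counts)
  taxa_kingdom <- c(rep("fungi", nrow(fungi$counts)),
                    rep("bacteria", nrow(bacteria$counts)))
  rownames(stack) <- make.unique(rownames(stack))
  names(taxa_kingdom) <- rownames(stack)
  prevalent <- rowMeans(stack > 0) >= min_prevalence
  constant <- apply(stack, 1, function(x) stats::sd(x) == 0)
  keep <- prevalent & !constant
  dropped <- rownames(stack)[!keep]
  if (sum(keep) < 2L) abort("fewer than 2 taxa pass the prevalence filter")
  rho <- stats::cor(t(stack[keep, , drop = FALSE]), method = "spearman")
  structure(rho, class = c("cooccurrence_matrix", "matrix", "array"),
            kingdom = taxa_kingdom[keep], dropped = dropped,
            n_samples = length(shared))
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' Adds an undirected edge for every taxon pair with `|rho| >
#' threshold`, carrying the sign and value of rho.  Isolated taxa are
#' retained as nodes with `isolated = TRUE`.
#'
#' @param corr a `cooccurrence_matrix` (or plain labelled symmetric
#'   matrix, in which case `kingdom` must be supplied).
#' @param threshold absolute-correlation cutoff in (0, 1); default 0.5.
#' @param kingdom optional named vector of node kingdoms.
#' @param phylum optional named vector of node phylum labels.
#' @param group optional label (host species or class) carried on the
#'   network.
#' @return a `cooccurrence_network`: list with `graph` (igraph),
#'   `nodes` and `edges` data frames, `threshold`, `group`.
#' @export
build_network <- function(corr, threshold = 0.5, kingdom = NULL, phylum = NULL,
                          group = NA_character_) {
  threshold <- check_scalar_num(threshold, "threshold", 1e-12, 1 - 1e-12)
  rho <- unclass(as.matrix(corr))
  kingdom <- kingdom %||% attr(corr, "kingdom")
  taxa <- rownames(rho)
  if (is.null(kingdom)) abort("node kingdom labels required")
  kingdom <- kingdom[taxa]
  pair <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = taxa[pair[, 1]], to = taxa[pair[, 2]],
    rho = rho[pair], sign = ifelse(rho[pair] > 0, "+", "-"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = taxa))
  igraph::V(g)$kingdom <- unname(kingdom)
  if (!is.null(phylum)) igraph::V(g)$phylum <- unname(phylum[taxa])
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$sign <- edges$sign
  nodes <- data.frame(taxon = taxa, kingdom = unname(kingdom),
                      phylum = if (!is.null(phylum)) unname(phylum[taxa]) else NA_character_,
                      isolated = !(taxa %in% c(edges$from, edges$to)),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 threshold = threshold, group = group),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges (|rho| > %.2f)%s\n",
              nrow(x$nodes), nrow(x$edges), x$threshold,
              if (!is.na(x$group)) paste0(", group ", x$group) else ""))
  invisible(x)
}

#' Structural traits of a co-occurrence network
#'
#' Components are connected components of the full (signed) graph.
#' Communities come from greedy modularity maximization on the
#' unweighted positive-edge subgraph (all nodes retained; nodes with no
#' positive edge form singleton communities); `modularity` is the
#' modularity of that partition on the positive subgraph.  Betweenness
#' is computed on the full unsigned, unweighted graph, so negative
#' edges still transmit structural position.
#'
#' @param net a `cooccurrence_network`.
#' @return a one-row `network_traits` data frame: `n_nodes`, `n_edges`,
#'   `n_components`, `n_communities`, `modularity`,
#'   `proportion_positive_edges`, `mean_betweenness_fungi`,
#'   `mean_betweenness_bacteria`.  An empty graph yields `NA` sentinels
#'   with a warning.
#' @export
network_traits <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  n_edges <- igraph::ecount(g)
  if (n_edges == 0L) {
    warning("empty network: traits are NA sentinels")
    return(data.frame(group = net$group, n_nodes = igraph::vcount(g), n_edges = 0L,
                      n_components = igraph::vcount(g), n_communities = NA_integer_,
                      modularity = NA_real_, proportion_positive_edges = NA_real_,
                      mean_betweenness_fungi = NA_real_,
                      mean_betweenness_bacteria = NA_real_,
                      stringsAsFactors = FALSE))
  }
  pos <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$sign == "+"],
                                     delete.vertices = FALSE)
  comm <- igraph::cluster_fast_greedy(pos, weights = NULL)
  mod <- if (igraph::ecount(pos) > 0) {
    igraph::modularity(pos, igraph::membership(comm))
  } else NA_real_
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  kingdom <- igraph::V(g)$kingdom
  data.frame(
    group = net$group,
    n_nodes = igraph::vcount(g),
    n_edges = n_edges,
    n_components = igraph::count_components(g),
    n_communities = length(unique(igraph::membership(comm))),
    modularity = mod,
    proportion_positive_edges = mean(igraph::E(g)$sign == "+"),
    mean_betweenness_fungi = mean(btw[kingdom == "fungi"]),
    mean_betweenness_bacteria = mean(btw[kingdom == "bacteria"]),
    stringsAsFactors = FALSE
  )
}

#' Permutation null test for mean fungal betweenness
#'
#' Observed statistic: mean betweenness of fungal nodes (unsigned,
#' unweighted graph).  Null: shuffle kingdom labels over nodes,
#' preserving counts, and recompute; lower-tail
#' `p = (b + 1) / (n_perm + 1)` asks whether fungi are more peripheral
#' than chance predicts.
#'
#' @param net a `cooccurrence_network` containing both kingdoms.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param direction `"lower"` (default), `"upper"` or `"two_sided"`.
#' @return a `permutation_null_result` list: `observed`, `null`, `p`,
#'   `n_perm`, `seed`, `direction`, `statistic`.
#' @export
betweenness_null_test <- function(net, n_perm = 999L, seed,
                                  direction = c("lower", "upper", "two_sided")) {
  direction <- match.arg(direction)
  n_perm <- check_scalar_int(n_perm, "n_perm", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  kingdom <- igraph::V(net$graph)$kingdom
  if (length(unique(kingdom)) < 2L) {
    abort("network contains a single kingdom", class = "phylosym_argument_error")
  }
  btw <- igraph::betweenness(net$graph, directed = FALSE, weights = NA)
  is_fun <- kingdom == "fungi"
  obs <- mean(btw[is_fun])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  k <- sum(is_fun)
  null <- vapply(seq_len(n_perm), function(b) {
    mean(btw[sample.int(length(btw), k)])
  }, numeric(1))
  structure(list(observed = obs, null = null,
                 p = perm_pvalue(null, obs, direction),
                 n_perm = n_perm, seed = seed, direction = direction,
                 statistic = "mean_betweenness_fungi"),
            class = "permutation_null_result")
}

cross_kingdom_positive_edges <- function(net) {
  e <- net$edges
  nd <- net$nodes
  kg <- stats::setNames(nd$kingdom, nd$taxon)
  ph <- stats::setNames(nd$phylum, nd$taxon)
  cross <- e[kg[e$from] != kg[e$to] & e$sign == "+", , drop = FALSE]
  if (!nrow(cross)) abort("no cross-kingdom positive edges",
                          class = "phylosym_validation_error")
  fp <- ifelse(kg[cross$from] == "fungi", ph[cross$from], ph[cross$to])
  bp <- ifelse(kg[cross$from] == "bacteria", ph[cross$from], ph[cross$to])
  data.frame(fungal_phylum = unname(fp), bacterial_phylum = unname(bp),
             stringsAsFactors = FALSE)
}

#' Phylum-pair positive co-occurrence frequencies
#'
#' Cell (f, b) is the number of positive cross-kingdom edges between
#' fungal phylum f and bacterial phylum b divided by the total number
#' of positive cross-kingdom edges; cells over all pairs sum to 1.
#'
#' @param net a `cooccurrence_network` whose nodes carry `phylum`.
#' @return matrix of proportions (fungal phyla x bacterial phyla).
#' @export
phylum_pair_frequency <- function(net) {
  cross <- cross_kingdom_positive_edges(net)
  tab <- table(cross$fungal_phylum, cross$bacterial_phylum)
  as.matrix(tab / sum(tab))
}

#' Permutation null test for a focal phylum-pair coupling
#'
#' Observed statistic: the focal pair's share of positive cross-kingdom
#' edges.  Null: shuffle phylum labels within each kingdom and
#' recompute; upper-tail `p = (b + 1) / (n_perm + 1)`.
#'
#' @param net a `cooccurrence_network` with `phylum` node labels.
#' @param pair length-2 character: `c(fungal_phylum, bacterial_phylum)`.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return a `permutation_null_result`.
#' @export
phylum_pair_null_test <- function(net, pair, n_perm = 999L, seed) {
  n_perm <- check_scalar_int(n_perm, "n_perm", 1L)
  seed <- check_scalar_int(seed, "seed", 0L)
  stopifnot(length(pair) == 2L)
  nd <- net$nodes
  if (!pair[1] %in% nd$phylum[nd$kingdom == "fungi"] ||
      !pair[2] %in% nd$phylum[nd$kingdom == "bacteria"]) {
    abort("focal pair phyla not present in the network",
          class = "phylosym_argument_error")
  }
  e <- net$edges
  kg <- stats::setNames(nd$kingdom, nd$taxon)
  cross <- e[kg[e$from] != kg[e$to] & e$sign == "+", , drop = FALSE]
  if (!nrow(cross)) abort("no cross-kingdom positive edges",
                          class = "phylosym_validation_error")
  ## orient each edge as (fungal endpoint, bacterial endpoint)
  fnode <- ifelse(kg[cross$from] == "fungi", cross$from, cross$to)
  bnode <- ifelse(kg[cross$from] == "bacteria", cross$from, cross$to)
  freq_for <- function(ph) {
    mean(ph[fnode] == pair[1] & ph[bnode] == pair[2])
  }
  ph_obs <- stats::setNames(nd$phylum, nd$taxon)
  obs <- freq_for(ph_obs)
  is_fun <- nd$kingdom == "fungi"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  seed_rng(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    ph <- ph_obs
    ph[is_fun] <- sample(ph[is_fun])
    ph[!is_fun] <- sample(ph[!is_fun])
    freq_for(ph)
  }, numeric(1))
  structure(list(observed = obs, null = null,
                 p = perm_pvalue(null, obs, "upper"),
                 n_perm = n_perm, seed = seed, direction = "upper",
                 statistic = paste0("positive_edge_freq_", pair[1], "x", pair[2])),
            class = "permutation_null_result")
}

#' Per-group co-occurrence networks and traits
#'
#' For each host group (species, and classes by pooling samples):
#' rarefy each kingdom, agglomerate to family, merge on shared
#' samples, build the Spearman network and compute its traits.  Groups
#' with fewer than `min_samples` paired post-rarefaction samples are
#' skipped and reported.
#'
#' @param fungi,bacteria `feature_table`s (raw counts).
#' @param taxonomy_fungi,taxonomy_bacteria matching taxonomies.
#' @param metadata a `sample_metadata`.
#' @param depth rarefaction depth (default 500).
#' @param threshold edge threshold on |rho| (default 0.5).
#' @param min_prevalence prevalence filter (default 0.2).
#' @param min_samples minimum paired samples per group (default 5).
#' @param seed integer seed (rarefaction).
#' @return list with `species` and `class` elements, each a list of
#'   `cooccurrence_network`s, a combined `traits` data frame, and
#'   `skipped` group names.
#' @export
species_and_class_networks <- function(fungi, bacteria, taxonomy_fungi,
                                       taxonomy_bacteria, metadata,
                                       depth = 500L, threshold = 0.5,
                                       min_prevalence = 0.2, min_samples = 5L,
                                       seed) {
  seed <- check_scalar_int(seed, "seed", 0L)
  min_samples <- check_scalar_int(min_samples, "min_samples", 2L)
  rf <- suppressMessages(rarefy(fungi, depth, seed))
  rb <- suppressMessages(rarefy(bacteria, depth, seed + 1L))
  ff <- agglomerate(rf, taxonomy_fungi, "family")
  fb <- agglomerate(rb, taxonomy_bacteria, "family")
  phylum_of <- function(aggl) {
    ## lineage strings are kingdom;phylum;...: recover the phylum bin
    vapply(strsplit(feature_ids(aggl), ";", fixed = TRUE), `[`, character(1), 2)
  }
  shared <- intersect(sample_ids(ff), sample_ids(fb))
  groups <- function(col) {
    split(shared, metadata[[col]][match(shared, metadata$sample_id)])
  }
  build_group <- function(ids, label) {
    if (length(ids) < min_samples) return(NULL)
    sm <- tryCatch(
      spearman_matrix(subset_samples(ff, ids), subset_samples(fb, ids),
                      min_prevalence),
      error = function(e) NULL)
    if (is.null(sm)) return(NULL)
    kingdom <- attr(sm, "kingdom")
    ph_all <- c(stats::setNames(phylum_of(ff), feature_ids(ff)),
                stats::setNames(phylum_of(fb), feature_ids(fb)))
    build_network(sm, threshold, kingdom = kingdom,
                  phylum = ph_all[rownames(sm)], group = label)
  }
  run_level <- function(col) {
    gs <- groups(col)
    nets <- Filter(Negate(is.null),
                   Map(build_group, gs, names(gs)))
    skipped <- setdiff(names(gs), names(nets))
    traits <- do.call(rbind, lapply(nets, function(n) {
      suppressWarnings(network_traits(n))
    }))
    list(networks = nets, traits = traits, skipped = skipped)
  }
  list(species = run_level("host_species"), class = run_level("host_class"))
}

#' Export a network as edge-list and node-attribute TSVs
#' @param net a `cooccurrence_network`.
#' @param edge_path,node_path output paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  write_tsv_schema(net$edges, edge_path, "network_edges")
  write_tsv_schema(net$nodes, node_path, "network_nodes")
  invisible(edge_path)
}
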