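## helper: wrap a hand-built correlation matrix + labels into a network
net_from_matrix <- function(rho, kingdom, phylum = NULL, threshold = 0.5) {
  structure(rho, class = c("cooccurrence_matrix", "matrix", "array"),
            kingdom = kingdom) |>
    build_network(threshold = threshold, phylum = phylum)
}

sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1; m }

test_that("Spearman matrix equals rank-then-Pearson brute force", {
  set.seed(1)
  nf <- 15; nb <- 15; n <- 20
  fungi <- feature_table(matrix(rpois(nf * n, 20), nf, n,
                                dimnames = list(paste0("f", 1:nf),
                                                paste0("s", 1:n))), "fungi")
  bact <- feature_table(matrix(rpois(nb * n, 20), nb, n,
                               dimnames = list(paste0("b", 1:nb),
                                               paste0("s", 1:n))), "bacteria")
  rho <- spearman_matrix(fungi, bact, min_prevalence = 0)
  stack <- rbind(fungi$counts, bact$counts)[rownames(rho), ]
  for (k in 1:50) {
    ij <- sample(nrow(rho), 2)
    brute <- cor(rank(stack[ij[1], ]), rank(stack[ij[2], ]))
    expect_equal(rho[ij[1], ij[2]], brute, tolerance = 1e-12)
  }

  ## monotone / anti-monotone pairs hit exactly +-1
  up <- feature_table(matrix(c(1:6, 2 * (1:6) + 3), 2, 6, byrow = TRUE,
                             dimnames = list(c("f1", "f2"), paste0("s", 1:6))),
                      "fungi")
  down <- feature_table(matrix(c(6:1), 1, 6,
                               dimnames = list("b1", paste0("s", 1:6))),
                        "bacteria")
  r2 <- spearman_matrix(up, down, min_prevalence = 0)
  expect_equal(r2["f1", "f2"], 1)
  expect_equal(r2["f1", "b1"], -1)

  ## constant taxa are dropped and reported
  cst <- feature_table(matrix(c(5, 5, 5, 5, 5, 5), 1, 6,
                              dimnames = list("bconst", paste0("s", 1:6))),
                       "bacteria")
  r3 <- spearman_matrix(up, cst, min_prevalence = 0)
  expect_true("bconst" %in% attr(r3, "dropped"))
  expect_error(spearman_matrix(subset_samples(up, paste0("s", 1:4)),
                               subset_samples(down, paste0("s", 1:4))),
               class = "phylosym_argument_error")
})

test_that("network building applies the threshold with signs", {
  rho <- sym(matrix(c(1, 0.6, -0.7,
                      0, 1, 0.4,
                      0, 0, 1), 3, 3, byrow = TRUE,
                    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  net <- net_from_matrix(rho, c(a = "fungi", b = "bacteria", c = "bacteria"))
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("+", "-"))
  expect_false(any(net$nodes$isolated))

  ## edge count is monotone non-increasing in the threshold
  set.seed(2)
  big <- sym(matrix(runif(400, -1, 1), 20, 20,
                    dimnames = list(paste0("t", 1:20), paste0("t", 1:20))))
  kg <- setNames(rep(c("fungi", "bacteria"), 10), paste0("t", 1:20))
  counts <- vapply(c(0.2, 0.5, 0.8, 0.99),
                   function(th) nrow(net_from_matrix(big, kg, threshold = th)$edges),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_lte(counts[4], 2)
})

test_that("network traits: hand-computed modularity and betweenness", {
  ## two disjoint positive triangles: components 2, modularity 1/2
  taxa <- paste0("t", 1:6)
  rho <- diag(6); dimnames(rho) <- list(taxa, taxa)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    rho[e[1], e[2]] <- rho[e[2], e[1]] <- 0.9
  }
  kg <- setNames(rep(c("fungi", "bacteria"), 3), taxa)
  tr <- network_traits(net_from_matrix(rho, kg))
  expect_equal(tr$n_components, 2)
  expect_equal(tr$n_communities, 2)
  expect_equal(tr$modularity, 0.5, tolerance = 1e-12)
  expect_equal(tr$proportion_positive_edges, 1)

  ## all-positive 4-clique: betweenness 0 everywhere
  rho4 <- matrix(0.9, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  diag(rho4) <- 1
  tr4 <- network_traits(net_from_matrix(rho4, setNames(rep(c("fungi", "bacteria"), 2),
                                                       paste0("t", 1:4))))
  expect_equal(tr4$proportion_positive_edges, 1)
  expect_equal(tr4$mean_betweenness_fungi, 0)
  expect_equal(tr4$mean_betweenness_bacteria, 0)

  ## star S4 (centre + 3 leaves): centre betweenness C(3,2) = 3, leaves 0
  rho5 <- diag(4); dimnames(rho5) <- list(paste0("t", 1:4), paste0("t", 1:4))
  rho5[1, 2:4] <- rho5[2:4, 1] <- 0.8
  net5 <- net_from_matrix(rho5, setNames(c("fungi", rep("bacteria", 3)),
                                         paste0("t", 1:4)))
  btw <- igraph::betweenness(net5$graph, weights = NA)
  expect_equal(unname(btw[1]), 3)
  expect_equal(unname(btw[2:4]), rep(0, 3))
  tr5 <- network_traits(net5)
  expect_equal(tr5$mean_betweenness_fungi, 3)

  ## empty graph: sentinel traits and a warning
  rho0 <- diag(3); dimnames(rho0) <- list(letters[1:3], letters[1:3])
  expect_warning(tr0 <- network_traits(net_from_matrix(rho0,
    setNames(c("fungi", "bacteria", "bacteria"), letters[1:3]))),
    "sentinel")
  expect_true(is.na(tr0$modularity))
})

test_that("greedy communities match exhaustive search on small graphs", {
  graphs <- list(
    two_triangles = igraph::graph_from_edgelist(
      rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)), FALSE),
    barbell = igraph::graph_from_edgelist(
      rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6), c(4, 6)), FALSE),
    two_squares = igraph::graph_from_edgelist(
      rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(5, 6), c(6, 7), c(7, 8), c(5, 8)), FALSE),
    star_plus_clique = igraph::graph_from_edgelist(
      rbind(c(1, 2), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(1, 4)), FALSE)
  )
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    greedy <- igraph::cluster_fast_greedy(g, weights = NULL)
    brute <- best_partition_bruteforce(g)
    expect_equal(igraph::modularity(g, igraph::membership(greedy)),
                 brute$modularity, tolerance = 1e-12,
                 label = paste("modularity of", nm))
    expect_equal(length(unique(igraph::membership(greedy))),
                 brute$n_communities, label = paste("communities of", nm))
  }
})

test_that("betweenness null test: constructed extreme and determinism", {
  ## two stars joined at centres: fungi at leaves, bacteria at centres
  taxa <- c(paste0("f", 1:6), "b1", "b2")
  rho <- diag(8); dimnames(rho) <- list(taxa, taxa)
  for (i in 1:3) { rho[paste0("f", i), "b1"] <- rho["b1", paste0("f", i)] <- 0.9 }
  for (i in 4:6) { rho[paste0("f", i), "b2"] <- rho["b2", paste0("f", i)] <- 0.9 }
  rho["b1", "b2"] <- rho["b2", "b1"] <- 0.9
  kg <- setNames(c(rep("fungi", 6), rep("bacteria", 2)), taxa)
  net <- net_from_matrix(rho, kg)
  bt <- betweenness_null_test(net, n_perm = 499, seed = 1)
  expect_lt(bt$p, 0.05)
  expect_equal(bt$observed, 0)
  expect_identical(betweenness_null_test(net, n_perm = 499, seed = 1)$null,
                   bt$null)

  solo <- net_from_matrix(rho[1:6, 1:6], kg[1:6])
  expect_error(betweenness_null_test(solo, n_perm = 9, seed = 1),
               class = "phylosym_argument_error")
})

test_that("phylum-pair frequencies normalize and the null test flags extremes", {
  taxa <- c(paste0("f", 1:4), paste0("b", 1:4))
  kg <- setNames(rep(c("fungi", "bacteria"), each = 4), taxa)
  ph <- setNames(c("Asco", "Asco", "Basidio", "Basidio",
                   "Actino", "Actino", "Proteo", "Proteo"), taxa)
  rho <- diag(8); dimnames(rho) <- list(taxa, taxa)
  link <- function(a, b, v) rho[a, b] <<- rho[b, a] <<- v
  ## all positive cross-kingdom edges on the focal Asco-Actino pair
  link("f1", "b1", 0.9); link("f2", "b2", 0.9); link("f1", "b2", 0.9)
  net <- net_from_matrix(rho, kg, phylum = ph)
  freq <- phylum_pair_frequency(net)
  expect_equal(sum(freq), 1)
  expect_equal(freq["Asco", "Actino"], 1)
  pp <- phylum_pair_null_test(net, c("Asco", "Actino"), n_perm = 499, seed = 1)
  expect_lt(pp$p, 0.2)      # labels 2+2 per kingdom: minimum attainable p
  expect_equal(pp$observed, 1)
  expect_identical(phylum_pair_null_test(net, c("Asco", "Actino"),
                                         n_perm = 499, seed = 1)$null, pp$null)

  ## single cross-kingdom edge: that cell gets everything
  rho2 <- diag(8); dimnames(rho2) <- list(taxa, taxa)
  rho2["f3", "b3"] <- rho2["b3", "f3"] <- 0.9
  net2 <- net_from_matrix(rho2, kg, phylum = ph)
  freq2 <- phylum_pair_frequency(net2)
  expect_equal(unname(freq2["Basidio", "Proteo"]), 1)

  no_cross <- net_from_matrix(diag(8) |> `dimnames<-`(list(taxa, taxa)), kg,
                              phylum = ph)
  expect_error(phylum_pair_frequency(no_cross),
               class = "phylosym_validation_error")
})

test_that("species and class networks assemble with group filtering", {
  ds <- sim_dataset(seed = 31, n_species = 8, samples_per_species = 6,
                    coupling = 0.9, phylo_strength = 1.5, depth = 1200)
  nets <- species_and_class_networks(ds$fungi, ds$bacteria, ds$taxonomy_fungi,
                                     ds$taxonomy_bacteria, ds$metadata,
                                     depth = 500, threshold = 0.5,
                                     min_samples = 5, seed = 1)
  expect_true(length(nets$species$networks) >= 1)
  expect_true(all(c("n_components", "modularity", "proportion_positive_edges")
                  %in% names(nets$class$traits)))
  ## deterministic given seed
  nets2 <- species_and_class_networks(ds$fungi, ds$bacteria, ds$taxonomy_fungi,
                                      ds$taxonomy_bacteria, ds$metadata,
                                      depth = 500, threshold = 0.5,
                                      min_samples = 5, seed = 1)
  expect_identical(nets$class$traits, nets2$class$traits)

  ## min_samples filter reports skipped groups
  nets3 <- species_and_class_networks(ds$fungi, ds$bacteria, ds$taxonomy_fungi,
                                      ds$taxonomy_bacteria, ds$metadata,
                                      depth = 500, threshold = 0.5,
                                      min_samples = 7, seed = 1)
  expect_true(length(nets3$species$skipped) == 8)
})
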