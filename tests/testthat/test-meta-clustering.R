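# helper: symmetric signed matrix from an undirected edge list
sym_matrix <- function(n, edges, labels = sprintf("v%02d", seq_len(n))) {
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_len(nrow(edges))) {
    W[edges$u[k], edges$v[k]] <- W[edges$u[k], edges$v[k]] + edges$w[k]
    W[edges$v[k], edges$u[k]] <- W[edges$v[k], edges$u[k]] + edges$w[k]
  }
  W
}

clique_edges <- function(members, w = 1) {
  pairs <- t(utils::combn(members, 2))
  tibble::tibble(u = pairs[, 1], v = pairs[, 2], w = w)
}

test_that("signed modularity agrees with igraph on positive graphs", {
  skip_if_not_installed("igraph")
  set.seed(81)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (sum(keep) < 3) next
    e <- tibble::tibble(u = pairs[keep, 1], v = pairs[keep, 2],
                        w = sample(1:5, sum(keep), replace = TRUE))
    W <- sym_matrix(n, e)
    m <- sample(1:3, n, replace = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(signed_modularity(W, m),
                 igraph::modularity(ig, m, weights = igraph::E(ig)$weight))
  }
})

test_that("Louvain recovers components and matches exhaustive search on small graphs", {
  # two disconnected positive 4-cliques
  W <- sym_matrix(8, dplyr::bind_rows(clique_edges(1:4), clique_edges(5:8)))
  p <- louvain_signed(W, seed = 3)
  expect_equal(max(p$membership), 2)
  expect_equal(length(unique(p$membership[1:4])), 1)
  expect_equal(length(unique(p$membership[5:8])), 1)
  expect_equal(p$modularity, max_modularity_exhaustive(W), tolerance = 1e-12)

  # a single positive clique stays one cluster at gamma = 1
  W1 <- sym_matrix(5, clique_edges(1:5))
  p1 <- louvain_signed(W1, seed = 4)
  expect_equal(max(p1$membership), 1)

  # random small signed graphs: Q within 2% of the exhaustive maximum
  set.seed(82)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (sum(keep) < 3) next
    e <- tibble::tibble(u = pairs[keep, 1], v = pairs[keep, 2],
                        w = sample(c(-2, -1, 1, 2, 3), sum(keep), TRUE))
    W <- sym_matrix(n, e)
    if (sum(pmax(W, 0)) == 0) next
    best <- max_modularity_exhaustive(W)
    got <- louvain_signed(W, seed = rep, restarts = 20)$modularity
    expect_gte(got, best - 0.02 * abs(best) - 1e-12)
  }

  # Q of the returned partition is at least the all-singletons Q (positive graphs)
  set.seed(83)
  pairs <- t(utils::combn(10, 2))
  keep <- runif(nrow(pairs)) < 0.3
  e <- tibble::tibble(u = pairs[keep, 1], v = pairs[keep, 2], w = 1)
  W <- sym_matrix(10, e)
  p <- louvain_signed(W, seed = 5)
  expect_gte(p$modularity, signed_modularity(W, 1:10))
})

test_that("partitions are deterministic given a seed and tidy correctly", {
  W <- sym_matrix(8, dplyr::bind_rows(clique_edges(1:4), clique_edges(5:8)))
  p1 <- louvain_signed(W, seed = 11)
  p2 <- louvain_signed(W, seed = 11)
  expect_identical(p1$membership, p2$membership)
  td <- tidy(p1)
  expect_named(td, c("root_id", "cluster"))
  expect_equal(nrow(td), 8)
  expect_equal(glance(p1)$n_clusters, 2)
})

test_that("consensus co-clustering has valid entries and finds planted blocks", {
  W <- sym_matrix(8, dplyr::bind_rows(clique_edges(1:4), clique_edges(5:8)))
  cc <- consensus_coclustering(W, n_runs = 10, seed = 2)
  C <- cc$cocluster
  expect_true(isSymmetric(C))
  expect_true(all(diag(C) == 1))
  expect_true(all(C %in% c(0, 1)))  # all runs identical on this graph
  expect_equal(nrow(cc$run_stats), 10)

  sim <- generate_connectome(connectome_sim_spec(n_dns = 60, n_clusters = 3,
                                                 n_nondn = 0, seed = 14))
  g <- toy_graph_from_sim(sim)
  su <- quietly(symmetrize_signed(g))
  cc <- consensus_coclustering(su, n_runs = 20, seed = 7)
  truth <- sim$truth$membership[rownames(cc$cocluster)]
  same <- outer(truth, truth, "==")
  diag(same) <- NA
  expect_gt(mean(cc$cocluster[same & !is.na(same)]), 0.9)
  expect_lt(mean(cc$cocluster[!same & !is.na(same)]), 0.1)
})

test_that("Ward ordering makes co-clustered blocks contiguous", {
  ids <- sprintf("d%02d", 1:9)
  blocks <- rep(1:3, each = 3)
  C <- outer(blocks, blocks, "==") * 1
  dimnames(C) <- list(ids, ids)
  ord <- order_by_hierarchy(C)
  expect_setequal(ord, ids)
  expect_equal(length(rle(blocks[match(ord, ids)])$values), 3)

  # permuting the input rows recovers the same contiguous blocks
  perm <- sample(9)
  Cp <- C[perm, perm]
  ordp <- order_by_hierarchy(Cp)
  expect_equal(length(rle(blocks[match(ordp, ids)])$values), 3)

  single <- matrix(1, 1, 1, dimnames = list("only", "only"))
  expect_equal(order_by_hierarchy(single), "only")
})

test_that("cluster extraction joins at the threshold and drops small clusters", {
  sizes <- c(12, 11, 9)
  blocks <- rep(seq_along(sizes), times = sizes)
  ids <- sprintf("d%02d", seq_along(blocks))
  C <- outer(blocks, blocks, "==") * 1
  dimnames(C) <- list(ids, ids)
  cs <- extract_clusters(C, leaf_order = ids)
  expect_equal(length(cs$clusters), 2)   # the 9-block is dropped
  expect_equal(cs$n_unclustered, 9)
  expect_equal(lengths(cs$clusters), c("1" = 12L, "2" = 11L))

  # boundary co-membership exactly at the threshold joins
  C2 <- matrix(0.25, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  diag(C2) <- 1
  cs2 <- extract_clusters(C2, leaf_order = c("a", "b"), min_size = 1)
  expect_equal(length(cs2$clusters), 1)
  C3 <- C2
  C3["a", "b"] <- C3["b", "a"] <- 0.249
  cs3 <- extract_clusters(C3, leaf_order = c("a", "b"), min_size = 1)
  expect_equal(length(cs3$clusters), 2)
})

test_that("inter-cluster synapse matrix equals the dense block-sum oracle", {
  # 30 excitatory synapses c1 -> c2 over 10 receivers: entry +3
  e <- tibble::tibble(
    pre = rep(c("a1", "a2", "a3"), each = 2),
    post = rep(c("b1", "b2"), 3),
    syn_count = 5L, nt = "ACH"
  )
  g <- toy_graph(e, nodes = c(paste0("a", 1:3), paste0("b", 1:10)))
  members <- list(paste0("a", 1:3), paste0("b", 1:10))
  M <- intercluster_synapse_matrix(g, members)
  expect_equal(M[1, 2], 3)
  expect_equal(M[2, 1], 0)

  # equal excitation and inhibition cancel
  e2 <- tibble::tibble(pre = c("a1", "a2"), post = c("b1", "b1"),
                       syn_count = 5L, nt = c("ACH", "GABA"))
  g2 <- toy_graph(e2, nodes = c("a1", "a2", "b1"))
  M2 <- intercluster_synapse_matrix(g2, list(c("a1", "a2"), "b1"))
  expect_equal(M2[1, 2], 0)

  # random signed graph vs brute-force oracle
  set.seed(91)
  er <- random_digraph_edges(12, 0.35)
  er$nt <- sample(c("ACH", "GABA"), nrow(er), replace = TRUE)
  gr <- toy_graph(er)
  members <- split(gr$nodes$root_id, rep(1:3, length.out = 12))
  expect_equal(unname(intercluster_synapse_matrix(gr, members)),
               intercluster_oracle(gr, members))

  expect_error(intercluster_synapse_matrix(gr, list(character(), "n001")),
               "empty cluster")
})

test_that("Welch comparison of per-run statistics matches the closed form", {
  x <- c(10, 12, 14, 13)
  y <- c(9, 8, 11, 7)
  got <- compare_cluster_sizes(x, y)
  oracle <- welch_oracle(x, y)
  expect_equal(got$statistic, oracle$statistic)
  expect_equal(got$p_value, oracle$p)

  same <- c(1, 2, 3, 4)
  res <- compare_cluster_sizes(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.5)

  expect_error(compare_cluster_sizes(c(1, 1), c(1, 1)), "zero variance")
})

test_that("cluster annotation fractions follow the 5% projection rule", {
  e <- tibble::tibble(pre = paste0("x", 1:4), post = "y1",
                      syn_count = 6L, nt = "ACH",
                      neuropil = c("GNG_L", "GNG_L", "T1_L", "GNG_R"))
  g <- toy_graph(e, nodes = c(paste0("x", 1:4), "y1"))
  C <- matrix(1, 5, 5, dimnames = list(g$nodes$root_id, g$nodes$root_id))
  cs <- extract_clusters(C, leaf_order = g$nodes$root_id, min_size = 1)
  nm <- setNames(g$nodes$name, g$nodes$root_id)
  vnc <- tibble::tibble(
    name = nm[paste0("x", 1:4)],
    neuropil = "T1",
    presyn_fraction = c(0.5, 0.2, 0.04, 0.06)  # 0.04 is below the 5% rule
  )
  beh <- tibble::tibble(name = nm[paste0("x", 1:4)],
                        behaviour = c("walking", "walking", "walking",
                                      "grooming"))
  ann <- annotate_clusters(cs, g, vnc_projections = vnc, behaviours = beh)
  expect_equal(ann$vnc$n_projecting, 3L)          # the 4% DN does not project
  expect_equal(ann$vnc$fraction, 0.75)
  walking <- ann$behaviour[ann$behaviour$behaviour == "walking", ]
  expect_equal(walking$fraction, 0.75)
  expect_true(all(ann$cluster_summary$low_evidence)) # < 5 known DNs
  expect_equal(sum(ann$brain_inputs$fraction), 1)

  bad <- tibble::tibble(name = "unknownDN", behaviour = "flight")
  expect_warning(annotate_clusters(cs, g, behaviours = bad), "skipped")
})
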