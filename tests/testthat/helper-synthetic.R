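`%||%` <- function(x, y) if (is.null(x)) y else x

# Fixture builders and independent oracles shared across the test files.
# All fixtures are generated in code; nothing is read from disk except the
# CSVs the tests themselves write to tempdir().

# Build a dn_graph directly from a toy edge description. `gng` lists the
# node ids whose consensus type should mark them as GNG DNs.
toy_graph <- function(edges, nodes = NULL, gng = character(),
                      min_synapses = 5, policy = sign_policy()) {
  nodes <- nodes %||% sort(unique(c(edges$pre, edges$post, gng)))
  neurons <- tibble::tibble(
    root_id = nodes,
    super_class = "descending",
    cell_type = ifelse(nodes %in% gng,
                       sprintf("DNge%03d", seq_along(nodes)),
                       sprintf("DNpe%03d", seq_along(nodes))),
    hemibrain_type = NA_character_,
    community_labels = NA_character_,
    side = "left"
  )
  col_or <- function(col, default) {
    if (col %in% names(edges)) edges[[col]] else default
  }
  connections <- tibble::tibble(
    pre_root_id = edges$pre,
    post_root_id = edges$post,
    neuropil = col_or("neuropil", "GNG_L"),
    syn_count = as.integer(edges$syn_count),
    nt_type = col_or("nt", "ACH")
  )
  quietly(build_dn_graph(neurons, connections, min_synapses = min_synapses,
                         policy = policy))
}

quietly <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}

# dn_graph straight from generate_connectome() output (no CSV round trip)
toy_graph_from_sim <- function(sim, ...) {
  quietly(build_dn_graph(sim$neurons, sim$connections, ...))
}

# Random directed graph as an edge tibble (no self loops), used for
# BFS-oracle and conservation tests.
random_digraph_edges <- function(n, p, nt = "ACH", syn = 6L) {
  pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
  pairs <- pairs[pairs$pre != pairs$post, ]
  keep <- runif(nrow(pairs)) < p
  tibble::tibble(
    pre = sprintf("n%03d", pairs$pre[keep]),
    post = sprintf("n%03d", pairs$post[keep]),
    syn_count = syn, nt = nt
  )
}

# All set partitions of n elements as restricted-growth strings (Bell(n)
# rows); the exhaustive-search oracle for modularity maximisation.
set_partitions <- function(n) {
  out <- list(1L)
  for (i in seq_len(n - 1L)) {
    out <- unlist(lapply(out, function(code) {
      lapply(seq_len(max(code) + 1L), function(b) c(code, b))
    }), recursive = FALSE)
  }
  out
}

max_modularity_exhaustive <- function(W, gamma = 1) {
  parts <- set_partitions(nrow(W))
  max(vapply(parts, function(m) signed_modularity(W, m, gamma), numeric(1)))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (distinct values assumed).
mwu_exact_enumeration <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(length(pooled), na)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Welch's t closed form (one-sided, alternative: mean(x) > mean(y)).
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, p = pt(t, df, lower.tail = FALSE))
}

# Dense block-sum oracle for the inter-cluster synapse matrix.
intercluster_oracle <- function(graph, members) {
  k <- length(members)
  M <- matrix(0, k, k)
  e <- graph$edges
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      sel <- e$pre %in% members[[i]] & e$post %in% members[[j]] &
        !is.na(e$sign) & e$sign != 0
      M[i, j] <- sum(e$sign[sel] * e$syn_count[sel]) / length(members[[j]])
    }
  }
  M
}

# BFS-reachability oracle via igraph shortest-path distances.
reachable_oracle <- function(graph, source_ids, max_hops) {
  A <- dn_adjacency(graph, "binary")
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  d <- igraph::distances(ig, mode = "out")
  dmin <- apply(d[source_ids, , drop = FALSE], 2, min)
  dmin <- dmin[!names(dmin) %in% source_ids]
  vapply(seq_len(max_hops), function(k) sum(dmin <= k), numeric(1))
}
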