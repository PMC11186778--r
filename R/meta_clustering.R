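# Signed Louvain consensus clustering of the undirected DN graph:
# signed modularity, greedy Louvain with reseeded retries, co-clustering
# across runs, Ward ordering, sequential cluster extraction, inter-cluster
# synapse matrices and cluster annotation.

as_signed_matrix <- function(x) {
  if (inherits(x, "signed_undirected")) return(x$matrix)
  if (is.matrix(x)) {
    if (!isTRUE(all.equal(x, t(x)))) abort("signed adjacency must be symmetric")
    if (is.null(rownames(x))) dimnames(x) <- list(seq_len(nrow(x)), seq_len(nrow(x)))
    return(x)
  }
  abort("expected a signed_undirected graph or a symmetric matrix")
}

# Modularity of one (non-negative) layer. Convention: W symmetric, each
# undirected edge stored in both triangles; a diagonal entry holds twice the
# self-loop weight, so strengths are plain row sums and 2m = sum(W).
layer_modularity <- function(W, membership, gamma) {
  m2 <- sum(W)
  if (m2 <= 0) return(0)
  k <- rowSums(W)
  K_c <- rowsum(k, membership)
  S <- rowsum(t(rowsum(W, membership)), membership)
  sum(diag(S)) / m2 - gamma * sum((K_c / m2)^2)
}

#' Signed modularity of a partition
#'
#' The signed generalisation scores the positive and negative subgraphs
#' separately and combines them weighted by their total weights:
#' `Q = (w+ Q+ - w- Q-) / (w+ + w-)`. Dense within-cluster excitation raises
#' `Q`; within-cluster inhibition lowers it. `method = "naive"` instead
#' plugs the signed weights directly into the standard formula.
#'
#' @param x a [symmetrize_signed()] result or symmetric signed matrix.
#' @param membership integer cluster labels, one per node.
#' @param gamma resolution parameter (default 1).
#' @param method `"signed"` (default) or `"naive"`.
#' @return numeric modularity.
#' @export
signed_modularity <- function(x, membership, gamma = 1,
                              method = c("signed", "naive")) {
  method <- match.arg(method)
  W <- as_signed_matrix(x)
  stopifnot(length(membership) == nrow(W), gamma > 0)
  if (method == "naive") {
    return(layer_modularity(W, membership, gamma))
  }
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  m2p <- sum(Wp)
  m2n <- sum(Wn)
  if (m2p + m2n <= 0) abort("graph has no edges")
  (m2p * layer_modularity(Wp, membership, gamma) -
      m2n * layer_modularity(Wn, membership, gamma)) / (m2p + m2n)
}

# One Louvain level: greedy local moving on the two layers until no single
# node move improves signed modularity. Gains are compared through the
# common positive denominator (w+ + w-), which never changes, so only the
# numerator terms are scored. Candidate communities are the node's
# neighbouring communities, plus the community with the best degree-penalty
# "field" (on signed graphs the optimal move can be to a community the node
# has no edges to), plus an empty community (singleton escape).
louvain_one_level <- function(Wp, Wn, gamma, max_sweeps) {
  n <- nrow(Wp)
  m2p <- sum(Wp)
  m2n <- sum(Wn)
  kp <- rowSums(Wp)
  kn <- rowSums(Wn)
  comm <- seq_len(n)
  Kp <- kp
  Kn <- kn
  csize <- rep(1L, n)
  link_sums <- function(wrow, i, comm, cand) {
    wrow[i] <- 0
    nz <- which(wrow != 0)
    if (!length(nz)) return(setNames(numeric(length(cand)), cand))
    l <- rowsum(wrow[nz], comm[nz])
    out <- setNames(numeric(length(cand)), cand)
    hit <- intersect(rownames(l), as.character(cand))
    out[hit] <- l[hit, 1]
    out
  }
  sweeps <- 0L
  repeat {
    moved <- 0L
    for (i in sample.int(n)) {
      a <- comm[i]
      Kp[a] <- Kp[a] - kp[i]
      Kn[a] <- Kn[a] - kn[i]
      csize[a] <- csize[a] - 1L
      # degree-penalty field over all communities: the score any community
      # gets from the null terms alone (exact for communities without links
      # to i, a lower bound for the rest)
      field <- 0
      if (m2n > 0) field <- field + gamma * 2 * kn[i] * Kn / m2n
      if (m2p > 0) field <- field - gamma * 2 * kp[i] * Kp / m2p
      if (n <= 64) {
        # small level: score every community (plus one empty) exactly
        cand <- c(which(csize > 0L), a, which(csize == 0L)[1])
      } else {
        neigh <- which(Wp[i, ] != 0 | Wn[i, ] != 0)
        cand <- c(a, comm[neigh[neigh != i]], which.max(field),
                  which(csize == 0L)[1])
      }
      cand <- sort(unique(cand[!is.na(cand)]))
      lp <- link_sums(Wp[i, ], i, comm, cand)
      ln <- link_sums(Wn[i, ], i, comm, cand)
      sp <- if (m2p > 0) 2 * lp - gamma * 2 * kp[i] * Kp[cand] / m2p else 0
      sn <- if (m2n > 0) 2 * ln - gamma * 2 * kn[i] * Kn[cand] / m2n else 0
      score <- sp - sn
      s_stay <- score[match(a, cand)]
      best <- cand[which.max(score)]
      if (max(score) <= s_stay + 1e-12) best <- a
      comm[i] <- best
      Kp[best] <- Kp[best] + kp[i]
      Kn[best] <- Kn[best] + kn[i]
      csize[best] <- csize[best] + 1L
      if (best != a) moved <- moved + 1L
    }
    sweeps <- sweeps + 1L
    if (moved == 0L) break
    if (sweeps >= max_sweeps) return(NULL) # signal non-convergence
  }
  match(comm, unique(comm))
}

aggregate_layer <- function(W, comm) {
  rowsum(t(rowsum(W, comm)), comm)
}

#' Signed Louvain community detection
#'
#' Greedy modularity maximisation on the undirected signed DN graph
#' (positive and negative layers combined as in [signed_modularity()]),
#' with the usual Louvain aggregation phases. The node sweep order is
#' randomised, so results are deterministic given `seed`. If the local
#' moving phase fails to converge within `max_sweeps` sweeps the run is
#' restarted with a derived seed, up to `max_retries` times. Being greedy,
#' a single run can land in a local optimum; `restarts > 1` runs best-of-k
#' with derived seeds and keeps the highest-Q partition (the consensus
#' machinery in [consensus_coclustering()] instead keeps every run).
#'
#' @param x a [symmetrize_signed()] result or symmetric signed matrix.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed.
#' @param restarts independent runs, best Q kept (default 1).
#' @param max_sweeps local-moving sweep cap per level (default 100).
#' @param max_retries reseeded restarts before giving up (default 5).
#' @return object of class `dn_partition`: `membership` (named integer
#'   vector, labels contiguous from 1), `modularity` (signed Q), `gamma`,
#'   `seed`. Has [tidy()] and [glance()] methods.
#' @export
louvain_signed <- function(x, gamma = 1, seed = 1, restarts = 1,
                           max_sweeps = 100, max_retries = 5) {
  W0 <- as_signed_matrix(x)
  ids <- rownames(W0)
  stopifnot(gamma > 0, restarts >= 1)
  run_once <- function(run_seed) {
    set.seed(as.integer(run_seed))
    Wp <- pmax(W0, 0)
    Wn <- pmax(-W0, 0)
    membership <- seq_len(nrow(W0))
    repeat {
      comm <- louvain_one_level(Wp, Wn, gamma, max_sweeps)
      if (is.null(comm)) return(NULL)
      k <- max(comm)
      membership <- comm[membership]
      if (k == nrow(Wp) || k == 1L) break
      Wp <- aggregate_layer(Wp, comm)
      Wn <- aggregate_layer(Wn, comm)
    }
    membership
  }
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    membership <- NULL
    for (attempt in 0:max_retries) {
      membership <- run_once(as.integer(seed) + (r - 1L) * 7919L +
                               attempt * 10007L)
      if (!is.null(membership)) break
    }
    if (is.null(membership)) {
      abort(sprintf("Louvain did not converge within %d sweeps after %d retries",
                    max_sweeps, max_retries))
    }
    q <- signed_modularity(W0, membership, gamma)
    if (q > best_q) {
      best <- membership
      best_q <- q
    }
  }
  membership <- match(best, unique(best))
  names(membership) <- ids
  structure(
    list(membership = membership, modularity = best_q,
         gamma = gamma, seed = seed),
    class = "dn_partition"
  )
}

#' @export
print.dn_partition <- function(x, ...) {
  cat(sprintf("<dn_partition> %d nodes, %d clusters, Q = %.4f\n",
              length(x$membership), max(x$membership), x$modularity))
  invisible(x)
}

#' @export
tidy.dn_partition <- function(x, ...) {
  tibble(root_id = names(x$membership), cluster = unname(x$membership))
}

#' @export
glance.dn_partition <- function(x, ...) {
  tibble(n_clusters = max(x$membership), modularity = x$modularity,
         gamma = x$gamma, n_nodes = length(x$membership))
}

five_largest_total <- function(membership) {
  sizes <- sort(tabulate(membership), decreasing = TRUE)
  sum(head(sizes, 5))
}

#' Consensus co-clustering over repeated Louvain runs
#'
#' Runs [louvain_signed()] `n_runs` times with derived seeds and records,
#' for every DN pair, the fraction of runs in which the two ended up in the
#' same cluster (the co-clustering matrix), together with per-run summary
#' statistics (cluster count, total size of the five largest clusters,
#' modularity) used for the real-versus-shuffled comparison.
#'
#' @param x a [symmetrize_signed()] result or symmetric signed matrix.
#' @param n_runs number of Louvain runs (default 100).
#' @param gamma resolution parameter (default 1).
#' @param seed master seed; per-run seeds are derived from it.
#' @return object of class `dn_cocluster`: `cocluster` (symmetric matrix of
#'   co-membership frequencies, unit diagonal), `run_stats` (tibble `run`,
#'   `n_clusters`, `five_largest_total`, `modularity`), `gamma`, `n_runs`.
#' @export
consensus_coclustering <- function(x, n_runs = 100, gamma = 1, seed = 1) {
  stopifnot(n_runs >= 1)
  W <- as_signed_matrix(x)
  ids <- rownames(W)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  C <- matrix(0, nrow(W), nrow(W), dimnames = list(ids, ids))
  stats_list <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    part <- louvain_signed(W, gamma = gamma, seed = run_seeds[r])
    C <- C + outer(part$membership, part$membership, "==")
    stats_list[[r]] <- tibble(
      run = r,
      n_clusters = max(part$membership),
      five_largest_total = five_largest_total(part$membership),
      modularity = part$modularity
    )
  }
  structure(
    list(cocluster = C / n_runs, run_stats = list_rbind(stats_list),
         gamma = gamma, n_runs = n_runs),
    class = "dn_cocluster"
  )
}

#' @export
print.dn_cocluster <- function(x, ...) {
  cat(sprintf("<dn_cocluster> %d nodes, %d runs, mean Q = %.4f\n",
              nrow(x$cocluster), x$n_runs, mean(x$run_stats$modularity)))
  invisible(x)
}

#' @export
tidy.dn_cocluster <- function(x, ...) x$run_stats

#' @export
glance.dn_cocluster <- function(x, ...) {
  tibble(n_runs = x$n_runs,
         mean_modularity = mean(x$run_stats$modularity),
         mean_five_largest = mean(x$run_stats$five_largest_total),
         sd_five_largest = sd(x$run_stats$five_largest_total))
}

#' Hierarchical ordering of the co-clustering matrix
#'
#' Agglomerative Ward linkage on the distance `1 - co-membership`; the
#' dendrogram leaf order gives the final sorting of DNs.
#'
#' @param cocluster a [consensus_coclustering()] result (or its matrix).
#' @return character vector of root IDs in leaf order.
#' @export
order_by_hierarchy <- function(cocluster) {
  C <- if (inherits(cocluster, "dn_cocluster")) cocluster$cocluster else cocluster
  if (nrow(C) == 1) return(rownames(C))
  hc <- hclust(as.dist(1 - C), method = "ward.D2")
  rownames(C)[hc$order]
}

#' Extract clusters from the ordered co-clustering matrix
#'
#' A single left-to-right pass over the leaf order: a DN joins the current
#' cluster iff its co-membership frequency with the immediately preceding DN
#' is at least `join_threshold` (boundary value joins); otherwise it opens a
#' new cluster. Clusters smaller than `min_size` are dropped and their
#' members marked unclustered.
#'
#' @param cocluster a [consensus_coclustering()] result (or its matrix).
#' @param leaf_order character root-ID order; defaults to
#'   [order_by_hierarchy()].
#' @param join_threshold co-membership frequency needed to join (default
#'   0.25).
#' @param min_size minimum kept cluster size (default 10).
#' @return object of class `dn_clusterset`: `assignment` (tibble `root_id`,
#'   `cluster`, `NA` for unclustered), `leaf_order`, `clusters` (list of
#'   root-ID vectors), plus the parameters. Has a [tidy()] method.
#' @export
extract_clusters <- function(cocluster, leaf_order = NULL,
                             join_threshold = 0.25, min_size = 10) {
  C <- if (inherits(cocluster, "dn_cocluster")) cocluster$cocluster else cocluster
  leaf_order <- leaf_order %||% order_by_hierarchy(cocluster)
  stopifnot(setequal(leaf_order, rownames(C)))
  n <- length(leaf_order)
  raw <- integer(n)
  raw[1] <- 1L
  if (n > 1) {
    for (k in 2:n) {
      same <- C[leaf_order[k], leaf_order[k - 1]] >= join_threshold
      raw[k] <- if (same) raw[k - 1] else raw[k - 1] + 1L
    }
  }
  sizes <- tabulate(raw)
  kept <- which(sizes >= min_size)
  relabel <- setNames(rep(NA_integer_, length(sizes)), seq_along(sizes))
  relabel[as.character(kept)] <- seq_along(kept)
  cluster <- unname(relabel[as.character(raw)])
  assignment <- tibble(root_id = leaf_order, cluster = cluster)
  clusters <- split(assignment$root_id[!is.na(cluster)],
                    cluster[!is.na(cluster)])
  structure(
    list(assignment = assignment, leaf_order = leaf_order,
         clusters = clusters, join_threshold = join_threshold,
         min_size = min_size, n_unclustered = sum(is.na(cluster))),
    class = "dn_clusterset"
  )
}

#' @export
print.dn_clusterset <- function(x, ...) {
  cat(sprintf("<dn_clusterset> %d clusters (sizes %s), %d unclustered\n",
              length(x$clusters),
              toString(lengths(x$clusters)), x$n_unclustered))
  invisible(x)
}

#' @export
tidy.dn_clusterset <- function(x, ...) x$assignment

#' Signed synapse matrix between clusters
#'
#' Entry (i, j) is the signed synapse count (positive excitatory, negative
#' inhibitory) summed over all edges from cluster i members to cluster j
#' members, divided by the size of the receiving cluster j. The diagonal is
#' within-cluster connectivity. Unsigned edges (policy-excluded or
#' glutamatergic-distinct) are ignored.
#'
#' @param graph a `dn_graph`.
#' @param clusters a [extract_clusters()] result or a named list of root-ID
#'   vectors.
#' @return numeric cluster-by-cluster matrix.
#' @export
intercluster_synapse_matrix <- function(graph, clusters) {
  members <- if (inherits(clusters, "dn_clusterset")) clusters$clusters else clusters
  if (any(lengths(members) == 0)) abort("empty cluster")
  k <- length(members)
  labels <- names(members) %||% as.character(seq_len(k))
  lookup <- setNames(rep(seq_len(k), lengths(members)), unlist(members))
  e <- filter(graph$edges, !is.na(.data$sign), .data$sign != 0)
  M <- matrix(0, k, k, dimnames = list(labels, labels))
  ci <- lookup[e$pre]
  cj <- lookup[e$post]
  ok <- !is.na(ci) & !is.na(cj)
  if (any(ok)) {
    sums <- rowsum((e$sign * e$syn_count)[ok],
                   group = paste(ci[ok], cj[ok]))
    idx <- do.call(rbind, strsplit(rownames(sums), " "))
    M[cbind(as.integer(idx[, 1]), as.integer(idx[, 2]))] <- sums[, 1]
  }
  sweep(M, 2, lengths(members), "/")
}

#' One-sided Welch test on per-run cluster statistics
#'
#' Compares the per-run consensus statistics of the real network against a
#' shuffled null (alternative: real larger), by default on the total size of
#' the five largest clusters.
#'
#' @param real,shuffled [consensus_coclustering()] results or numeric
#'   vectors of per-run values.
#' @param statistic run-stat column to compare when given `dn_cocluster`
#'   objects.
#' @return tibble with `statistic` (Welch t), `p_value` (one-sided),
#'   `df`, `mean_real`, `mean_shuffled`.
#' @export
compare_cluster_sizes <- function(real, shuffled,
                                  statistic = "five_largest_total") {
  pull_stat <- function(x) {
    if (inherits(x, "dn_cocluster")) x$run_stats[[statistic]] else as.numeric(x)
  }
  x <- pull_stat(real)
  y <- pull_stat(shuffled)
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 runs per arm")
  if (sd(x) == 0 && sd(y) == 0) abort("zero variance in both arms")
  tt <- t.test(x, y, alternative = "greater", var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), mean_real = mean(x),
         mean_shuffled = mean(y))
}

#' Annotate clusters with VNC projections, behaviours and brain inputs
#'
#' Produces up to three per-cluster fraction tables. A DN is considered to
#' project to a VNC neuropil if at least `min_presyn_fraction` of its
#' presynaptic sites are there; fractions are over the known DNs of the
#' cluster (a DN is "known" if it appears in the annotation table).
#' Behaviour fractions are likewise over known DNs. Brain input fractions
#' are the synapses received by cluster members per brain neuropil, out of
#' all synapses received by that cluster. Clusters with fewer than
#' `min_known` known DNs are flagged as low evidence.
#'
#' @param clusters a [extract_clusters()] result.
#' @param graph the `dn_graph` (provides DN names and the neuropil synapse
#'   breakdown).
#' @param vnc_projections optional tibble `name`, `neuropil`,
#'   `presyn_fraction`.
#' @param behaviours optional tibble `name`, `behaviour`.
#' @param min_presyn_fraction projection threshold (default 0.05).
#' @param min_known low-evidence flag threshold (default 5).
#' @return list with tibbles `vnc`, `behaviour`, `brain_inputs` (those whose
#'   inputs were supplied) and `cluster_summary`.
#' @export
annotate_clusters <- function(clusters, graph, vnc_projections = NULL,
                              behaviours = NULL, min_presyn_fraction = 0.05,
                              min_known = 5) {
  assign <- filter(clusters$assignment, !is.na(.data$cluster))
  assign$name <- graph$nodes$name[match(assign$root_id, graph$nodes$root_id)]
  known_names <- unique(c(vnc_projections$name, behaviours$name))
  check_unknown <- function(tab, what) {
    missing <- setdiff(unique(tab$name), assign$name)
    if (length(missing)) {
      warn(sprintf("%d %s annotation name(s) not among clustered DNs; skipped",
                   length(missing), what))
    }
    filter(tab, .data$name %in% assign$name)
  }
  summ <- assign |>
    group_by(.data$cluster) |>
    summarise(n_dns = n(),
              n_known = sum(unique(.data$name) %in% known_names),
              .groups = "drop") |>
    mutate(low_evidence = .data$n_known < min_known)
  out <- list(cluster_summary = summ)
  if (!is.null(vnc_projections)) {
    vnc <- check_unknown(vnc_projections, "VNC") |>
      filter(.data$presyn_fraction >= min_presyn_fraction) |>
      distinct(.data$name, .data$neuropil) |>
      inner_join(assign, by = "name")
    known_per_cluster <- assign |>
      filter(.data$name %in% vnc_projections$name) |>
      count(.data$cluster, name = "n_known_vnc")
    out$vnc <- vnc |>
      count(.data$cluster, .data$neuropil, name = "n_projecting") |>
      left_join(known_per_cluster, by = "cluster") |>
      mutate(fraction = .data$n_projecting / .data$n_known_vnc)
  }
  if (!is.null(behaviours)) {
    beh <- check_unknown(behaviours, "behaviour") |>
      distinct(.data$name, .data$behaviour) |>
      inner_join(assign, by = "name")
    known_per_cluster <- assign |>
      filter(.data$name %in% behaviours$name) |>
      count(.data$cluster, name = "n_known_beh")
    out$behaviour <- beh |>
      count(.data$cluster, .data$behaviour, name = "n_dns") |>
      left_join(known_per_cluster, by = "cluster") |>
      mutate(fraction = .data$n_dns / .data$n_known_beh)
  }
  np <- graph$neuropil
  if (!is.null(np) && nrow(np)) {
    incoming <- np |>
      mutate(cluster = assign$cluster[match(.data$post, assign$root_id)]) |>
      filter(!is.na(.data$cluster)) |>
      group_by(.data$cluster, .data$neuropil) |>
      summarise(synapses = sum(.data$syn_count), .groups = "drop_last") |>
      mutate(fraction = .data$synapses / sum(.data$synapses)) |>
      ungroup()
    out$brain_inputs <- incoming
  }
  out
}
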