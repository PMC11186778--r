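# The signed, directed DN-DN graph: edge aggregation at a synapse threshold,
# neurotransmitter-derived signs, degree/reachability statistics.

#' Neurotransmitter sign policy
#'
#' Acetylcholine is excitatory (+1) and GABA inhibitory (-1). Glutamate can
#' be either depending on the receptor, so its handling is a policy choice:
#' `"inhibitory"` treats it as -1 (the convention used for clustering),
#' `"distinct"` keeps glutamatergic edges as their own unsigned class (sign
#' 0, used for display), and `"excluded"` drops them. Neuromodulators
#' (dopamine, serotonin, octopamine) and unknown transmitters are always
#' excluded from signed analyses.
#'
#' @param glut one of `"inhibitory"`, `"distinct"`, `"excluded"`.
#' @return an object of class `sign_policy`.
#' @export
sign_policy <- function(glut = c("inhibitory", "distinct", "excluded")) {
  glut <- match.arg(glut)
  structure(list(ach = 1, gaba = -1, glut = glut), class = "sign_policy")
}

#' Map neurotransmitters to edge signs
#'
#' @param nt character vector of neurotransmitter labels.
#' @param policy a [sign_policy()].
#' @return numeric vector: +1 (excitatory), -1 (inhibitory), 0 (glutamatergic
#'   kept as a distinct class) or `NA` (excluded).
#' @export
edge_sign <- function(nt, policy = sign_policy()) {
  stopifnot(inherits(policy, "sign_policy"))
  nt <- first_upper(nt)
  glut_sign <- switch(policy$glut,
    inhibitory = -1,
    distinct = 0,
    excluded = NA_real_
  )
  out <- rep(NA_real_, length(nt))
  out[nt == "ACH"] <- 1
  out[nt == "GABA"] <- -1
  out[nt == "GLUT"] <- glut_sign
  out
}

sign_class_of <- function(sign) {
  case_when(
    is.na(sign) ~ "excluded",
    sign > 0 ~ "excitatory",
    sign < 0 ~ "inhibitory",
    TRUE ~ "glutamatergic"
  )
}

NT_PRIORITY <- c("ACH", "GABA", "GLUT", "DA", "SER", "OCT", "unknown")

#' Aggregate connection rows into DN-DN edges
#'
#' Connection rows between DN pairs are summed across neuropils; pairs whose
#' total synapse count falls below `min_synapses` are not considered
#' connected. The edge neurotransmitter is the synapse-count-weighted
#' majority across the pair's rows; ties are broken by the fixed priority
#' ACH > GABA > GLUT > DA > SER > OCT > unknown (logged when invoked).
#'
#' @param connections connection tibble (see [read_codex_tables()]).
#' @param dn_ids character vector of DN root IDs.
#' @param min_synapses minimum total synapses for a pair to count as
#'   connected (default 5, the Codex convention).
#' @return tibble with `pre`, `post`, `syn_count`, `nt`.
#' @export
aggregate_edges <- function(connections, dn_ids, min_synapses = 5) {
  stopifnot(min_synapses >= 1)
  conn <- connections |>
    filter(.data$pre_root_id %in% dn_ids,
           .data$post_root_id %in% dn_ids,
           .data$pre_root_id != .data$post_root_id)
  if (!nrow(conn)) {
    return(tibble(pre = character(), post = character(),
                  syn_count = integer(), nt = character()))
  }
  nt_votes <- conn |>
    group_by(.data$pre_root_id, .data$post_root_id, .data$nt_type) |>
    summarise(nt_syn = sum(.data$syn_count), .groups = "drop_last")
  ties <- nt_votes |>
    filter(.data$nt_syn == max(.data$nt_syn)) |>
    summarise(n_top = n(), .groups = "drop")
  n_ties <- sum(ties$n_top > 1)
  if (n_ties > 0) {
    inform(sprintf("neurotransmitter vote tie on %d pair(s); broken by fixed priority",
                   n_ties))
  }
  winners <- nt_votes |>
    mutate(prio = match(.data$nt_type, NT_PRIORITY)) |>
    arrange(desc(.data$nt_syn), .data$prio, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(pre = "pre_root_id", post = "post_root_id", nt = "nt_type")
  conn |>
    group_by(pre = .data$pre_root_id, post = .data$post_root_id) |>
    summarise(syn_count = as.integer(sum(.data$syn_count)), .groups = "drop") |>
    filter(.data$syn_count >= min_synapses) |>
    left_join(winners, by = c("pre", "post"))
}

#' Build the signed, directed DN-DN graph
#'
#' Nodes are DNs (with display names and GNG flags); edges are aggregated
#' DN-DN connections at the synapse threshold, each carrying its total
#' synapse count, majority neurotransmitter, sign under `policy`, and a
#' per-neuropil synapse breakdown. Edges whose transmitter is excluded by
#' the policy are retained in the graph (they still count as connections for
#' degree and reachability) but carry sign `NA` and are dropped by the
#' signed operations.
#'
#' @param neurons neuron tibble.
#' @param connections connection tibble.
#' @param dn_ids DN root IDs; defaults to [select_descending()] on `neurons`.
#' @param names optional tibble from [assign_dn_names()]; computed if absent.
#' @param min_synapses connection threshold (default 5).
#' @param policy a [sign_policy()].
#' @return an object of class `dn_graph`: list with `nodes`, `edges`,
#'   `neuropil` (per-edge, per-neuropil synapse counts), `min_synapses`,
#'   `policy`.
#' @export
build_dn_graph <- function(neurons, connections, dn_ids = NULL, names = NULL,
                           min_synapses = 5, policy = sign_policy()) {
  dn_ids <- dn_ids %||% select_descending(neurons)
  names <- names %||% assign_dn_names(neurons, dn_ids)
  edges <- aggregate_edges(connections, dn_ids, min_synapses)
  edges$sign <- edge_sign(edges$nt, policy)
  edges$sign_class <- sign_class_of(edges$sign)
  retained <- paste(edges$pre, edges$post)
  neuropil <- connections |>
    filter(paste(.data$pre_root_id, .data$post_root_id) %in% retained) |>
    group_by(pre = .data$pre_root_id, post = .data$post_root_id,
             neuropil = .data$neuropil) |>
    summarise(syn_count = as.integer(sum(.data$syn_count)), .groups = "drop")
  nodes <- tibble(
    root_id = dn_ids,
    name = names$display_name[match(dn_ids, names$root_id)],
    is_gng = names$is_gng[match(dn_ids, names$root_id)]
  )
  g <- structure(
    list(nodes = nodes, edges = edges, neuropil = neuropil,
         min_synapses = min_synapses, policy = policy),
    class = "dn_graph"
  )
  if (!nrow(edges)) warn("DN graph has no edges at this synapse threshold")
  inform(sprintf(
    "DN graph: %d nodes, %d edges (%d excitatory, %d inhibitory, %d glutamatergic, %d excluded)",
    nrow(nodes), nrow(edges),
    sum(edges$sign_class == "excitatory"), sum(edges$sign_class == "inhibitory"),
    sum(edges$sign_class == "glutamatergic"), sum(edges$sign_class == "excluded")
  ))
  g
}

#' @export
print.dn_graph <- function(x, ...) {
  cat(sprintf("<dn_graph> %d DNs, %d edges (min %d synapses, glutamate: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$min_synapses, x$policy$glut))
  invisible(x)
}

#' Adjacency matrix of a DN graph
#'
#' @param graph a `dn_graph`.
#' @param what `"binary"` (connected or not), `"synapses"` (total synapse
#'   counts) or `"signed"` (sign x synapses; policy-excluded and unsigned
#'   glutamatergic edges contribute 0).
#' @return square numeric matrix with root IDs as dimnames.
#' @export
dn_adjacency <- function(graph, what = c("binary", "synapses", "signed")) {
  what <- match.arg(what)
  ids <- graph$nodes$root_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- graph$edges
  if (nrow(e)) {
    w <- switch(what,
      binary = rep(1, nrow(e)),
      synapses = e$syn_count,
      signed = ifelse(is.na(e$sign), 0, e$sign) * e$syn_count
    )
    A[cbind(match(e$pre, ids), match(e$post, ids))] <- w
  }
  A
}

#' Per-DN in/out degree table
#'
#' Binary-connection degrees (a pair counts once if retained at the synapse
#' threshold), plus the GNG-restricted out-degree (number of downstream GNG
#' DNs).
#'
#' @param graph a `dn_graph`.
#' @return tibble with `root_id`, `name`, `out_degree`, `in_degree`,
#'   `total_degree`, `out_degree_gng`.
#' @export
dn_degree <- function(graph) {
  ids <- graph$nodes$root_id
  e <- graph$edges
  gng_ids <- graph$nodes$root_id[graph$nodes$is_gng %in% TRUE]
  out_deg <- table(factor(e$pre, levels = ids))
  in_deg <- table(factor(e$post, levels = ids))
  out_gng <- table(factor(e$pre[e$post %in% gng_ids], levels = ids))
  tibble(
    root_id = ids,
    name = graph$nodes$name,
    out_degree = as.integer(out_deg),
    in_degree = as.integer(in_deg),
    total_degree = as.integer(out_deg) + as.integer(in_deg),
    out_degree_gng = as.integer(out_gng)
  )
}

#' Number of DNs monosynaptically downstream of a source set
#'
#' Counts the unique DNs receiving at least one retained edge from any
#' source; the sources themselves are excluded from the count.
#'
#' @param graph a `dn_graph`.
#' @param source_ids character vector of source root IDs.
#' @param gng_only count only GNG targets.
#' @return integer count.
#' @export
downstream_dn_count <- function(graph, source_ids, gng_only = FALSE) {
  unknown <- setdiff(source_ids, graph$nodes$root_id)
  if (length(unknown)) abort(paste0("unknown source id(s): ", toString(unknown)))
  targets <- unique(graph$edges$post[graph$edges$pre %in% source_ids])
  targets <- setdiff(targets, source_ids)
  if (gng_only) {
    gng_ids <- graph$nodes$root_id[graph$nodes$is_gng %in% TRUE]
    targets <- intersect(targets, gng_ids)
  }
  length(targets)
}

#' Cumulative DN reachability across hops
#'
#' Number of distinct DNs reachable from the source set within 1..`max_hops`
#' DN-DN synaptic hops (boolean reachability on thresholded edges; sources
#' are excluded from the counts). With `source_ids = NULL` the per-node
#' curves for every DN are computed and summarised by their median, the
#' population reference curve.
#'
#' @param graph a `dn_graph`.
#' @param source_ids source root IDs, or `NULL` for the all-DN median curve.
#' @param max_hops maximum number of hops (>= 1).
#' @return tibble with `hop` and `n_reachable` (for a source set) or
#'   `hop`, `median_reachable` plus a `curves` attribute holding the full
#'   per-node tibble (for `source_ids = NULL`).
#' @export
reachable_within_hops <- function(graph, source_ids = NULL, max_hops = 1) {
  stopifnot(max_hops >= 1)
  ids <- graph$nodes$root_id
  A <- dn_adjacency(graph, "binary") > 0
  if (!is.null(source_ids)) {
    unknown <- setdiff(source_ids, ids)
    if (length(unknown)) abort(paste0("unknown source id(s): ", toString(unknown)))
    src <- ids %in% source_ids
    reach <- if (sum(src) == 1) A[src, ] else colSums(A[src, , drop = FALSE]) > 0
    counts <- integer(max_hops)
    counts[1] <- sum(reach & !src)
    if (max_hops > 1) {
      for (k in 2:max_hops) {
        reach <- reach | (as.numeric(reach) %*% A > 0)[1, ]
        counts[k] <- sum(reach & !src)
      }
    }
    return(tibble(hop = seq_len(max_hops), n_reachable = counts))
  }
  R <- A
  diag(R) <- FALSE
  per_hop <- matrix(0L, length(ids), max_hops)
  per_hop[, 1] <- rowSums(R)
  if (max_hops > 1) {
    for (k in 2:max_hops) {
      R <- R | ((R %*% A) > 0)
      diag(R) <- FALSE
      per_hop[, k] <- rowSums(R)
    }
  }
  curves <- tibble(
    root_id = rep(ids, max_hops),
    hop = rep(seq_len(max_hops), each = length(ids)),
    n_reachable = as.integer(per_hop)
  )
  out <- curves |>
    group_by(.data$hop) |>
    summarise(median_reachable = median(.data$n_reachable), .groups = "drop")
  attr(out, "curves") <- curves
  out
}

#' Fraction of DN-DN synapses located in the GNG
#'
#' Synapses in neuropils whose acronym denotes the gnathal ganglia (either
#' hemisphere), divided by all synapses on retained DN-DN edges.
#'
#' @param graph a `dn_graph`.
#' @param gng_neuropils character vector of neuropil acronyms counted as
#'   GNG; hemisphere suffixes (`_L`, `_R`) are matched automatically.
#' @return fraction in \\[0, 1\\].
#' @export
gng_synapse_fraction <- function(graph, gng_neuropils = "GNG") {
  np <- graph$neuropil
  total <- sum(np$syn_count)
  if (!isTRUE(total > 0)) abort("graph has no synapses in its neuropil table")
  base <- sub("_[LR]$", "", np$neuropil)
  sum(np$syn_count[base %in% gng_neuropils]) / total
}

#' Collapse the signed digraph to an undirected signed graph
#'
#' Reciprocal connectivity is summed: the undirected weight between two DNs
#' is the signed synapse count (positive excitatory, negative inhibitory)
#' added over both directions. Requires a policy under which every signed
#' edge resolves to +/-1 (glutamate must be `"inhibitory"` or `"excluded"`);
#' policy-excluded edges are dropped. Pairs whose excitation and inhibition
#' cancel exactly keep an explicit zero-weight edge, flagged and logged.
#'
#' @param graph a `dn_graph`.
#' @return object of class `signed_undirected`: list with `nodes`, `edges`
#'   (tibble `u`, `v`, `weight`, `zero_sum`) and `matrix` (dense symmetric
#'   signed adjacency).
#' @export
symmetrize_signed <- function(graph) {
  if (graph$policy$glut == "distinct") {
    abort("symmetrize_signed needs a policy resolving every edge to +/-1; use glut = 'inhibitory' or 'excluded'")
  }
  ids <- graph$nodes$root_id
  e <- filter(graph$edges, !is.na(.data$sign))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(e)) {
    idx <- cbind(match(e$pre, ids), match(e$post, ids))
    w <- e$sign * e$syn_count
    S <- matrix(0, length(ids), length(ids))
    S[idx] <- w
    W <- S + t(S)
    dimnames(W) <- list(ids, ids)
  }
  pairs <- e |>
    mutate(u = pmin(.data$pre, .data$post), v = pmax(.data$pre, .data$post)) |>
    group_by(.data$u, .data$v) |>
    summarise(weight = sum(.data$sign * .data$syn_count), .groups = "drop") |>
    mutate(zero_sum = .data$weight == 0)
  if (any(pairs$zero_sum)) {
    inform(sprintf("%d DN pair(s) with exactly cancelling excitation/inhibition (zero-weight edges kept)",
                   sum(pairs$zero_sum)))
  }
  structure(list(nodes = graph$nodes, edges = pairs, matrix = W),
            class = "signed_undirected")
}

#' @export
print.signed_undirected <- function(x, ...) {
  cat(sprintf("<signed_undirected> %d DNs, %d pairs (%d zero-sum)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$zero_sum)))
  invisible(x)
}

#' Export the edge list as TSV
#'
#' @param graph a `dn_graph`.
#' @param path output path.
#' @return the graph, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  nm <- setNames(graph$nodes$name, graph$nodes$root_id)
  out <- graph$edges |>
    transmute(pre_name = nm[.data$pre], post_name = nm[.data$post],
              synapses = .data$syn_count, nt = .data$nt, sign = .data$sign)
  write_tsv(out, path)
  invisible(graph)
}
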