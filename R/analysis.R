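#' Growth-mechanism analysis and link prediction on restored sequences
#'
#' Given an edge ordering (restored, true, random, or a pure
#' preferential-attachment null), these functions replay the growth and
#' measure: the cumulative preferential-attachment kernel `kappa(k)`,
#' trajectories of structural metrics at checkpoints, the evolution of a
#' labelled meso-level (community-by-community) adjacency, and
#' temporally-weighted truncated-SVD link prediction.
#'
#' @name analysis
NULL

order_indices <- function(net, order) {
  if (inherits(order, "restored_sequence")) order <- order$positions
  order <- as.integer(order)
  E <- n_edges(net)
  if (length(order) != E || !setequal(order, seq_len(E)))
    stop("`order` must assign a position to every edge")
  order(order)   # edge indices sorted oldest-first
}

#' Cumulative preferential-attachment function kappa(k)
#'
#' Replays the growth in the given order. Edges joining one new node to
#' one existing node are attachment events: the event is recorded at the
#' existing endpoint's current degree `k` (edges between two new or two
#' existing nodes carry no attachment information about the kernel and
#' are skipped). The exposure of class `k` is the number of degree-`k`
#' nodes present, summed over those events. The attachment kernel is
#' `pi(k) = attachments(k) / exposure(k)` and
#' `kappa(k) = sum_{k' <= k} pi(k')`, normalised so `kappa(k_max) = 1`.
#' Superlinear growth of `kappa` on log-log axes signals preferential
#' attachment; slope 1 is the neutral (uniform attachment) reference.
#'
#' @param net a [temporal_network].
#' @param order an edge ordering: `restored_sequence` or integer
#'   permutation (positions per edge, in `net`'s edge storage order).
#' @param min_exposure_frac degree classes whose exposure is below this
#'   fraction of the total exposure are dropped from the kernel (their
#'   rate estimate is dominated by noise); default 0.001.
#' @return a `pa_kernel`: data.frame `k`, `kappa` over the retained
#'   degree classes, plus `attachments` and `exposure` vectors.
#' @export
cumulative_pa <- function(net, order, min_exposure_frac = 1e-3) {
  idx <- order_indices(net, order)
  N <- length(net$nodes)
  ui <- match(net$edges[, 1], net$nodes)
  vi <- match(net$edges[, 2], net$nodes)
  deg <- integer(N)
  kmax_possible <- n_edges(net)
  attach <- numeric(kmax_possible)
  expo <- numeric(kmax_possible)
  nk <- numeric(kmax_possible)          # nk[k] = count of degree-k nodes
  # first replay position at which each node appears
  first_pos <- rep(Inf, N)
  for (s in seq_along(idx)) {
    e <- idx[s]
    first_pos[ui[e]] <- min(first_pos[ui[e]], s)
    first_pos[vi[e]] <- min(first_pos[vi[e]], s)
  }
  for (s in seq_along(idx)) {
    e <- idx[s]
    u <- ui[e]; v <- vi[e]
    new_u <- first_pos[u] == s
    new_v <- first_pos[v] == s
    if (xor(new_u, new_v)) {            # one new node attaching to one old
      old <- if (new_u) v else u
      k <- deg[old]
      if (k >= 1) {
        attach[k] <- attach[k] + 1
        kmax_now <- max(deg)
        expo[1:kmax_now] <- expo[1:kmax_now] + nk[1:kmax_now]
      }
    }
    for (w in c(u, v)) {
      k <- deg[w]
      if (k >= 1) nk[k] <- nk[k] - 1
      deg[w] <- k + 1L
      nk[k + 1L] <- nk[k + 1L] + 1
    }
  }
  kmax <- max(deg)
  ks <- seq_len(max(kmax - 1L, 1L))      # classes attachable to
  keep <- expo[ks] >= max(1, min_exposure_frac * sum(expo[ks]))
  ks <- ks[keep]
  pi_k <- attach[ks] / expo[ks]
  kappa <- cumsum(pi_k)
  if (length(kappa) && kappa[length(kappa)] > 0)
    kappa <- kappa / kappa[length(kappa)]
  structure(list(kernel = data.frame(k = ks, kappa = kappa),
                 attachments = attach[ks], exposure = expo[ks]),
            class = "pa_kernel")
}

subgraph_at <- function(net, idx, c) {
  sub <- net$edges[idx[seq_len(c)], , drop = FALSE]
  # canonical vertex and edge order: the checkpoint graph (and hence any
  # tie-break-sensitive metric) must not depend on the ordering source
  sub <- cbind(pmin(sub[, 1], sub[, 2]), pmax(sub[, 1], sub[, 2]))
  sub <- sub[order(sub[, 1], sub[, 2]), , drop = FALSE]
  ids <- sort(unique(as.vector(sub)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  igraph::add_edges(g, match(as.vector(t(sub)), ids))
}

metric_value <- function(g, metric, community_seed = 1) {
  switch(metric,
    modularity = {
      set.seed(community_seed)
      cl <- igraph::cluster_fast_greedy(g)
      igraph::modularity(cl)
    },
    assortativity = {
      v <- suppressWarnings(igraph::assortativity_degree(g))
      if (!is.finite(v)) NA_real_ else v
    },
    clustering = igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
    shortest_path = {
      v <- igraph::mean_distance(g)
      if (!is.finite(v)) NA_real_ else v
    },
    stop("unknown metric: ", metric))
}

TRAJECTORY_METRICS <- c("modularity", "assortativity", "clustering",
                        "shortest_path")

#' Structural-metric trajectory along a growth ordering
#'
#' At each checkpoint `c`, computes the metric on the subgraph formed by
#' the first `c` edges under each requested ordering source. The
#' shortest-path metric averages over connected node pairs only;
#' assortativity on a degree-regular checkpoint is undefined and returned
#' as `NA`.
#'
#' @param net a [temporal_network].
#' @param order the restored ordering (`restored_sequence` or permutation).
#' @param metric one of `"modularity"`, `"assortativity"`, `"clustering"`,
#'   `"shortest_path"`.
#' @param checkpoints increasing edge counts (each at most `E`).
#' @param baselines character subset of `c("true", "random", "pure_pa")`.
#' @param seed integer for the random baseline / the pure-PA null.
#' @return a `growth_trajectory`: data.frame with `checkpoint` and one
#'   column per ordering source.
#' @export
structural_trajectory <- function(net, order, metric,
                                  checkpoints = NULL,
                                  baselines = c("true", "random"),
                                  seed = 1) {
  metric <- match.arg(metric, TRAJECTORY_METRICS)
  E <- n_edges(net)
  if (is.null(checkpoints))
    checkpoints <- unique(round(seq(max(2, E / 10), E, length.out = 10)))
  if (any(checkpoints > E) || any(checkpoints < 1))
    stop("checkpoints must lie in 1..E")
  if (is.unsorted(checkpoints)) stop("checkpoints must be ascending")
  if (length(baselines) > 0)
    baselines <- match.arg(baselines, c("true", "random", "pure_pa"),
                           several.ok = TRUE)
  orderings <- list(restored = order_indices(net, order))
  if ("true" %in% baselines) orderings$true <- seq_len(E)
  if ("random" %in% baselines) {
    set.seed(seed)
    orderings$random <- sample(E)
  }
  pa_net <- NULL
  if ("pure_pa" %in% baselines) {
    core <- ceiling(E / 10)
    base <- temporal_network(net$edges[orderings$restored[seq_len(core)],
                                       , drop = FALSE],
                             nodes = net$nodes,
                             node_labels = net$node_labels)
    pa_net <- grow_pure_pa(base, E, seed = offset_seed(seed, 7))
    orderings$pure_pa <- seq_len(E)
  }
  out <- data.frame(checkpoint = checkpoints)
  for (src in names(orderings)) {
    src_net <- if (src == "pure_pa") pa_net else net
    out[[src]] <- vapply(checkpoints, function(c)
      metric_value(subgraph_at(src_net, orderings[[src]], c), metric,
                   community_seed = seed), 0)
  }
  structure(list(metric = metric, trajectory = out),
            class = "growth_trajectory")
}

#' Modularity trajectory: restored ordering versus the pure-PA null
#'
#' Newman modularity of a greedy community partition at each checkpoint,
#' under the restored ordering and under a pure preferential-attachment
#' regrowth from the restored earliest core.
#'
#' @inheritParams structural_trajectory
#' @return a `growth_trajectory` with columns `restored` and `pure_pa`.
#' @export
modularity_trajectory <- function(net, order, checkpoints = NULL, seed = 1) {
  structural_trajectory(net, order, "modularity", checkpoints,
                        baselines = "pure_pa", seed = seed)
}

#' Meso-level labelled adjacency evolution
#'
#' Collapses nodes sharing a label into one meso-node and counts, at each
#' checkpoint of the given ordering, the edges between every pair of
#' labels; edges inside one label land on the diagonal.
#'
#' @param net a [temporal_network] whose every node is labelled.
#' @param order edge ordering (`restored_sequence` or permutation).
#' @param checkpoints increasing edge counts.
#' @return list of symmetric label-by-label count matrices, one per
#'   checkpoint (named by checkpoint).
#' @export
meso_adjacency <- function(net, order, checkpoints) {
  if (is.null(net$node_labels)) stop("network has no node labels")
  lab <- net$node_labels[net$nodes]
  if (any(is.na(lab))) {
    miss <- net$nodes[which(is.na(lab))[1]]
    stop("unlabeled node encountered: ", miss)
  }
  idx <- order_indices(net, order)
  labs <- sort(unique(lab))
  lu <- lab[match(net$edges[idx, 1], net$nodes)]
  lv <- lab[match(net$edges[idx, 2], net$nodes)]
  out <- lapply(checkpoints, function(c) {
    M <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (e in seq_len(c)) {
      a <- lu[e]; b <- lv[e]
      M[a, b] <- M[a, b] + 1
      if (a != b) M[b, a] <- M[b, a] + 1
    }
    M
  })
  names(out) <- checkpoints
  out
}

#' Temporally-weighted collapsed adjacency matrix
#'
#' The restored order turns the network into a three-way tensor (node,
#' node, arrival position); collapsing it with geometric decay `theta`
#' gives a weighted adjacency `X(u, v) = theta^(max(alpha_hat) -
#' alpha_hat_i)` on existing edges - the newest edge has weight exactly 1,
#' the oldest `theta^(E-1)`.
#'
#' @param net a [temporal_network].
#' @param order edge ordering (`restored_sequence` or permutation).
#' @param theta decay in (0, 1); `theta = 1` (a plain binary adjacency,
#'   the unordered baseline) is permitted only with `allow_binary = TRUE`.
#' @param allow_binary logical.
#' @return a `temporal_score_matrix`: `X` (dense symmetric matrix with
#'   node-id dimnames), `theta`, `order`.
#' @export
collapsed_tensor <- function(net, order, theta, allow_binary = FALSE) {
  if (theta <= 0 || theta > 1 || (theta == 1 && !allow_binary))
    stop("`theta` must lie in (0, 1)")
  pos <- if (inherits(order, "restored_sequence")) order$positions
         else as.integer(order)
  E <- n_edges(net)
  if (length(pos) != E || !setequal(pos, seq_len(E)))
    stop("`order` must be a complete permutation")
  N <- length(net$nodes)
  X <- matrix(0, N, N, dimnames = list(net$nodes, net$nodes))
  i <- match(net$edges[, 1], net$nodes)
  j <- match(net$edges[, 2], net$nodes)
  w <- theta^(max(pos) - pos)
  X[cbind(i, j)] <- w
  X[cbind(j, i)] <- w
  structure(list(X = X, theta = theta, positions = pos),
            class = "temporal_score_matrix")
}

#' Truncated-SVD link scores from a collapsed adjacency
#'
#' Reconstructs the weighted adjacency at rank `r`; the reconstruction
#' value of each non-edge is its score, and candidates are ranked
#' descending (existing edges are excluded).
#'
#' @param tsm a `temporal_score_matrix` (or plain symmetric matrix).
#' @param r truncation rank, between 1 and the matrix rank.
#' @return a `link_scores`: `scores` (dense reconstruction),
#'   `candidates` (data.frame `u`, `v`, `score`, ranked descending).
#' @export
tsvd_link_scores <- function(tsm, r) {
  X <- if (inherits(tsm, "temporal_score_matrix")) tsm$X else tsm
  if (r < 1 || r > min(dim(X))) stop("rank `r` out of range")
  sv <- svd(X, nu = r, nv = r)
  S <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
  dimnames(S) <- dimnames(X)
  N <- nrow(X)
  ut <- which(upper.tri(X), arr.ind = TRUE)
  nonedge <- ut[X[ut] == 0, , drop = FALSE]
  cand <- data.frame(u = rownames(X)[nonedge[, 1]],
                     v = colnames(X)[nonedge[, 2]],
                     score = S[nonedge], stringsAsFactors = FALSE)
  cand <- cand[order(-cand$score, cand$u, cand$v), ]
  rownames(cand) <- NULL
  structure(list(scores = S, candidates = cand), class = "link_scores")
}

#' Number of held-out edges among the top-r predicted links
#'
#' @param scores a `link_scores` object.
#' @param held_out two-column matrix of held-out edges (disjoint from the
#'   observed edges).
#' @param r number of top-ranked candidates to consider (>= 0).
#' @return integer hit count; non-decreasing in `r`.
#' @export
hits_at_r <- function(scores, held_out, r) {
  if (r < 0) stop("`r` must be non-negative")
  if (r == 0) return(0L)
  if (is.null(dim(held_out))) held_out <- matrix(held_out, ncol = 2)
  top <- utils::head(scores$candidates, r)
  sum(edge_key(top$u, top$v) %in% edge_key(held_out[, 1], held_out[, 2]))
}
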