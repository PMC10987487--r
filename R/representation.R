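#' Node embeddings and per-edge vector views
#'
#' Six fixed-length vector representations are built for every edge: five
#' come from node-embedding methods (the edge vector is the Hadamard
#' product of its two endpoint vectors), the sixth is a vector of eleven
#' classical link features computed on the final topology. The five
#' node-embedding views:
#'
#' * `DW` — DeepWalk: uniform random walks (10 per node, length 40),
#'   skip-gram with negative sampling (SGNS) over a 5-step window.
#' * `N2V` — node2vec: second-order biased random walks (return parameter
#'   `p = 1`, in-out parameter `q = 0.5`), SGNS over a 5-step window.
#' * `LINE` — SGNS directly on the edge list (1-step neighbourhood, i.e.
#'   second-order proximity with negative sampling).
#' * `SDNE` — a single-hidden-layer autoencoder on adjacency rows with a
#'   reconstruction penalty up-weighting observed edges and a Laplacian
#'   first-order term pulling connected nodes together; the hidden
#'   activations are the embedding.
#' * `S2V` — struct2vec-style structural identity: per-node structural
#'   degree-profile features (degree, clustering, coreness, neighbour- and
#'   second-neighbourhood degree summaries), z-scored and rotated by PCA.
#'
#' The walk sampling and SGNS inner loops are implemented in C++ and
#' driven by R's RNG, so every embedding is reproducible from its seed.
#'
#' @name representation
NULL

offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

EMBED_METHODS <- c("N2V", "DW", "SDNE", "LINE", "S2V")

#' Embed the nodes of a network
#'
#' @param net a [temporal_network]; must have at least one node.
#' @param method one of `"N2V"`, `"DW"`, `"SDNE"`, `"LINE"`, `"S2V"`.
#' @param dim embedding dimension, at least 2.
#' @param seed integer; the embedding is deterministic given the seed.
#' @param ... method parameters: `window` (DW, default 10), `p`, `q`,
#'   `walks_per_node`, `walk_length`, `window` (N2V, defaults 1, 0.5, 10,
#'   40, 5).
#' @return a `node_embedding`: list with `method`, `dim`, `seed` and
#'   `vectors`, an N x dim matrix with one row per node (row names are the
#'   node ids). Isolated nodes get zero vectors.
#' @export
embed_nodes <- function(net, method, dim, seed, ...) {
  if (length(net$nodes) == 0) stop("cannot embed an empty graph")
  if (dim < 2) stop("`dim` must be at least 2")
  method <- match.arg(method, EMBED_METHODS)
  set.seed(seed)
  A <- dense_adjacency(net)
  V <- switch(method,
    DW   = emb_sgns_walks(A, dim, p = 1, q = 1, ...),
    N2V  = emb_sgns_walks(A, dim, p = 1, q = 0.5, ...),
    LINE = emb_line(A, dim, ...),
    SDNE = emb_sdne(A, dim, ...),
    S2V  = emb_struct(net, A, dim, ...))
  V[!is.finite(V)] <- 0
  rownames(V) <- net$nodes
  structure(list(method = method, dim = dim, seed = seed, vectors = V),
            class = "node_embedding")
}

dense_adjacency <- function(net) {
  N <- length(net$nodes)
  A <- matrix(0, N, N)
  i <- match(net$edges[, 1], net$nodes)
  j <- match(net$edges[, 2], net$nodes)
  A[cbind(i, j)] <- 1
  A[cbind(j, i)] <- 1
  A
}

fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (length(j) && V[j, k] < 0) V[, k] <- -V[, k]
  }
  V
}

pad_dim <- function(V, dim) {
  if (ncol(V) < dim) V <- cbind(V, matrix(0, nrow(V), dim - ncol(V)))
  V
}

# CSR adjacency (0-based, sorted neighbour lists) for the C++ walkers.
graph_csr <- function(A) {
  adj <- apply(A > 0, 1, which, simplify = FALSE)
  list(indptr = as.integer(cumsum(c(0, lengths(adj)))),
       indices = as.integer(unlist(adj) - 1L),
       degree = lengths(adj))
}

# Skip-gram pairs from a walk matrix (both directions, offsets 1..window).
walk_pairs <- function(walks, window) {
  wl <- ncol(walks)
  ctr <- integer(0); ctx <- integer(0)
  for (off in seq_len(min(window, wl - 1))) {
    a <- as.vector(walks[, seq_len(wl - off)])
    b <- as.vector(walks[, seq_len(wl - off) + off])
    ctr <- c(ctr, a, b); ctx <- c(ctx, b, a)
  }
  list(ctr = ctr, ctx = ctx)
}

run_sgns <- function(ctr, ctx, N, dim, epochs = 5L, lr0 = 0.025, neg = 5L) {
  perm <- sample(length(ctr))            # decorrelate the SGD stream
  ctr <- ctr[perm]; ctx <- ctx[perm]
  freq <- tabulate(ctx + 1L, nbins = N)^0.75
  cdf <- cumsum(freq) / sum(freq)
  sgns_train_cpp(ctr, ctx, N, as.integer(dim), as.integer(epochs),
                 lr0, as.integer(neg), cdf)
}

# DeepWalk / node2vec: sampled (biased) walks + SGNS.
emb_sgns_walks <- function(A, dim, p = 1, q = 1, walks_per_node = 10L,
                           walk_length = 40L, window = 5L, epochs = 5L,
                           lr0 = 0.025, neg = 5L) {
  N <- nrow(A)
  csr <- graph_csr(A)
  active <- which(csr$degree > 0)
  if (length(active) == 0) return(matrix(0, N, dim))
  starts <- rep(active - 1L, walks_per_node)
  walks <- random_walks_cpp(csr$indptr, csr$indices, starts,
                            as.integer(walk_length), p, q)
  pr <- walk_pairs(walks, window)
  run_sgns(pr$ctr, pr$ctx, N, dim, epochs = epochs, lr0 = lr0, neg = neg)
}

# LINE (second-order proximity): SGNS on the edge list itself.
emb_line <- function(A, dim, target_updates = 2e6, lr0 = 0.025, neg = 5L) {
  N <- nrow(A)
  idx <- which(A > 0, arr.ind = TRUE)   # both orientations of every edge
  if (nrow(idx) == 0) return(matrix(0, N, dim))
  epochs <- max(5L, min(500L, ceiling(target_updates / nrow(idx))))
  run_sgns(idx[, 1] - 1L, idx[, 2] - 1L, N, dim, epochs = epochs,
           lr0 = lr0, neg = neg)
}

# SDNE-style autoencoder: tanh hidden layer on adjacency rows, sigmoid
# reconstruction with observed edges up-weighted by `beta`, plus a
# Laplacian first-order term; trained full-batch with Adam.
emb_sdne <- function(A, dim, beta = 5, alpha = 0.1, epochs = 150L,
                     lr = 0.01) {
  N <- nrow(A)
  d <- rowSums(A)
  B <- 1 + (beta - 1) * A
  W1 <- matrix(stats::rnorm(N * dim, sd = 1 / sqrt(N)), N, dim)
  b1 <- numeric(dim)
  W2 <- matrix(stats::rnorm(dim * N, sd = 1 / sqrt(dim)), dim, N)
  b2 <- numeric(N)
  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
  upd <- function(s, g, t) {
    s$m <- 0.9 * s$m + 0.1 * g
    s$v <- 0.999 * s$v + 0.001 * g^2
    step <- lr * sqrt(1 - 0.999^t) / (1 - 0.9^t) * s$m / (sqrt(s$v) + 1e-8)
    list(state = s, step = step)
  }
  for (t in seq_len(epochs)) {
    H <- tanh(sweep(A %*% W1, 2, b1, "+"))
    Z <- sweep(H %*% W2, 2, b2, "+")
    Xhat <- stats::plogis(Z)
    dZ <- 2 * B * (Xhat - A) * Xhat * (1 - Xhat) / (N * N)
    gW2 <- crossprod(H, dZ)
    gb2 <- colSums(dZ)
    dH <- dZ %*% t(W2)
    if (alpha > 0) dH <- dH + (2 * alpha / N) * (d * H - A %*% H)
    dZ1 <- dH * (1 - H^2)
    gW1 <- crossprod(A, dZ1)
    gb1 <- colSums(dZ1)
    for (nm in c("W1", "b1", "W2", "b2")) {
      g <- switch(nm, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      u <- upd(st[[nm]], g, t)
      st[[nm]] <- u$state
      if (nm == "W1") W1 <- W1 - u$step
      else if (nm == "b1") b1 <- b1 - u$step
      else if (nm == "W2") W2 <- W2 - u$step
      else b2 <- b2 - u$step
    }
  }
  tanh(sweep(A %*% W1, 2, b1, "+"))
}

# Structural-identity embedding from z-scored degree-profile features.
emb_struct <- function(net, A, dim) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  core <- igraph::coreness(g)
  nbr_stats <- t(vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) == 0) return(c(0, 0, 0))
    kd <- deg[nb]
    c(mean(kd), min(kd), max(kd))
  }, numeric(3)))
  A2 <- (A %*% A > 0) * 1
  diag(A2) <- 0
  hop2 <- rowSums(A2)
  FM <- cbind(log1p(deg), lc, core,
              log1p(nbr_stats[, 1]), log1p(nbr_stats[, 2]),
              log1p(nbr_stats[, 3]), log1p(hop2))
  sdv <- apply(FM, 2, stats::sd)
  keep <- which(sdv > 0)
  if (length(keep) == 0) return(matrix(0, nrow(A), dim))
  Z <- scale(FM[, keep, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  V <- fix_signs(pc$x)
  pad_dim(V[, seq_len(min(dim, ncol(V))), drop = FALSE], dim)
}

#' Hadamard edge vector from a node embedding
#'
#' @param emb a `node_embedding`.
#' @param edge character vector of length two (the endpoints).
#' @return elementwise product of the two endpoint vectors; symmetric in
#'   endpoint order.
#' @export
edge_vector <- function(emb, edge) {
  i <- match(edge[1], rownames(emb$vectors))
  j <- match(edge[2], rownames(emb$vectors))
  if (is.na(i) || is.na(j)) stop("unknown node in `edge`")
  emb$vectors[i, ] * emb$vectors[j, ]
}

CLASSICAL_FEATURES <- c(
  "common_neighbors", "jaccard", "adamic_adar", "resource_allocation",
  "pa_score", "degree_sum", "degree_diff", "degree_min", "degree_max",
  "clustering_sum", "edge_triangles")

#' Eleven classical link features for the edges of a network
#'
#' Computed on the final topology only and symmetric in endpoint order:
#' common neighbours, Jaccard coefficient, Adamic-Adar, resource
#' allocation, preferential-attachment score (`k_u * k_v`), degree sum,
#' absolute degree difference, min and max endpoint degree, sum of
#' endpoint local clustering coefficients, and the number of triangles
#' containing the edge.
#'
#' @param net a [temporal_network].
#' @param edges optional two-column matrix of edges to evaluate; defaults
#'   to all edges of `net`. Each requested edge must exist in `net`.
#' @return numeric matrix, one row per edge, with columns named after the
#'   features. All entries are finite.
#' @export
classical_edge_features <- function(net, edges = NULL) {
  if (is.null(edges)) edges <- net$edges
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2)
  keys <- edge_key(net$edges[, 1], net$edges[, 2])
  want <- edge_key(edges[, 1], edges[, 2])
  if (!all(want %in% keys)) stop("edge not present in network: ",
                                 gsub("\t", "--", want[!want %in% keys][1]))
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(deg) <- names(lc) <- net$nodes
  nbrs <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                 function(v) net$nodes[as.integer(v)])
  names(nbrs) <- net$nodes
  out <- matrix(0, nrow(edges), length(CLASSICAL_FEATURES),
                dimnames = list(NULL, CLASSICAL_FEATURES))
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    nu <- nbrs[[u]]; nv <- nbrs[[v]]
    cn <- intersect(nu, nv)
    un <- union(nu, nv)
    kcn <- deg[cn]
    out[r, ] <- c(
      length(cn),
      if (length(un) > 0) length(cn) / length(un) else 0,
      if (length(cn) > 0) sum(1 / log(kcn)) else 0,
      if (length(cn) > 0) sum(1 / kcn) else 0,
      deg[u] * deg[v],
      deg[u] + deg[v],
      abs(deg[u] - deg[v]),
      min(deg[u], deg[v]),
      max(deg[u], deg[v]),
      lc[u] + lc[v],
      length(cn))
  }
  out
}

#' Build the full set of six edge views
#'
#' Runs the five node-embedding methods, takes Hadamard products per edge,
#' computes the classical feature matrix, and standardises the feature
#' columns (zero mean, unit variance over edges; zero-variance columns are
#' kept as zeros).
#'
#' @param net a [temporal_network].
#' @param dim embedding dimension (default 64).
#' @param seed integer; each embedding method gets a distinct sub-seed
#'   derived from it.
#' @return an `edge_view_set`: `views` (list of six E x * matrices, views
#'   1-5 of width `dim`, view 6 of width 11), `feature_names`,
#'   `classical_raw` (unstandardised features, used for the best-feature
#'   comparator), and `node_embeddings` (the five `node_embedding`
#'   objects, kept for transfer alignment).
#' @export
build_edge_views <- function(net, dim = 64, seed = 1) {
  embs <- lapply(seq_along(EMBED_METHODS), function(k)
    embed_nodes(net, EMBED_METHODS[k], dim, offset_seed(seed, k)))
  names(embs) <- EMBED_METHODS
  i <- match(net$edges[, 1], net$nodes)
  j <- match(net$edges[, 2], net$nodes)
  views <- lapply(embs, function(e) e$vectors[i, , drop = FALSE] *
                    e$vectors[j, , drop = FALSE])
  raw <- classical_edge_features(net)
  # count-like features are heavy-tailed; log1p before z-scoring
  views$classical <- standardize_columns(log1p(raw))
  structure(list(views = views, feature_names = CLASSICAL_FEATURES,
                 classical_raw = raw, node_embeddings = embs,
                 dim = dim, seed = seed),
            class = "edge_view_set")
}

standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Z <- sweep(X, 2, mu, "-")
  for (k in seq_len(ncol(X))) {
    Z[, k] <- if (is.finite(sdv[k]) && sdv[k] > 0) Z[, k] / sdv[k] else 0
  }
  Z
}

#' @export
print.edge_view_set <- function(x, ...) {
  cat("<edge_view_set> ", nrow(x$views[[1]]), " edges, views: ",
      paste(names(x$views), collapse = ", "), ", dim = ", x$dim, "\n", sep = "")
  invisible(x)
}
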