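#' Synthetic growing networks with known edge arrival order
#'
#' Generators for the three classical growth models used as ground-truth
#' testbeds: Barabasi-Albert preferential attachment, the
#' popularity-similarity-optimisation (PSO) model in the hyperbolic disk,
#' and the Bianconi-Barabasi fitness model. All three record the exact
#' arrival position of every edge; the `m` edges brought in by one node
#' get consecutive positions in the order the attachment draws were made.
#'
#' @name netgen
NULL

# Sample one attachment target with probability proportional to `w`
# (uniform when all weights vanish, e.g. at the very first step of m = 1
# growth where every seed degree is zero).
sample_target <- function(w) {
  s <- sum(w)
  if (s <= 0) sample.int(length(w), 1L)
  else sample.int(length(w), 1L, prob = w)
}

check_sizes <- function(n_nodes, m) {
  if (m < 1L) stop("`m` must be at least 1")
  if (n_nodes <= m) stop("`n_nodes` must exceed `m`")
}

seed_clique_edges <- function(m) {
  if (m < 2L) return(matrix(character(), ncol = 2))
  pairs <- utils::combn(m, 2L)
  cbind(as.character(pairs[1, ]), as.character(pairs[2, ]))
}

#' Barabasi-Albert growth
#'
#' Starts from an `m`-node clique; each subsequent node attaches `m` edges
#' to distinct existing nodes chosen with probability proportional to
#' degree (without replacement within one arrival step).
#'
#' @param n_nodes number of nodes, greater than `m`.
#' @param m edges added per new node.
#' @param seed integer; fully determines the output.
#' @return a [temporal_network] with fine-grained arrival order.
#' @examples
#' net <- generate_ba(50, 2, seed = 1)
#' n_edges(net)  # choose(2, 2) is 1 clique edge + 2 * 48
#' @export
generate_ba <- function(n_nodes, m, seed) {
  check_sizes(n_nodes, m)
  set.seed(seed)
  grow_degree_weighted(n_nodes, m, fitness = rep(1, n_nodes))
}

#' Bianconi-Barabasi fitness growth
#'
#' As [generate_ba] but attachment probability is proportional to
#' degree times a node-intrinsic fitness drawn i.i.d. at birth. With all
#' fitness values equal the model reduces exactly to pure preferential
#' attachment.
#'
#' @inheritParams generate_ba
#' @param fitness_fun function of one argument `n` returning `n` positive
#'   fitness draws; default uniform on (0, 1].
#' @return a [temporal_network]; node fitness values are attached as the
#'   `fitness` attribute.
#' @export
generate_fitness <- function(n_nodes, m, seed,
                             fitness_fun = function(n) stats::runif(n)) {
  check_sizes(n_nodes, m)
  set.seed(seed)
  fit <- fitness_fun(n_nodes)
  if (length(fit) != n_nodes || any(!is.finite(fit)) || any(fit <= 0))
    stop("fitness distribution must yield `n_nodes` positive finite values")
  grow_degree_weighted(n_nodes, m, fitness = fit)
}

grow_degree_weighted <- function(n_nodes, m, fitness) {
  E <- m * (m - 1) / 2 + m * (n_nodes - m)
  from <- character(E); to <- character(E)
  deg <- integer(n_nodes)
  ne <- 0L
  if (m >= 2L) {
    cl <- seed_clique_edges(m)
    k <- nrow(cl)
    from[1:k] <- cl[, 1]; to[1:k] <- cl[, 2]
    deg[1:m] <- m - 1L
    ne <- k
  }
  for (t in seq.int(m + 1L, n_nodes)) {
    w <- deg[seq_len(t - 1L)] * fitness[seq_len(t - 1L)]
    for (j in seq_len(m)) {
      tgt <- sample_target(w)
      w[tgt] <- 0                      # no duplicate edges within a step
      ne <- ne + 1L
      from[ne] <- as.character(t); to[ne] <- as.character(tgt)
      deg[tgt] <- deg[tgt] + 1L
    }
    deg[t] <- m
  }
  net <- temporal_network(cbind(from, to), nodes = as.character(seq_len(n_nodes)))
  attr(net, "fitness") <- fitness
  net
}

#' Popularity-similarity-optimisation (PSO) growth
#'
#' Nodes arrive at hyperbolic coordinates (radius `2 log t`, uniform
#' angle); existing radii fade toward the newcomer's radius with exponent
#' `beta` (popularity fading). At temperature 0 each new node connects to
#' its `m` hyperbolically nearest predecessors; at `T > 0` the `m` targets
#' are drawn without replacement with probability proportional to
#' `exp(-d / (2 T))` of the hyperbolic distance `d`. The first `m + 1`
#' nodes connect to all predecessors.
#'
#' @inheritParams generate_ba
#' @param temperature non-negative; 0 gives deterministic nearest-neighbour
#'   choice.
#' @param beta popularity-fading exponent in (0, 1].
#' @return a [temporal_network] with fine-grained arrival order.
#' @export
generate_pso <- function(n_nodes, m, seed, temperature = 0.1, beta = 0.5) {
  check_sizes(n_nodes, m)
  if (temperature < 0) stop("`temperature` must be >= 0")
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]")
  set.seed(seed)
  angles <- stats::runif(n_nodes, 0, 2 * pi)
  radii <- 2 * log(seq_len(n_nodes))
  from <- character(0); to <- character(0)
  for (t in 2:n_nodes) {
    prev <- seq_len(t - 1L)
    r_faded <- beta * radii[prev] + (1 - beta) * radii[t]
    dtheta <- pi - abs(pi - abs(angles[prev] - angles[t]))
    arg <- cosh(r_faded) * cosh(radii[t]) -
      sinh(r_faded) * sinh(radii[t]) * cos(dtheta)
    d <- acosh(pmax(arg, 1))
    if (t <= m + 1L) {
      tgt <- prev
    } else if (temperature == 0) {
      tgt <- order(d, prev)[seq_len(m)]
    } else {
      w <- exp(-(d - min(d)) / (2 * temperature))
      tgt <- integer(m)
      for (j in seq_len(m)) {
        pick <- sample_target(w)
        w[pick] <- 0
        tgt[j] <- pick
      }
    }
    from <- c(from, rep(as.character(t), length(tgt)))
    to <- c(to, as.character(tgt))
  }
  net <- temporal_network(cbind(from, to), nodes = as.character(seq_len(n_nodes)))
  attr(net, "coords") <- cbind(radius = radii, angle = angles)
  net
}

#' Grow a network by the pure preferential-attachment rule
#'
#' Null baseline used to contrast restored growth trajectories: starting
#' from `base` (typically the earliest core of a restored or true
#' sequence, with the full node set retained so far-unborn nodes are
#' present as isolates), edges are added one at a time: the source
#' endpoint is drawn uniformly over the node list and the target with
#' probability proportional to degree plus a small smoothing constant
#' `a`, rejecting self-loops and duplicates, until `n_edges_target`
#' edges exist. (Drawing *both* endpoints preferentially is available
#' via `both_preferential = TRUE`, but with duplicate rejection that
#' variant saturates the degree-weighted core — every high-degree pair
#' gets used up — which caps the maximum degree near `sqrt(2 E)` and
#' erases the hub structure the null is meant to preserve.)
#'
#' @param base a `temporal_network`; returned unchanged when it already has
#'   `n_edges_target` edges.
#' @param n_edges_target total edge count to reach; must not exceed the
#'   simple-graph capacity of the node set.
#' @param seed integer.
#' @param a degree smoothing constant (default 0.01, keeping the process
#'   close to pure preferential attachment).
#' @param both_preferential draw the source endpoint preferentially too
#'   (default FALSE; see above).
#' @return a [temporal_network] whose first edges are `base`'s.
#' @export
grow_pure_pa <- function(base, n_edges_target, seed, a = 0.01,
                         both_preferential = FALSE) {
  if (n_edges(base) == 0 && length(base$nodes) == 0)
    stop("`base` network is empty")
  N <- length(base$nodes)
  if (n_edges_target > N * (N - 1) / 2)
    stop("`n_edges_target` exceeds simple-graph capacity of ", N, " nodes")
  if (n_edges_target < n_edges(base))
    stop("`n_edges_target` is below the base edge count")
  if (n_edges_target == n_edges(base)) return(base)
  set.seed(seed)
  deg <- tabulate(match(as.vector(base$edges), base$nodes), nbins = N)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in edge_key(base$edges[, 1], base$edges[, 2])) assign(k, TRUE, seen)
  extra <- n_edges_target - n_edges(base)
  from <- character(extra); to <- character(extra)
  got <- 0L
  attempts <- 0L
  max_attempts <- 200L * extra + 1000L
  while (got < extra) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", extra, " edges without duplicates; graph too dense")
    w <- deg + a
    u <- if (both_preferential) sample.int(N, 1L, prob = w)
         else sample.int(N, 1L)
    w[u] <- 0
    v <- sample.int(N, 1L, prob = w)
    k <- edge_key(base$nodes[u], base$nodes[v])
    if (exists(k, envir = seen, inherits = FALSE)) next
    assign(k, TRUE, seen)
    got <- got + 1L
    from[got] <- base$nodes[u]; to[got] <- base$nodes[v]
    deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
  }
  temporal_network(rbind(base$edges, cbind(from, to)), nodes = base$nodes,
                   node_labels = base$node_labels)
}
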