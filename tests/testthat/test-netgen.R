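test_that("BA growth: tree for m = 1, determinism, valid invariants", {
  net <- generate_ba(5, 1, seed = 3)
  expect_equal(n_edges(net), 4L)
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::gsize(g), 4)        # a tree on 5 nodes
  a <- generate_ba(200, 2, seed = 9)
  b <- generate_ba(200, 2, seed = 9)
  expect_identical(a$edges, b$edges)
  expect_error(generate_ba(3, 3, seed = 1), "exceed")
  expect_error(generate_ba(10, 0, seed = 1), "at least 1")
})

test_that("BA degree exponent from a maximum-likelihood fit is near 3", {
  # discrete power-law MLE (Clauset-style continuous approximation),
  # k_min at the attachment parameter m
  alphas <- vapply(1:20, function(s) {
    net <- generate_ba(1000, 3, seed = 100 + s)
    deg <- igraph::degree(as_igraph(net))
    k <- deg[deg >= 3]
    1 + length(k) / sum(log(k / 2.5))
  }, 0)
  expect_gt(mean(alphas), 2.5)
  expect_lt(mean(alphas), 3.5)
})

test_that("BA degree distribution is heavy-tailed", {
  hits <- sum(vapply(1:10, function(s) {
    deg <- igraph::degree(as_igraph(generate_ba(2000, 2, seed = s)))
    max(deg) > 10 * stats::median(deg)
  }, TRUE))
  expect_gte(hits, 9)
})

test_that("PSO at zero temperature picks the nearest predecessors", {
  n <- 12; m <- 2; seed <- 5; beta <- 0.6
  net <- generate_pso(n, m, seed, temperature = 0, beta = beta)
  # independent recomputation of coordinates and hyperbolic distances
  set.seed(seed)
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- 2 * log(seq_len(n))
  hyp <- function(s, t) {
    rs <- beta * rad[s] + (1 - beta) * rad[t]
    dth <- pi - abs(pi - abs(ang[s] - ang[t]))
    acosh(max(1, cosh(rs) * cosh(rad[t]) - sinh(rs) * sinh(rad[t]) * cos(dth)))
  }
  for (t in (m + 2):n) {
    chosen <- sort(as.integer(net$edges[net$edges[, 1] == as.character(t), 2]))
    d <- vapply(seq_len(t - 1), function(s) hyp(s, t), 0)
    expect_equal(chosen, sort(order(d)[1:m]))
  }
  expect_error(generate_pso(3, 3, seed = 1), "exceed")
  expect_error(generate_pso(10, 2, 1, beta = 0), "beta")
  expect_error(generate_pso(10, 2, 1, temperature = -1), "temperature")
})

test_that("PSO similarity space induces more clustering than BA", {
  cc <- vapply(1:10, function(s) {
    g_pso <- as_igraph(generate_pso(500, 2, s, temperature = 0.1, beta = 0.5))
    g_ba <- as_igraph(generate_ba(500, 2, s))
    c(igraph::transitivity(g_pso, type = "localaverage", isolates = "zero"),
      igraph::transitivity(g_ba, type = "localaverage", isolates = "zero"))
  }, numeric(2))
  expect_gt(mean(cc[1, ]), mean(cc[2, ]))
})

test_that("fitness model with equal fitness reduces to pure PA", {
  a <- generate_fitness(300, 2, seed = 7, fitness_fun = function(n) rep(1, n))
  b <- generate_ba(300, 2, seed = 7)
  expect_identical(a$edges, b$edges)
})

test_that("fitness model edge count is deterministic and fitness matters", {
  net <- generate_fitness(500, 2, seed = 4)
  expect_equal(n_edges(net), 2 * (500 - 2) + 1)
  diffs <- vapply(1:10, function(s) {
    net <- generate_fitness(300, 2, seed = s,
                            fitness_fun = function(n) sample(c(1, 10), n,
                                                             replace = TRUE))
    fit <- attr(net, "fitness")
    deg <- igraph::degree(as_igraph(net))[net$nodes]
    mean(deg[fit == 10]) - mean(deg[fit == 1])
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_error(generate_fitness(100, 2, 1, fitness_fun = function(n) rep(-1, n)),
               "positive")
})

test_that("pure-PA growth keeps the base, favours hubs, respects capacity", {
  base <- generate_ba(30, 2, seed = 1)
  expect_identical(grow_pure_pa(base, n_edges(base), seed = 1), base)
  expect_error(grow_pure_pa(base, 30 * 29 / 2 + 1, seed = 1), "capacity")
  # preferential continuation favours the seeded hub: its mean final
  # degree dominates every other node's, and it is the strict maximum
  # far more often than its 1/104 uniform share (overtaking by a leaf
  # retains Polya-urn probability ~1/8, so strict dominance is not
  # near-certain for any linear-PA continuation of a 3:1 advantage)
  star <- temporal_network(cbind("hub", c("l1", "l2", "l3")),
                           nodes = c("hub", paste0("l", 1:3),
                                     paste0("x", 1:100)))
  degs <- vapply(1:100, function(s) {
    g <- grow_pure_pa(star, 103, seed = s)
    igraph::degree(as_igraph(g))[star$nodes]
  }, numeric(104))
  wins <- sum(vapply(1:100, function(s)
    degs[1, s] == max(degs[, s]) && sum(degs[, s] == max(degs[, s])) == 1,
    TRUE))
  expect_gte(wins, 40)
  mean_deg <- rowMeans(degs)
  expect_equal(unname(which.max(mean_deg)), 1L)
  expect_gt(mean_deg[1], 1.5 * max(mean_deg[-1]))
})

test_that("pure-PA regrowth washes out planted community structure", {
  net <- sbm_network(n_per_block = 25, n_edge = 150, p_within = 0.95, seed = 2)
  q_sbm <- igraph::modularity(igraph::cluster_fast_greedy(as_igraph(net)))
  base <- temporal_network(net$edges[1:15, ], nodes = net$nodes)
  grown <- grow_pure_pa(base, 150, seed = 3)
  q_pa <- igraph::modularity(igraph::cluster_fast_greedy(as_igraph(grown)))
  expect_gt(q_sbm, q_pa)
})

test_that("generator outputs satisfy temporal-network invariants", {
  for (s in 1:3) {
    for (net in list(generate_ba(100, 2, s), generate_pso(100, 2, s),
                     generate_fitness(100, 3, s))) {
      keys <- apply(net$edges, 1, function(e) paste(sort(e), collapse = "|"))
      expect_false(any(duplicated(keys)))
      expect_false(any(net$edges[, 1] == net$edges[, 2]))
    }
  }
})
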