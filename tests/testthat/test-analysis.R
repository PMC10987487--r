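test_that("cumulative PA kernel matches a hand-computed star trace", {
  star <- temporal_network(rbind(c("a", "b"), c("a", "c"), c("a", "d")))
  pk <- cumulative_pa(star, 1:3)
  # edge 2 attaches to a at degree 1 (exposure: a and b); edge 3 attaches
  # to a at degree 2 (exposure: two degree-1 nodes, one degree-2 node)
  expect_equal(pk$attachments, c(1, 1))
  expect_equal(pk$exposure, c(4, 1))
  expect_equal(pk$kernel$kappa, c(0.25, 1.25) / 1.25)
})

test_that("uniform attachment gives a near-linear kernel, PA superlinear", {
  unif <- uniform_attach_network(400, seed = 1)
  pk_u <- cumulative_pa(unif, arrival_order(unif))
  kern <- pk_u$kernel[pk_u$kernel$kappa > 0 & pk_u$kernel$k <= 20, ]
  slope_u <- unname(stats::coef(stats::lm(log(kappa) ~ log(k), kern))[2])
  expect_gt(slope_u, 0.7)
  expect_lt(slope_u, 1.3)
  ba <- generate_ba(1000, 2, seed = 2)
  pk_b <- cumulative_pa(ba, arrival_order(ba))
  kb <- pk_b$kernel[pk_b$kernel$kappa > 0 & pk_b$kernel$k <= 30, ]
  slope_b <- unname(stats::coef(stats::lm(log(kappa) ~ log(k), kb))[2])
  expect_gt(slope_b, 1.1)
})

test_that("restored-order kernel tracks truth more closely than random", {
  ba <- generate_ba(400, 2, seed = 3)
  res <- restore_network(ba, dim = 8, train_fraction = 0.05, seed = 3,
                         n_test_pairs = 2000, epochs = 80, max_pairs = 6000)
  kap <- function(ord) {
    k <- cumulative_pa(ba, ord)$kernel
    k$kappa[match(1:10, k$k)]
  }
  k_true <- kap(arrival_order(ba))
  k_rest <- kap(res$sequence$positions)
  set.seed(4)
  k_rand <- kap(sample(n_edges(ba)))
  ok <- stats::complete.cases(cbind(k_true, k_rest, k_rand))
  expect_lt(max(abs(k_rest - k_true)[ok]), max(abs(k_rand - k_true)[ok]))
})

test_that("structural metrics match hand enumeration on small graphs", {
  tri <- triangle_network()
  t_cl <- structural_trajectory(tri, 1:3, "clustering", checkpoints = 3,
                                baselines = character(0))
  expect_equal(t_cl$trajectory$restored, 1)
  p4 <- path_network(4)
  t_sp <- structural_trajectory(p4, 1:3, "shortest_path", checkpoints = 3,
                                baselines = character(0))
  expect_equal(t_sp$trajectory$restored, 10 / 6)
  st <- star_network(5)
  t_as <- structural_trajectory(st, 1:5, "assortativity", checkpoints = 5,
                                baselines = character(0))
  expect_lt(t_as$trajectory$restored, 0)
  expect_error(structural_trajectory(tri, 1:3, "bogus"), "should be one of")
})

test_that("all metrics are ordering-invariant at the final checkpoint", {
  net <- generate_pso(80, 2, seed = 5)
  E <- n_edges(net)
  set.seed(6)
  shuffled <- sample(E)
  for (metric in c("modularity", "assortativity", "clustering",
                   "shortest_path")) {
    a <- structural_trajectory(net, seq_len(E), metric, checkpoints = E,
                               baselines = character(0))$trajectory$restored
    b <- structural_trajectory(net, shuffled, metric, checkpoints = E,
                               baselines = character(0))$trajectory$restored
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("meso-level adjacency counts edges between labelled communities", {
  net <- sbm_network(n_per_block = 20, n_edge = 80, p_within = 0.9, seed = 7)
  mats <- meso_adjacency(net, arrival_order(net), checkpoints = c(20, 50, 80))
  for (k in seq_along(mats)) {
    M <- mats[[k]]
    cp <- c(20, 50, 80)[k]
    expect_equal(sum(M[upper.tri(M)]) + sum(diag(M)), cp)
    expect_equal(M, t(M))
    expect_gt(sum(diag(M)), sum(M[upper.tri(M)]))   # within-block bias
  }
  one <- temporal_network(rbind(c("a", "b"), c("b", "c")),
                          node_labels = c(a = "X", b = "X", c = "X"))
  m1 <- meso_adjacency(one, 1:2, checkpoints = 2)[[1]]
  expect_equal(unname(m1["X", "X"]), 2)
  bad <- temporal_network(rbind(c("a", "b")), node_labels = c(a = "X"))
  expect_error(meso_adjacency(bad, 1, 1), "unlabeled node.*b")
})

test_that("modularity trajectories separate cliques from a single clique", {
  cl2 <- utils::combn(4, 2)
  edges <- rbind(cbind(paste0("p", cl2[1, ]), paste0("p", cl2[2, ])),
                 cbind(paste0("q", cl2[1, ]), paste0("q", cl2[2, ])))
  two <- temporal_network(edges)
  tr <- structural_trajectory(two, 1:12, "modularity", checkpoints = 12,
                              baselines = character(0))
  expect_equal(tr$trajectory$restored, 0.5, tolerance = 1e-9)
  one <- temporal_network(cbind(paste0("p", cl2[1, ]), paste0("p", cl2[2, ])))
  tr1 <- structural_trajectory(one, 1:6, "modularity", checkpoints = 6,
                               baselines = character(0))
  expect_equal(tr1$trajectory$restored, 0, tolerance = 1e-9)
})

test_that("true-order modularity beats the pure-PA null on planted blocks", {
  wins <- sum(vapply(1:10, function(s) {
    net <- sbm_network(n_per_block = 20, n_edge = 100, p_within = 0.95,
                       seed = 50 + s)
    tr <- modularity_trajectory(net, arrival_order(net),
                                checkpoints = n_edges(net), seed = s)
    tr$trajectory$restored >= tr$trajectory$pure_pa
  }, TRUE))
  expect_gte(wins, 8)
})

test_that("collapsed tensor weights decay geometrically with age", {
  net <- path_network(5)
  X <- collapsed_tensor(net, 1:4, theta = 0.5)
  expect_equal(unname(X$X["4", "5"]), 1)          # newest edge
  expect_equal(unname(X$X["1", "2"]), 0.5^3)      # oldest edge
  expect_equal(X$X, t(X$X))
  Xb <- collapsed_tensor(net, 1:4, theta = 1, allow_binary = TRUE)
  A <- netchrono:::dense_adjacency(net)
  expect_equal(unname(Xb$X), A)
  expect_error(collapsed_tensor(net, 1:4, theta = 1), "theta")
  expect_error(collapsed_tensor(net, 1:4, theta = 0), "theta")
})

test_that("truncated SVD reconstructs and ranks planted structure", {
  net <- generate_ba(40, 2, seed = 8)
  Xb <- collapsed_tensor(net, arrival_order(net), theta = 1,
                         allow_binary = TRUE)
  sc_full <- tsvd_link_scores(Xb, r = 40)
  expect_equal(sc_full$scores, Xb$X, tolerance = 1e-8)
  expect_equal(sc_full$scores, t(sc_full$scores), tolerance = 1e-8)
  expect_error(tsvd_link_scores(Xb, 41), "out of range")
  # rank-1 planted bipartite block: top candidates lie inside the block
  nodes <- paste0("n", 1:12)
  block_edges <- rbind(c("n1", "n4"), c("n1", "n5"), c("n2", "n4"),
                       c("n2", "n6"), c("n3", "n5"), c("n3", "n6"),
                       c("n7", "n8"), c("n9", "n10"))
  bn <- temporal_network(block_edges, nodes = nodes)
  Xp <- collapsed_tensor(bn, arrival_order(bn), theta = 1,
                         allow_binary = TRUE)
  sc <- tsvd_link_scores(Xp, r = 2)
  top <- utils::head(sc$candidates, 3)
  expect_true(all(top$u %in% c("n1", "n2", "n3", "n4", "n5", "n6") &
                    top$v %in% c("n1", "n2", "n3", "n4", "n5", "n6")))
})

test_that("hits@r counts held-out edges among top candidates", {
  net <- generate_ba(30, 2, seed = 9)
  sc <- tsvd_link_scores(collapsed_tensor(net, arrival_order(net), 0.9), 8)
  expect_equal(hits_at_r(sc, net$edges[1:3, ], 0), 0L)
  held <- as.matrix(utils::head(sc$candidates, 5)[, c("u", "v")])
  expect_equal(hits_at_r(sc, held, 5), 5L)
  expect_equal(hits_at_r(sc, held, nrow(sc$candidates)), 5L)
  hv <- vapply(c(1, 5, 20, 100), function(r) hits_at_r(sc, held, r), 0L)
  expect_true(all(diff(hv) >= 0))
  expect_error(hits_at_r(sc, held, -1), "non-negative")
})

test_that("random scores give hypergeometric hit counts on average", {
  n_cand <- 500; K <- 20; r <- 50
  hits <- vapply(1:300, function(s) {
    set.seed(s)
    held <- sample(n_cand, K)
    sum(order(stats::runif(n_cand), decreasing = TRUE)[1:r] %in% held)
  }, 0)
  expect_equal(mean(hits), r * K / n_cand, tolerance = 0.15)
})
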