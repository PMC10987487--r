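test_that("training pairs cover exactly the distinguishable pairs", {
  net <- coarsen_to_snapshots(path_network(4), 2)   # snapshots (1, 1, 2)
  p <- make_training_pairs(net, 1, seed = 1)
  expect_equal(nrow(p), 2L)
  keys <- paste(pmin(p$a, p$b), pmax(p$a, p$b))
  expect_setequal(keys, c("1 3", "2 3"))
  # label says "first edge newer"; edge 3 is the newer one in every pair
  expect_equal(p$label, as.integer(p$a == 3))
  net1 <- coarsen_to_snapshots(path_network(4), 1)
  expect_error(make_training_pairs(net1, 1, seed = 1), "no edge pairs")
})

test_that("pair sampling yields the exact requested count and balance", {
  net <- generate_ba(334, 3, seed = 2)
  E <- n_edges(net)
  p <- make_training_pairs(net, 0.05, seed = 3)
  expect_equal(nrow(p), floor(0.05 * E * (E - 1) / 2))
  expect_true(all(p$a != p$b))
  expect_true(all(p$label == as.integer(p$a > p$b)))  # later edge is newer
  expect_gt(mean(p$label), 0.4)
  expect_lt(mean(p$label), 0.6)
})

test_that("comparators are antisymmetric and learn separable pairs", {
  set.seed(1)
  E <- 120
  X <- cbind(stats::rnorm(E), seq_len(E) / E + stats::rnorm(E, sd = 0.01),
             stats::rnorm(E))
  net_age <- seq_len(E)
  ij <- t(utils::combn(E, 2))
  take <- sample(nrow(ij), 500)
  pairs <- data.frame(a = ij[take, 2], b = ij[take, 1], label = 1L)
  flip <- seq_len(250)
  pairs[flip, c("a", "b")] <- pairs[flip, c("b", "a")]
  pairs$label[flip] <- 0L
  cmp <- train_comparator(X, pairs, seed = 4, hidden = 8, epochs = 300)
  held <- data.frame(a = ij[-take, 2][1:400], b = ij[-take, 1][1:400],
                     label = 1L)
  p_held <- comparator_prob(cmp, X[held$a, ], X[held$b, ])
  expect_gt(mean(p_held > 0.5), 0.95)
  p_ab <- comparator_prob(cmp, X[1:20, ], X[21:40, ])
  p_ba <- comparator_prob(cmp, X[21:40, ], X[1:20, ])
  expect_equal(p_ab + p_ba, rep(1, 20), tolerance = 1e-12)
  expect_equal(comparator_prob(cmp, X[5:8, ], X[5:8, ]), rep(0.5, 4))
  expect_error(train_comparator(X, pairs[pairs$label == 1, ], seed = 1),
               "degenerate")
})

test_that("best-feature selection maximizes the larger-is-newer rule", {
  set.seed(2)
  E <- 80
  raw <- matrix(stats::rnorm(E * 11), E, 11)
  raw[, 3] <- seq_len(E)                 # perfectly orders the edges
  ij <- t(utils::combn(E, 2))
  pairs <- data.frame(a = ij[, 2], b = ij[, 1], label = 1L)
  bf <- select_best_feature(raw, pairs)
  expect_equal(bf$index, 3L)
  expect_equal(bf$accuracy, 1)
  # equal values predict "not newer"
  const <- matrix(1, E, 2)
  bfc <- select_best_feature(const, pairs)
  expect_equal(bfc$accuracies, c(0, 0))
  expect_equal(bfc$index, 1L)            # tie broken to lowest index
  # random features sit near chance, ties go to the lowest index
  accs <- replicate(20, {
    set.seed(sample.int(1e6, 1))
    select_best_feature(matrix(stats::rnorm(E * 11), E, 11), pairs)$accuracies
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("grid search finds simplex weights favouring a perfect component", {
  set.seed(3)
  n <- 400
  labels <- rep(0:1, each = n / 2)
  # one perfect low-margin component among six saturated coin-flip ones:
  # any weight on the noise flips some decisions, so the optimum is pure
  O <- matrix(round(stats::runif(n * 7)), n, 7)
  O[, 4] <- ifelse(labels == 1, 0.55, 0.45)
  gs <- fit_ensemble_weights(O, labels)
  expect_equal(sum(gs$weights), 1)
  expect_true(all(gs$weights >= 0))
  expect_gte(gs$weights[4], 0.9)
  expect_equal(gs$accuracy, 1)
  # independent exhaustive-grid oracle must agree exactly
  oracle_best <- NULL; oracle_acc <- -1
  comp <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(k)
      cbind(k, comp(total - k, parts - 1))))
  }
  G <- comp(10L, 7L) / 10
  for (r in seq_len(nrow(G))) {
    p <- drop(O %*% G[r, ])
    acc <- mean((p > 0.5) == (labels == 1) & p != 0.5)
    if (acc > oracle_acc + 1e-12) { oracle_acc <- acc; oracle_best <- G[r, ] }
  }
  expect_equal(gs$weights, unname(oracle_best))
  expect_equal(gs$accuracy, oracle_acc)
  # identical components: deterministic lexicographic-first optimum
  Oid <- matrix(rep(ifelse(labels == 1, 0.8, 0.2), 7), n, 7)
  g1 <- fit_ensemble_weights(Oid, labels)
  g2 <- fit_ensemble_weights(Oid, labels)
  expect_identical(g1$weights, g2$weights)
  expect_error(fit_ensemble_weights(O[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("ensemble prediction is the weighted component average", {
  net <- generate_ba(60, 2, seed = 7)
  views <- build_edge_views(net, dim = 8, seed = 7)
  fit <- fit_order_model(net, views = views, train_fraction = 0.4, seed = 7,
                         n_test_pairs = 500, epochs = 60, max_pairs = 2000)
  m <- fit$model
  a <- c(1, 5, 9); b <- c(2, 6, 10)
  O <- ensemble_components(m, views, a, b)
  expect_equal(ensemble_predict(m, views, a, b), drop(O %*% m$weights))
  m1 <- m; m1$weights <- c(1, rep(0, 6))
  expect_equal(ensemble_predict(m1, views, a, b),
               comparator_prob(m$comparators[[1]],
                               views$views[[1]][a, ], views$views[[1]][b, ]))
  expect_true(all(ensemble_predict(m, views, a, b) >= 0 &
                    ensemble_predict(m, views, a, b) <= 1))
})

test_that("Borda counts follow the pairwise decisions exactly", {
  D <- matrix(FALSE, 3, 3)
  D[2, 1] <- TRUE; D[3, 1] <- TRUE; D[3, 2] <- TRUE
  expect_equal(borda_counts(D), c(0L, 1L, 2L))
  # flipping the (1, 3) decision produces a complete tie
  Df <- D; Df[3, 1] <- FALSE; Df[1, 3] <- TRUE
  expect_equal(borda_counts(Df), c(1L, 1L, 1L))
  for (s in 1:5) {
    E <- sample(4:12, 1)
    Dr <- random_orientation(E, seed = s)
    expect_equal(sum(borda_counts(Dr)), E * (E - 1) / 2)
  }
  Dbad <- D; Dbad[2, 1] <- FALSE
  expect_error(borda_counts(Dbad), "missing")
  Dconf <- D; Dconf[1, 2] <- TRUE
  expect_error(borda_counts(Dconf), "conflict")
})

test_that("sequence restoration ranks Borda counts with stable ties", {
  expect_equal(restore_sequence(c(0, 1, 2))$positions, 1:3)
  expect_equal(restore_sequence(c(1, 1, 1))$positions, 1:3)
  set.seed(8)
  u <- sample(0:20, 50, replace = TRUE)
  r <- restore_sequence(u)
  ord <- order(u, seq_along(u))
  expected <- integer(50)
  expected[ord] <- seq_len(50)
  expect_equal(r$positions, expected)
})

test_that("thresholded all-pair decisions form a complete orientation", {
  net <- generate_ba(50, 2, seed = 9)
  fit <- fit_order_model(net, dim = 8, train_fraction = 0.3, seed = 9,
                         n_test_pairs = 300, epochs = 60, max_pairs = 1500)
  u <- netchrono:::all_pairs_borda(fit$model, fit$views)
  E <- n_edges(net)
  expect_equal(sum(u), E * (E - 1) / 2)
  expect_true(all(u >= 0 & u <= E - 1))
  seqr <- restore_sequence(u)
  expect_setequal(seqr$positions, seq_len(E))
})
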