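#' Pairwise order model: comparators, ensemble, Borda aggregation
#'
#' The relative age of two edges is predicted by an ensemble of seven
#' components: six comparative classifiers (one per edge view) and a
#' best-feature rule. Each comparative classifier is a shared-trunk
#' scoring network: both edge vectors pass through the same small
#' one-hidden-layer scorer `f`, and the output is
#' `o(i, j) = sigmoid(f(e_i) - f(e_j))`, the probability that edge `i` is
#' younger (arrived later) than edge `j`. This construction is
#' antisymmetric by design (`o(i, j) + o(j, i) = 1`, `o(i, i) = 0.5`) and
#' its pairwise decisions are transitive, since they are comparisons of a
#' scalar score. The final ensemble output is the weighted average
#' `o_final = sum_l w_l o_l` with simplex weights found by grid search.
#' Thresholding `o_final` at 0.5 over all pairs and counting, for each
#' edge, how many other edges it is judged younger than gives its Borda
#' count; ranking Borda counts ascending restores the arrival sequence.
#'
#' @name ordermodel
NULL

#' Sample labelled training pairs from known history
#'
#' Only edge pairs whose order is distinguishable are eligible: all pairs
#' when the fine arrival order is known, pairs from different snapshots
#' otherwise. Each sampled pair is given a random orientation, so labels
#' are class-balanced by construction; `label = 1` means the first edge of
#' the pair is the newer one.
#'
#' @param net a [temporal_network] with fine arrival order and/or
#'   snapshot labels.
#' @param fraction fraction of distinguishable pairs to sample (0, 1].
#' @param seed integer.
#' @param max_pairs optional cap on the number of sampled pairs.
#' @return data.frame with columns `a`, `b` (edge indices) and `label`
#'   (1 if `a` newer than `b`); attribute `n_distinguishable`.
#' @export
make_training_pairs <- function(net, fraction, seed, max_pairs = Inf) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  E <- n_edges(net)
  ndist <- n_distinguishable_pairs(net)
  if (ndist == 0) stop("no edge pairs with distinguishable order")
  n_take <- min(floor(fraction * ndist), max_pairs)
  if (n_take < 1) stop("requested fraction yields zero pairs")
  set.seed(seed)
  total <- E * (E - 1) / 2
  snap <- net$snapshot
  if (total <= 3e6) {
    # enumerate all pairs, filter to distinguishable, sample exactly
    pi_ <- rep(seq_len(E - 1), times = (E - 1):1)
    pj_ <- sequence((E - 1):1) + pi_
    if (!is.null(snap)) {
      ok <- snap[pi_] != snap[pj_]
      pi_ <- pi_[ok]; pj_ <- pj_[ok]
    }
    take <- sample.int(length(pi_), n_take)
    i <- pi_[take]; j <- pj_[take]
  } else {
    collected_i <- integer(0); collected_j <- integer(0)
    # rejection-sample uniform distinguishable pairs without materialising all
    while (length(collected_i) < n_take) {
      need <- n_take - length(collected_i)
      draw <- ceiling(need * max(1.5, 1.5 * total / ndist))
      t_idx <- sample(total, min(draw, total), replace = TRUE)
      ij <- decode_pair_index(t_idx, E)
      if (!is.null(snap)) {
        ok <- snap[ij$i] != snap[ij$j]
        ij$i <- ij$i[ok]; ij$j <- ij$j[ok]
      }
      key <- (ij$i - 1) * E + ij$j
      keep <- !duplicated(key) &
        !(key %in% ((collected_i - 1) * E + collected_j))
      collected_i <- c(collected_i, ij$i[keep])
      collected_j <- c(collected_j, ij$j[keep])
    }
    i <- collected_i[seq_len(n_take)]
    j <- collected_j[seq_len(n_take)]
  }
  # i < j along arrival order, so j is the newer edge
  flip <- stats::runif(n_take) < 0.5
  out <- data.frame(a = ifelse(flip, j, i), b = ifelse(flip, i, j),
                    label = as.integer(flip))
  attr(out, "n_distinguishable") <- ndist
  out
}

# Decode linear index over unordered pairs (i < j, ordered by i then j).
decode_pair_index <- function(t, E) {
  tw <- 2 * E - 1
  i <- ceiling((tw - sqrt(tw^2 - 8 * t)) / 2)
  # guard rounding at block boundaries
  Fi <- i * E - i * (i + 1) / 2
  Fprev <- (i - 1) * E - (i - 1) * i / 2
  over <- t > Fi
  i[over] <- i[over] + 1
  under <- t <= Fprev
  i[under] <- i[under] - 1
  Fprev <- (i - 1) * E - (i - 1) * i / 2
  j <- t - Fprev + i
  list(i = as.integer(i), j = as.integer(j))
}

#' Train a comparative pairwise classifier on one edge view
#'
#' Fits the shared scorer `f(e) = v' tanh(W e + b)` by full-batch Adam on
#' the logistic pairwise loss of `sigmoid(f(e_a) - f(e_b))` against the
#' pair labels. Inputs are z-scored with statistics stored in the
#' comparator so new edges (or transferred ones) are scaled identically.
#'
#' @param X numeric matrix of edge vectors for this view (edges x dim).
#' @param pairs labelled pair data.frame from [make_training_pairs].
#' @param seed integer.
#' @param hidden hidden width of the scorer (default 16).
#' @param epochs full-batch Adam steps (default 300).
#' @param lr learning rate (default 0.02).
#' @return a `cpnn_comparator` object.
#' @export
train_comparator <- function(X, pairs, seed, hidden = 16L, epochs = 300L,
                             lr = 0.02) {
  if (nrow(pairs) < 2) stop("need at least two labelled pairs")
  y <- pairs$label
  if (length(unique(y)) < 2) stop("degenerate labels: all pairs one class")
  if (any(!is.finite(X))) stop("edge vectors must be finite")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  d <- ncol(Z)
  set.seed(seed)
  W <- matrix(stats::rnorm(hidden * d, sd = 1 / sqrt(d)), hidden, d)
  b <- numeric(hidden)
  v <- stats::rnorm(hidden, sd = 1 / sqrt(hidden))
  Za <- Z[pairs$a, , drop = FALSE]
  Zb <- Z[pairs$b, , drop = FALSE]
  n <- nrow(Za)
  mW <- vW <- matrix(0, hidden, d); mb <- vb <- numeric(hidden)
  mv <- vv <- numeric(hidden)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    Ha <- tanh(Za %*% t(W) + rep(b, each = n))
    Hb <- tanh(Zb %*% t(W) + rep(b, each = n))
    p <- stats::plogis(drop((Ha - Hb) %*% v))
    g <- (p - y) / n
    gv <- drop(crossprod(Ha - Hb, g))
    Ga <- (g * (1 - Ha^2)) %*% diag(v, hidden)
    Gb <- (g * (1 - Hb^2)) %*% diag(v, hidden)
    gW <- t(Ga) %*% Za - t(Gb) %*% Zb
    gb <- colSums(Ga) - colSums(Gb)
    mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
    mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
    mv <- b1 * mv + (1 - b1) * gv; vv <- b2 * vv + (1 - b2) * gv^2
    corr <- sqrt(1 - b2^t) / (1 - b1^t)
    W <- W - lr * corr * mW / (sqrt(vW) + eps)
    b <- b - lr * corr * mb / (sqrt(vb) + eps)
    v <- v - lr * corr * mv / (sqrt(vv) + eps)
  }
  structure(list(W = W, b = b, v = v, center = mu, scale = sdv,
                 hidden = hidden, seed = seed),
            class = "cpnn_comparator")
}

#' Scalar scores of a comparator on a matrix of edge vectors
#' @param cmp a `cpnn_comparator`.
#' @param X edge-vector matrix on the comparator's view.
#' @return numeric score vector `f(e)`; `sigmoid(f(e_i) - f(e_j))` is the
#'   probability that edge `i` is newer than edge `j`.
#' @export
comparator_score <- function(cmp, X) {
  Z <- sweep(sweep(X, 2, cmp$center, "-"), 2, cmp$scale, "/")
  unname(drop(tanh(Z %*% t(cmp$W) + rep(cmp$b, each = nrow(Z))) %*% cmp$v))
}

#' Pairwise probability that edge a is newer than edge b
#' @param cmp a `cpnn_comparator`.
#' @param Xa,Xb matrices of edge vectors (same number of rows).
#' @return vector of probabilities in \[0, 1\].
#' @export
comparator_prob <- function(cmp, Xa, Xb) {
  stats::plogis(comparator_score(cmp, Xa) - comparator_score(cmp, Xb))
}

#' Select the best single classical feature
#'
#' Evaluates, for each of the eleven classical features, the training
#' accuracy of the fixed rule "the edge with the larger feature value is
#' the newer one" (equal values predict "not newer"), and returns the
#' index of the most accurate feature; ties go to the lowest index.
#'
#' @param classical_raw unstandardised classical feature matrix
#'   (edges x 11).
#' @param pairs labelled pair data.frame.
#' @return list with `index`, `accuracy` and per-feature `accuracies`.
#' @export
select_best_feature <- function(classical_raw, pairs) {
  if (nrow(pairs) == 0) stop("`pairs` is empty")
  acc <- vapply(seq_len(ncol(classical_raw)), function(k) {
    pred <- classical_raw[pairs$a, k] > classical_raw[pairs$b, k]
    mean(pred == (pairs$label == 1))
  }, 0)
  best <- which.max(acc)
  list(index = best, accuracy = acc[best], accuracies = acc)
}

simplex_grid <- function(parts, total = 10L) {
  if (parts == 1L) return(matrix(total, 1, 1))
  out <- vector("list", total + 1L)
  for (k in 0:total) {
    rest <- simplex_grid(parts - 1L, total - k)
    out[[k + 1L]] <- cbind(k, rest)
  }
  do.call(rbind, out)
}

#' Fit the ensemble weights by exhaustive simplex grid search
#'
#' Searches all weight vectors on the 7-simplex with step 0.1 and returns
#' the first (lexicographically, largest weight on component 1 first) that
#' maximises validation pairwise accuracy; exact-0.5 ensemble outputs
#' count as incorrect.
#'
#' @param O matrix of component outputs on validation pairs (pairs x 7).
#' @param labels validation labels (1 = first edge newer).
#' @param step grid step (default 0.1).
#' @return list with `weights` (length 7, summing to 1) and `accuracy`.
#' @export
fit_ensemble_weights <- function(O, labels, step = 0.1) {
  if (nrow(O) == 0) stop("empty validation set")
  total <- round(1 / step)
  G <- simplex_grid(ncol(O), total) / total
  best_acc <- -1; best_row <- 1L
  y1 <- labels == 1
  for (start in seq(1, nrow(G), by = 500)) {
    rows <- start:min(start + 499, nrow(G))
    P <- G[rows, , drop = FALSE] %*% t(O)
    correct <- (P > 0.5) == matrix(y1, nrow(P), ncol(P), byrow = TRUE) &
      (P != 0.5)
    acc <- rowMeans(correct)
    k <- which.max(acc)
    if (acc[k] > best_acc + 1e-12) {
      best_acc <- acc[k]; best_row <- rows[k]
    }
  }
  list(weights = unname(G[best_row, ]), accuracy = best_acc)
}

#' Component outputs of the ensemble on a set of edge pairs
#'
#' @param model a `pairwise_order_model`.
#' @param views an `edge_view_set` on the same network the pairs index.
#' @param a,b vectors of edge indices (the pair is "is `a` newer than `b`").
#' @return matrix (pairs x 7) of component outputs `o^1..o^7`.
#' @export
ensemble_components <- function(model, views, a, b) {
  O <- matrix(0, length(a), 7)
  for (l in 1:6) {
    s <- comparator_score(model$comparators[[l]], views$views[[l]])
    O[, l] <- stats::plogis(s[a] - s[b])
  }
  f <- views$classical_raw[, model$best_feature]
  O[, 7] <- as.numeric(f[a] > f[b])
  O
}

#' Ensemble probability that edge i is newer than edge j
#'
#' Weighted average of the seven component outputs (the ensemble rule).
#'
#' @inheritParams ensemble_components
#' @param i,j edge indices (vectors of equal length).
#' @return probabilities in \[0, 1\].
#' @export
ensemble_predict <- function(model, views, i, j) {
  if (is.null(model$weights)) stop("model has no trained ensemble weights")
  drop(ensemble_components(model, views, i, j) %*% model$weights)
}

#' Pairwise accuracy of the ensemble on labelled test pairs
#'
#' Fraction of pairs whose relative age is predicted correctly;
#' predictions at exactly 0.5 count as incorrect.
#'
#' @inheritParams ensemble_components
#' @param pairs labelled pair data.frame.
#' @return accuracy in \[0, 1\].
#' @export
pairwise_accuracy <- function(model, views, pairs) {
  if (nrow(pairs) == 0) stop("empty test set")
  p <- ensemble_predict(model, views, pairs$a, pairs$b)
  mean(((p > 0.5) == (pairs$label == 1)) & (p != 0.5))
}

#' Borda counts from a complete pairwise decision matrix
#'
#' @param decisions E x E logical matrix; `decisions[i, j]` is TRUE when
#'   edge `i` is judged newer than edge `j`. Exactly one of
#'   `decisions[i, j]`, `decisions[j, i]` must be TRUE for every pair.
#' @return integer vector `u` of Borda counts, `u_i` in `[0, E-1]`.
#' @export
borda_counts <- function(decisions) {
  E <- nrow(decisions)
  if (E != ncol(decisions)) stop("`decisions` must be square")
  if (any(diag(decisions))) stop("self-comparisons must be FALSE")
  off <- decisions | t(decisions)
  diag(off) <- TRUE
  if (!all(off)) stop("missing pair decision")
  if (any(decisions & t(decisions))) stop("conflicting pair decision")
  as.integer(rowSums(decisions))
}

#' Restore the arrival sequence from Borda counts
#'
#' Edges are ranked by Borda count ascending (oldest first); ties are
#' broken by stable input edge order.
#'
#' @param u Borda counts, one per edge.
#' @param source optional provenance string.
#' @return a `restored_sequence`: list with `positions` (the permutation
#'   `alpha_hat`), `borda` (`u`) and `source`.
#' @export
restore_sequence <- function(u, source = "borda") {
  positions <- rank(u, ties.method = "first")
  structure(list(positions = as.integer(positions), borda = u,
                 source = source),
            class = "restored_sequence")
}

#' @export
print.restored_sequence <- function(x, ...) {
  cat("<restored_sequence> ", length(x$positions), " edges, source: ",
      x$source, "\n", sep = "")
  invisible(x)
}

# All-pairs thresholded decisions -> Borda counts, computed per component
# score vector so the E x E probability matrix is built only once.
# Exact-0.5 ensemble ties are broken toward the later-indexed edge.
all_pairs_borda <- function(model, views) {
  E <- nrow(views$views[[1]])
  Ofin <- matrix(0, E, E)
  for (l in 1:6) {
    if (model$weights[l] == 0) next
    s <- comparator_score(model$comparators[[l]], views$views[[l]])
    Ofin <- Ofin + model$weights[l] * stats::plogis(outer(s, s, "-"))
  }
  if (model$weights[7] > 0) {
    f <- views$classical_raw[, model$best_feature]
    Ofin <- Ofin + model$weights[7] * outer(f, f, ">")
  }
  up <- upper.tri(Ofin)
  D <- matrix(FALSE, E, E)
  D[up] <- Ofin[up] > 0.5          # i newer than j for i < j
  D <- D | (t(!D) & lower.tri(D))  # mirror: exactly one decision per pair
  diag(D) <- FALSE
  as.integer(rowSums(D))
}

#' Train the full pairwise order model on a network
#'
#' End-to-end training: samples labelled pairs from the known history,
#' splits them into training and validation parts, trains the six
#' comparators, selects the best classical feature, fits the ensemble
#' weights by grid search, and measures held-out pairwise accuracy on a
#' disjoint sample of test pairs.
#'
#' @param net a [temporal_network] with (partial) history.
#' @param views optional precomputed [build_edge_views] result.
#' @param dim embedding dimension when `views` is NULL.
#' @param train_fraction fraction of distinguishable pairs used for
#'   training (default 0.05).
#' @param seed integer.
#' @param max_pairs cap on training pairs (default 25000).
#' @param val_fraction fraction of the training pairs held out for the
#'   weight grid search (default 0.2).
#' @param n_test_pairs size of the disjoint test-pair sample.
#' @param hidden,epochs comparator hyperparameters.
#' @return an `order_model_fit`: `model` (`pairwise_order_model`), `views`,
#'   `net`, `test_accuracy`, `val_accuracy`, `component_val_accuracy`.
#' @export
fit_order_model <- function(net, views = NULL, dim = 64,
                            train_fraction = 0.05, seed = 1,
                            max_pairs = 25000, val_fraction = 0.2,
                            n_test_pairs = 20000, hidden = 16L,
                            epochs = 300L) {
  if (is.null(views)) views <- build_edge_views(net, dim = dim, seed = seed)
  pairs <- make_training_pairs(net, train_fraction, offset_seed(seed, 11),
                               max_pairs = max_pairs)
  set.seed(offset_seed(seed, 12))
  n <- nrow(pairs)
  val_idx <- sample.int(n, max(1L, floor(val_fraction * n)))
  train <- pairs[-val_idx, , drop = FALSE]
  val <- pairs[val_idx, , drop = FALSE]
  comparators <- lapply(1:6, function(l)
    train_comparator(views$views[[l]], train, offset_seed(seed, 20 + l),
                     hidden = hidden, epochs = epochs))
  bf <- select_best_feature(views$classical_raw, train)
  model <- structure(
    list(comparators = comparators, best_feature = bf$index,
         weights = NULL, feature_names = views$feature_names,
         dim = views$dim, seed = seed,
         training_meta = list(train_fraction = train_fraction,
                              n_train = nrow(train), n_val = nrow(val),
                              best_feature_accuracy = bf$accuracy)),
    class = "pairwise_order_model")
  Oval <- ensemble_components(model, views, val$a, val$b)
  gs <- fit_ensemble_weights(Oval, val$label)
  model$weights <- gs$weights
  comp_acc <- vapply(1:7, function(l)
    mean(((Oval[, l] > 0.5) == (val$label == 1)) & (Oval[, l] != 0.5)), 0)
  test <- sample_eval_pairs(net, n_test_pairs, offset_seed(seed, 13),
                            exclude = pairs)
  acc <- pairwise_accuracy(model, views, test)
  structure(list(model = model, views = views, net = net,
                 test_accuracy = acc, val_accuracy = gs$accuracy,
                 component_val_accuracy = comp_acc),
            class = "order_model_fit")
}

#' @export
print.order_model_fit <- function(x, ...) {
  cat("<order_model_fit> dim =", x$model$dim,
      " best feature:", x$model$feature_names[x$model$best_feature], "\n")
  cat("  weights:", paste(sprintf("%.1f", x$model$weights), collapse = " "), "\n")
  cat("  held-out pairwise accuracy:", sprintf("%.3f", x$test_accuracy), "\n")
  invisible(x)
}

# Uniform labelled evaluation pairs (distinguishable order), optionally
# disjoint from a previously sampled set.
sample_eval_pairs <- function(net, n, seed, exclude = NULL) {
  ndist <- n_distinguishable_pairs(net)
  frac <- min(1, n / ndist)
  p <- make_training_pairs(net, frac, seed)
  if (!is.null(exclude)) {
    E <- n_edges(net)
    key <- function(d) (pmin(d$a, d$b) - 1) * E + pmax(d$a, d$b)
    p <- p[!(key(p) %in% key(exclude)), , drop = FALSE]
  }
  p
}

#' Restore a network's edge arrival sequence end-to-end
#'
#' Trains the order model (unless given one), predicts all pairwise
#' orders, aggregates them by Borda count, and evaluates the restored
#' sequence against the fine ground truth when available.
#'
#' @inheritParams fit_order_model
#' @param fit optional existing `order_model_fit` for this network.
#' @param ... passed to [fit_order_model].
#' @return list with `fit`, `sequence` (a `restored_sequence`) and
#'   `report` (an `error_report`, or NULL without fine ground truth).
#' @export
restore_network <- function(net, fit = NULL, ...) {
  if (is.null(fit)) fit <- fit_order_model(net, ...)
  u <- all_pairs_borda(fit$model, fit$views)
  seq_ <- restore_sequence(u, source = sprintf("ensemble(seed=%d)",
                                               fit$model$seed))
  report <- overall_error(arrival_order(net), seq_$positions)
  list(fit = fit, sequence = seq_, report = report)
}
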