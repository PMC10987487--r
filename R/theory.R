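#' Error metric and closed-form accuracy-error theory
#'
#' The restored sequence is scored by the displacement of every edge,
#' `D_i = alpha_i - alpha_hat_i`, summarised as the root-mean-squared
#' displacement normalised by the edge count:
#' `E_err = sqrt(mean((D_i / E)^2))`. A mean-field argument links this
#' error to the pairwise accuracy `x` of the comparator ensemble:
#' corrupting each pair decision independently at accuracy `x` makes the
#' Borda count of edge `i` an unbiased estimate of its position with
#' variance `x(1-x) / (E (2x-1)^2)`, so the expected sequence error is
#' `sqrt(x(1-x)) / (2x-1) / sqrt(E)` - valid well above the singular
#' accuracy 0.5, concretely for `x > 0.5 + 1/(4 sqrt(E))`.
#'
#' @name theory
NULL

#' Overall error report for a restored sequence
#'
#' @param truth integer permutation of `1:E`; true arrival positions.
#' @param restored integer permutation of `1:E`; restored positions.
#' @return an `error_report`: `displacements` (`D_i`), `overall_error`,
#'   `kendall_tau`, `spearman_rho`, and `E`.
#' @examples
#' overall_error(1:10, 10:1)$overall_error
#' @export
overall_error <- function(truth, restored) {
  E <- length(truth)
  if (length(restored) != E) stop("sequence length mismatch")
  if (!setequal(truth, seq_len(E)) || anyDuplicated(truth))
    stop("`truth` is not a permutation of 1..E")
  if (!setequal(restored, seq_len(E)) || anyDuplicated(restored))
    stop("`restored` is not a permutation of 1..E")
  D <- truth - restored
  structure(
    list(displacements = D,
         overall_error = sqrt(mean((D / E)^2)),
         kendall_tau = stats::cor(truth, restored, method = "kendall"),
         spearman_rho = stats::cor(truth, restored, method = "spearman"),
         E = E),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> E = %d, error = %.4g, tau = %.3f, rho = %.3f\n",
              x$E, x$overall_error, x$kendall_tau, x$spearman_rho))
  invisible(x)
}

#' Closed-form expected sequence error at pairwise accuracy x
#'
#' @param x pairwise accuracy, must exceed the validity bound
#'   `0.5 + 1 / (4 sqrt(E))` (the formula diverges at `x = 0.5`).
#' @param E number of edges.
#' @return expected overall error (positive scalar, decreasing in both
#'   arguments).
#' @examples
#' theoretical_error(0.8, 1000)
#' @export
theoretical_error <- function(x, E) {
  bound <- 0.5 + 1 / (4 * sqrt(E))
  if (any(x <= bound))
    stop("accuracy x must exceed the validity bound 0.5 + 1/(4 sqrt(E)) = ",
         signif(bound, 4))
  if (any(x > 1)) stop("accuracy cannot exceed 1")
  sqrt(x * (1 - x)) / (2 * x - 1) / sqrt(E)
}

# One corrupted-ranking repetition: exactly floor(|S| x) pairs keep the
# correct order, the rest are flipped; Borda-rank the result.
corrupt_and_rank <- function(E, x) {
  S <- E * (E - 1) / 2
  n_wrong <- S - floor(S * x)
  u <- 0:(E - 1)                       # all-correct Borda counts
  if (n_wrong > 0) {
    wrong <- sample(S, n_wrong)
    ij <- decode_pair_index(wrong, E)
    # flipping pair (i < j) moves one count from j to i
    u <- u - tabulate(ij$j, nbins = E) + tabulate(ij$i, nbins = E)
  }
  rank(u, ties.method = "first")
}

#' Corrupted-ranking simulation of the accuracy-error relationship
#'
#' For each repetition, assigns the correct relative order to exactly
#' `floor(x * E(E-1)/2)` uniformly chosen edge pairs and the wrong order
#' to the rest, aggregates by Borda count, and records the displacements
#' of the restored sequence against the ground truth `1:E`.
#'
#' @param E number of edges (at least 2).
#' @param x pairwise accuracy in (0.5, 1].
#' @param R repetitions.
#' @param seed integer.
#' @return list with `displacements` (R x E matrix), `errors` (per-rep
#'   overall error), `mean_error`, `positions` (R x E matrix of restored
#'   positions), `E`, `x`.
#' @export
simulate_corrupted_ranking <- function(E, x, R, seed) {
  if (E < 2) stop("`E` must be at least 2")
  if (R < 1) stop("`R` must be at least 1")
  if (x <= 0 || x > 1) stop("`x` must be in (0, 1]")
  set.seed(seed)
  D <- matrix(0L, R, E)
  P <- matrix(0L, R, E)
  for (r in seq_len(R)) {
    ah <- corrupt_and_rank(E, x)
    P[r, ] <- ah
    D[r, ] <- seq_len(E) - ah
  }
  errs <- sqrt(rowMeans((D / E)^2))
  list(displacements = D, errors = errs, mean_error = mean(errs),
       positions = P, E = E, x = x)
}

# Draw an intermediate fine-grained sequence compatible with the given
# snapshot block sizes: positions are shuffled uniformly within each block.
draw_intermediate <- function(sizes) {
  offs <- cumsum(c(0, sizes[-length(sizes)]))
  unlist(lapply(seq_along(sizes), function(k) offs[k] + sample(sizes[k])))
}

#' Displacements of a restoration against coarse-grained ground truth
#'
#' When only snapshot labels are known, the displacement of an edge is
#' computed against an intermediate sequence that assigns random
#' fine-grained order within each snapshot; pooling over many such
#' intermediates accounts for the within-snapshot uncertainty.
#'
#' @param net a [temporal_network] with snapshot labels.
#' @param restored a `restored_sequence` (or an integer permutation) for
#'   the same edges.
#' @param R number of intermediate sequences to pool (default 200).
#' @param seed integer.
#' @return list with `displacements` (R x E matrix of
#'   `alpha_star - alpha_hat`), `sizes` (snapshot sizes) and `E`.
#' @export
displacement_vs_coarse_truth <- function(net, restored, R = 200, seed = 1) {
  if (is.null(net$snapshot)) stop("network has no snapshot labels")
  ah <- if (inherits(restored, "restored_sequence")) restored$positions
        else as.integer(restored)
  E <- n_edges(net)
  if (length(ah) != E || !setequal(ah, seq_len(E)))
    stop("`restored` must be a permutation of 1..E")
  sizes <- tabulate(net$snapshot)
  sizes <- sizes[sizes > 0]
  set.seed(seed)
  D <- matrix(0L, R, E)
  for (r in seq_len(R)) D[r, ] <- draw_intermediate(sizes) - ah
  list(displacements = D, sizes = sizes, E = E)
}

#' Corrupted-ranking simulation under coarse-grained ground truth
#'
#' Mirrors [displacement_vs_coarse_truth] for a fully synthetic setting:
#' each repetition draws an intermediate within-snapshot order, corrupts
#' the pairwise orders of the underlying fine sequence at accuracy `x`,
#' Borda-ranks them, and records `alpha_star - alpha_hat`.
#'
#' @param sizes snapshot sizes `l_1..l_n` (positive integers).
#' @param x pairwise accuracy in (0.5, 1].
#' @param R repetitions.
#' @param seed integer.
#' @return list with `displacements` (R x E), `sizes`, `E`, `x`.
#' @export
displacement_sim_coarse <- function(sizes, x, R, seed) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("snapshot sizes must be positive")
  if (x <= 0 || x > 1) stop("`x` must be in (0, 1]")
  E <- sum(sizes)
  set.seed(seed)
  D <- matrix(0L, R, E)
  for (r in seq_len(R)) {
    astar <- draw_intermediate(sizes)
    ah <- corrupt_and_rank(E, x)
    D[r, ] <- astar - ah
  }
  list(displacements = D, sizes = sizes, E = E, x = x)
}
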