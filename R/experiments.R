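#' Cross-network transfer experiment
#'
#' Repeats, for several seeds: generate a source network with full
#' ground-truth arrival order, train the comparator ensemble on it,
#' generate a target network of a (possibly different) growth model,
#' and evaluate the source model on the target both after least-squares
#' embedding alignment (transfer, `x^T`) and on raw target
#' representations (direct validation, `x^D`). One target embedding run
#' is shared between the two evaluations.
#'
#' @param source_model,target_model growth model names
#'   (`"ba"`, `"pso"`, `"fitness"`).
#' @param n_source,n_target node counts.
#' @param m edges per new node (default 2).
#' @param n_reps number of repetitions (seeds).
#' @param seed base seed; repetition `r` uses sub-seeds derived from it.
#' @param dim embedding dimension (default 64).
#' @param train_fraction fraction of pairs used for training (default
#'   0.05).
#' @param n_eval_pairs held-out pairs per evaluation (default 20000).
#' @param source_fits optional list of pre-trained `order_model_fit`s
#'   (one per repetition) to reuse across several targets.
#' @param ... further arguments to [fit_order_model].
#' @return a `transfer_experiment`: data.frame `runs` with columns
#'   `seed`, `x_transfer`, `x_direct`, `x_source`; means `x_transfer`,
#'   `x_direct`; and `source_fits` for reuse.
#' @export
transfer_experiment <- function(source_model, target_model,
                                n_source, n_target, m = 2,
                                n_reps = 3, seed = 1, dim = 64,
                                train_fraction = 0.05,
                                n_eval_pairs = 20000,
                                source_fits = NULL, ...) {
  runs <- data.frame(seed = integer(0), x_transfer = numeric(0),
                     x_direct = numeric(0), x_source = numeric(0))
  fits <- if (is.null(source_fits)) vector("list", n_reps) else source_fits
  for (r in seq_len(n_reps)) {
    s <- offset_seed(seed, 1000 * r)
    if (is.null(fits[[r]])) {
      src <- generate_network(source_model, n_source, m, s)
      fits[[r]] <- fit_order_model(src, dim = dim,
                                   train_fraction = train_fraction,
                                   seed = s, ...)
    }
    tgt <- generate_network(target_model, n_target, m, offset_seed(s, 1))
    tviews <- build_edge_views(tgt, dim = dim, seed = offset_seed(s, 2))
    tr <- transfer_restore(tgt, fits[[r]], seed = offset_seed(s, 3),
                           target_views = tviews,
                           n_eval_pairs = n_eval_pairs, restore = FALSE)
    dv <- direct_validate(tgt, fits[[r]], seed = offset_seed(s, 3),
                          target_views = tviews,
                          n_eval_pairs = n_eval_pairs)
    runs[r, ] <- list(s, tr$accuracy, dv$accuracy, fits[[r]]$test_accuracy)
  }
  structure(list(runs = runs,
                 x_transfer = mean(runs$x_transfer),
                 x_direct = mean(runs$x_direct),
                 source_model = source_model, target_model = target_model,
                 source_fits = fits),
            class = "transfer_experiment")
}

#' @export
print.transfer_experiment <- function(x, ...) {
  cat(sprintf("<transfer_experiment> %s -> %s over %d runs\n",
              x$source_model, x$target_model, nrow(x$runs)))
  cat(sprintf("  x^T = %.3f, x^D = %.3f\n", x$x_transfer, x$x_direct))
  invisible(x)
}
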