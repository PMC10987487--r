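#' Transfer a trained order model to a history-less network
#'
#' A model trained on network A can order the edges of a structurally
#' similar network B that has no history at all. Nodes of the two
#' networks are put in correspondence by degree quantiles (sorted by
#' degree descending), and for each embedding view a linear map `L`
#' minimising `||H_B L - H_A||` in the least-squares sense
#' (`L = (H_B' H_B)^{-1} H_B' H_A`) carries B's node vectors into A's
#' latent space before the Hadamard edge vectors are formed. The
#' classical-feature view is topology-intrinsic and is only
#' re-standardised on B. Direct validation - feeding B's raw
#' representations into A's model with no alignment - is the baseline the
#' transfer is compared against.
#'
#' @name transfer
NULL

#' Degree-quantile node correspondence between two networks
#'
#' Sorts the nodes of both networks by degree descending (ties broken by
#' node id, so re-runs are stable); when the node counts differ, rank `r`
#' of the smaller network is matched to rank `floor(r * N_large /
#' N_small)` of the larger one.
#'
#' @param netA,netB two [temporal_network]s (source and target).
#' @return data.frame with columns `source` and `target` (node ids),
#'   `min(N_A, N_B)` rows.
#' @export
correspond_nodes_by_degree <- function(netA, netB) {
  if (length(netA$nodes) == 0 || length(netB$nodes) == 0)
    stop("cannot correspond an empty network")
  rank_nodes <- function(net) {
    deg <- tabulate(match(as.vector(net$edges), net$nodes),
                    nbins = length(net$nodes))
    net$nodes[order(-deg, net$nodes)]
  }
  sa <- rank_nodes(netA)
  sb <- rank_nodes(netB)
  na <- length(sa); nb <- length(sb)
  n <- min(na, nb)
  r <- seq_len(n)
  if (na >= nb) {
    data.frame(source = sa[pmin(na, floor(r * na / nb))], target = sb[r],
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = sa[r], target = sb[pmin(nb, floor(r * nb / na))],
               stringsAsFactors = FALSE)
  }
}

#' Least-squares alignment of two matched embedding matrices
#'
#' Solves `min_L ||H_B L - H_A||_F` via the normal equations
#' `L = (H_B' H_B)^{-1} H_B' H_A`; when `H_B` is column-rank deficient the
#' minimum-norm solution via the pseudo-inverse is used and flagged.
#'
#' @param H_B target-network embedding rows (matched node order).
#' @param H_A source-network embedding rows (same row count).
#' @return an `alignment_map`: `L`, `residual` (Frobenius norm of
#'   `H_B L - H_A`) and `pseudo_inverse` flag.
#' @export
align_embeddings <- function(H_B, H_A) {
  if (nrow(H_B) != nrow(H_A)) stop("matched matrices must have equal rows")
  G <- crossprod(H_B)
  pseudo <- FALSE
  L <- tryCatch(solve(G, crossprod(H_B, H_A)), error = function(e) NULL)
  if (is.null(L)) {
    pseudo <- TRUE
    sv <- svd(H_B)
    pos <- sv$d > max(dim(H_B)) * .Machine$double.eps * sv$d[1]
    dinv <- ifelse(pos, 1 / sv$d, 0)
    L <- sv$v %*% (dinv * crossprod(sv$u, H_A))
  }
  structure(list(L = L, residual = norm(H_B %*% L - H_A, "F"),
                 pseudo_inverse = pseudo),
            class = "alignment_map")
}

# Build target-network edge views in the source model's latent spaces:
# each embedding view is linearly aligned through its own L; the
# classical-feature view is recomputed and standardised on the target.
aligned_target_views <- function(netB, source_fit, target_views) {
  corr <- correspond_nodes_by_degree(source_fit$net, netB)
  i <- match(netB$edges[, 1], netB$nodes)
  j <- match(netB$edges[, 2], netB$nodes)
  views <- vector("list", 6)
  maps <- vector("list", 5)
  for (l in 1:5) {
    Ha <- source_fit$views$node_embeddings[[l]]$vectors
    Hb <- target_views$node_embeddings[[l]]$vectors
    am <- align_embeddings(Hb[corr$target, , drop = FALSE],
                           Ha[corr$source, , drop = FALSE])
    maps[[l]] <- am
    Zb <- Hb %*% am$L
    views[[l]] <- Zb[i, , drop = FALSE] * Zb[j, , drop = FALSE]
  }
  views[[6]] <- target_views$views$classical
  out <- target_views
  out$views <- views
  names(out$views) <- names(target_views$views)
  out$alignments <- maps
  out
}

#' Restore a target network with a source-trained model (transfer)
#'
#' Embeds the target with the same methods, dimension and seed scheme as
#' the source, aligns every embedding view through its least-squares map,
#' then applies the source-trained ensemble and Borda aggregation. When
#' the target has ground truth, held-out pairwise accuracy `x^T` is
#' reported.
#'
#' @param netB target [temporal_network].
#' @param source_fit an `order_model_fit` trained on the source network.
#' @param seed integer (target embedding and evaluation-pair sampling).
#' @param target_views optional precomputed [build_edge_views] for `netB`
#'   (lets transfer and direct validation share one embedding run).
#' @param n_eval_pairs evaluation pairs to sample (default 20000).
#' @param restore if TRUE (default) also Borda-restore the full sequence.
#' @return list with `accuracy` (`x^T`), `sequence`, `report`,
#'   `alignments` and `views` (the aligned view set).
#' @export
transfer_restore <- function(netB, source_fit, seed = 1,
                             target_views = NULL, n_eval_pairs = 20000,
                             restore = TRUE) {
  if (is.null(source_fit$model$weights)) stop("source model is untrained")
  if (is.null(target_views))
    target_views <- build_edge_views(netB, dim = source_fit$views$dim,
                                     seed = seed)
  av <- aligned_target_views(netB, source_fit, target_views)
  pairs <- sample_eval_pairs(netB, n_eval_pairs, offset_seed(seed, 31))
  acc <- pairwise_accuracy(source_fit$model, av, pairs)
  seq_ <- NULL; report <- NULL
  if (restore) {
    u <- all_pairs_borda(source_fit$model, av)
    seq_ <- restore_sequence(u, source = "transfer")
    report <- overall_error(arrival_order(netB), seq_$positions)
  }
  list(accuracy = acc, sequence = seq_, report = report,
       alignments = av$alignments, views = av)
}

#' Direct validation: apply a source model to a target without alignment
#'
#' @inheritParams transfer_restore
#' @return list with `accuracy` (`x^D`) and the raw target `views`.
#' @export
direct_validate <- function(netB, source_fit, seed = 1,
                            target_views = NULL, n_eval_pairs = 20000) {
  if (is.null(source_fit$model$weights)) stop("source model is untrained")
  if (is.null(target_views))
    target_views <- build_edge_views(netB, dim = source_fit$views$dim,
                                     seed = seed)
  pairs <- sample_eval_pairs(netB, n_eval_pairs, offset_seed(seed, 31))
  acc <- pairwise_accuracy(source_fit$model, target_views, pairs)
  list(accuracy = acc, views = target_views)
}
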