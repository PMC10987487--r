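# netchrono

Networks are usually observed once, as a final snapshot; the order in
which their edges appeared is lost. `netchrono` reconstructs that
growth history — the permutation α giving each edge's arrival
position — from the final topology, optionally helped by a few coarse
snapshots, and uses the restored sequence for growth-mechanism analysis
and link prediction. It is aimed at researchers studying the evolution
of biological (e.g. protein–protein interaction), ecological and social
networks.

## Method in brief

1. **Edge views.** Every edge gets six vector representations: Hadamard
   products of endpoint node embeddings from five methods (DeepWalk,
   node2vec, LINE, SDNE, struct2vec-style structural profiles) plus a
   vector of eleven classical link features.
2. **Pairwise comparator ensemble.** For each view, a comparative
   classifier with a shared scorer f outputs
   o(i, j) = σ(f(eᵢ) − f(eⱼ)), the probability that edge *i* is younger
   than edge *j* — antisymmetric by construction. A seventh component is
   the best single classical feature under the rule "larger ⇒ newer".
   The ensemble is the weighted average o^final = Σₗ wₗ oˡ with simplex
   weights from exhaustive grid search (step 0.1). Training pairs come
   only from distinguishable history (different snapshots, or fine
   order).
3. **Borda aggregation.** Thresholding o^final at 0.5 over all pairs
   gives each edge a Borda count uᵢ = #{j : i judged newer than j};
   ranking uᵢ ascending restores the arrival sequence α̂.
4. **Error theory.** With displacements Dᵢ = αᵢ − α̂ᵢ and
   𝓔 = sqrt(mean((Dᵢ/E)²)), corrupting pair decisions at accuracy x
   gives the closed form 𝓔 = sqrt(x(1−x)) / (2x−1) / sqrt(E) — so for
   large networks, slightly-better-than-random pairwise accuracy already
   recovers the global sequence. Monte-Carlo corruption routines verify
   the formula and handle coarse-grained ground truth.
5. **Transfer.** A model trained on network A orders a history-less
   network B after degree-quantile node correspondence and a
   least-squares linear map L = (H_B'H_B)⁻¹H_B'H_A aligns B's embedding
   spaces with A's.
6. **Analyses.** Cumulative preferential-attachment kernel κ(k),
   modularity/assortativity/clustering/shortest-path growth
   trajectories against random and pure-PA nulls, meso-level labelled
   adjacency evolution, and temporally-weighted truncated-SVD link
   prediction with hits@r.

Synthetic generators (Barabási–Albert, Bianconi–Barabási fitness,
popularity–similarity optimisation) provide networks with exact
ground-truth arrival order for calibration and testing.

## Worked example

```r
library(netchrono)

net <- generate_ba(300, 2, seed = 1)          # 597 edges, known order
res <- restore_network(net, dim = 32, train_fraction = 0.05, seed = 1,
                       n_test_pairs = 5000, epochs = 200,
                       max_pairs = 10000)

res$fit$test_accuracy
#> [1] 0.9457983
res$report
#> <error_report> E = 597, error = 0.05089, tau = 0.892, rho = 0.984
theoretical_error(res$fit$test_accuracy, n_edges(net))
#> [1] 0.01039322
```

Reading: with 5% of edge pairs used for training, the ensemble orders
held-out edge pairs correctly 94.6% of the time; the fully restored
sequence deviates from the true arrival order by a normalised RMSE of
0.051 (Spearman ρ = 0.98 against ground truth). The closed form gives
the error an idealised independent-corruption model would reach at that
accuracy; the gap reflects the spatial correlation of real model
errors.

```r
# transfer a model trained on a fitness network to a BA network
src <- generate_fitness(500, 2, seed = 1)
fit <- fit_order_model(src, dim = 64, seed = 1)
tgt <- generate_ba(500, 2, seed = 2)
transfer_restore(tgt, fit, seed = 3)$accuracy   # x^T on held-out pairs
direct_validate(tgt, fit, seed = 3)$accuracy    # x^D, no alignment
```

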