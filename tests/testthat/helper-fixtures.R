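# Small graph fixtures built in code.

path_network <- function(n) {
  temporal_network(cbind(as.character(seq_len(n - 1)),
                         as.character(seq_len(n - 1) + 1)))
}

triangle_network <- function() {
  temporal_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
}

star_network <- function(n_leaves) {
  temporal_network(cbind("hub", paste0("leaf", seq_len(n_leaves))))
}

# Two-block planted-partition graph grown edge by edge: each new edge picks
# a block (within with probability p_in), then two distinct members.
sbm_network <- function(n_per_block = 30, n_edge = 120, p_within = 0.9,
                        seed = 1) {
  set.seed(seed)
  blocks <- list(paste0("a", seq_len(n_per_block)),
                 paste0("b", seq_len(n_per_block)))
  seen <- character(0)
  from <- character(0); to <- character(0)
  while (length(from) < n_edge) {
    if (stats::runif(1) < p_within) {
      b <- sample(1:2, 1)
      pair <- sample(blocks[[b]], 2)
    } else {
      pair <- c(sample(blocks[[1]], 1), sample(blocks[[2]], 1))
    }
    k <- paste(sort(pair), collapse = "\t")
    if (k %in% seen) next
    seen <- c(seen, k)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  labels <- c(rep("A", n_per_block), rep("B", n_per_block))
  names(labels) <- c(blocks[[1]], blocks[[2]])
  temporal_network(cbind(from, to), nodes = names(labels),
                   node_labels = labels)
}

# Uniform-attachment growth (no preferential attachment): each new node
# links to one uniformly chosen existing node.
uniform_attach_network <- function(n, seed = 1) {
  set.seed(seed)
  from <- as.character(2:n)
  to <- vapply(2:n, function(t) as.character(sample.int(t - 1L, 1L)), "")
  temporal_network(cbind(from, to), nodes = as.character(seq_len(n)))
}

# Independent Borda oracle: explicit double-loop count and stable
# insertion ranking (no shared code with the package internals).
borda_oracle <- function(decisions) {
  E <- nrow(decisions)
  u <- integer(E)
  for (i in seq_len(E)) for (j in seq_len(E))
    if (i != j && decisions[i, j]) u[i] <- u[i] + 1L
  # stable ascending rank
  ord <- order(u, seq_len(E))
  pos <- integer(E)
  pos[ord] <- seq_len(E)
  list(u = u, positions = pos)
}

random_orientation <- function(E, seed) {
  set.seed(seed)
  D <- matrix(FALSE, E, E)
  for (i in seq_len(E - 1)) for (j in (i + 1):E) {
    if (stats::runif(1) < 0.5) D[i, j] <- TRUE else D[j, i] <- TRUE
  }
  D
}
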