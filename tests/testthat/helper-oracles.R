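# Independent brute-force oracles for the structural measures. These are
# deliberately naive (dense matrices, exhaustive triple enumeration) and
# share no code with the package implementations they check.

oracle_adjacency <- function(g) {
  n <- n_nodes(g)
  A <- matrix(0, n, n)
  if (n_edges(g) > 0) {
    A[cbind(g$from, g$to)] <- 1
    A[cbind(g$to, g$from)] <- 1
  }
  A
}

# exhaustive enumeration of all node triples
oracle_triangle_counts <- function(g) {
  n <- n_nodes(g)
  A <- oracle_adjacency(g)
  counts <- integer(n)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          if (A[i, j] && A[i, k] && A[j, k]) {
            counts[i] <- counts[i] + 1L
            counts[j] <- counts[j] + 1L
            counts[k] <- counts[k] + 1L
          }
        }
      }
    }
  }
  stats::setNames(counts, g$nodes)
}

oracle_local_clustering <- function(g) {
  A <- oracle_adjacency(g)
  deg <- rowSums(A)
  tri <- oracle_triangle_counts(g)
  ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
}

# dense power iteration, dangling nodes teleport uniformly
oracle_pagerank <- function(g, damping = 0.85, iters = 2000L) {
  n <- n_nodes(g)
  A <- oracle_adjacency(g)
  deg <- rowSums(A)
  M <- matrix(1 / n, n, n) # dangling columns
  for (i in seq_len(n)) {
    if (deg[i] > 0) M[, i] <- A[i, ] / deg[i]
  }
  x <- rep(1 / n, n)
  for (it in seq_len(iters)) {
    x <- (1 - damping) / n + damping * as.numeric(M %*% x)
  }
  stats::setNames(x, g$nodes)
}

# small random graph built straight from uniform draws over node pairs
# (independent of the package's Erdos-Renyi sampler)
rand_small_graph <- function(n, p) {
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) edges <- rbind(edges, c(i, j))
    }
  }
  kgraph(edges, nodes = as.character(seq_len(n)))
}

# complete graph on n labelled nodes
complete_graph <- function(n) {
  pr <- t(utils::combn(n, 2))
  kgraph(cbind(as.character(pr[, 1]), as.character(pr[, 2])),
    nodes = as.character(seq_len(n))
  )
}
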