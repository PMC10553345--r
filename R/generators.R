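#' Random-graph models
#'
#' The four classical generators used as artificial knowledge networks:
#' Barabasi-Albert preferential attachment, the two Erdos-Renyi variants
#' G(n, p) and G(n, m), and the random d-regular graph. The G(n, p),
#' G(n, m) and regular samplers delegate to igraph; the BA variant is a
#' direct implementation of a construction in which the seed node
#' `v[e+1]` is linked to `v[1]..v[e]` and every later node attaches `e`
#' distinct edges chosen with degree-proportional probability (duplicate
#' proposals are redrawn), so that `|E| = e * (n - e)` exactly.
#'
#' @param n number of nodes.
#' @param e number of attachment edges per incoming node (`1 <= e < n`).
#' @param p independent edge probability in `[0, 1]`.
#' @param m exact number of edges (`0 <= m <= choose(n, 2)`).
#' @param d regular degree (`3 <= d < n`, `n * d` even).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a [kgraph] on nodes `"1"..."n"`.
#' @examples
#' ba_graph(200, 20, seed = 1) # 3600 edges
#' er_gnp(281, 0.0611, seed = 1) # worm-matched null draw
#' @export
ba_graph <- function(n, e, seed = NULL) {
  n <- as.integer(n)
  e <- as.integer(e)
  if (e < 1L || e >= n) {
    stop_parameter("Barabasi-Albert needs 1 <= e < n")
  }
  with_seed(seed, {
    cap <- 2L * e * (n - e) # final degree sum
    stubs <- integer(cap) # node i appears deg(i) times: uniform draws
    n_stubs <- 0L # from `stubs` are degree-proportional
    add_edge_stubs <- function(u, v) {
      stubs[n_stubs + 1L] <<- u
      stubs[n_stubs + 2L] <<- v
      n_stubs <<- n_stubs + 2L
    }
    from <- integer(e * (n - e))
    to <- integer(e * (n - e))
    k <- 0L
    for (i in seq_len(e)) { # seed star: v[e+1] -- v[1]..v[e]
      k <- k + 1L
      from[k] <- i
      to[k] <- e + 1L
      add_edge_stubs(i, e + 1L)
    }
    if (n > e + 1L) {
      for (v in (e + 2L):n) {
        chosen <- integer(0)
        while (length(chosen) < e) {
          need <- e - length(chosen)
          cand <- stubs[sample.int(n_stubs, 2L * need + 2L, replace = TRUE)]
          chosen <- unique(c(chosen, cand))
          if (length(chosen) > e) chosen <- chosen[seq_len(e)]
        }
        for (u in chosen) {
          k <- k + 1L
          from[k] <- u
          to[k] <- v
          add_edge_stubs(u, v)
        }
      }
    }
    canonical_kgraph(as.character(seq_len(n)), from, to)
  })
}

#' @rdname ba_graph
#' @export
er_gnp <- function(n, p, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop_parameter("G(n,p) needs n >= 1")
  if (p < 0 || p > 1) stop_parameter("edge probability p must be in [0, 1]")
  with_seed(seed, as_kgraph(igraph::sample_gnp(n, p)))
}

#' @rdname ba_graph
#' @export
er_gnm <- function(n, m, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop_parameter("G(n,m) needs n >= 1")
  if (m < 0 || m > choose(n, 2)) {
    stop_parameter("G(n,m) needs 0 <= m <= choose(n, 2)")
  }
  with_seed(seed, as_kgraph(igraph::sample_gnm(n, m)))
}

#' @rdname ba_graph
#' @export
random_regular <- function(n, d, seed = NULL) {
  n <- as.integer(n)
  d <- as.integer(d)
  if (d < 3L || d >= n) stop_parameter("regular graph needs 3 <= d < n")
  if ((as.numeric(n) * d) %% 2 != 0) {
    stop_parameter("regular graph needs n * d even")
  }
  with_seed(seed, as_kgraph(igraph::sample_k_regular(n, d)))
}

#' Grow a random-graph model and profile each stage
#'
#' Regenerates the chosen model at increasing size `n_k = k * step_nodes`
#' for `k = 1..iterations` with fixed parameters, computes the
#' four-measure profile of each draw, and averages over `reps`
#' independent repetitions per stage. Defaults follow the growth
#' experiment conditions: 20 iterations of 200 nodes (4,000 final nodes),
#' 20 repetitions, `p = 0.015` and `e = d = 20`. G(n, m) keeps a fixed
#' per-node edge budget (`m_k = m_per_node * n_k`) so its average degree
#' stays static during expansion, as does the regular model.
#'
#' @param model one of `"gnp"`, `"gnm"`, `"regular"`, `"ba"`.
#' @param iterations number of growth stages (>= 1).
#' @param step_nodes nodes added per stage (>= 1).
#' @param reps independent draws averaged per stage (>= 1).
#' @param p G(n, p) edge probability.
#' @param e BA attachment edges per node.
#' @param m_per_node G(n, m) edges per node (`m_k = m_per_node * n_k`).
#' @param d regular degree.
#' @param seed integer seed for the whole experiment.
#' @return a `trajectory` data.frame with columns `iteration`, `n`,
#'   `avg_degree`, `avg_pagerank`, `avg_clustering`, `avg_triangles`.
#' @export
growth_experiment <- function(model = c("gnp", "gnm", "regular", "ba"),
                              iterations = 20L, step_nodes = 200L,
                              reps = 20L, p = 0.015, e = 20L,
                              m_per_node = 20L, d = 20L, seed = NULL) {
  model <- match.arg(model)
  iterations <- as.integer(iterations)
  step_nodes <- as.integer(step_nodes)
  reps <- as.integer(reps)
  if (iterations < 1L || step_nodes < 1L || reps < 1L) {
    stop_parameter("iterations, step_nodes and reps must all be >= 1")
  }
  with_seed(seed, {
    rows <- vector("list", iterations)
    for (k in seq_len(iterations)) {
      n_k <- k * step_nodes
      mvs <- matrix(0, nrow = reps, ncol = 4L)
      for (r in seq_len(reps)) {
        g <- switch(model,
          gnp = er_gnp(n_k, p),
          gnm = er_gnm(n_k, m_per_node * n_k),
          regular = random_regular(n_k, d),
          ba = ba_graph(n_k, e)
        )
        mvs[r, ] <- measure_vector(g)
      }
      avg <- colMeans(mvs)
      rows[[k]] <- data.frame(
        iteration = k, n = n_k,
        avg_degree = avg[1L], avg_pagerank = avg[2L],
        avg_clustering = avg[3L], avg_triangles = avg[4L]
      )
    }
    traj <- do.call(rbind, rows)
    rownames(traj) <- NULL
    class(traj) <- c("trajectory", "data.frame")
    traj
  })
}
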