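#' Average degree
#'
#' The first of the four structural measures: `2|E| / |V|`, the number of
#' edge endpoints per node. Isolated nodes count towards `|V|`.
#'
#' @param g a [kgraph].
#' @return a single non-negative number.
#' @export
average_degree <- function(g) {
  if (n_nodes(g) == 0L) stop_empty_graph("average degree")
  2 * n_edges(g) / n_nodes(g)
}

#' PageRank of every node
#'
#' Standard damped PageRank by power iteration on the (symmetrized)
#' adjacency structure: each node spreads its current mass equally over
#' its neighbours; a fraction `1 - damping` of the total mass teleports
#' uniformly, and the mass held by degree-0 nodes is redistributed
#' uniformly as well. On an undirected graph in- and out-neighbourhoods
#' coincide and out-degree is the node degree.
#'
#' @param g a [kgraph].
#' @param damping damping factor in `[0, 1)`; 0.85 is the classical value.
#' @param tol convergence tolerance on the L1 change per iteration.
#' @param max_iter iteration cap; hitting it raises a warning and the
#'   result is flagged via `attr(, "converged")`.
#' @return named numeric vector of masses summing to 1, with attributes
#'   `converged` (logical) and `iterations` (integer).
#' @export
pagerank_vector <- function(g, damping = 0.85, tol = 1e-10, max_iter = 200L) {
  n <- n_nodes(g)
  if (n == 0L) stop_empty_graph("PageRank")
  deg <- tabulate(c(g$from, g$to), nbins = n)
  x <- rep.int(1 / n, n)
  if (n_edges(g) == 0L || damping == 0) {
    # all mass teleports/dangles: uniform fixed point, reached immediately
    x <- rep.int(1 / n, n)
    names(x) <- g$nodes
    attr(x, "converged") <- TRUE
    attr(x, "iterations") <- 0L
    return(x)
  }
  adj <- Matrix::sparseMatrix(
    i = c(g$from, g$to), j = c(g$to, g$from),
    x = 1, dims = c(n, n)
  )
  dangling <- deg == 0L
  inv_deg <- ifelse(dangling, 0, 1 / deg)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    spread <- as.numeric(adj %*% (x * inv_deg))
    x_new <- (1 - damping) / n + damping * (spread + sum(x[dangling]) / n)
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "PageRank did not converge within %d iterations (last L1 change %.3g)",
      max_iter, delta
    ))
  }
  names(x) <- g$nodes
  attr(x, "converged") <- converged
  attr(x, "iterations") <- iter
  x
}

#' Average PageRank
#'
#' Mean PageRank mass per node. Because the masses are normalized to sum
#' to one, this equals `1 / |V|` for every graph; it is retained as a
#' measure because it tracks network size on a probability scale and is
#' computed, not assumed, here.
#'
#' @inheritParams pagerank_vector
#' @return a single mass in `(0, 1]`.
#' @export
average_pagerank <- function(g, damping = 0.85, tol = 1e-10, max_iter = 200L) {
  mean(pagerank_vector(g, damping = damping, tol = tol, max_iter = max_iter))
}

#' Per-node triangle membership
#'
#' Number of unordered node triples forming 3-cycles that each node is a
#' member of.
#'
#' @param g a [kgraph].
#' @return named integer vector over all nodes.
#' @export
node_triangle_counts <- function(g) {
  n <- n_nodes(g)
  counts <- if (n == 0L) {
    integer(0)
  } else {
    count_triangles_cpp(n, g$from, g$to)
  }
  names(counts) <- g$nodes
  counts
}

#' Average triangles
#'
#' Mean per-node triangle membership over all nodes, i.e. `3T / |V|` for
#' `T` distinct triangles (each triangle has three member nodes). Read as
#' an approximate ratio of network completeness: how much of the graph is
#' built from the smallest possible cliques.
#'
#' @param g a [kgraph].
#' @return a single non-negative number.
#' @export
average_triangles <- function(g) {
  if (n_nodes(g) == 0L) stop_empty_graph("average triangles")
  mean(node_triangle_counts(g))
}

#' Local clustering coefficient
#'
#' `2 Tri(v) / (deg(v) (deg(v) - 1))`: the fraction of a node's neighbour
#' pairs that are themselves connected. Nodes of degree < 2 have no
#' neighbour pair and are assigned 0 (and still count in the average).
#'
#' @param g a [kgraph].
#' @param v a node id present in `g`.
#' @return `node_clustering()`: one ratio in `[0, 1]`;
#'   `local_clustering()`: the named vector over all nodes.
#' @export
node_clustering <- function(g, v) {
  idx <- match(as.character(v), g$nodes)
  if (is.na(idx)) stop_parameter(sprintf("node '%s' is not in the graph", v))
  local_clustering(g)[[idx]]
}

#' @rdname node_clustering
#' @export
local_clustering <- function(g) {
  deg <- tabulate(c(g$from, g$to), nbins = n_nodes(g))
  tri <- node_triangle_counts(g)
  cc <- ifelse(deg < 2L, 0, 2 * as.numeric(tri) / (deg * (deg - 1)))
  names(cc) <- g$nodes
  cc
}

#' Average clustering coefficient
#'
#' Mean local clustering over all nodes (degree < 2 nodes contribute 0).
#'
#' @param g a [kgraph].
#' @return a ratio in `[0, 1]`.
#' @export
average_clustering <- function(g) {
  if (n_nodes(g) == 0L) stop_empty_graph("average clustering")
  mean(local_clustering(g))
}

#' Edge-completion ratio
#'
#' The fraction of realized unordered node pairs,
#' `p = 2|E| / (|V| (|V| - 1))`. This is the density matched when an
#' Erdos-Renyi null model is generated for a real network.
#'
#' @param g a [kgraph] with at least 2 nodes.
#' @return a ratio in `[0, 1]`.
#' @export
edge_probability <- function(g) {
  n <- n_nodes(g)
  if (n < 2L) stop_parameter("edge probability needs at least 2 nodes")
  2 * n_edges(g) / (n * (n - 1))
}

#' The four-measure structural profile
#'
#' Bundles average degree, average PageRank, average clustering and
#' average triangles into one named vector — the unit of comparison used
#' for every system in the package.
#'
#' @param g a [kgraph] with at least one node.
#' @return a named numeric vector of class `measure_vector` with entries
#'   `avg_degree`, `avg_pagerank`, `avg_clustering`, `avg_triangles`.
#' @examples
#' g <- er_gnp(50, 0.2, seed = 1)
#' measure_vector(g)
#' @export
measure_vector <- function(g) {
  if (n_nodes(g) == 0L) stop_empty_graph("the measure profile")
  structure(
    c(
      avg_degree = average_degree(g),
      avg_pagerank = average_pagerank(g),
      avg_clustering = average_clustering(g),
      avg_triangles = average_triangles(g)
    ),
    class = c("measure_vector", "numeric")
  )
}

#' @export
print.measure_vector <- function(x, digits = 4, ...) {
  cat("<measure_vector>\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Write a measure profile as JSON
#'
#' @param mv a `measure_vector` (or any named numeric vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
measure_report <- function(mv, path) {
  jsonlite::write_json(as.list(unclass(mv)), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
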