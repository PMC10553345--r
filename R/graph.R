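#' Simple undirected graph
#'
#' `kgraph()` builds the package's common graph currency: a simple,
#' undirected, unweighted graph stored as a node vector plus a canonical
#' edge list. Every analysis stage (neural-activation subgraphs, topic
#' co-occurrence networks, random models, connectomes) is reduced to this
#' type before the structural measures are applied. Directed or repeated
#' input edges are symmetrized and deduplicated; self-loops are dropped.
#'
#' @param edges a two-column matrix or data.frame of edge endpoints
#'   (coerced to character node ids), or `NULL` for an edgeless graph.
#' @param nodes optional character vector of node ids; must contain every
#'   edge endpoint, and may add isolated nodes (which always count towards
#'   `|V|` in the averages).
#' @return an object of class `kgraph`: a list with elements `nodes`
#'   (character), `from` and `to` (integer indices into `nodes`, with
#'   `from < to` and each unordered pair stored once).
#' @examples
#' g <- kgraph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' n_edges(g) # triangle
#' @export
kgraph <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) {
      stop_parameter("`edges` must have exactly two columns")
    }
    storage.mode(edges) <- "character"
  }
  if (is.null(nodes)) {
    nodes <- if (is.null(edges)) character(0) else sort(unique(as.vector(edges)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop_parameter("duplicate node ids in `nodes`")
    if (!is.null(edges) && !all(edges %in% nodes)) {
      stop_parameter("edge endpoints must all appear in `nodes`")
    }
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    return(new_kgraph(nodes, integer(0), integer(0)))
  }
  i <- match(edges[, 1L], nodes)
  j <- match(edges[, 2L], nodes)
  canonical_kgraph(nodes, i, j)
}

# Fast path: endpoints already canonical (from < to, unique, no loops).
new_kgraph <- function(nodes, from, to) {
  structure(
    list(nodes = nodes, from = as.integer(from), to = as.integer(to)),
    class = "kgraph"
  )
}

# Symmetrize + deduplicate integer endpoint pairs, drop self-loops.
canonical_kgraph <- function(nodes, i, j) {
  keep <- i != j
  i <- i[keep]
  j <- j[keep]
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  # unordered-pair key; numeric stays exact well past 2^31 pairs
  key <- (as.numeric(lo) - 1) * length(nodes) + as.numeric(hi)
  keep <- !duplicated(key)
  new_kgraph(nodes, lo[keep], hi[keep])
}

#' @rdname kgraph
#' @param g a `kgraph`.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname kgraph
#' @export
n_edges <- function(g) length(g$from)

#' Node degrees
#'
#' @param g a `kgraph`.
#' @return named integer vector of degrees (isolated nodes have degree 0).
#' @export
degrees <- function(g) {
  d <- tabulate(c(g$from, g$to), nbins = n_nodes(g))
  names(d) <- g$nodes
  d
}

#' @export
print.kgraph <- function(x, ...) {
  cat(sprintf(
    "<kgraph> simple undirected graph: %d nodes, %d edges\n",
    n_nodes(x), n_edges(x)
  ))
  invisible(x)
}

#' @export
format.kgraph <- function(x, ...) {
  sprintf("<kgraph: %d nodes, %d edges>", n_nodes(x), n_edges(x))
}

#' Edge-list input/output
#'
#' Graphs are exchanged as two-column whitespace- or tab-separated edge
#' lists with an optional header line; node ids are arbitrary strings.
#' A first line whose fields look like column names (`from`/`to`,
#' `source`/`target`, `node1`/`node2`, `neuron1`/`neuron2`) is treated as
#' a header when `header = "auto"`.
#'
#' @param path file path.
#' @param header `"auto"`, `TRUE` or `FALSE`.
#' @param nodes optional node universe passed through to [kgraph()].
#' @return `read_edgelist()` returns a `kgraph`; `write_edgelist()` its
#'   input, invisibly.
#' @export
read_edgelist <- function(path, header = "auto", nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(kgraph(NULL, nodes = nodes))
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop_parameter(sprintf(
      "malformed edge-list row at line %d: expected 2 fields, got %d",
      bad[1L], length(fields[[bad[1L]]])
    ))
  }
  if (identical(header, "auto")) {
    first <- tolower(fields[[1L]])
    headerish <- list(
      c("from", "to"), c("source", "target"),
      c("node1", "node2"), c("neuron1", "neuron2")
    )
    header <- any(vapply(headerish, identical, logical(1), y = first))
  }
  if (isTRUE(header)) fields <- fields[-1L]
  if (length(fields) == 0L) return(kgraph(NULL, nodes = nodes))
  m <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  kgraph(m, nodes = nodes)
}

#' @rdname read_edgelist
#' @param g a `kgraph`.
#' @param sep field separator used when writing.
#' @export
write_edgelist <- function(g, path, sep = "\t") {
  df <- data.frame(
    from = g$nodes[g$from], to = g$nodes[g$to],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = sep, quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(g)
}

#' Convert an igraph object
#'
#' Used internally to wrap the classical random-graph samplers; exported
#' because it is handy when comparing against igraph's own statistics.
#'
#' @param ig an `igraph` graph.
#' @return a `kgraph` on node ids `"1"..."n"` (or the igraph names).
#' @export
as_kgraph <- function(ig) {
  n <- igraph::vcount(ig)
  nms <- igraph::vertex_attr(ig, "name")
  if (is.null(nms)) nms <- as.character(seq_len(n))
  el <- igraph::as_edgelist(ig, names = FALSE)
  canonical_kgraph(nms, el[, 1L], el[, 2L])
}

# --- error conditions ----------------------------------------------------

stop_empty_graph <- function(what) {
  stop(errorCondition(
    sprintf("%s is undefined on an empty graph (no nodes)", what),
    class = "netpattern_empty_graph"
  ))
}

stop_parameter <- function(msg) {
  stop(errorCondition(msg, class = "netpattern_parameter_error"))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# RNG state afterwards; `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
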