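#' Animal roster
#'
#' Eight animals with published estimated neuron counts, used as
#' intermediates between the two fully mapped connectomes (roundworm and
#' fruit fly) in the density-projection sweep.
#'
#' @return a data.frame with `animal` and `n_neurons`.
#' @export
animal_roster <- function() {
  data.frame(
    animal = c(
      "rotifer", "sea_squirt_larva", "roundworm", "jellyfish",
      "fairy_wasp", "leech", "pond_snail", "sea_slug"
    ),
    n_neurons = c(200L, 231L, 302L, 5600L, 7400L, 10000L, 11000L, 18000L)
  )
}

wormatlas_types <- c("S", "Sp", "R", "Rp", "EJ", "NMJ")

#' Connectome specification
#'
#' Bundles what the null-model machinery needs to know about an animal:
#' a name, a neuron count, optionally the mapped synapse graph, and the
#' edge-completion ratio `p` (derived from the graph when present).
#'
#' @param name label.
#' @param n_neurons neuron count (>= 2).
#' @param graph optional [kgraph] of mapped connections.
#' @param p edge-completion ratio; derived from `graph` when omitted.
#' @return an object of class `connectome_spec`.
#' @export
connectome_spec <- function(name, n_neurons, graph = NULL, p = NULL) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 2L) stop_parameter("a connectome needs at least 2 neurons")
  if (!is.null(graph) && is.null(p)) p <- edge_probability(graph)
  structure(
    list(name = name, n_neurons = n_neurons, graph = graph, p = p),
    class = "connectome_spec"
  )
}

#' @export
print.connectome_spec <- function(x, ...) {
  cat(sprintf(
    "<connectome_spec> %s: %d neurons%s%s\n",
    x$name, x$n_neurons,
    if (is.null(x$graph)) "" else sprintf(", %d mapped connections", n_edges(x$graph)),
    if (is.null(x$p)) "" else sprintf(", p = %.6f", x$p)
  ))
  invisible(x)
}

#' Read a connectome file
#'
#' Two dialects are supported. `"edgelist"` is a bare two-column
#' neuron-pair list. `"wormatlas"` is the four-column neuronal-wiring
#' table layout (`neuron1`, `neuron2`, `type`, `count`): connection types
#' are S/Sp (sending mono-/poly-synaptic), R/Rp (receiving; these
#' duplicate the sending rows and are excluded by default), EJ (electric
#' junction) and NMJ (neuromuscular junction). Synapse multiplicities and
#' directionality are discarded; the result is a simple undirected graph.
#'
#' @param path file path.
#' @param dialect `"edgelist"` or `"wormatlas"`.
#' @param exclude_types connection types to drop (wormatlas dialect);
#'   defaults to the receiving duplicates `c("R", "Rp")`.
#' @param name label for the resulting spec; defaults to the file name.
#' @return a [connectome_spec()] with the graph and derived `p`.
#' @export
read_connectome <- function(path, dialect = c("edgelist", "wormatlas"),
                            exclude_types = c("R", "Rp"), name = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "edgelist") {
    g <- read_edgelist(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[ \t]+")
    if (length(fields) && grepl("neuron", tolower(fields[[1L]][1L]))) {
      fields <- fields[-1L]
      offset <- 1L
    } else {
      offset <- 0L
    }
    bad <- which(lengths(fields) != 4L)
    if (length(bad)) {
      stop_parameter(sprintf(
        "malformed wormatlas row at line %d: expected 4 fields, got %d",
        bad[1L] + offset, length(fields[[bad[1L]]])
      ))
    }
    if (length(fields) == 0L) stop_parameter("empty connectome file")
    m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
    type <- m[, 3L]
    unknown <- setdiff(unique(type), wormatlas_types)
    if (length(unknown)) {
      warning(sprintf(
        "unknown connection type(s) kept: %s",
        paste(unknown, collapse = ", ")
      ))
    }
    keep <- !(type %in% exclude_types)
    g <- kgraph(m[keep, 1:2, drop = FALSE],
      nodes = sort(unique(as.vector(m[, 1:2])))
    )
  }
  connectome_spec(name, n_nodes(g), graph = g)
}

#' Density-matched Erdos-Renyi null model
#'
#' Draws a G(n, p) graph with the connectome's neuron count and
#' edge-completion ratio — the structural baseline a real neural map is
#' compared against.
#'
#' @param spec a [connectome_spec()] carrying `n_neurons` and `p`.
#' @param seed integer seed.
#' @return a [kgraph].
#' @export
matched_null <- function(spec, seed = NULL) {
  if (is.null(spec$p)) {
    stop_parameter("the spec has no edge-completion ratio p (no graph either)")
  }
  er_gnp(spec$n_neurons, spec$p, seed = seed)
}

#' Real-versus-generated comparison table
#'
#' For each connectome spec: one row with the real graph's profile (when
#' mapped connections are present) and one `Generated_` row with the
#' profile of its density-matched null, averaged over the given seeds.
#'
#' @param specs a list of [connectome_spec()] objects.
#' @param seeds integer vector of seeds for the generated rows.
#' @return a data.frame with `name`, `neurons`, `synapses` and the four
#'   measures.
#' @export
comparison_table <- function(specs, seeds = 1L) {
  if (inherits(specs, "connectome_spec")) specs <- list(specs)
  rows <- list()
  for (spec in specs) {
    if (!is.null(spec$graph)) {
      mv <- measure_vector(spec$graph)
      rows[[length(rows) + 1L]] <- data.frame(
        name = spec$name, neurons = n_nodes(spec$graph),
        synapses = n_edges(spec$graph),
        avg_degree = mv[["avg_degree"]], avg_pagerank = mv[["avg_pagerank"]],
        avg_clustering = mv[["avg_clustering"]],
        avg_triangles = mv[["avg_triangles"]]
      )
    }
    prof <- vapply(seeds, function(s) {
      g <- matched_null(spec, seed = s)
      c(n_edges(g), as.numeric(measure_vector(g)))
    }, numeric(5L))
    avg <- rowMeans(prof)
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("Generated_", spec$name), neurons = spec$n_neurons,
      synapses = avg[1L],
      avg_degree = avg[2L], avg_pagerank = avg[3L],
      avg_clustering = avg[4L], avg_triangles = avg[5L]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Animal density-projection sweep
#'
#' Projects structural profiles for animals whose connectomes are not
#' mapped: for every animal (node count `n`) and every density on a grid
#' of `n_p` values linearly spaced between `p_low` and `p_high`
#' (inclusive of both ends; defaults are the fruit-fly and roundworm
#' edge-completion ratios), draws G(n, p) per seed and records the
#' realized synapse count plus the four-measure profile.
#'
#' @param animals a data.frame with `animal` and `n_neurons`; defaults
#'   to [animal_roster()].
#' @param p_low,p_high density grid bounds.
#' @param n_p number of grid points.
#' @param seeds integer vector of seeds per (animal, p) cell.
#' @param max_n skip animals with more than `max_n` neurons — the
#'   desk-scale profile caps the roster at 5,600 neurons; pass `Inf` for
#'   the full roster.
#' @return a `projection_result` data.frame: `animal`, `n_neurons`,
#'   `p_index`, `p`, `seed`, `synapses` and the four measures.
#' @export
projection_sweep <- function(animals = animal_roster(),
                             p_low = 0.012164, p_high = 0.061134,
                             n_p = 10L, seeds = 1L, max_n = Inf) {
  animals <- animals[animals$n_neurons <= max_n, , drop = FALSE]
  if (nrow(animals) == 0L) stop_parameter("no animals under the `max_n` cap")
  p_grid <- seq(p_low, p_high, length.out = n_p)
  rows <- list()
  for (a in seq_len(nrow(animals))) {
    n <- animals$n_neurons[a]
    for (k in seq_len(n_p)) {
      for (s in seeds) {
        g <- er_gnp(n, p_grid[k], seed = s)
        mv <- measure_vector(g)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = animals$animal[a], n_neurons = n,
          p_index = k, p = p_grid[k], seed = s,
          synapses = n_edges(g),
          avg_degree = mv[["avg_degree"]], avg_pagerank = mv[["avg_pagerank"]],
          avg_clustering = mv[["avg_clustering"]],
          avg_triangles = mv[["avg_triangles"]]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("projection_result", "data.frame")
  out
}

#' Extract trend series from a projection sweep
#'
#' `projection_series()` returns the per-animal profile (seed-averaged,
#' ordered by neuron count) at one fixed density grid index — the
#' fixed-p reading of the animal trend row. `projection_diagonal()`
#' instead pairs the k-th smallest animal with the k-th *largest*
#' density, mirroring how density shrinks from the roundworm to the
#' fruit fly across the two real maps.
#'
#' @param sweep a `projection_result` from [projection_sweep()].
#' @param p_index density grid index (1 = `p_low`).
#' @return a `trajectory` data.frame ordered by `n_neurons`.
#' @export
projection_series <- function(sweep, p_index = 1L) {
  sub <- sweep[sweep$p_index == p_index, , drop = FALSE]
  if (nrow(sub) == 0L) stop_parameter("no rows at that p_index")
  agg <- stats::aggregate(
    sub[c(
      "synapses", "avg_degree", "avg_pagerank",
      "avg_clustering", "avg_triangles"
    )],
    by = list(animal = sub$animal, n_neurons = sub$n_neurons), FUN = mean
  )
  agg <- agg[order(agg$n_neurons), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("trajectory", "data.frame")
  agg
}

#' @rdname projection_series
#' @export
projection_diagonal <- function(sweep) {
  n_p <- max(sweep$p_index)
  ns <- sort(unique(sweep$n_neurons))
  rows <- lapply(seq_along(ns), function(k) {
    pk <- n_p - ((k - 1L) %% n_p) # descending density with rising n
    sub <- sweep[sweep$n_neurons == ns[k] & sweep$p_index == pk, , drop = FALSE]
    cbind(
      sub[1L, c("animal", "n_neurons", "p_index", "p"), drop = FALSE],
      as.data.frame(as.list(colMeans(sub[c(
        "synapses", "avg_degree", "avg_pagerank",
        "avg_clustering", "avg_triangles"
      )])))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trajectory", "data.frame")
  out
}
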