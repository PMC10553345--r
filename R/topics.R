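#' Publication records
#'
#' A publication record is a calendar year plus a set of topic labels;
#' records are the raw material of the cumulative topic co-occurrence
#' networks. On disk the format is CSV with a `year` column and a
#' `topics` column holding the topic labels joined by a separator
#' (semicolon by default). Records with an empty topic set are rejected
#' on read, with the rejection count reported and attached as an
#' attribute.
#'
#' @param path CSV file path.
#' @param topic_sep separator joining topics inside the `topics` field.
#' @return a data.frame with columns `year` (integer) and `topics` (list
#'   of character vectors), with attribute `n_rejected`.
#' @export
read_publications <- function(path, topic_sep = ";") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "topics") %in% names(df))) {
    stop_parameter("publication CSV needs `year` and `topics` columns")
  }
  topics <- strsplit(as.character(df$topics), topic_sep, fixed = TRUE)
  topics <- lapply(topics, function(t) unique(t[nzchar(trimws(t))]))
  keep <- lengths(topics) > 0L
  n_rejected <- sum(!keep)
  if (n_rejected > 0L) {
    message(sprintf("rejected %d record(s) with an empty topic set", n_rejected))
  }
  out <- data.frame(year = as.integer(df$year[keep]))
  out$topics <- topics[keep]
  attr(out, "n_rejected") <- n_rejected
  out
}

#' @rdname read_publications
#' @param records a publication data.frame (`year` + list-column `topics`).
#' @export
write_publications <- function(records, path, topic_sep = ";") {
  df <- data.frame(
    year = records$year,
    topics = vapply(records$topics, paste, character(1), collapse = topic_sep)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Cumulative yearly topic co-occurrence networks
#'
#' For every year `y` on a contiguous axis, builds the union over all
#' records with year `<= y` of the clique on each record's topic set
#' (topics co-occurring in one publication are pairwise linked). Past
#' activity is never removed, so node and edge sets are non-decreasing
#' in `y`; years without records carry the previous year's graph
#' forward. Repeat co-occurrences do not add weight: the graphs are
#' simple and unweighted like every other graph in the package.
#'
#' @param records a publication data.frame as from [read_publications()]
#'   or [make_publications()].
#' @param from,to optional year range; defaults to the observed range.
#' @return a named list, year as name, each element a [kgraph].
#' @export
cumulative_networks <- function(records, from = NULL, to = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    stop_parameter("`records` must contain at least one publication")
  }
  if (any(lengths(records$topics) == 0L)) {
    stop_parameter("records with empty topic sets must be filtered out first")
  }
  if (is.null(from)) from <- min(records$year)
  if (is.null(to)) to <- max(records$year)
  years <- seq(from, to)
  node_seen <- new.env(parent = emptyenv())
  edge_seen <- new.env(parent = emptyenv())
  nodes <- character(0)
  efrom <- character(0)
  eto <- character(0)
  nets <- stats::setNames(vector("list", length(years)), years)
  for (yi in seq_along(years)) {
    y <- years[yi]
    recs <- which(records$year == y)
    for (r in recs) {
      ts <- sort(records$topics[[r]])
      for (t in ts) {
        if (is.null(node_seen[[t]])) {
          node_seen[[t]] <- TRUE
          nodes <- c(nodes, t)
        }
      }
      if (length(ts) >= 2L) {
        pr <- all_index_pairs(length(ts))
        for (k in seq_len(nrow(pr))) {
          a <- ts[pr[k, 1L]]
          b <- ts[pr[k, 2L]]
          key <- paste(a, b, sep = "\r")
          if (is.null(edge_seen[[key]])) {
            edge_seen[[key]] <- TRUE
            efrom <- c(efrom, a)
            eto <- c(eto, b)
          }
        }
      }
    }
    g <- if (length(nodes) == 0L) {
      kgraph(NULL)
    } else {
      new_kgraph(nodes, match(efrom, nodes), match(eto, nodes))
    }
    # edge indices are not guaranteed from < to after matching: fix up
    nets[[yi]] <- canonical_kgraph(g$nodes, g$from, g$to)
  }
  nets
}

#' Yearly measure trajectory of cumulative topic networks
#'
#' @param nets a named year -> [kgraph] list from [cumulative_networks()].
#' @return a `trajectory` data.frame with `year`, `n_nodes`, `n_edges`
#'   and the four measures (all-zero profile for years before the first
#'   topic appears).
#' @export
yearly_trajectory <- function(nets) {
  rows <- lapply(seq_along(nets), function(i) {
    g <- nets[[i]]
    mv <- if (n_nodes(g) == 0L) c(0, 0, 0, 0) else as.numeric(measure_vector(g))
    data.frame(
      year = as.integer(names(nets)[i]),
      n_nodes = n_nodes(g), n_edges = n_edges(g),
      avg_degree = mv[1L], avg_pagerank = mv[2L],
      avg_clustering = mv[3L], avg_triangles = mv[4L]
    )
  })
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Node-edge growth correlation
#'
#' Pearson correlation between the yearly cumulative node and edge
#' counts — high when the network's edge growth tracks its node growth
#' over the whole period.
#'
#' @param traj a trajectory with `n_nodes` and `n_edges` columns.
#' @return the Pearson correlation coefficient.
#' @export
growth_correlation <- function(traj) {
  if (!all(c("n_nodes", "n_edges") %in% names(traj))) {
    stop_parameter("trajectory needs `n_nodes` and `n_edges` columns")
  }
  stats::cor(traj$n_nodes, traj$n_edges)
}
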