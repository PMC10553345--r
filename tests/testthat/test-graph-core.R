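test_that("construction symmetrizes, deduplicates and drops self-loops", {
  g <- kgraph(cbind(
    c("a", "b", "b", "a", "c"),
    c("b", "a", "c", "a", "c")
  ))
  expect_equal(n_nodes(g), 3)
  expect_equal(n_edges(g), 2) # a-b (deduped both directions), b-c; loops gone
  expect_true(all(g$from < g$to))

  iso <- kgraph(cbind("a", "b"), nodes = c("a", "b", "z"))
  expect_equal(n_nodes(iso), 3)
  expect_equal(unname(degrees(iso)["z"]), 0)

  expect_error(kgraph(cbind("a", "q"), nodes = c("a", "b")), "endpoints")
  expect_error(kgraph(matrix("a", 1, 3)), "two columns")
})

test_that("edge lists round-trip through disk, with and without header", {
  g <- er_gnp(30, 0.2, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(g, path)
  g2 <- read_edgelist(path, nodes = g$nodes)
  expect_equal(sort(paste(g$nodes[g$from], g$nodes[g$to])),
               sort(paste(g2$nodes[g2$from], g2$nodes[g2$to])))

  withheader <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "a\tb", "b\tc"), withheader)
  g3 <- read_edgelist(withheader)
  expect_equal(n_edges(g3), 2)

  bad <- withr::local_tempfile()
  writeLines(c("a b", "c d e"), bad)
  expect_error(read_edgelist(bad), "line 2")
})

test_that("average degree matches closed forms and rejects empty graphs", {
  k4 <- complete_graph(4)
  expect_equal(average_degree(k4), 3)
  edgeless <- kgraph(NULL, nodes = letters[1:7])
  expect_equal(average_degree(edgeless), 0)
  expect_error(average_degree(kgraph(NULL)), class = "netpattern_empty_graph")
})

test_that("PageRank normalizes, converges, and matches symmetry cases", {
  single <- kgraph(NULL, nodes = "v")
  expect_equal(as.numeric(pagerank_vector(single)), 1)

  cyc <- kgraph(cbind(as.character(1:8), as.character(c(2:8, 1))))
  pr <- pagerank_vector(cyc)
  expect_equal(as.numeric(pr), rep(1 / 8, 8), tolerance = 1e-9)
  expect_true(attr(pr, "converged"))

  # a star never reaches its fixed point in one step from uniform
  star <- kgraph(cbind("hub", paste0("leaf", 1:4)))
  expect_warning(
    pagerank_vector(star, max_iter = 1L, tol = 1e-15),
    "did not converge"
  )
})

test_that("PageRank agrees with a dense power-iteration oracle", {
  g <- kgraph(
    cbind(c("a", "a", "b"), c("b", "c", "c")),
    nodes = c("a", "b", "c", "d") # d dangles
  )
  expect_equal(
    as.numeric(pagerank_vector(g)),
    unname(oracle_pagerank(g)),
    tolerance = 1e-8
  )
  set.seed(404)
  for (rep in 1:5) {
    g <- rand_small_graph(sample(4:10, 1), stats::runif(1, 0.2, 0.8))
    expect_equal(
      as.numeric(pagerank_vector(g)),
      unname(oracle_pagerank(g)),
      tolerance = 1e-8
    )
  }
})

test_that("triangle, clustering and PageRank match brute force on all small graphs", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    g <- rand_small_graph(n, sample(c(0.2, 0.5, 0.8), 1))
    expect_identical(
      as.integer(node_triangle_counts(g)),
      as.integer(oracle_triangle_counts(g))
    )
    expect_equal(
      as.numeric(local_clustering(g)),
      unname(oracle_local_clustering(g)),
      tolerance = 1e-12
    )
    pr <- suppressWarnings(pagerank_vector(g))
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(as.numeric(pr), unname(oracle_pagerank(g)), tolerance = 1e-8)
  }
})

test_that("measures agree with igraph on a mid-sized random graph", {
  g <- er_gnp(60, 0.15, seed = 11)
  ig <- igraph::graph_from_edgelist(
    cbind(g$from, g$to),
    directed = FALSE
  )
  expect_equal(
    unname(node_triangle_counts(g)),
    igraph::count_triangles(ig)
  )
  expect_equal(
    average_clustering(g),
    igraph::transitivity(ig, type = "localaverageundirected", isolates = "zero"),
    tolerance = 1e-12
  )
  expect_equal(
    as.numeric(pagerank_vector(g)),
    igraph::page_rank(ig, damping = 0.85)$vector,
    tolerance = 1e-6
  )
})

test_that("clustering handles K3, stars, paths and low-degree nodes", {
  k3 <- complete_graph(3)
  expect_equal(node_clustering(k3, "1"), 1)
  expect_equal(average_clustering(k3), 1)

  star <- kgraph(cbind("hub", paste0("leaf", 1:5)))
  expect_equal(node_clustering(star, "hub"), 0)
  expect_equal(average_clustering(star), 0)

  path <- kgraph(cbind(c("a", "b"), c("b", "c")))
  expect_equal(unname(node_triangle_counts(path)), c(0, 0, 0))
  expect_equal(node_clustering(path, "a"), 0) # degree-1 decision case
  expect_error(node_clustering(path, "zz"), "not in the graph")
})

test_that("edge probability matches printed connectome densities", {
  worm <- er_gnm(281, 2405, seed = 1)
  expect_equal(average_degree(worm), 17.1174, tolerance = 1e-4)
  expect_equal(round(edge_probability(worm), 6), 0.061134)
  expect_equal(edge_probability(complete_graph(5)), 1)
  expect_error(edge_probability(kgraph(NULL, nodes = "a")), "at least 2")
})

test_that("measure_vector bundles the four measures coherently", {
  k4 <- complete_graph(4)
  mv <- measure_vector(k4)
  expect_equal(
    unclass(mv),
    c(avg_degree = 3, avg_pagerank = 0.25, avg_clustering = 1, avg_triangles = 3)
  )
  edgeless <- kgraph(NULL, nodes = as.character(1:10))
  mv0 <- measure_vector(edgeless)
  expect_equal(unname(unclass(mv0)), c(0, 0.1, 0, 0))

  path <- withr::local_tempfile(fileext = ".json")
  measure_report(mv, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$avg_degree, 3)
})

test_that("ER draws track the closed-form clustering and triangle expectations", {
  for (n in c(100, 281)) {
    p <- 0.0611
    cl <- vapply(1:20, function(s) average_clustering(er_gnp(n, p, seed = s)), 0)
    tr <- vapply(1:20, function(s) average_triangles(er_gnp(n, p, seed = s)), 0)
    se_cl <- stats::sd(cl) / sqrt(length(cl))
    se_tr <- stats::sd(tr) / sqrt(length(tr))
    expect_lt(abs(mean(cl) - p), 3 * se_cl)
    expect_lt(abs(mean(tr) - choose(n - 1, 2) * p^3), 3 * se_tr)
  }
})

test_that("measure ranges hold on random graphs", {
  set.seed(77)
  for (rep in 1:10) {
    g <- rand_small_graph(sample(5:12, 1), stats::runif(1))
    expect_gte(average_clustering(g), 0)
    expect_lte(average_clustering(g), 1)
    expect_lte(average_degree(g), n_nodes(g) - 1)
    expect_equal(average_pagerank(g), 1 / n_nodes(g), tolerance = 1e-9)
  }
})
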