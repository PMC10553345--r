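# hand-built 2-2-2 network used by several cases below
toy_mlp <- function() {
  m <- mlp_init(c(2L, 2L, 2L), seed = 1)
  m$W[[1]] <- matrix(c(0.5, 0.25, -0.3, 0.8), 2, 2)
  m$b[[1]] <- c(0.1, -0.2)
  m$W[[2]] <- matrix(c(1, 0.5, -1, 0.5), 2, 2)
  m$b[[2]] <- c(0, 0)
  m
}

test_that("a single Adam step matches the closed-form update", {
  # f(theta) = theta^2 at theta = 1: grad = 2
  up <- netpattern:::adam_update(
    theta = 1, grad = 2, m = 0, v = 0, t = 1,
    lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8
  )
  # m_hat = grad, v_hat = grad^2 at t = 1, so the step is lr * g/(|g|+eps)
  expect_equal(up$theta, 1 - 1e-3 * 2 / (2 + 1e-8), tolerance = 1e-15)
  expect_equal(up$m, 0.1 * 2)
  expect_equal(up$v, 0.001 * 4)

  # zero gradient moves nothing at all
  up0 <- netpattern:::adam_update(3, 0, 0, 0, t = 1)
  expect_identical(up0$theta, 3)
})

test_that("forward pass reproduces hand-computed sigmoid/softmax values", {
  m <- toy_mlp()
  out <- forward_outputs(m, c(0.9, 0.6))
  # hidden pre-activations written out longhand
  z1 <- 0.9 * 0.5 + 0.6 * 0.25 + 0.1
  z2 <- 0.9 * -0.3 + 0.6 * 0.8 - 0.2
  h1 <- 1 / (1 + exp(-z1))
  h2 <- 1 / (1 + exp(-z2))
  o1 <- h1 * 1 + h2 * 0.5
  o2 <- h1 * -1 + h2 * 0.5
  p1 <- exp(o1) / (exp(o1) + exp(o2))
  expect_equal(unname(out[c("in_1", "in_2")]), c(0.9, 0.6))
  expect_equal(unname(out[c("h1_1", "h1_2")]), c(h1, h2), tolerance = 1e-12)
  expect_equal(unname(out[c("out_1", "out_2")]), c(p1, 1 - p1), tolerance = 1e-12)
  expect_equal(sum(out[c("out_1", "out_2")]), 1, tolerance = 1e-12)
})

test_that("zero-weight networks sit exactly on the firing threshold and stay silent", {
  m <- mlp_init(c(4L, 3L, 2L), seed = 1)
  m$W <- lapply(m$W, function(w) w * 0)
  out <- forward_outputs(m, rep(0.9, 4))
  expect_equal(unname(out[paste0("h1_", 1:3)]), rep(0.5, 3))
  pat <- fired_pattern(m, rep(0.9, 4))
  # strict > 0.5: hidden neurons at exactly 0.5 do not fire
  expect_false(any(grepl("^h", pat$fired)))
  expect_true(all(paste0("in_", 1:4) %in% pat$fired))
})

test_that("training reduces loss and learns a separable problem", {
  imgs <- make_images(side = 8, n_train = 400, n_test = 100, noise_sd = 0.1, seed = 3)
  set.seed(4)
  m <- mlp_init(c(64L, 20L, 10L))
  l0 <- mlp_loss(m, imgs$train$x, imgs$train$y)
  for (i in 1:5) m <- train_epoch(m, imgs$train$x, imgs$train$y)
  expect_lt(mlp_loss(m, imgs$train$x, imgs$train$y), l0)
  for (i in 1:20) m <- train_epoch(m, imgs$train$x, imgs$train$y)
  expect_gt(mlp_accuracy(m, imgs$test$x, imgs$test$y), 0.9)
  expect_error(train_epoch(m, imgs$train$x[, 1:10], imgs$train$y), "columns")
})

test_that("fired patterns respect thresholds, subset relation and edge modes", {
  m <- toy_mlp()
  pat <- fired_pattern(m, c(0.9, 0.6))
  expect_true(all(pat$fired %in% pat$active))
  # fired by hand: both inputs, both hidden (0.668, 0.502), output 1 (0.739)
  expect_setequal(pat$fired, c("in_1", "in_2", "h1_1", "h1_2", "out_1"))
  # cross-layer pairs on layer sizes (2, 2, 1): C(5,2) - within-layer pairs
  expect_equal(n_edges(pat$pattern_graph), choose(5, 2) - 2)

  allp <- fired_pattern(m, c(0.9, 0.6), edge_mode = "all")
  expect_equal(n_edges(allp$pattern_graph), choose(5, 2))

  set.seed(8)
  m3 <- mlp_init(c(6L, 5L, 4L, 3L))
  x <- stats::runif(6)
  cross <- fired_pattern(m3, x, edge_mode = "cross")
  adj <- fired_pattern(m3, x, edge_mode = "adjacent")
  expect_true(all(adj$fired %in% adj$active))
  # adjacent-only multipartite graphs cannot close triangles
  expect_equal(sum(node_triangle_counts(adj$pattern_graph)), 0)
  if (length(cross$fired) >= 3) {
    expect_gte(sum(node_triangle_counts(cross$pattern_graph)), 0)
  }
})

test_that("cross-layer patterns on 3+ layers do produce triangles once trained", {
  imgs <- make_images(side = 8, n_train = 300, n_test = 50, noise_sd = 0.1, seed = 5)
  set.seed(6)
  m <- mlp_init(c(64L, 10L, 8L, 10L))
  for (i in 1:3) m <- train_epoch(m, imgs$train$x, imgs$train$y)
  tri <- vapply(1:20, function(q) {
    pat <- fired_pattern(m, imgs$test$x[q, ])
    sum(node_triangle_counts(pat$pattern_graph))
  }, 0)
  expect_gt(sum(tri), 0)
})

test_that("cohesion is the fired/active edge ratio with sane degenerate cases", {
  m <- toy_mlp()
  pat <- fired_pattern(m, c(0.9, 0.6))
  expect_gte(cohesion(pat), 0)
  expect_lte(cohesion(pat), 1)
  # active == fired here (out_2 = 0.261 > 0.1 though: recompute by hand)
  # active = all 6 neurons; fired = 5. cross pairs: active (2,2,2): 12; fired: 8
  expect_equal(cohesion(pat), 8 / 12, tolerance = 1e-12)

  # active == fired (same threshold both sides) -> cohesion exactly 1
  pat2 <- fired_pattern(m, c(0.9, 0.6), graph_threshold = 0.5)
  expect_equal(cohesion(pat2), 1)

  # nothing fired, something active -> 0
  mz <- mlp_init(c(3L, 2L, 2L), seed = 2)
  mz$W <- lapply(mz$W, function(w) w * 0)
  patz <- fired_pattern(mz, rep(0.05, 3)) # inputs below both thresholds
  expect_equal(length(patz$fired), 0)
  expect_equal(cohesion(patz), 0)

  # input 2 below the background threshold: one hidden unit is active
  # but not fired; hand enumeration gives fired cross-pairs 3 of 8 active
  pat3 <- fired_pattern(m, c(0.9, 0.05))
  expect_setequal(pat3$fired, c("in_1", "h1_1", "out_1"))
  expect_true("h1_2" %in% setdiff(pat3$active, pat3$fired))
  expect_equal(cohesion(pat3), 3 / 8, tolerance = 1e-12)
  # either-active denominator ranges over all neurons (12 cross pairs)
  expect_equal(cohesion(pat3, denominator = "either_active"), 3 / 12,
               tolerance = 1e-12)
})

test_that("epoch sweep records the stated checkpoints and coherent series", {
  expected_cp <- c(1:10, seq(20, 100, 10))
  expect_length(expected_cp, 19)

  imgs <- make_images(side = 8, n_train = 300, n_test = 120, noise_sd = 0.1, seed = 7)
  traj <- epoch_sweep(imgs,
    layer_sizes = c(64L, 20L, 10L, 10L),
    epochs = 12, checkpoints = c(1:10, seq(20, 100, 10)),
    eval_n = 25, seed = 8
  )
  expect_equal(traj$epoch, 1:10) # only checkpoints <= epochs survive
  expect_true(all(traj$accuracy >= 0 & traj$accuracy <= 1))
  expect_true(all(traj$cohesion >= 0 & traj$cohesion <= 1))
  expect_true(all(traj$avg_clustering >= 0 & traj$avg_clustering <= 1))
  # accuracy trend is upward on separable data (smoothed monotone)
  sm <- stats::filter(traj$accuracy, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_gte(utils::tail(sm, 1), sm[1])
})

test_that("trajectory correlation behaves like Pearson correlation", {
  traj <- data.frame(a = c(1, 3, 7), b = c(2, 6, 14), c = -c(1, 3, 7), d = c(2, 1, 5))
  expect_equal(trajectory_correlation(traj, "a", "a"), 1)
  expect_equal(trajectory_correlation(traj, "a", "b"), 1)
  expect_equal(trajectory_correlation(traj, "a", "c"), -1)
  # 3-point case against the closed form
  r <- stats::cor(traj$a, traj$d)
  expect_equal(trajectory_correlation(traj, "a", "d"), r)
  expect_error(trajectory_correlation(traj, "a", "zz"), "columns")
})
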