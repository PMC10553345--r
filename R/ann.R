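#' Sigmoid multilayer perceptron
#'
#' A plain fully connected classifier used as the artificial knowledge
#' processing system: sigmoid activations on the hidden layers (0.5 is
#' the median output of an untrained unit) and a normalized categorical
#' (softmax) output layer, trained with mini-batch Adam on categorical
#' cross-entropy over integer labels. The reference architecture is
#' 784-80-40-20-10 for 28x28 inputs; any layer sizes are accepted, and an
#' 8x8 (64-input) reduced profile is used for desk-scale runs.
#'
#' @param layer_sizes integer vector of layer widths, input first,
#'   output last (>= 2 layers).
#' @param seed integer seed for the Glorot-uniform weight initialization.
#' @return an object of class `mlp`.
#' @export
mlp_init <- function(layer_sizes = c(784L, 80L, 40L, 20L, 10L), seed = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop_parameter("`layer_sizes` needs >= 2 positive layer widths")
  }
  with_seed(seed, {
    L <- length(layer_sizes)
    W <- vector("list", L - 1L)
    b <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      fan_in <- layer_sizes[l]
      fan_out <- layer_sizes[l + 1L]
      limit <- sqrt(6 / (fan_in + fan_out))
      W[[l]] <- matrix(
        stats::runif(fan_in * fan_out, -limit, limit),
        nrow = fan_in, ncol = fan_out
      )
      b[[l]] <- numeric(fan_out)
    }
    structure(
      list(
        layer_sizes = layer_sizes, W = W, b = b,
        adam = NULL, epochs_trained = 0L
      ),
      class = "mlp"
    )
  })
}

#' @export
print.mlp <- function(x, ...) {
  cat(sprintf(
    "<mlp> %s sigmoid network, %d epochs trained\n",
    paste(x$layer_sizes, collapse = "-"), x$epochs_trained
  ))
  invisible(x)
}

sigmoid <- function(z) stats::plogis(z)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Full forward pass; returns activations of every layer (input included).
mlp_forward <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$layer_sizes[1L]) {
    stop_parameter(sprintf(
      "input has %d columns but the network expects %d",
      ncol(X), model$layer_sizes[1L]
    ))
  }
  L <- length(model$layer_sizes)
  A <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A[[l]] %*% model$W[[l]], 2L, model$b[[l]], "+")
    A[[l + 1L]] <- if (l == L - 1L) softmax_rows(Z) else sigmoid(Z)
  }
  A
}

# One Adam moment/parameter update; exposed internally for unit testing
# against the closed-form single-step update.
adam_update <- function(theta, grad, m, v, t,
                        lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  m_hat <- m / (1 - beta1^t)
  v_hat <- v / (1 - beta2^t)
  theta <- theta - lr * m_hat / (sqrt(v_hat) + eps)
  list(theta = theta, m = m, v = v)
}

default_hyper <- function(hyper = list()) {
  utils::modifyList(
    list(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8, batch_size = 32L),
    hyper
  )
}

#' Train for one epoch
#'
#' One full pass of shuffled mini-batch Adam updates on categorical
#' cross-entropy. The Adam moment estimates live inside the model object,
#' so repeated calls continue the same optimizer trajectory.
#'
#' @param model an [mlp_init()] model.
#' @param x numeric matrix, one flattened image in `[0, 1]` per row.
#' @param y integer labels in `0 .. n_classes - 1`.
#' @param hyper optional list overriding `lr` (1e-3), `beta1` (0.9),
#'   `beta2` (0.999), `eps` (1e-8), `batch_size` (32).
#' @param shuffle shuffle sample order each epoch (uses the RNG stream).
#' @return the updated `mlp`.
#' @export
train_epoch <- function(model, x, y, hyper = list(), shuffle = TRUE) {
  hp <- default_hyper(hyper)
  if (!is.matrix(x) || ncol(x) != model$layer_sizes[1L]) {
    stop_parameter(sprintf(
      "training matrix must have %d columns", model$layer_sizes[1L]
    ))
  }
  n_out <- model$layer_sizes[length(model$layer_sizes)]
  y <- as.integer(y)
  if (length(y) != nrow(x) || any(y < 0L) || any(y >= n_out)) {
    stop_parameter(sprintf("labels must be integers in 0..%d, one per row", n_out - 1L))
  }
  if (is.null(model$adam)) {
    model$adam <- list(
      mW = lapply(model$W, function(w) w * 0),
      vW = lapply(model$W, function(w) w * 0),
      mb = lapply(model$b, function(b) b * 0),
      vb = lapply(model$b, function(b) b * 0),
      t = 0L
    )
  }
  n <- nrow(x)
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  starts <- seq(1L, n, by = hp$batch_size)
  L <- length(model$layer_sizes)
  for (s in starts) {
    idx <- ord[s:min(s + hp$batch_size - 1L, n)]
    Xb <- x[idx, , drop = FALSE]
    yb <- y[idx]
    A <- mlp_forward(model, Xb)
    nb <- length(idx)
    # softmax + cross-entropy: delta = (P - onehot) / batch
    delta <- A[[L]]
    delta[cbind(seq_len(nb), yb + 1L)] <-
      delta[cbind(seq_len(nb), yb + 1L)] - 1
    delta <- delta / nb
    model$adam$t <- model$adam$t + 1L
    t <- model$adam$t
    for (l in (L - 1L):1L) {
      gW <- crossprod(A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        H <- A[[l]]
        delta <- (delta %*% t(model$W[[l]])) * H * (1 - H)
      }
      upW <- adam_update(
        model$W[[l]], gW, model$adam$mW[[l]], model$adam$vW[[l]], t,
        hp$lr, hp$beta1, hp$beta2, hp$eps
      )
      model$W[[l]] <- upW$theta
      model$adam$mW[[l]] <- upW$m
      model$adam$vW[[l]] <- upW$v
      upb <- adam_update(
        model$b[[l]], gb, model$adam$mb[[l]], model$adam$vb[[l]], t,
        hp$lr, hp$beta1, hp$beta2, hp$eps
      )
      model$b[[l]] <- upb$theta
      model$adam$mb[[l]] <- upb$m
      model$adam$vb[[l]] <- upb$v
    }
  }
  model$epochs_trained <- model$epochs_trained + 1L
  model
}

#' Mean cross-entropy loss
#'
#' @inheritParams train_epoch
#' @return a single non-negative number.
#' @export
mlp_loss <- function(model, x, y) {
  A <- mlp_forward(model, x)
  P <- A[[length(A)]]
  p_true <- P[cbind(seq_len(nrow(P)), as.integer(y) + 1L)]
  -mean(log(pmax(p_true, 1e-300)))
}

#' Classification accuracy (argmax match)
#'
#' @inheritParams train_epoch
#' @return a ratio in `[0, 1]`.
#' @export
mlp_accuracy <- function(model, x, y) {
  A <- mlp_forward(model, x)
  P <- A[[length(A)]]
  mean(max.col(P, ties.method = "first") - 1L == as.integer(y))
}

# Neuron ids and layer indices for a given architecture.
neuron_layout <- function(layer_sizes) {
  L <- length(layer_sizes)
  prefix <- c("in", if (L > 2L) paste0("h", seq_len(L - 2L)), "out")
  ids <- unlist(lapply(seq_len(L), function(l) {
    paste0(prefix[l], "_", seq_len(layer_sizes[l]))
  }))
  list(ids = ids, layer = rep(seq_len(L), layer_sizes))
}

#' Outputs of every neuron for one input
#'
#' Input neurons output the (normalized) pixel intensity itself; hidden
#' neurons their sigmoid activation; output neurons their softmax
#' probability.
#'
#' @param model an `mlp`.
#' @param x one flattened input vector.
#' @return a named numeric vector over all neurons, with an integer
#'   attribute `layer` (1 = input layer).
#' @export
forward_outputs <- function(model, x) {
  A <- mlp_forward(model, matrix(as.numeric(x), nrow = 1L))
  out <- unlist(lapply(A, as.numeric))
  layout <- neuron_layout(model$layer_sizes)
  names(out) <- layout$ids
  attr(out, "layer") <- layout$layer
  out
}

# All unordered index pairs 1..k, as a 2-column matrix.
all_index_pairs <- function(k) {
  if (k < 2L) {
    return(matrix(integer(0), ncol = 2L))
  }
  cbind(
    rep(seq_len(k - 1L), times = (k - 1L):1L),
    sequence((k - 1L):1L, from = 2L:k)
  )
}

# Edge pairs on a node subset under the chosen connectivity universe.
pattern_edges <- function(layer, edge_mode) {
  pr <- all_index_pairs(length(layer))
  if (nrow(pr) == 0L) {
    return(pr)
  }
  keep <- switch(edge_mode,
    cross = layer[pr[, 1L]] != layer[pr[, 2L]],
    adjacent = abs(layer[pr[, 1L]] - layer[pr[, 2L]]) == 1L,
    all = rep(TRUE, nrow(pr))
  )
  pr[keep, , drop = FALSE]
}

#' Fired-neuron pattern of one input
#'
#' The per-input knowledge pattern: the set of neurons whose output is
#' strictly greater than the activation threshold (0.5), turned into a
#' graph under a configurable connectivity universe. The default,
#' `"cross"`, connects every fired pair lying in different layers;
#' `"adjacent"` restricts to consecutive layers (which can never form a
#' triangle); `"all"` connects every fired pair. The `active` superset
#' (output strictly > 0.1) with the same edge rule is kept as the
#' reference for [cohesion()].
#'
#' @param model an `mlp`.
#' @param x one flattened input vector.
#' @param edge_mode `"cross"` (default), `"adjacent"` or `"all"`.
#' @param activation_threshold strict firing threshold, default 0.5.
#' @param graph_threshold strict background-activity threshold, 0.1.
#' @return an object of class `fired_pattern`: list with `fired`,
#'   `active` (character id vectors), `pattern_graph`, `active_graph`
#'   ([kgraph]s), the thresholds, and layer bookkeeping.
#' @export
fired_pattern <- function(model, x, edge_mode = c("cross", "adjacent", "all"),
                          activation_threshold = 0.5, graph_threshold = 0.1) {
  edge_mode <- match.arg(edge_mode)
  out <- forward_outputs(model, x)
  layer <- attr(out, "layer")
  fired_idx <- which(as.numeric(out) > activation_threshold)
  active_idx <- which(as.numeric(out) > graph_threshold)
  ids <- names(out)

  build <- function(idx) {
    pr <- pattern_edges(layer[idx], edge_mode)
    new_kgraph(
      ids[idx],
      pr[, 1L], pr[, 2L]
    )
  }
  structure(
    list(
      fired = ids[fired_idx],
      active = ids[active_idx],
      pattern_graph = build(fired_idx),
      active_graph = build(active_idx),
      edge_mode = edge_mode,
      activation_threshold = activation_threshold,
      graph_threshold = graph_threshold,
      layer_sizes = model$layer_sizes,
      fired_per_layer = tabulate(layer[fired_idx], length(model$layer_sizes)),
      active_per_layer = tabulate(layer[active_idx], length(model$layer_sizes))
    ),
    class = "fired_pattern"
  )
}

#' @export
print.fired_pattern <- function(x, ...) {
  cat(sprintf(
    "<fired_pattern> %d fired / %d active neurons (%s edges): %d pattern edges\n",
    length(x$fired), length(x$active), x$edge_mode, n_edges(x$pattern_graph)
  ))
  invisible(x)
}

#' Cohesion of a fired pattern
#'
#' The ratio of edges internal to the fired subgraph relative to the
#' above-background graph: `|E(fired)| / |E(active)|` under the pattern's
#' edge rule, where active means output > 0.1. Returns 0 when the
#' denominator is empty. The default denominator requires both endpoints
#' to be active; `denominator = "either_active"` instead counts every
#' potential edge (under the same edge rule, over all neurons) with at
#' least one active endpoint.
#'
#' @param p a [fired_pattern()].
#' @param denominator `"both_active"` (default) or `"either_active"`.
#' @return a ratio in `[0, 1]` for `"both_active"`.
#' @export
cohesion <- function(p, denominator = c("both_active", "either_active")) {
  denominator <- match.arg(denominator)
  num <- n_edges(p$pattern_graph)
  if (denominator == "both_active") {
    den <- n_edges(p$active_graph)
  } else {
    s <- p$layer_sizes
    i <- s - p$active_per_layer # inactive per layer
    total <- switch(p$edge_mode,
      cross = (sum(s)^2 - sum(s^2)) / 2,
      adjacent = sum(s[-length(s)] * s[-1L]),
      all = choose(sum(s), 2)
    )
    none <- switch(p$edge_mode,
      cross = (sum(i)^2 - sum(i^2)) / 2,
      adjacent = sum(i[-length(i)] * i[-1L]),
      all = choose(sum(i), 2)
    )
    den <- total - none
  }
  if (den == 0) 0 else num / den
}

#' Epoch sweep: train and profile the fired patterns
#'
#' Trains the network for `epochs` epochs and, at each checkpoint
#' (defaults: every epoch up to 10, then every 10th up to 100), records
#' the held-out accuracy together with the four-measure profile and
#' cohesion of the fired-neuron pattern graphs, averaged over `eval_n`
#' held-out inputs. Patterns with an empty fired set contribute an
#' all-zero profile.
#'
#' @param data a dataset as returned by [make_images()]: a list with
#'   `train` and `test`, each holding `x` (rows = flattened images) and
#'   `y` (integer labels).
#' @param layer_sizes network architecture; default is
#'   `c(ncol(x), 80, 40, 20, 10)`.
#' @param epochs total training epochs.
#' @param checkpoints epochs at which to record the profile.
#' @param eval_n number of held-out inputs averaged per checkpoint.
#' @param edge_mode pattern-graph connectivity, see [fired_pattern()].
#' @param hyper Adam hyperparameters, see [train_epoch()].
#' @param seed integer seed covering initialization and batch order.
#' @return an `ann_trajectory` data.frame: one row per checkpoint with
#'   `epoch`, `accuracy`, `n_fired`, `cohesion` and the four measures.
#' @export
epoch_sweep <- function(data, layer_sizes = NULL, epochs = 100L,
                        checkpoints = c(1:10, seq(20L, 100L, by = 10L)),
                        eval_n = 100L, edge_mode = "cross",
                        hyper = list(), seed = NULL) {
  stopifnot(is.list(data), !is.null(data$train), !is.null(data$test))
  if (is.null(layer_sizes)) {
    layer_sizes <- c(ncol(data$train$x), 80L, 40L, 20L, 10L)
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  checkpoints <- checkpoints[checkpoints >= 1L & checkpoints <= epochs]
  eval_idx <- seq_len(min(eval_n, nrow(data$test$x)))
  with_seed(seed, {
    model <- mlp_init(layer_sizes)
    rows <- vector("list", length(checkpoints))
    ri <- 0L
    for (ep in seq_len(epochs)) {
      model <- train_epoch(model, data$train$x, data$train$y, hyper = hyper)
      if (!ep %in% checkpoints) next
      acc <- mlp_accuracy(model, data$test$x, data$test$y)
      prof <- matrix(0, nrow = length(eval_idx), ncol = 6L)
      for (q in seq_along(eval_idx)) {
        pat <- fired_pattern(model, data$test$x[eval_idx[q], ],
          edge_mode = edge_mode
        )
        mv <- if (length(pat$fired) == 0L) {
          c(0, 0, 0, 0)
        } else {
          as.numeric(measure_vector(pat$pattern_graph))
        }
        prof[q, ] <- c(mv, cohesion(pat), length(pat$fired))
      }
      avg <- colMeans(prof)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        epoch = ep, accuracy = acc,
        avg_degree = avg[1L], avg_pagerank = avg[2L],
        avg_clustering = avg[3L], avg_triangles = avg[4L],
        cohesion = avg[5L], n_fired = avg[6L]
      )
    }
    traj <- do.call(rbind, rows)
    rownames(traj) <- NULL
    class(traj) <- c("ann_trajectory", "trajectory", "data.frame")
    traj
  })
}

#' Pearson correlation between two trajectory series
#'
#' @param traj a trajectory data.frame (e.g. from [epoch_sweep()]).
#' @param a,b column names of the two series to correlate.
#' @return the Pearson correlation coefficient.
#' @export
trajectory_correlation <- function(traj, a, b) {
  if (!all(c(a, b) %in% names(traj))) {
    stop_parameter("both series must be columns of the trajectory")
  }
  stats::cor(traj[[a]], traj[[b]])
}
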