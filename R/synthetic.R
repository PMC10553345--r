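#' Synthetic separable image dataset
#'
#' A stand-in for MNIST-format digit data with the statistical structure
#' the training analysis needs — a learnable 10-class problem over
#' flattened grayscale images — without any visual realism. Each class
#' has a fixed random prototype in `[0, 1]^(side^2)`; samples are the
#' prototype plus Gaussian pixel noise, clipped back to `[0, 1]`, split
#' into stratified train/test sets. The class prototypes must stay
#' pairwise distinguishable: generation fails unless the minimum pairwise
#' prototype distance exceeds `4 * noise_sd`.
#'
#' @param n_classes number of classes (labels `0 .. n_classes - 1`).
#' @param side image side length; 28 matches the reference format, 8 is
#'   the reduced desk-scale profile.
#' @param n_train,n_test sample counts.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   units).
#' @param seed integer seed.
#' @return an object of class `synth_images`: list with `train` and
#'   `test` (each `x` matrix + `y` integer labels), `prototypes`,
#'   `side`, `noise_sd`.
#' @export
make_images <- function(n_classes = 10L, side = 28L, n_train = 2000L,
                        n_test = 500L, noise_sd = 0.1, seed = NULL) {
  n_classes <- as.integer(n_classes)
  d <- as.integer(side)^2
  with_seed(seed, {
    prototypes <- matrix(stats::runif(n_classes * d), nrow = n_classes)
    dmin <- min(stats::dist(prototypes))
    if (dmin <= 4 * noise_sd) {
      stop_parameter(sprintf(
        "prototypes are not separable: min pairwise distance %.3f <= 4 * noise_sd = %.3f",
        dmin, 4 * noise_sd
      ))
    }
    draw <- function(n) {
      y <- rep_len(seq_len(n_classes) - 1L, n) # balanced up to +/- 1
      y <- sample(y)
      x <- prototypes[y + 1L, , drop = FALSE] +
        matrix(stats::rnorm(n * d, sd = noise_sd), nrow = n)
      x[x < 0] <- 0
      x[x > 1] <- 1
      list(x = x, y = y)
    }
    structure(
      list(
        train = draw(n_train), test = draw(n_test),
        prototypes = prototypes, side = as.integer(side),
        noise_sd = noise_sd
      ),
      class = "synth_images"
    )
  })
}

#' @export
print.synth_images <- function(x, ...) {
  cat(sprintf(
    "<synth_images> %d classes, %dx%d pixels, %d train / %d test, noise sd %.3g\n",
    nrow(x$prototypes), x$side, x$side,
    nrow(x$train$x), nrow(x$test$x), x$noise_sd
  ))
  invisible(x)
}

#' Write/read an image dataset directory
#'
#' The on-disk layout is a directory with `images.csv` (one flattened
#' image per row, no header) and `labels.csv` (one integer label per
#' row), separately for train and test (`train_images.csv`, ...).
#'
#' @param data a `synth_images` (or any train/test `x`/`y` list).
#' @param dir directory path (created if needed).
#' @return `write_images()` returns `dir` invisibly; `read_images()` a
#'   train/test list usable by [epoch_sweep()].
#' @export
write_images <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in c("train", "test")) {
    utils::write.table(data[[split]]$x,
      file.path(dir, paste0(split, "_images.csv")),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
    utils::write.table(data[[split]]$y,
      file.path(dir, paste0(split, "_labels.csv")),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  invisible(dir)
}

#' @rdname write_images
#' @export
read_images <- function(dir) {
  load_split <- function(split) {
    x <- as.matrix(utils::read.csv(
      file.path(dir, paste0(split, "_images.csv")),
      header = FALSE
    ))
    dimnames(x) <- NULL
    y <- utils::read.csv(
      file.path(dir, paste0(split, "_labels.csv")),
      header = FALSE
    )[[1L]]
    list(x = x, y = as.integer(y))
  }
  list(train = load_split("train"), test = load_split("test"))
}

#' Synthetic publication stream
#'
#' Emulates a maturing research field. Each year introduces
#' `new_topics_per_year` fresh topics (each force-seeded into one of
#' that year's publications, so the cumulative node count grows
#' linearly), while the yearly publication volume itself grows at rate
#' `pub_growth` — scientific output compounds at a few percent per year,
#' and this volume growth is what makes cumulative co-occurrence (edge)
#' counts grow super-linearly relative to the topic vocabulary. Every
#' publication fills its remaining topic slots by sampling existing
#' topics without replacement with probability proportional to
#' `(past frequency + 1)^reuse_bias`; preferential reuse concentrates
#' co-occurrences on hub topics. `reuse_bias = 0` reduces the reuse step
#' to uniform sampling.
#'
#' @param years integer vector of consecutive years.
#' @param pubs_per_year publications in the first year.
#' @param pub_growth annual growth rate of the publication volume.
#' @param topics_per_pub topics per publication (>= 2 so every record
#'   contributes edges).
#' @param new_topics_per_year fresh topics injected per year.
#' @param reuse_bias preferential-reuse exponent (>= 0).
#' @param seed integer seed.
#' @return a publication data.frame (`year` + list-column `topics`).
#' @export
make_publications <- function(years = 1901:2000, pubs_per_year = 10L,
                              pub_growth = 0.04, topics_per_pub = 3L,
                              new_topics_per_year = 30L,
                              reuse_bias = 1, seed = NULL) {
  topics_per_pub <- as.integer(topics_per_pub)
  if (topics_per_pub < 2L) {
    stop_parameter("publications need >= 2 topics to contribute edges")
  }
  if (reuse_bias < 0) stop_parameter("`reuse_bias` must be >= 0")
  with_seed(seed, {
    vocab <- character(0)
    freq <- numeric(0)
    next_id <- 1L
    out_year <- integer(0)
    out_topics <- list()
    for (yi in seq_along(years)) {
      y <- years[yi]
      n_pubs <- max(1L, round(pubs_per_year * (1 + pub_growth)^(yi - 1L)))
      n_new <- max(
        new_topics_per_year,
        if (length(vocab) < topics_per_pub) topics_per_pub else 0L
      )
      fresh <- paste0("T", next_id:(next_id + n_new - 1L))
      next_id <- next_id + n_new
      vocab <- c(vocab, fresh)
      freq <- c(freq, numeric(n_new))
      carriers <- sample.int(n_pubs, length(fresh), replace = TRUE)
      for (pb in seq_len(n_pubs)) {
        seeded <- fresh[carriers == pb]
        if (length(seeded) > topics_per_pub) {
          seeded <- seeded[seq_len(topics_per_pub)]
        }
        need <- topics_per_pub - length(seeded)
        pool <- setdiff(seq_along(vocab), match(seeded, vocab))
        picked <- if (need > 0L) {
          w <- (freq[pool] + 1)^reuse_bias
          pool[sample.int(length(pool), need, prob = w)]
        } else {
          integer(0)
        }
        topics <- c(seeded, vocab[picked])
        idx <- match(topics, vocab)
        freq[idx] <- freq[idx] + 1
        out_year <- c(out_year, y)
        out_topics[[length(out_topics) + 1L]] <- topics
      }
    }
    records <- data.frame(year = out_year)
    records$topics <- out_topics
    records
  })
}

#' Synthetic connectome fixture file
#'
#' Writes a small wormatlas-dialect table around a planted Erdos-Renyi
#' graph. Every planted edge appears once with a sending-side type drawn
#' from `type_mix` (S, Sp, EJ, NMJ), and a fraction of edges additionally
#' emit the reversed receiving duplicate (type R or Rp) that the reader
#' excludes by default — so reading the file with the default exclusion
#' recovers exactly the planted edge set. The file is synthetic: it
#' mimics the layout and filtering semantics of the neuronal-wiring
#' table, not its biology.
#'
#' @param n neurons in the planted graph.
#' @param p planted edge probability.
#' @param directed_fraction fraction of edges that also emit a receiving
#'   duplicate row.
#' @param type_mix named probabilities over sending-side types.
#' @param seed integer seed.
#' @param path output TSV path.
#' @return invisibly, a list with `path` and the planted `graph`.
#' @export
make_toy_connectome <- function(n = 20L, p = 0.3, directed_fraction = 0.5,
                                type_mix = c(S = 0.4, Sp = 0.2, EJ = 0.2, NMJ = 0.2),
                                seed = NULL, path) {
  bad <- setdiff(names(type_mix), c("S", "Sp", "EJ", "NMJ"))
  if (length(bad)) {
    stop_parameter(sprintf(
      "`type_mix` may only contain sending-side types (got %s)",
      paste(bad, collapse = ", ")
    ))
  }
  with_seed(seed, {
    ids <- sprintf("N%03d", seq_len(n))
    planted <- er_gnp(n, p)
    planted$nodes <- ids
    m <- n_edges(planted)
    type <- sample(names(type_mix), m, replace = TRUE, prob = type_mix)
    count <- sample.int(20L, m, replace = TRUE)
    a <- ids[planted$from]
    b <- ids[planted$to]
    rows <- data.frame(
      neuron1 = a, neuron2 = b, type = type, count = count,
      stringsAsFactors = FALSE
    )
    dup <- stats::runif(m) < directed_fraction
    if (any(dup)) {
      rtype <- ifelse(type[dup] == "Sp", "Rp", "R")
      rows <- rbind(rows, data.frame(
        neuron1 = b[dup], neuron2 = a[dup], type = rtype, count = count[dup],
        stringsAsFactors = FALSE
      ))
    }
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    writeLines(
      c(
        "Neuron1\tNeuron2\tType\tNbr",
        sprintf("%s\t%s\t%s\t%d", rows$neuron1, rows$neuron2, rows$type, rows$count)
      ),
      path
    )
    invisible(list(path = path, graph = planted))
  })
}
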