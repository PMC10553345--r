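#' Classify a trajectory as Up, Down or Flat
#'
#' Fits a least-squares slope of the series against its index, divides
#' it by the series' mean absolute value (so the rule is scale-free),
#' and reports the sign: normalized slopes smaller than `flat_tol` per
#' index step are Flat. Slope sign is used rather than a first-vs-last
#' comparison because several of the trajectories under study are
#' jagged.
#'
#' @param series ordered numeric vector, length >= 3, no NAs.
#' @param flat_tol normalized-slope threshold for Flat, default 0.01.
#' @return `"Up"`, `"Down"` or `"Flat"`.
#' @examples
#' classify_trend(1:10) # "Up"
#' classify_trend(1 / (1:10)) # "Down"
#' classify_trend(rep(2, 5)) # "Flat"
#' @export
classify_trend <- function(series, flat_tol = 0.01) {
  series <- as.numeric(series)
  if (length(series) < 3L) {
    stop_parameter("trend classification needs a series of length >= 3")
  }
  if (anyNA(series)) stop_parameter("series contains NA")
  idx <- seq_along(series)
  slope <- stats::cov(idx, series) / stats::var(idx)
  scale <- mean(abs(series))
  if (scale == 0) {
    return("Flat")
  }
  norm <- slope / scale
  if (abs(norm) < flat_tol) "Flat" else if (norm > 0) "Up" else "Down"
}

trend_measures <- c("avg_degree", "avg_pagerank", "avg_clustering", "avg_triangles")

#' Cross-system trend summary
#'
#' Classifies the four measure trajectories of every system into
#' Up/Down/Flat with one shared rule, yielding the machine twin of the
#' cross-system comparison table.
#'
#' @param trajectories named list of trajectory data.frames, each
#'   containing the four measure columns in checkpoint order.
#' @param flat_tol passed to [classify_trend()].
#' @return a `trend_summary` data.frame: one row per system, columns
#'   `system` plus the four measures holding direction labels.
#' @export
summarize_trends <- function(trajectories, flat_tol = 0.01) {
  if (length(trajectories) == 0L) {
    stop_parameter("`trajectories` must contain at least one system")
  }
  if (is.null(names(trajectories)) || any(!nzchar(names(trajectories)))) {
    stop_parameter("`trajectories` must be a named list (system labels)")
  }
  rows <- lapply(names(trajectories), function(sys) {
    traj <- trajectories[[sys]]
    missing <- setdiff(trend_measures, names(traj))
    if (length(missing)) {
      stop_parameter(sprintf(
        "trajectory '%s' lacks column(s): %s",
        sys, paste(missing, collapse = ", ")
      ))
    }
    dirs <- vapply(
      trend_measures,
      function(mcol) classify_trend(traj[[mcol]], flat_tol),
      character(1)
    )
    cbind(
      data.frame(system = sys, stringsAsFactors = FALSE),
      as.data.frame(as.list(dirs), stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trend_summary", "data.frame")
  out
}

#' @export
print.trend_summary <- function(x, ...) {
  cat("<trend_summary> direction of each measure as the network grows/learns\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write a trend summary and check it against an expected pattern
#'
#' Writes the summary as CSV and a human-readable text table. When an
#' expected-pattern table is given (data.frame or CSV path; empty/NA
#' cells are unasserted), each asserted cell is compared and mismatches
#' are reported.
#'
#' @param summary a `trend_summary`.
#' @param out_dir output directory (created if needed).
#' @param expected optional expected-pattern data.frame or CSV path with
#'   the same `system` + measure columns.
#' @return invisibly, a list with `ok` (TRUE iff every asserted cell
#'   matches) and `mismatches` (data.frame of failures).
#' @export
trend_report <- function(summary, out_dir, expected = NULL) {
  if (!inherits(summary, "data.frame") || nrow(summary) == 0L) {
    stop_parameter("`summary` must be a non-empty trend summary")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary, file.path(out_dir, "trend_summary.csv"),
    row.names = FALSE
  )
  txt <- utils::capture.output(print.data.frame(summary, row.names = FALSE))
  writeLines(txt, file.path(out_dir, "trend_summary.txt"))
  result <- list(ok = TRUE, mismatches = data.frame(
    system = character(0), measure = character(0),
    expected = character(0), observed = character(0)
  ))
  if (!is.null(expected)) {
    if (is.character(expected)) {
      expected <- utils::read.csv(expected, stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(expected))) {
      sys <- expected$system[r]
      obs_row <- summary[summary$system == sys, , drop = FALSE]
      for (mcol in intersect(trend_measures, names(expected))) {
        want <- expected[[mcol]][r]
        if (is.na(want) || !nzchar(want)) next
        got <- if (nrow(obs_row)) obs_row[[mcol]][1L] else NA_character_
        if (!identical(got, want)) {
          result$mismatches <- rbind(result$mismatches, data.frame(
            system = sys, measure = mcol,
            expected = want, observed = as.character(got)
          ))
        }
      }
    }
    result$ok <- nrow(result$mismatches) == 0L
    if (!result$ok) {
      message(
        "trend mismatches:\n",
        paste(utils::capture.output(print(result$mismatches)), collapse = "\n")
      )
    }
  }
  invisible(result)
}

#' Run the full cross-system comparison pipeline
#'
#' Executes all four system pipelines — the ANN epoch sweep on a
#' synthetic image set, the cumulative topic network on a synthetic
#' publication stream, the Erdos-Renyi G(n, p) growth experiment, and
#' the animal density-projection sweep — classifies every trajectory,
#' writes per-system trajectory CSVs, the trend-summary CSV and a JSON
#' run manifest into `out_dir`, and checks the summary against the
#' packaged expected-pattern file. Per-stage timings go to `stderr`.
#'
#' The `"test"` profile runs everything at desk scale (8x8 images,
#' 5 growth repetitions, roster capped at 5,600 neurons, 1 seed per
#' cell); `"full"` uses the reference conditions (28x28 images, 20
#' repetitions, the whole roster).
#'
#' @param out_dir output directory.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param profile `"test"` or `"full"`.
#' @return invisibly, a list with `trajectories` (named list),
#'   `summary`, and `report` (the expected-pattern check).
#' @export
run_all <- function(out_dir, seed = 1L, profile = c("test", "full")) {
  profile <- match.arg(profile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cfg <- if (profile == "test") {
    list(
      side = 8L, n_train = 1500L, n_test = 400L, eval_n = 50L,
      growth_reps = 5L, roster_max_n = 5600L, sweep_seeds = 1L
    )
  } else {
    list(
      side = 28L, n_train = 10000L, n_test = 2000L, eval_n = 100L,
      growth_reps = 20L, roster_max_n = Inf, sweep_seeds = 1:3
    )
  }
  stage <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    message(sprintf(
      "[run_all] %-16s %.1fs", label, proc.time()[["elapsed"]] - t0
    ))
    res
  }

  imgs <- stage("synth images", make_images(
    side = cfg$side, n_train = cfg$n_train, n_test = cfg$n_test,
    noise_sd = 0.1, seed = seed + 11L
  ))
  ann <- stage("ann sweep", epoch_sweep(imgs,
    epochs = 100L, eval_n = cfg$eval_n, seed = seed + 12L
  ))

  pubs <- stage("synth pubs", make_publications(seed = seed + 21L))
  topic <- stage("topic nets", yearly_trajectory(cumulative_networks(pubs)))

  er <- stage("er growth", growth_experiment("gnp",
    reps = cfg$growth_reps, seed = seed + 31L
  ))

  sweep <- stage("animal sweep", projection_sweep(
    seeds = seed + 41L + seq_along(cfg$sweep_seeds) - 1L,
    max_n = cfg$roster_max_n
  ))
  animal <- projection_series(sweep, p_index = 1L)

  trajectories <- list(
    ann = ann, topic = topic, er_growth = er, animal = animal
  )
  for (sys in names(trajectories)) {
    utils::write.csv(trajectories[[sys]],
      file.path(out_dir, paste0("trajectory_", sys, ".csv")),
      row.names = FALSE
    )
  }
  utils::write.csv(sweep, file.path(out_dir, "projection_sweep.csv"),
    row.names = FALSE
  )
  summary <- summarize_trends(trajectories)
  expected_path <- system.file("extdata", "expected_trends.csv",
    package = "netpattern"
  )
  report <- trend_report(summary, out_dir,
    expected = if (nzchar(expected_path)) expected_path else NULL
  )
  manifest <- list(
    package = "netpattern",
    version = as.character(utils::packageVersion("netpattern")),
    seed = seed, profile = profile, config = cfg,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(list(trajectories = trajectories, summary = summary, report = report))
}
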