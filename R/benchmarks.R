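#' Unsupervised score of a clustering against embedded ground truth
#'
#' @param cs a `cluster_set` (or per-window label vector).
#' @param truth a `synth_truth` object.
#' @param ws the `window_set` the clustering refers to.
#' @return The `f_us` score (see [f_unsupervised()]).
#' @export
score_detection <- function(cs, truth, ws) {
  labels <- if (inherits(cs, "cluster_set")) {
    cluster_labels(cs, ws$n_windows)
  } else {
    cs
  }
  f_unsupervised(labels, window_truth(truth, ws))$f_us
}

#' Best unsupervised score over a clustering-parameter grid
#'
#' Computes the similarity stage once, then re-runs the clustering stage
#' over a grid of (`min_pts`, `v`) values and returns the best F-score,
#' mirroring the benchmark protocol of searching the parameter set that
#' maximises detection performance.
#'
#' @param data a [spike_data] object.
#' @param truth the matching `synth_truth`.
#' @param config a [pipeline_config] (its `min_pts` and `v` are ignored).
#' @param min_pts_grid,v_grid parameter values to try.
#' @return List with `f_us` (best score), `best` (the winning parameters),
#'   `grid` (data frame of all scores), `reduction_rate`.
#' @export
best_fus_over_grid <- function(data, truth, config,
                               min_pts_grid = c(2, 5, 10, 15, 20),
                               v_grid = c(2, 5, 10, 15, 20)) {
  sim <- similarity_stage(data, config)
  true_lab <- window_truth(truth, sim$windows)
  D <- as.matrix(distance_from_similarity(sim$store))
  rows <- list()
  best <- list(f_us = -Inf)
  for (mp in min_pts_grid) {
    flt <- optics_filter(D, min_pts = mp, xi = config$xi)
    for (vv in v_grid) {
      f <- if (length(flt$retained) == 0) {
        f_unsupervised(rep(NA_integer_, sim$windows$n_windows), true_lab)$f_us
      } else {
        g <- build_similarity_graph(sim$store, flt$retained,
                                    edge_rule = config$edge_rule)
        cs <- suppressWarnings(copra(g, v = vv,
                                     max_iter = config$copra_max_iter,
                                     seed = derive_seed(config$seed, "copra")))
        score_detection(cs, truth, sim$windows)
      }
      rows[[length(rows) + 1L]] <- data.frame(min_pts = mp, v = vv, f_us = f)
      if (f > best$f_us) best <- list(f_us = f, min_pts = mp, v = vv)
    }
  }
  list(f_us = best$f_us, best = best, grid = do.call(rbind, rows),
       reduction_rate = sim$reduction_rate)
}

#' Mean unsupervised score of a benchmark regime
#'
#' Generates `n_datasets` datasets of the named regime and evaluates the
#' pipeline on each; with a grid, the clustering parameters are searched
#' per dataset.
#'
#' @param name regime name, see [benchmark_suite()].
#' @param n_datasets number of datasets.
#' @param seed master seed.
#' @param min_pts_grid,v_grid clustering-parameter grid; pass a single
#'   value each to skip the search.
#' @param ... forwarded to [benchmark_suite()] (e.g. `duration_s`).
#' @return List with `mean_f_us`, `sd_f_us`, `scores` (per dataset),
#'   `n_datasets`.
#' @export
evaluate_benchmark <- function(name, n_datasets, seed = 1L,
                               min_pts_grid = NULL, v_grid = NULL, ...) {
  sets <- benchmark_suite(name, n_datasets, seed = seed, ...)
  scores <- vapply(seq_along(sets), function(d) {
    ds <- sets[[d]]
    cfg <- ds$config
    cfg$seed <- derive_seed(seed, paste0(name, "-run"), d)
    if (is.null(min_pts_grid)) {
      det <- run_pipeline(ds$data, cfg, profiles = FALSE)
      score_detection(det$clusters, ds$truth, det$windows)
    } else {
      best_fus_over_grid(ds$data, ds$truth, cfg,
                         min_pts_grid = min_pts_grid,
                         v_grid = v_grid %||% min_pts_grid)$f_us
    }
  }, numeric(1))
  list(mean_f_us = mean(scores), sd_f_us = sd(scores), scores = scores,
       n_datasets = n_datasets)
}
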