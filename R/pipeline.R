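#' Pipeline configuration
#'
#' Bundles all stage parameters of the detection pipeline. A single master
#' seed fans out to per-stage seeds deterministically.
#'
#' @param window_s sliding-window length T_w in seconds.
#' @param bin_s bin size in seconds.
#' @param stride_s window stride (default: non-overlapping).
#' @param alpha gap-penalty weight of the edit similarity.
#' @param n3 assumed extra coincident neurons for the Jaccard_2 threshold.
#' @param p_low,p_high banding probabilities at the two Jaccard thresholds.
#' @param search_max band-parameter grid bound.
#' @param min_pts OPTICS minimum dense-group size.
#' @param xi OPTICS steepness parameter.
#' @param v COPRA maximum labels per node.
#' @param copra_max_iter COPRA sweep limit.
#' @param edge_rule similarity-graph rule, see [build_similarity_graph()].
#' @param seed master seed.
#' @return An object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(window_s = 0.2, bin_s = 0.01, stride_s = window_s,
                            alpha = 1, n3 = 10, p_low = 0.1, p_high = 0.8,
                            search_max = 50, min_pts = 5, xi = 0.05, v = 5,
                            copra_max_iter = 100, edge_rule = "positive",
                            seed = 1L) {
  structure(list(window_s = window_s, bin_s = bin_s, stride_s = stride_s,
                 alpha = alpha, n3 = n3, p_low = p_low, p_high = p_high,
                 search_max = search_max, min_pts = min_pts, xi = xi, v = v,
                 copra_max_iter = copra_max_iter, edge_rule = edge_rule,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Pairwise edit similarities of a recording's windows, MinHash-pruned
#'
#' The expensive first half of the pipeline: segment the recording,
#' estimate the data-driven Jaccard thresholds, choose band parameters,
#' build MinHash signatures, collect candidate window pairs by banding and
#' score them with the edit similarity.
#'
#' @param data a [spike_data] object.
#' @param config a [pipeline_config].
#' @return List with `windows` (`window_set`), `store`
#'   (`similarity_store`), `band_params`, `reduction_rate` (fraction of all
#'   unordered pairs actually scored, the "R.R."), `n_candidates`.
#' @export
similarity_stage <- function(data, config) {
  stopifnot(inherits(data, "spike_data"), inherits(config, "pipeline_config"))
  cfg <- window_config(config$window_s, config$bin_s, config$stride_s)
  ws <- segment_windows(data, cfg)
  setup <- band_setup(data, cfg, n3 = config$n3, p_low = config$p_low,
                      p_high = config$p_high, search_max = config$search_max)
  thr <- setup$thresholds
  bp <- setup$band_params
  masks <- activity_masks(ws)
  sig <- build_signatures(masks, bp, seed = derive_seed(config$seed, "minhash"))
  cand <- candidate_pairs(sig)
  if (nrow(cand) == 0) stop("MinHash banding produced no candidate pairs")
  store <- score_candidate_pairs(ws, cand, alpha = config$alpha)
  n_pairs <- ws$n_windows * (ws$n_windows - 1) / 2
  list(windows = ws, store = store, band_params = bp,
       thresholds = thr, n_candidates = nrow(cand),
       reduction_rate = nrow(cand) / n_pairs)
}

#' Run the full detection pipeline
#'
#' Segment, prune, score, cluster and (optionally) profile: the complete
#' unsupervised detection of repeated cell-assembly sequences in one call.
#'
#' @param data a [spike_data] object.
#' @param config a [pipeline_config].
#' @param profiles build a consensus profile per detected cluster
#'   (default TRUE).
#' @return An object of class `assembly_detection`: list with `clusters`
#'   (a `cluster_set`), `labels` (per-window labels, `NA` = noise),
#'   `profiles` (list of `assembly_profile` or NULL), `store`, `windows`,
#'   `band_params`, `reduction_rate` and `config`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), profiles = TRUE) {
  sim <- similarity_stage(data, config)
  cs <- cluster_pipeline(sim$store, min_pts = config$min_pts, v = config$v,
                         xi = config$xi, edge_rule = config$edge_rule,
                         max_iter = config$copra_max_iter,
                         seed = config$seed)
  labels <- cluster_labels(cs, sim$windows$n_windows)
  profs <- NULL
  if (profiles && nrow(cs$membership) > 0) {
    z <- zscore_windows(sim$windows)
    res <- resolve_overlaps(cs)
    profs <- lapply(sort(unique(res$cluster)), function(cl) {
      members <- lapply(res$node[res$cluster == cl], z$get)
      if (length(members) < 2) return(NULL)
      build_profile(members, alpha = config$alpha,
                    seed = derive_seed(config$seed, "profile", cl))
    })
    names(profs) <- sort(unique(res$cluster))
  }
  structure(list(clusters = cs, labels = labels, profiles = profs,
                 store = sim$store, windows = sim$windows,
                 band_params = sim$band_params,
                 reduction_rate = sim$reduction_rate, config = config),
            class = "assembly_detection")
}

#' @export
print.assembly_detection <- function(x, ...) {
  k <- length(unique(x$clusters$membership$cluster))
  cat(sprintf(paste0("<assembly_detection> %d clusters, %d / %d windows ",
                     "assigned, %.1f%% of pairs scored\n"),
              k, sum(!is.na(x$labels)), length(x$labels),
              100 * x$reduction_rate))
  invisible(x)
}

#' Two-dimensional embedding of window distances for visualisation
#'
#' Projects the pairwise distance structure to 2-D, for plotting only.
#' Classical metric scaling (`cmdscale`) is the deterministic default;
#' `"nmds"` uses non-metric multidimensional scaling (vegan).
#'
#' @param D a `distance_store` or dense distance matrix.
#' @param method `"cmdscale"` or `"nmds"`.
#' @param seed integer seed (used by `"nmds"`).
#' @return Numeric matrix (points x 2).
#' @export
embed_2d <- function(D, method = c("cmdscale", "nmds"), seed = 1L) {
  method <- match.arg(method)
  if (inherits(D, "distance_store")) D <- as.matrix(D)
  if (method == "cmdscale") {
    y <- stats::cmdscale(stats::as.dist(D), k = 2)
  } else {
    if (!requireNamespace("vegan", quietly = TRUE)) {
      stop("the nmds method needs the vegan package")
    }
    y <- with_seed(seed, vegan::monoMDS(stats::as.dist(D), k = 2)$points)
  }
  unname(as.matrix(y))
}
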