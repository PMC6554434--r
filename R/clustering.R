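#' Similarity graph over retained windows
#'
#' Builds the weighted undirected graph on which community detection runs.
#' The default rule connects every computed pair with positive edit
#' similarity (the MinHash stage has already restricted computation to
#' plausible pairs); alternatives are mutual strongest neighbours
#' (`"topk"`: an edge is kept when each endpoint ranks the other among its
#' `k` strongest, bounding the degree by `k`) or a fixed similarity
#' threshold (`"threshold"`).
#'
#' @param store a `similarity_store`.
#' @param retained window indices surviving the noise filter.
#' @param edge_rule one of `"positive"`, `"topk"`, `"threshold"`.
#' @param k neighbours per node for `"topk"`.
#' @param threshold minimal similarity for `"threshold"`.
#' @return An `igraph` graph whose vertex names are window indices.
#' @export
build_similarity_graph <- function(store, retained,
                                   edge_rule = c("positive", "topk", "threshold"),
                                   k = 10, threshold = 0) {
  stopifnot(inherits(store, "similarity_store"))
  edge_rule <- match.arg(edge_rule)
  if (length(retained) == 0) stop("no retained windows to build a graph from")
  pr <- store$pairs
  pr <- pr[pr$i %in% retained & pr$j %in% retained, , drop = FALSE]
  pr <- switch(edge_rule,
    positive = pr[pr$E > 0, , drop = FALSE],
    threshold = pr[pr$E > threshold, , drop = FALSE],
    topk = {
      pp <- pr[pr$E > 0, , drop = FALSE]
      long <- rbind(data.frame(a = pp$i, b = pp$j, E = pp$E),
                    data.frame(a = pp$j, b = pp$i, E = pp$E))
      long <- long[order(long$a, -long$E), , drop = FALSE]
      sel <- unlist(lapply(split(seq_len(nrow(long)), long$a),
                           function(ix) head(ix, k)), use.names = FALSE)
      long <- long[sel, , drop = FALSE]
      i2 <- pmin(long$a, long$b); j2 <- pmax(long$a, long$b)
      key <- paste(i2, j2)
      keep <- key %in% key[duplicated(key)] & !duplicated(key) # mutual
      data.frame(i = i2[keep], j = j2[keep], E = long$E[keep])
    })
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pr$i), to = as.character(pr$j),
               weight = pr$E),
    directed = FALSE,
    vertices = data.frame(name = as.character(sort(retained))))
  if (igraph::ecount(g) == 0 && nrow(store$pairs) > 0 &&
      edge_rule == "positive") {
    warning("similarity graph has no positive-weight edges")
  }
  g
}

#' Two-stage clustering of windows: OPTICS noise removal, then COPRA
#'
#' Applies the two qualitatively different clustering stages in sequence:
#' a density-based stage ([optics_filter()]) removes windows that sit in no
#' dense region of the edit-distance space, then overlapping label
#' propagation ([copra()]) on the similarity graph of the survivors fixes
#' the cluster labels. The combination separates adjacent clusters (which
#' the density stage alone cannot) while rejecting background windows
#' (which label propagation alone cannot).
#'
#' @param store a `similarity_store` over all windows.
#' @param min_pts OPTICS minimum dense-group size.
#' @param v COPRA maximum labels per node.
#' @param xi OPTICS steepness parameter.
#' @param edge_rule graph construction rule, see [build_similarity_graph()].
#' @param max_iter COPRA sweep limit.
#' @param seed integer seed (community detection is stochastic).
#' @return A `cluster_set` (see [copra()]) whose `membership$node` values
#'   are window indices; windows absent from it are noise. Attribute
#'   `retained` lists the windows surviving the density stage.
#' @export
cluster_pipeline <- function(store, min_pts, v, xi = 0.05,
                             edge_rule = "positive", max_iter = 100,
                             seed = 1L) {
  D <- distance_from_similarity(store)
  flt <- optics_filter(as.matrix(D), min_pts = min_pts, xi = xi)
  if (length(flt$retained) == 0) {
    cs <- structure(list(membership = data.frame(node = integer(0),
                                                 cluster = integer(0),
                                                 coefficient = numeric(0)),
                         converged = TRUE, n_iter = 0L),
                    class = "cluster_set")
    attr(cs, "retained") <- integer(0)
    return(cs)
  }
  g <- build_similarity_graph(store, flt$retained, edge_rule = edge_rule)
  cs <- suppressWarnings(copra(g, v = v, max_iter = max_iter,
                               seed = derive_seed(seed, "copra")))
  attr(cs, "retained") <- flt$retained
  cs
}

#' Cluster memberships as a per-window label vector
#'
#' @param cs a `cluster_set`.
#' @param n_windows total number of windows.
#' @return Integer vector of length `n_windows`; `NA` marks noise windows.
#'   Overlaps are resolved by the highest belonging coefficient.
#' @export
cluster_labels <- function(cs, n_windows) {
  lab <- rep(NA_integer_, n_windows)
  res <- resolve_overlaps(cs)
  lab[res$node] <- res$cluster
  lab
}
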