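# OPTICS (Ordering Points To Identify the Clustering Structure) on a
# precomputed distance matrix, with xi-steep cluster extraction from the
# reachability plot. Used as the noise-removal stage: windows that fall in
# no dense region of the edit-distance space are discarded before community
# detection. No installed package offers OPTICS on precomputed distances,
# so the ordering (C++) and the xi extraction (below) are implemented here;
# the xi extraction follows the published steep-area algorithm, including
# the later sign corrections for Definitions 9 and 11.

#' OPTICS clustering on a precomputed distance matrix
#'
#' Computes the OPTICS reachability ordering (with an infinite
#' neighbourhood radius) and extracts clusters from the reachability plot
#' with the xi-steep method: cluster boundaries are places where the plot
#' falls (rises) by a relative factor of at least `xi`.
#'
#' @param D dense symmetric distance matrix.
#' @param min_pts minimum number of points of a dense group (>= 2); also the
#'   smallest extracted cluster size.
#' @param xi minimum relative steepness of a cluster boundary (default 0.05).
#' @return A list with `order` (visit order), `reachability` (per point, in
#'   original index order), `core_dist`, `labels` (integer per point, 0 =
#'   noise) and `clusters` (list of original-index vectors).
#' @export
optics <- function(D, min_pts, xi = 0.05) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n == ncol(D), min_pts >= 2, xi > 0, xi < 1)
  if (n < min_pts) {
    warning("fewer points than min_pts; everything is noise")
    return(list(order = seq_len(n), reachability = rep(Inf, n),
                core_dist = rep(Inf, n), labels = integer(n),
                clusters = list()))
  }
  res <- cpp_optics_order(D, as.integer(min_pts))
  ord <- res$order
  reach_plot <- res$reachability[ord]
  cl_ranges <- xi_clusters(reach_plot, min_pts, xi, min_cluster_size = min_pts)
  # a "cluster" spanning (almost) the whole ordering conveys no grouping:
  # on featureless data (e.g. all points mutually equidistant) the steep
  # transition to the terminal padding would otherwise promote the entire
  # plot to one cluster
  cl_ranges <- Filter(function(rg) rg[2] - rg[1] + 1 < 0.9 * n, cl_ranges)
  labels_plot <- integer(n) # 0 = noise; smaller (leaf) clusters claim first
  lab <- 0L
  clusters <- list()
  for (rg in cl_ranges) {
    span <- rg[1]:rg[2]
    if (all(labels_plot[span] == 0L)) {
      lab <- lab + 1L
      labels_plot[span] <- lab
      clusters[[lab]] <- sort(ord[span])
    }
  }
  labels <- integer(n)
  labels[ord] <- labels_plot
  # dense regions for noise removal: the disjoint leaf clusters, plus any
  # nested parent range that is essentially a single valley -- at least 90%
  # of its span lies well below its boundary levels (factor 1 - 2 xi).
  # Edit-similarity distances are integer-quantised, so a deep valley whose
  # floor spans two or three adjacent integer levels is split by the
  # relative-steepness test into nested sub-clusters; the mostly-deep
  # parent rule merges such valleys back while still rejecting super-ranges
  # that span the noise plateau between genuine clusters.
  rp_pad <- c(reach_plot, Inf)
  dense <- lapply(clusters, identity)
  for (rg in cl_ranges) {
    bound <- min(rp_pad[rg[1]], rp_pad[rg[2] + 1])
    cut <- (1 - 2 * xi) * bound
    if (!is.finite(cut)) next
    span <- rg[1]:rg[2]
    deep <- span[reach_plot[span] <= cut | span == rg[1]]
    if (length(deep) < min_pts || length(deep) < 0.9 * length(span)) next
    # depth contrast: a genuine valley sits well below its boundary level
    # in (nearly) its whole extent; without this, featureless plots
    # (quantised shallow levels, or distance measures saturating at their
    # ceiling) would pass
    if (bound < 2 * stats::quantile(reach_plot[deep], 0.9, names = FALSE)) next
    dense[[length(dense) + 1L]] <- sort(ord[deep])
  }
  list(order = ord, reachability = res$reachability, core_dist = res$core_dist,
       labels = labels, clusters = clusters, dense_regions = dense)
}

#' Density-based noise removal of windows
#'
#' Runs [optics()] on the distances derived from the edit-similarity store
#' and keeps only the windows that belong to some dense tentative group;
#' all other windows are discarded as noise before community detection.
#'
#' @param D a `distance_store` (from [distance_from_similarity()]) or a
#'   dense distance matrix.
#' @param min_pts minimum dense-group size.
#' @param xi steepness parameter of the cluster extraction.
#' Retention uses every extracted dense region (nested parents included),
#' not only the disjoint leaf clusters: the later community-detection stage
#' is responsible for splitting dense regions into separate assemblies, so
#' dropping points of a parent region here would discard genuine signal.
#'
#' @return A list with `retained` (sorted window indices in some dense
#'   group), `groups` (list of disjoint leaf clusters) and the full
#'   [optics()] result as `optics`.
#' @export
optics_filter <- function(D, min_pts, xi = 0.05) {
  if (inherits(D, "distance_store")) D <- as.matrix(D)
  o <- optics(D, min_pts, xi)
  list(retained = sort(unique(unlist(o$dense_regions))), groups = o$clusters,
       optics = o)
}

# xi-steep cluster extraction from an ordered reachability plot.
# Returns a list of c(start, end) index ranges (1-based, inclusive) into the
# ordering, smaller (leaf) clusters before the larger ones that contain them.
xi_clusters <- function(reach, min_pts, xi, min_cluster_size = min_pts) {
  n <- length(reach)
  rp <- c(reach, Inf) # padding finds clusters that touch the end of the plot
  xc <- 1 - xi
  ratio <- rp[1:n] / rp[2:(n + 1)]
  steep_up <- ratio <= xc
  steep_down <- ratio >= 1 / xc
  down <- ratio > 1
  up <- ratio < 1
  steep_up[is.na(steep_up)] <- FALSE
  steep_down[is.na(steep_down)] <- FALSE
  down[is.na(down)] <- FALSE
  up[is.na(up)] <- FALSE

  sdas <- list() # steep-down areas still eligible as cluster starts
  clusters <- list()
  index <- 1L
  mib <- 0 # maximum reachability in between

  for (si in which(steep_up | steep_down)) {
    if (si < index) next
    mib <- max(mib, max(rp[index:si]))
    if (steep_down[si]) {
      sdas <- filter_sdas(sdas, mib, xc, rp)
      d_start <- si
      d_end <- extend_region(steep_down, up, d_start, min_pts)
      sdas[[length(sdas) + 1L]] <- list(start = d_start, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- rp[index]
    } else {
      sdas <- filter_sdas(sdas, mib, xc, rp)
      u_start <- si
      u_end <- extend_region(steep_up, down, u_start, min_pts)
      index <- u_end + 1L
      mib <- rp[index]
      u_clusters <- list()
      for (D in sdas) {
        c_start <- D$start
        c_end <- u_end
        if (rp[c_end + 1] * xc < D$mib) next
        d_max <- rp[D$start]
        if (d_max * xc >= rp[c_end + 1]) {
          # shrink from the left to the level of the cluster end
          while (rp[c_start + 1] > rp[c_end + 1] && c_start < D$end) {
            c_start <- c_start + 1L
          }
        } else if (rp[c_end + 1] * xc >= d_max) {
          # shrink from the right to the level of the cluster start
          while (c_end > u_start && rp[c_end - 1] > d_max) {
            c_end <- c_end - 1L
          }
        }
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > D$end) next
        if (c_end < u_start) next
        u_clusters[[length(u_clusters) + 1L]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(u_clusters)) # smaller clusters first
    }
  }
  clusters
}

# extend a steep region, allowing at most min_pts consecutive non-steep
# points that still move in the right direction
extend_region <- function(steep, xward, start, min_pts) {
  n <- length(steep)
  non_xward <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep[index]) {
      non_xward <- 0L
      end <- index
    } else if (!xward[index]) {
      non_xward <- non_xward + 1L
      if (non_xward > min_pts) break
    } else {
      return(end)
    }
    index <- index + 1L
  }
  end
}

# drop steep-down areas that can no longer start a cluster given the
# maximum in between, and update the mib of the survivors
filter_sdas <- function(sdas, mib, xc, rp) {
  if (is.infinite(mib)) return(list())
  keep <- vapply(sdas, function(s) mib <= rp[s$start] * xc, logical(1))
  sdas <- sdas[keep]
  lapply(sdas, function(s) {
    s$mib <- max(s$mib, mib)
    s
  })
}
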