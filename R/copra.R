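# COPRA: Community Overlap PRopagation Algorithm (overlapping label
# propagation with at most v community labels per node). Implemented here
# on igraph graphs; no installed package provides the overlapping variant.

#' Overlapping community detection by label propagation (COPRA)
#'
#' Each node carries up to `v` (label, belonging coefficient) pairs.
#' In every sweep the nodes are visited in a seeded random order and each
#' node's labels are replaced by the edge-weighted average of its
#' neighbours' labels; labels whose coefficient falls below `1 / v` are
#' pruned (keeping the best label when all would vanish, ties broken at
#' random) and the remaining coefficients renormalised. Propagation stops
#' when the per-label node counts repeat between sweeps, or after
#' `max_iter` sweeps (with a warning flag).
#'
#' @param graph an `igraph` undirected graph; edge attribute `weight` is
#'   used when present.
#' @param v maximum number of community labels per node (>= 1).
#' @param max_iter maximum number of propagation sweeps.
#' @param seed integer seed for visit order and tie-breaking.
#' @return An object of class `cluster_set`: data frame `membership` with
#'   columns `node` (vertex name as integer if possible), `cluster`,
#'   `coefficient`, plus attributes `converged` and `n_iter`. Communities
#'   with fewer than 2 members are dropped.
#' @export
copra <- function(graph, v, max_iter = 100, seed = 1L) {
  stopifnot(igraph::is_igraph(graph), v >= 1)
  n <- igraph::vcount(graph)
  if (n == 0) stop("empty graph")
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, as.integer)
  has_w <- "weight" %in% igraph::edge_attr_names(graph)
  wts <- lapply(seq_len(n), function(i) {
    eids <- igraph::incident(graph, i, mode = "all")
    w <- if (has_w) igraph::edge_attr(graph, "weight", eids) else
      rep(1, length(eids))
    w
  })
  # align weights with adjacency order
  for (i in seq_len(n)) {
    eids <- igraph::incident(graph, i, mode = "all")
    ends <- igraph::ends(graph, eids, names = FALSE)
    nb <- ifelse(ends[, 1] == i, ends[, 2], ends[, 1])
    o <- match(adj[[i]], nb)
    wts[[i]] <- wts[[i]][o]
  }

  # labels stored as parallel integer/numeric vectors per node
  lab <- lapply(seq_len(n), function(i) i)
  coef <- lapply(seq_len(n), function(i) 1)
  thresh <- 1 / v
  hist_prev <- NULL
  converged <- FALSE
  n_iter <- 0L

  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      n_iter <- it
      for (i in sample.int(n)) {
        nbs <- adj[[i]]
        if (!length(nbs)) next
        w <- wts[[i]]
        pooled_lab <- unlist(lab[nbs], use.names = FALSE)
        pooled_coef <- unlist(lapply(seq_along(nbs), function(t) {
          coef[[nbs[t]]] * w[t]
        }), use.names = FALSE)
        agg <- rowsum(pooled_coef, pooled_lab)
        val <- agg[, 1] / sum(agg)
        labs <- as.integer(rownames(agg))
        keep <- val >= thresh
        if (!any(keep)) {
          best <- which(val == max(val))
          if (length(best) > 1) best <- sample(best, 1)
          lab[[i]] <- labs[best]
          coef[[i]] <- 1
        } else {
          lab[[i]] <- labs[keep]
          coef[[i]] <- val[keep] / sum(val[keep])
        }
      }
      all_labs <- unlist(lab, use.names = FALSE)
      counts <- rowsum(rep(1L, length(all_labs)), all_labs)
      hist_now <- paste0(rownames(counts), ":", counts[, 1], collapse = ";")
      if (!is.null(hist_prev) && identical(hist_now, hist_prev)) {
        converged <- TRUE
        break
      }
      hist_prev <- hist_now
    }
  })
  iter <- n_iter
  labels <- lapply(seq_len(n), function(i) setNames(coef[[i]], lab[[i]]))
  if (!converged) {
    warning("COPRA did not converge within max_iter sweeps; returning current labels")
  }

  node_names <- igraph::vertex_attr(graph, "name")
  node_ids <- if (!is.null(node_names)) {
    suppressWarnings(as.integer(node_names))
  } else {
    seq_len(n)
  }
  if (anyNA(node_ids)) node_ids <- seq_len(n)
  mem <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(node = node_ids[i], cluster = names(labels[[i]]),
               coefficient = as.numeric(labels[[i]]))
  }))
  # drop communities smaller than 2 and relabel consecutively
  sizes <- table(mem$cluster)
  mem <- mem[mem$cluster %in% names(sizes)[sizes >= 2], , drop = FALSE]
  mem$cluster <- as.integer(factor(mem$cluster,
                                   levels = unique(mem$cluster[order(mem$node)])))
  rownames(mem) <- NULL
  structure(list(membership = mem, converged = converged, n_iter = iter),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  k <- length(unique(x$membership$cluster))
  cat(sprintf("<cluster_set> %d clusters over %d memberships (%s after %d sweeps)\n",
              k, nrow(x$membership),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Resolve overlapping memberships to one label per node
#'
#' For scoring, each node is assigned to its highest-coefficient community
#' (first on ties).
#'
#' @param cs a `cluster_set`.
#' @return Data frame with columns `node`, `cluster` (one row per node).
#' @export
resolve_overlaps <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  mem <- cs$membership
  if (nrow(mem) == 0) return(data.frame(node = integer(0), cluster = integer(0)))
  mem <- mem[order(mem$node, -mem$coefficient), , drop = FALSE]
  mem <- mem[!duplicated(mem$node), c("node", "cluster")]
  rownames(mem) <- NULL
  mem
}
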