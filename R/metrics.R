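#' Supervised detection scores from a confusion table
#'
#' Precision, recall, specificity and their summary F-score (the harmonic
#' mean of precision and recall) from window-level true/false
#' positive/negative counts. Undefined ratios (zero denominators) score 0
#' with a warning.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return List with `precision`, `recall`, `specificity`, `f_s`.
#' @export
f_supervised <- function(tp, fp, fn, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); scoring 0")
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f_s <- if (precision + recall == 0) 0 else
    2 / (1 / precision + 1 / recall)
  list(precision = precision, recall = recall, specificity = specificity,
       f_s = f_s)
}

#' Window-level confusion table from label vectors
#'
#' @param detected logical (or NA-able label) vector: is the window claimed
#'   as signal?
#' @param truth logical vector: does the window contain an embedded pattern?
#' @return List with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_from_labels <- function(detected, truth) {
  stopifnot(length(detected) == length(truth))
  d <- !is.na(detected) & (as.logical(detected) %in% TRUE)
  t <- !is.na(truth) & (as.logical(truth) %in% TRUE)
  list(tp = sum(d & t), fp = sum(d & !t), fn = sum(!d & t), tn = sum(!d & !t))
}

#' Unsupervised clustering scores: purity, inverse purity, F-score
#'
#' Scores a detected partition of windows against the true one. Purity is
#' the size-weighted average, over detected clusters, of the largest
#' fraction of a cluster's members that share one true class; inverse
#' purity is the same with the roles of detected and true clusters
#' exchanged; the F-score is their harmonic mean, which penalises both
#' trivial solutions (every window its own cluster, or one big cluster).
#'
#' Windows assigned to no detected cluster form a single detected noise
#' cluster, and windows containing no embedded pattern form the true noise
#' class, so a perfect detection scores 1.
#'
#' @param detected integer vector of detected labels per window (`NA` =
#'   noise).
#' @param truth integer vector of true labels per window (`NA` = noise).
#' @return List with `purity`, `inverse_purity`, `f_us`.
#' @export
f_unsupervised <- function(detected, truth) {
  stopifnot(length(detected) == length(truth))
  T_ <- length(truth)
  if (T_ == 0) stop("no windows to score")
  d <- as.character(detected)
  d[is.na(d)] <- ".noise"
  t <- as.character(truth)
  t[is.na(t)] <- ".noise"
  ct <- table(d, t) # detected x true contingency
  ci <- rowSums(ct)
  lj <- colSums(ct)
  purity <- sum((ci / T_) * apply(ct, 1, max) / ci)
  inverse_purity <- sum((lj / T_) * apply(ct, 2, max) / lj)
  f_us <- if (purity + inverse_purity == 0) 0 else
    2 / (1 / purity + 1 / inverse_purity)
  list(purity = purity, inverse_purity = inverse_purity, f_us = f_us)
}

#' True window labels from embedded ground truth
#'
#' A window is a member of true cluster j if it overlaps an embedded
#' occurrence of assembly j; windows overlapping no occurrence are noise
#' (`NA`). If a window overlaps occurrences of several assemblies the
#' first embedded one wins.
#'
#' @param truth a `synth_truth` object from [embed_assemblies()].
#' @param ws a `window_set` covering the same recording.
#' @return Integer vector of length `ws$n_windows` with `NA` for noise.
#' @export
window_truth <- function(truth, ws) {
  stopifnot(inherits(truth, "synth_truth"), inherits(ws, "window_set"))
  lab <- rep(NA_integer_, ws$n_windows)
  occ <- truth$occurrences
  if (nrow(occ) == 0) return(lab)
  w_end <- ws$starts + ws$config$window_s
  for (r in seq_len(nrow(occ))) {
    hit <- which(ws$starts < occ$end[r] & w_end > occ$start[r])
    hit <- hit[is.na(lab[hit])]
    lab[hit] <- occ$assembly[r]
  }
  lab
}
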