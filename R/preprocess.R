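# Expression filtering and median-of-ratios normalization: the bridge
# between raw molecule counts and every downstream analysis.

#' Filter low-expression tag clusters and spots
#'
#' First drops ST-TCs detected (count >= 1) in fewer than `min_tc_spots`
#' spots, then drops spots whose total count is below `min_spot_counts` or
#' whose number of detected features is below `min_spot_features`.
#' Idempotent for any threshold combination that leaves the matrix
#' non-empty.
#'
#' @param m Raw-space [spot_matrix()].
#' @param min_spot_counts Minimum total molecules per spot (default 100).
#' @param min_spot_features Minimum detected ST-TCs per spot (default 100).
#' @param min_tc_spots Minimum spots an ST-TC must be detected in
#'   (default 2).
#' @return The filtered `spot_matrix`, with attributes `dropped_tcs` and
#'   `dropped_spots` listing the removed identifiers.
#' @export
filter_matrix <- function(m, min_spot_counts = 100, min_spot_features = 100,
                          min_tc_spots = 2) {
  stopifnot(inherits(m, "spot_matrix"), m$space == "raw",
            min_spot_counts >= 0, min_spot_features >= 0, min_tc_spots >= 0)
  detected <- m$values >= 1L
  keep_tc <- colSums(detected) >= min_tc_spots
  vals <- m$values[, keep_tc, drop = FALSE]
  keep_spot <- rowSums(vals) >= min_spot_counts &
    rowSums(vals >= 1L) >= min_spot_features
  if (!any(keep_tc) || !any(keep_spot)) {
    stop("filter_matrix: all ", if (!any(keep_tc)) "tag clusters" else "spots",
         " removed; thresholds too strict for this matrix")
  }
  out <- m[keep_spot, keep_tc]
  attr(out, "dropped_tcs") <- colnames(m$values)[!keep_tc]
  attr(out, "dropped_spots") <- rownames(m$values)[!keep_spot]
  out
}

#' Median-of-ratios size factors
#'
#' The DESeq2-style per-spot scaling constants.  The reference profile is
#' the per-ST-TC geometric mean across spots, computed over the set of
#' ST-TCs with a nonzero count in every spot; each spot's factor is the
#' median ratio of its counts to the reference.  Because sparse ST
#' matrices often have almost no all-nonzero features, when that
#' reference set has fewer than `min_reference` members the reference
#' falls back to positive-count geometric means (geometric mean over the
#' spots where the ST-TC is detected, restricted to ST-TCs detected in at
#' least 2 spots) and each spot's median is taken over its detected
#' features.  Factors are not rescaled afterward.  On an all-positive
#' matrix both routes coincide.
#'
#' @param m Raw-space [spot_matrix()] with at least 2 spots.
#' @param min_reference Minimum size of the all-nonzero reference set
#'   before the positive-count fallback engages (default 50).
#' @return Named numeric vector of positive factors, one per spot, in
#'   matrix row order.
#' @export
size_factors <- function(m, min_reference = 50) {
  stopifnot(inherits(m, "spot_matrix"), m$space == "raw")
  v <- m$values
  if (nrow(v) < 2) stop("size_factors: need at least 2 spots")
  storage.mode(v) <- "double"
  all_pos <- colSums(v > 0) == nrow(v)
  if (sum(all_pos) >= min_reference) {
    ref <- exp(colMeans(log(v[, all_pos, drop = FALSE])))
    ratios <- sweep(v[, all_pos, drop = FALSE], 2, ref, "/")
    sf <- apply(ratios, 1, stats::median)
  } else {
    usable <- colSums(v > 0) >= 2
    if (!any(usable)) {
      stop("size_factors: no usable reference ST-TCs even under the ",
           "positive-count fallback")
    }
    vv <- v[, usable, drop = FALSE]
    logv <- log(vv)
    logv[vv == 0] <- NA
    ref <- exp(colMeans(logv, na.rm = TRUE))
    ratios <- sweep(vv, 2, ref, "/")
    ratios[vv == 0] <- NA
    sf <- apply(ratios, 1, stats::median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("size_factors: non-positive or non-finite factor for spot ",
         rownames(v)[which(!is.finite(sf) | sf <= 0)][1])
  }
  names(sf) <- rownames(v)
  sf
}

#' Log2 normalization with a pseudocount
#'
#' `value = log2(count / factor + 1)`; a zero count maps to 0 for any
#' factor.
#'
#' @param m Raw-space [spot_matrix()].
#' @param factors Size factors aligned to the rows of `m`
#'   ([size_factors()]).
#' @return A `spot_matrix` in `lognorm` space.
#' @export
normalize_log <- function(m, factors) {
  stopifnot(inherits(m, "spot_matrix"), m$space == "raw")
  if (length(factors) != nrow(m$values)) {
    stop("normalize_log: ", length(factors), " factors for ",
         nrow(m$values), " spots")
  }
  if (!is.null(names(factors)) &&
      !identical(names(factors), rownames(m$values))) {
    stop("normalize_log: factor names do not match matrix spot keys")
  }
  if (any(!is.finite(factors) | factors <= 0)) {
    stop("normalize_log: factors must be positive and finite")
  }
  vals <- log2(sweep(m$values, 1, factors, "/") + 1)
  spot_matrix(vals, m$spots, space = "lognorm")
}

#' Filter, size-factor and log-normalize in one step
#'
#' Convenience wrapper running [filter_matrix()], [size_factors()] and
#' [normalize_log()].
#'
#' @param m Raw-space [spot_matrix()].
#' @param ... Passed to [filter_matrix()].
#' @param min_reference Passed to [size_factors()].
#' @return List with `matrix` (lognorm [spot_matrix()]), `filtered`
#'   (raw filtered matrix) and `size_factors`.
#' @export
preprocess_matrix <- function(m, ..., min_reference = 50) {
  f <- filter_matrix(m, ...)
  sf <- size_factors(f, min_reference = min_reference)
  list(matrix = normalize_log(f, sf), filtered = f, size_factors = sf)
}
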