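# Circular binary segmentation of the minimum distance, with gap splitting
# and breakpoint pruning.

#' Segmentation parameters
#'
#' Defaults mirror the standard circular binary segmentation (CBS) defaults:
#' changepoints are accepted when the permutation p-value of the max circular
#' two-sample t-statistic falls below `alpha`. Chromosome arms are split into
#' independently segmented regions at inter-marker gaps above `max_gap_bp`,
#' except that a region is never closed while it holds fewer than
#' `min_region_markers` markers. After segmentation, adjacent segments whose
#' standardized mean difference falls below `prune_z` are merged, as are
#' segments spanning fewer than `min_seg_markers` markers.
#'
#' @param alpha significance level for changepoint acceptance.
#' @param n_perm permutations per changepoint test.
#' @param max_gap_bp inter-marker gap (basepairs) that opens a new region.
#' @param min_region_markers minimum markers before a gap split is honored.
#' @param prune_z standardized mean-difference threshold for merging.
#' @param min_seg_markers minimum coverage of a retained segment.
#' @param seed RNG seed for the permutation tests.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(alpha = 0.01, n_perm = 10000L, max_gap_bp = 75000,
                       min_region_markers = 1000L, prune_z = 3.0,
                       min_seg_markers = 2L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1L, max_gap_bp > 0,
            min_region_markers >= 1L, prune_z >= 0, min_seg_markers >= 1L)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 max_gap_bp = max_gap_bp,
                 min_region_markers = as.integer(min_region_markers),
                 prune_z = prune_z,
                 min_seg_markers = as.integer(min_seg_markers),
                 seed = as.integer(seed)),
            class = "seg_params")
}

#' Split a chromosome arm into regions at large coverage gaps
#'
#' Greedy left-to-right partition of the marker positions: a new region opens
#' at any inter-marker gap above `max_gap_bp`, except that a region is not
#' closed while it holds fewer than `min_region_markers` markers (the gap is
#' ignored and accumulation continues). Promotes breakpoints flanking gaps in
#' the array's coverage of the genome.
#'
#' @param positions sorted basepair positions of the arm's markers.
#' @param params a [seg_params()] object.
#' @return Data frame with columns `start`, `end`: 1-based inclusive marker
#'   index ranges jointly covering all markers.
#' @export
split_by_gaps <- function(positions, params = seg_params()) {
  n <- length(positions)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  if (is.unsorted(positions)) stop("positions must be sorted")
  starts <- 1L
  region_start <- 1L
  for (i in seq_len(n)[-1L]) {
    if (positions[i] - positions[i - 1L] > params$max_gap_bp &&
        (i - region_start) >= params$min_region_markers) {
      starts <- c(starts, i)
      region_start <- i
    }
  }
  data.frame(start = starts, end = c(starts[-1L] - 1L, n))
}

.interval_seed <- function(seed, lo, n) {
  as.integer((as.numeric(seed) * 2654435 + lo * 97 + n) %% 2147483647)
}

#' Circular binary segmentation of a numeric vector
#'
#' Recursively finds the arc (contiguous window vs. complement) maximizing the
#' circular two-sample t-statistic; the split is accepted when its permutation
#' p-value (over `n_perm` permutations of the interval's values, seeded
#' deterministically per interval) falls below `alpha`, and the procedure
#' recurses on the resulting sub-intervals. The permutation test uses exact
#' pruning bounds and curtailed sampling, so its accept/reject decisions are
#' identical to the full `n_perm`-permutation test.
#'
#' @param d finite numeric vector (e.g. the minimum distance on one region).
#' @param params a [seg_params()] object.
#' @return Data frame of contiguous segments with columns `start_index`,
#'   `end_index` (1-based inclusive into `d`), `coverage` and `mean_d`.
#' @export
cbs_segment <- function(d, params = seg_params()) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  n <- length(d)
  if (n == 0L) stop("empty input")
  ends <- integer(0)  # right endpoints of segments, excluding n

  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L) return(invisible(NULL))
    seg <- d[lo:hi]
    scan <- .cbs_scan(seg)
    if (scan$stat <= 0) return(invisible(NULL))
    test <- .cbs_perm_test(seg, scan$stat, params$n_perm, params$alpha,
                           .interval_seed(params$seed, lo, len))
    if (!test$significant) return(invisible(NULL))
    cps <- integer(0)
    if (scan$a > 1L) cps <- c(cps, lo + scan$a - 2L)
    if (scan$b < len) cps <- c(cps, lo + scan$b - 1L)
    if (length(cps) == 0L) return(invisible(NULL))
    ends <<- c(ends, cps)
    bounds <- c(lo - 1L, cps, hi)
    for (k in seq_len(length(bounds) - 1L))
      recurse(bounds[k] + 1L, bounds[k + 1L])
    invisible(NULL)
  }
  recurse(1L, n)

  ends <- sort(unique(c(ends, n)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(start_index = starts, end_index = ends,
             coverage = ends - starts + 1L,
             mean_d = vapply(seq_along(starts), function(k)
               mean(d[starts[k]:ends[k]]), numeric(1L)))
}

.recount <- function(segments, d) {
  segments$coverage <- segments$end_index - segments$start_index + 1L
  segments$mean_d <- vapply(seq_len(nrow(segments)), function(k)
    mean(d[segments$start_index[k]:segments$end_index[k]]), numeric(1L))
  segments
}

#' Prune weak breakpoints from a segmentation
#'
#' Iteratively merges the adjacent pair of segments with the smallest
#' standardized mean difference `z = |m_i - m_j| / (sigma * sqrt(1/n_i +
#' 1/n_j))` while `z < prune_z`, where `sigma` is the MAD of the whole
#' vector (robust to the CNV segments themselves). Afterwards any segment
#' spanning fewer than `min_seg_markers` markers is merged into the neighbor
#' with the nearer mean. Means are recomputed after every merge.
#'
#' @param segments data frame of contiguous segments from [cbs_segment()].
#' @param d the segmented vector.
#' @param params a [seg_params()] object.
#' @return Pruned data frame of contiguous segments.
#' @export
prune_segments <- function(segments, d, params = seg_params()) {
  sigma <- if (length(d) >= 2L) mad_lrr(d) else 0
  sigma <- max(sigma, 1e-12)  # constant input: equal means still merge (z = 0)
  merge_pair <- function(seg, k) {
    seg$end_index[k] <- seg$end_index[k + 1L]
    .recount(seg[-(k + 1L), , drop = FALSE], d)
  }
  repeat {
    m <- nrow(segments)
    if (m < 2L) break
    z <- abs(diff(segments$mean_d)) /
      (sigma * sqrt(1 / segments$coverage[-m] + 1 / segments$coverage[-1L]))
    k <- which.min(z)
    if (z[k] >= params$prune_z) break
    segments <- merge_pair(segments, k)
  }
  repeat {
    m <- nrow(segments)
    small <- which(segments$coverage < params$min_seg_markers)
    if (length(small) == 0L || m < 2L) break
    k <- small[1L]
    if (k == 1L) nb <- 2L
    else if (k == m) nb <- m - 1L
    else nb <- if (abs(segments$mean_d[k - 1L] - segments$mean_d[k]) <=
                   abs(segments$mean_d[k + 1L] - segments$mean_d[k]))
      k - 1L else k + 1L
    segments <- merge_pair(segments, min(k, nb))
  }
  rownames(segments) <- NULL
  segments
}
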