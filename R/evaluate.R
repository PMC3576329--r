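# Scoring calls against simulated truth, and comparison of ranked call lists.

.called_de_novo_indicator <- function(calls, truth) {
  if (inherits(calls, "mdcnv")) calls <- calls$calls
  n <- truth$n_markers
  if (nrow(calls) > 0L &&
      (max(calls$end_index) > n || min(calls$start_index) < 1L))
    stop("calls and truth are not on the same marker index space")
  called <- rep(FALSE, n)
  for (j in which(calls$is_de_novo))
    called[seq.int(calls$start_index[j], calls$end_index[j])] <- TRUE
  called
}

#' Marker-level false positive and false negative counts
#'
#' Expands segment calls to a per-marker de novo indicator (a marker is
#' called de novo iff its segment's MAP state is de novo) and tallies against
#' the truth track: false positives are markers in truly non-de-novo regions
#' called de novo; false negatives are markers in true de novo regions called
#' not de novo.
#'
#' @param calls an `mdcnv` fit or its `calls` data frame (with
#'   `start_index`/`end_index` marker indices).
#' @param truth a `truth_track` object.
#' @return A list of class `cnv_eval` with counts `fp`, `fn`, totals, and
#'   rates `fp_rate` (fp / non-de-novo markers) and `fn_rate`
#'   (fn / de novo markers).
#' @export
marker_fp_fn <- function(calls, truth) {
  stopifnot(inherits(truth, "truth_track"))
  called <- .called_de_novo_indicator(calls, truth)
  truth_dn <- is_de_novo(unique(truth$state))[match(truth$state,
                                                    unique(truth$state))]
  fp <- sum(called & !truth_dn)
  fn <- sum(!called & truth_dn)
  structure(list(fp = fp, fn = fn,
                 n_de_novo = sum(truth_dn),
                 n_normal = sum(!truth_dn),
                 fp_rate = fp / sum(!truth_dn),
                 fn_rate = if (sum(truth_dn) > 0L) fn / sum(truth_dn)
                           else NA_real_),
            class = "cnv_eval")
}

#' @export
print.cnv_eval <- function(x, ...) {
  cat("Marker-level evaluation: FP", x$fp, "of", x$n_normal,
      sprintf("(rate %.4g);", x$fp_rate), "FN", x$fn, "of", x$n_de_novo,
      sprintf("(rate %.4g)\n", x$fn_rate))
  invisible(x)
}

#' Per-feature detection flags
#'
#' A true de novo feature is detected iff at least `frac` of its markers are
#' called de novo; a transmitted or homozygosity feature is miscalled iff at
#' least `frac` of its markers are called de novo. The default `frac = 0.5`
#' is the "50 percent or more of the markers" rule.
#'
#' @param calls an `mdcnv` fit or its `calls` data frame.
#' @param truth a `truth_track` object.
#' @param frac marker-fraction threshold (boundary inclusive).
#' @return The truth feature table with added columns `frac_called_de_novo`,
#'   `detected` (de novo features) and `miscalled` (other features).
#' @export
feature_detection <- function(calls, truth, frac = 0.5) {
  stopifnot(inherits(truth, "truth_track"), frac > 0, frac <= 1)
  called <- .called_de_novo_indicator(calls, truth)
  feats <- truth$features
  feats$frac_called_de_novo <- vapply(seq_len(nrow(feats)), function(j)
    mean(called[seq.int(feats$start[j], feats$end[j])]), numeric(1L))
  dn <- feats$type == "de_novo_del"
  feats$detected <- dn & feats$frac_called_de_novo >= frac
  feats$miscalled <- !dn & feats$frac_called_de_novo >= frac
  feats
}

# reciprocal overlap of two 1-based inclusive intervals, as a fraction of the
# longer interval
.reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- min(a_end, b_end) - max(a_start, b_start) + 1
  if (ov <= 0) return(0)
  min(ov / (a_end - a_start + 1), ov / (b_end - b_start + 1))
}

#' Concordance at the top of two ranked call lists
#'
#' The proportion of items shared between the top-k entries of two ranked
#' lists. Lists may be character vectors of identifiers (matched by
#' equality) or data frames with `chrom`, `start_bp`, `end_bp` (matched by
#' reciprocal genomic overlap of at least 50%, pairing greedily by
#' decreasing overlap so that the measure is symmetric).
#'
#' @param list_a,list_b ranked lists (best first).
#' @param k list size to compare; must not exceed either list length.
#' @return Proportion in \[0, 1\].
#' @export
concordance_at_top <- function(list_a, list_b, k) {
  if (k < 1L) stop("k must be positive")
  get_top <- function(x) {
    if (is.data.frame(x)) {
      if (k > nrow(x)) stop("k exceeds list length")
      x[seq_len(k), , drop = FALSE]
    } else {
      if (k > length(x)) stop("k exceeds list length")
      x[seq_len(k)]
    }
  }
  top_a <- get_top(list_a); top_b <- get_top(list_b)
  if (!is.data.frame(top_a)) return(length(intersect(top_a, top_b)) / k)

  pairs <- expand.grid(a = seq_len(k), b = seq_len(k))
  pairs$ov <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$a[r]; j <- pairs$b[r]
    if (top_a$chrom[i] != top_b$chrom[j]) return(0)
    .reciprocal_overlap(top_a$start_bp[i], top_a$end_bp[i],
                        top_b$start_bp[j], top_b$end_bp[j])
  }, numeric(1L))
  pairs <- pairs[pairs$ov >= 0.5, , drop = FALSE]
  pairs <- pairs[order(-pairs$ov, pairs$a, pairs$b), , drop = FALSE]
  used_a <- used_b <- logical(k)
  matched <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$a[r]; j <- pairs$b[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / k
}
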