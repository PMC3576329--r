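# The minimum distance statistic and the MAD noise summary.

#' Per-marker minimum distance between offspring and parental log R ratios
#'
#' For each marker, the paternal distance is the offspring minus father log R
#' ratio and the maternal distance the offspring minus mother log R ratio;
#' the minimum distance is whichever has the smaller magnitude (ties go to
#' the paternal distance). Because technical variation shared within a trio
#' (probe effects, genomic waves) enters all three samples, it largely cancels
#' in the minimum distance, while a copy number in the offspring that differs
#' from both parents does not.
#'
#' @param trio a `trio_signals` object.
#' @return An object of class `mindist`: a list with `markers`, `d` (signed
#'   minimum distance, same scale as the log R ratios) and `which_parent`
#'   (`"F"` or `"M"`, the arg-min parent).
#' @export
minimum_distance <- function(trio) {
  stopifnot(inherits(trio, "trio_signals"))
  delta_f <- trio$lrr[, "O"] - trio$lrr[, "F"]
  delta_m <- trio$lrr[, "O"] - trio$lrr[, "M"]
  use_f <- abs(delta_f) <= abs(delta_m)
  structure(list(markers = trio$markers,
                 d = ifelse(use_f, delta_f, delta_m),
                 which_parent = ifelse(use_f, "F", "M")),
            class = "mindist")
}

#' @export
print.mindist <- function(x, ...) {
  cat("Minimum distance track:", length(x$d), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  cat("  MAD:", format(mad_lrr(x$d), digits = 4L),
      " paternal arg-min fraction:",
      format(mean(x$which_parent == "F"), digits = 3L), "\n")
  invisible(x)
}

#' @describeIn minimum_distance export the track as a data frame
#'   (`chrom`, `position`, `d`, `which_parent`).
#' @param x a `mindist` object.
#' @param ... unused.
#' @export
as.data.frame.mindist <- function(x, ...) {
  data.frame(chrom = x$markers$chrom, position = x$markers$position,
             d = x$d, which_parent = x$which_parent,
             stringsAsFactors = FALSE)
}

#' Median absolute deviation of log R ratios
#'
#' Robust noise scale: `median(|x - median(x)|) * 1.4826`, the
#' normal-consistency scaling, computed over non-missing values.
#'
#' @param lrr numeric vector, possibly with missing values.
#' @return Non-negative scalar.
#' @export
mad_lrr <- function(lrr) {
  x <- lrr[!is.na(lrr)]
  if (length(x) < 2L) stop("mad_lrr needs at least 2 non-missing values")
  stats::mad(x)
}
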