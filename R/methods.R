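# S3 methods for the mdcnv fit object.

#' @export
print.mdcnv <- function(x, ...) {
  dn <- sum(x$calls$is_de_novo)
  cat("De novo CNV calls for a case-parent trio (minimum distance + CBS +",
      "MAP)\n")
  cat("  markers:", x$n_markers, " segments:", nrow(x$calls),
      " de novo calls:", dn, "\n")
  if (dn > 0L) {
    top <- rank_calls(x)[1L, ]
    cat("  top de novo call: chr", top$chrom, ":", top$start_bp, "-",
        top$end_bp, " state ", top$state, " (log10 odds ",
        format(top$log10_odds_vs_diploid, digits = 3L), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.mdcnv <- function(object, ...) {
  calls <- object$calls
  out <- list(
    n_markers = object$n_markers,
    n_segments = nrow(calls),
    n_de_novo = sum(calls$is_de_novo),
    mad_d = mad_lrr(object$mindist$d),
    state_table = table(calls$state),
    de_novo = rank_calls(object))
  class(out) <- "summary.mdcnv"
  out
}

#' @export
print.summary.mdcnv <- function(x, ...) {
  cat("Trio CNV fit:", x$n_markers, "markers,", x$n_segments, "segments,",
      x$n_de_novo, "de novo call(s)\n")
  cat("MAD of the minimum distance:", format(x$mad_d, digits = 4L), "\n")
  cat("Segment states:\n")
  print(x$state_table)
  if (x$n_de_novo > 0L) {
    cat("De novo calls (ranked by posterior odds vs. diploid):\n")
    print(x$de_novo[, c("chrom", "start_bp", "end_bp", "n_markers", "state",
                        "map_posterior", "log10_odds_vs_diploid")])
  }
  invisible(x)
}

#' Extract the call table from a fit
#'
#' @param x an `mdcnv` object.
#' @param row.names,optional,... passed on conventions of the generic;
#'   unused.
#' @return The `calls` data frame (one row per segment).
#' @export
as.data.frame.mdcnv <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$calls
}

#' Fitted emission parameters
#'
#' @param object an `mdcnv` object.
#' @param ... unused.
#' @return Named list of per-arm `emission_params` fits.
#' @export
coef.mdcnv <- function(object, ...) object$emission

#' Plot the minimum distance and segment calls for one chromosome
#'
#' Base-graphics display of the per-marker minimum distance with fitted
#' segment means overlaid; de novo segments are highlighted.
#'
#' @param x an `mdcnv` object.
#' @param chrom chromosome to display (default: the first).
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.mdcnv <- function(x, chrom = NULL, ...) {
  md <- x$mindist
  chrom <- chrom %||% md$markers$chrom[1L]
  sel <- md$markers$chrom == chrom
  pos <- md$markers$position[sel] / 1e6
  graphics::plot(pos, md$d[sel], pch = ".", col = "grey40",
                 xlab = sprintf("chr%s position (Mb)", chrom),
                 ylab = "minimum distance", ...)
  graphics::abline(h = 0, col = "grey70", lty = 2L)
  calls <- x$calls[x$calls$chrom == chrom, , drop = FALSE]
  for (j in seq_len(nrow(calls))) {
    col <- if (calls$is_de_novo[j]) "red" else "blue"
    graphics::segments(calls$start_bp[j] / 1e6, calls$mean_d[j],
                       calls$end_bp[j] / 1e6, calls$mean_d[j],
                       col = col, lwd = 2L)
  }
  invisible(x)
}
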