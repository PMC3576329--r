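# Reading PennCNV/BeadStudio-style signal files and assembling trios.

.normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  suppressWarnings(as.integer(x))  # non-autosomes (X, Y, XY, MT) become NA
}

.find_column <- function(cols, sample_label, what) {
  candidates <- if (is.null(sample_label)) what
                else c(paste(sample_label, what, sep = "."), what)
  hit <- candidates[candidates %in% cols]
  if (length(hit) == 0L)
    stop("signal file is missing required column '", candidates[1L], "'")
  hit[1L]
}

#' Read a PennCNV/BeadStudio-style signal file for one sample
#'
#' Reads a tab-delimited file with header columns `Name`, `Chr`, `Position`
#' and per-sample `"<label>.Log R Ratio"` / `"<label>.B Allele Freq"` columns
#' (plain `"Log R Ratio"` / `"B Allele Freq"` are also accepted). Only
#' autosomes 1--22 are retained; rows on other chromosomes are dropped with a
#' message. `"NA"` and empty cells become missing values.
#'
#' @param path path to the tab-delimited signal file.
#' @param sample_label optional sample name prefixing the signal columns.
#' @return An object of class `sample_signals`: a list with `markers` (data
#'   frame with `name`, `chrom`, `position`, sorted by chromosome then
#'   position), `lrr`, `baf`, and `sample`.
#' @export
read_signal_file <- function(path, sample_label = NULL) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                           colClasses = "character")
  for (col in c("Name", "Chr", "Position")) {
    if (!col %in% names(raw))
      stop("signal file is missing required column '", col, "'")
  }
  lrr_col <- .find_column(names(raw), sample_label, "Log R Ratio")
  baf_col <- .find_column(names(raw), sample_label, "B Allele Freq")

  pos <- suppressWarnings(as.numeric(raw$Position))
  bad <- which(is.na(pos) & !is.na(raw$Position))
  if (length(bad) > 0L)
    stop("non-numeric Position at line ", bad[1L] + 1L, " of ", path)

  chrom <- .normalize_chrom(raw$Chr)
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= 22L & !is.na(pos)
  if (any(!keep))
    message(sum(!keep), " non-autosomal or unmapped rows dropped from ", path)

  out <- data.frame(name = raw$Name[keep], chrom = chrom[keep],
                    position = as.integer(pos[keep]),
                    lrr = suppressWarnings(as.numeric(raw[[lrr_col]][keep])),
                    baf = suppressWarnings(as.numeric(raw[[baf_col]][keep])),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  dup <- duplicated(out[c("chrom", "name")])
  if (any(dup))
    stop("duplicate marker names within a chromosome in ", path, ": ",
         paste(utils::head(out$name[dup], 3L), collapse = ", "))
  bad_baf <- !is.na(out$baf) & (out$baf < 0 | out$baf > 1)
  if (any(bad_baf)) stop("B allele frequencies outside [0, 1] in ", path)
  structure(list(markers = out[c("name", "chrom", "position")],
                 lrr = out$lrr, baf = out$baf,
                 sample = sample_label %||% basename(path)),
            class = "sample_signals")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a trio signal object directly
#'
#' Low-level constructor used by [assemble_trio()] and the simulator.
#'
#' @param markers data frame with `name`, `chrom`, `position` (sorted by
#'   chromosome then position).
#' @param lrr,baf n x 3 numeric matrices with columns father, mother,
#'   offspring.
#' @return An object of class `trio_signals`.
#' @export
trio_signals <- function(markers, lrr, baf) {
  lrr <- as.matrix(lrr); baf <- as.matrix(baf)
  stopifnot(ncol(lrr) == 3L, ncol(baf) == 3L,
            nrow(lrr) == nrow(markers), nrow(baf) == nrow(markers))
  colnames(lrr) <- colnames(baf) <- c("F", "M", "O")
  ord <- order(markers$chrom, markers$position)
  if (is.unsorted(ord)) {
    markers <- markers[ord, , drop = FALSE]
    lrr <- lrr[ord, , drop = FALSE]
    baf <- baf[ord, , drop = FALSE]
  }
  for (ch in unique(markers$chrom)) {
    p <- markers$position[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within chromosome ",
           ch)
  }
  rownames(markers) <- NULL
  structure(list(markers = markers, lrr = lrr, baf = baf),
            class = "trio_signals")
}

#' Align father, mother and offspring signals on shared markers
#'
#' Restricts the three samples to the intersection of their markers (matched
#' on the name/chromosome/position triple), orders columns father, mother,
#' offspring, and drops any marker with a missing value in any of the six
#' signals (count reported via a message).
#'
#' @param father,mother,offspring `sample_signals` objects from
#'   [read_signal_file()].
#' @return A `trio_signals` object.
#' @export
assemble_trio <- function(father, mother, offspring) {
  samples <- list(father, mother, offspring)
  stopifnot(all(vapply(samples, inherits, logical(1L), "sample_signals")))
  keys <- lapply(samples, function(s)
    paste(s$markers$name, s$markers$chrom, s$markers$position, sep = "\r"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L) stop("no shared markers")
  idx <- lapply(keys, match, x = shared)
  markers <- samples[[1L]]$markers[idx[[1L]], , drop = FALSE]
  if (anyDuplicated(markers$name))
    stop("marker name maps to multiple chromosome/position pairs")
  lrr <- cbind(father$lrr[idx[[1L]]], mother$lrr[idx[[2L]]],
               offspring$lrr[idx[[3L]]])
  baf <- cbind(father$baf[idx[[1L]]], mother$baf[idx[[2L]]],
               offspring$baf[idx[[3L]]])
  complete <- stats::complete.cases(cbind(lrr, baf))
  if (any(!complete))
    message(sum(!complete), " markers dropped for missing signals")
  trio_signals(markers[complete, , drop = FALSE],
               lrr[complete, , drop = FALSE], baf[complete, , drop = FALSE])
}

#' Write a de novo CNV call table
#'
#' Tab-delimited output with one row per segment call, ordered by chromosome
#' and start position. Coordinates are the positions of the first and last
#' marker of the segment, 1-based inclusive (not BED half-open).
#'
#' @param calls data frame of calls as returned by [call_trio()] /
#'   [as.data.frame.mdcnv()], with columns `chrom`, `start_bp`, `end_bp`,
#'   `n_markers`, `state`, `map_posterior`, `log10_odds_vs_diploid`,
#'   `is_de_novo`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_calls <- function(calls, path) {
  cols <- c("chrom", "start_bp", "end_bp", "n_markers", "state",
            "map_posterior", "log10_odds_vs_diploid", "is_de_novo")
  if (is.null(calls) || nrow(as.data.frame(calls)) == 0L) {
    calls <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                           cols))
  } else {
    calls <- as.data.frame(calls)[, cols]
    calls <- calls[order(calls$chrom, calls$start_bp), , drop = FALSE]
    calls$map_posterior <- sprintf("%.6g", calls$map_posterior)
    calls$log10_odds_vs_diploid <- sprintf("%.6g",
                                           calls$log10_odds_vs_diploid)
  }
  ok <- tryCatch({
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write call table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a call table written by [write_calls()]
#'
#' @param path path to a tab-delimited call table.
#' @return Data frame of calls.
#' @export
read_calls <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    out$state <- sprintf("%03d", as.integer(out$state))
    out$is_de_novo <- as.logical(out$is_de_novo)
  }
  out
}

#' Read a centromere table defining chromosome arms
#'
#' Three tab-delimited columns: chromosome, end of the p arm, start of the q
#' arm. Markers at positions `<= p_end` are assigned to the p arm, the rest
#' to the q arm. When no table is supplied, whole chromosomes are treated as
#' single arms.
#'
#' @param path path to the tab-delimited table (header `chrom`, `p_end`,
#'   `q_start`).
#' @return Data frame with `chrom`, `p_end`, `q_start`.
#' @export
read_centromeres <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("chrom", "p_end", "q_start"))
    if (!col %in% names(out)) stop("centromere table missing column ", col)
  out$chrom <- .normalize_chrom(out$chrom)
  out
}

#' Read per-marker population A-allele frequencies
#'
#' Two tab-delimited columns: marker name and A-allele frequency. Frequencies
#' inform the genotype-cluster priors of the B allele frequency emission
#' model; markers absent from the file default to 0.5.
#'
#' @param path path to the tab-delimited table (header `name`, `p_A`).
#' @return Named numeric vector of A-allele frequencies.
#' @export
read_allele_freqs <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("name", "p_A"))
    if (!col %in% names(out)) stop("allele frequency table missing column ",
                                   col)
  stats::setNames(as.numeric(out$p_A), out$name)
}

.assign_arms <- function(markers, centromeres = NULL) {
  if (is.null(centromeres)) return(rep("", nrow(markers)))
  arm <- rep("q", nrow(markers))
  for (i in seq_len(nrow(centromeres))) {
    sel <- markers$chrom == centromeres$chrom[i] &
      markers$position <= centromeres$p_end[i]
    arm[sel] <- "p"
  }
  arm
}
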