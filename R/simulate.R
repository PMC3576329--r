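# Synthetic trio chromosomes with known truth: correlated multivariate-normal
# log R ratios with deletion features and genomic-wave drift, and
# Mendelian-consistent B allele frequencies.

#' Simulation configuration
#'
#' A synthetic chromosome carries four de novo hemizygous deletions and four
#' paternally transmitted deletions of 10, 25, 50 and 100 markers each, and
#' three runs of offspring homozygosity (diploid copy number) of 50, 100 and
#' 500 markers spanned by the trough of a genomic wave. Trio log R ratios are
#' drawn from a 3-dimensional multivariate normal whose correlation matrix
#' has a common off-diagonal `rho`; deletion regions shift the affected
#' means to `deletion_mean`, wave regions move all three means smoothly from
#' 0 down to `wave_depth` and back (half-cosine). Features are evenly spaced
#' with at least `buffer` diploid markers between them.
#'
#' @param n_markers markers per chromosome.
#' @param rho common trio log R ratio correlation.
#' @param sigma_r log R ratio standard deviation.
#' @param deletion_mean log R ratio mean inside deletions.
#' @param wave_depth trough depth of the simulated genomic wave.
#' @param de_novo_sizes,transmitted_sizes,homozygosity_sizes feature sizes in
#'   markers.
#' @param buffer minimum diploid markers between features.
#' @param spacing_bp inter-marker spacing in basepairs.
#' @param baf_sd sd of the truncated-normal B allele frequency noise around
#'   the genotype cluster means.
#' @param p_B population B-allele frequency.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 25000L, rho = 0, sigma_r = 0.15,
                       deletion_mean = -0.5, wave_depth = -0.2,
                       de_novo_sizes = c(10L, 25L, 50L, 100L),
                       transmitted_sizes = c(10L, 25L, 50L, 100L),
                       homozygosity_sizes = c(50L, 100L, 500L),
                       buffer = 200L, spacing_bp = 1000L, baf_sd = 0.03,
                       p_B = 0.5) {
  stopifnot(rho >= 0, rho < 1, sigma_r > 0, baf_sd > 0)
  n_feat <- length(de_novo_sizes) + length(transmitted_sizes) +
    length(homozygosity_sizes)
  total <- sum(de_novo_sizes, transmitted_sizes, homozygosity_sizes) +
    (n_feat + 1L) * buffer
  if (total > n_markers)
    stop("feature layout does not fit in ", n_markers, " markers")
  structure(list(n_markers = as.integer(n_markers), rho = rho,
                 sigma_r = sigma_r, deletion_mean = deletion_mean,
                 wave_depth = wave_depth,
                 de_novo_sizes = as.integer(de_novo_sizes),
                 transmitted_sizes = as.integer(transmitted_sizes),
                 homozygosity_sizes = as.integer(homozygosity_sizes),
                 buffer = as.integer(buffer),
                 spacing_bp = as.integer(spacing_bp),
                 baf_sd = baf_sd, p_B = p_B),
            class = "sim_config")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Evenly interleaved feature layout: de novo and transmitted deletions
# alternate by size, homozygosity runs last, equal diploid gaps between.
.feature_layout <- function(config) {
  sizes <- c(rbind(config$de_novo_sizes, config$transmitted_sizes),
             config$homozygosity_sizes)
  types <- c(rbind(rep("de_novo_del", length(config$de_novo_sizes)),
                   rep("transmitted_del", length(config$transmitted_sizes))),
             rep("homozygosity_wave", length(config$homozygosity_sizes)))
  k <- length(sizes)
  gap <- (config$n_markers - sum(sizes)) %/% (k + 1L)
  starts <- integer(k)
  cursor <- gap + 1L
  for (j in seq_len(k)) {
    starts[j] <- cursor
    cursor <- cursor + sizes[j] + gap
  }
  data.frame(type = types, start = starts, end = starts + sizes - 1L,
             size = sizes,
             state = c(de_novo_del = "332", transmitted_del = "232",
                       homozygosity_wave = "333")[types],
             stringsAsFactors = FALSE)
}

.rtnorm01 <- function(mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(1, mu, sd)
  stats::qnorm(stats::runif(length(mu), lo, hi), mu, sd)
}

#' Simulate one trio chromosome with known truth
#'
#' @param config a [sim_config()] object.
#' @param chrom_seed RNG seed for this chromosome.
#' @param chrom chromosome label.
#' @return A list of class `sim_trio` with components `trio` (a
#'   `trio_signals` object), `truth` (a `truth_track`: per-marker trio state
#'   codes plus the feature table), and the configuration.
#' @export
simulate_trio_chromosome <- function(config = sim_config(), chrom_seed = 1L,
                                     chrom = 1L) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(chrom_seed, {
    n <- config$n_markers
    feats <- .feature_layout(config)
    state <- rep("333", n)
    mu <- matrix(0, n, 3L, dimnames = list(NULL, c("F", "M", "O")))
    for (j in seq_len(nrow(feats))) {
      idx <- seq.int(feats$start[j], feats$end[j])
      switch(feats$type[j],
        de_novo_del = {
          mu[idx, "O"] <- config$deletion_mean
          state[idx] <- "332"
        },
        transmitted_del = {
          mu[idx, c("F", "O")] <- config$deletion_mean
          state[idx] <- "232"
        },
        homozygosity_wave = {
          t_rel <- (seq_along(idx) - 1L) / (length(idx) - 1L)
          wave <- config$wave_depth * (1 - cos(2 * pi * t_rel)) / 2
          mu[idx, ] <- mu[idx, ] + wave
        })
    }

    # equicorrelated trio noise: shared + independent components
    z_shared <- stats::rnorm(n)
    noise <- config$sigma_r * (sqrt(config$rho) * z_shared +
                               sqrt(1 - config$rho) *
                                 matrix(stats::rnorm(3L * n), n, 3L))
    lrr <- mu + noise

    # genotypes: 1 = B allele; two homologs per parent
    fa <- matrix(stats::rbinom(2L * n, 1L, config$p_B), n, 2L)
    mo <- matrix(stats::rbinom(2L * n, 1L, config$p_B), n, 2L)
    tf <- fa[cbind(seq_len(n), sample(2L, n, replace = TRUE))]
    tm <- mo[cbind(seq_len(n), sample(2L, n, replace = TRUE))]
    f_cn <- rep(2L, n); o_cn <- rep(2L, n)
    f_b <- rowSums(fa); m_b <- rowSums(mo); o_b <- tf + tm
    for (j in seq_len(nrow(feats))) {
      idx <- seq.int(feats$start[j], feats$end[j])
      switch(feats$type[j],
        de_novo_del = {
          # offspring retains one of the two transmitted alleles
          keep_f <- stats::rbinom(length(idx), 1L, 0.5) == 1L
          o_cn[idx] <- 1L
          o_b[idx] <- ifelse(keep_f, tf[idx], tm[idx])
        },
        transmitted_del = {
          # father is hemizygous and transmits the deletion
          f_cn[idx] <- 1L
          f_b[idx] <- fa[idx, 1L]
          o_cn[idx] <- 1L
          o_b[idx] <- tm[idx]
        },
        homozygosity_wave = {
          # offspring homozygous diploid; both parents carry the allele
          x <- stats::rbinom(length(idx), 1L, config$p_B)
          fa[idx, 1L] <- x; mo[idx, 1L] <- x
          f_b[idx] <- rowSums(fa[idx, , drop = FALSE])
          m_b[idx] <- rowSums(mo[idx, , drop = FALSE])
          o_b[idx] <- 2L * x
        })
    }
    baf_mean <- cbind(F = f_b / f_cn, M = m_b / 2L, O = o_b / o_cn)
    baf <- matrix(.rtnorm01(as.vector(baf_mean), config$baf_sd), n, 3L,
                  dimnames = list(NULL, c("F", "M", "O")))

    markers <- data.frame(
      name = sprintf("sim-%d-%06d", chrom, seq_len(n)),
      chrom = as.integer(chrom),
      position = seq_len(n) * config$spacing_bp,
      stringsAsFactors = FALSE)
    feats$chrom <- rep(as.integer(chrom), nrow(feats))
    feats$start_bp <- markers$position[feats$start]
    feats$end_bp <- markers$position[feats$end]
    truth <- structure(list(state = state, features = feats,
                            n_markers = n, chrom = as.integer(chrom)),
                       class = "truth_track")
    structure(list(trio = trio_signals(markers, lrr, baf), truth = truth,
                   config = config, chrom_seed = as.integer(chrom_seed)),
              class = "sim_trio")
  })
}

#' Simulate the full study grid
#'
#' Crosses the correlation and noise settings and simulates `n_chromosomes`
#' trio chromosomes per cell (the full design: 3 correlations x 4 sds x 25
#' chromosomes). Deterministic given `seed`.
#'
#' @param rho,sigma_r vectors of correlation and sd settings.
#' @param n_chromosomes chromosomes per (rho, sigma) cell.
#' @param seed master seed; each chromosome receives a seed derived from it.
#' @param n_markers markers per chromosome.
#' @param ... further arguments passed to [sim_config()].
#' @return List of `sim_trio` objects, each annotated with its `rho` and
#'   `sigma_r`.
#' @export
simulate_study <- function(rho = c(0, 0.2, 0.5),
                           sigma_r = c(0.15, 0.20, 0.25, 0.30),
                           n_chromosomes = 25L, seed = 1L,
                           n_markers = 25000L, ...) {
  grid <- expand.grid(rho = rho, sigma_r = sigma_r, rep = seq_len(n_chromosomes),
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(n_markers = n_markers, rho = grid$rho[i],
                      sigma_r = grid$sigma_r[i], ...)
    chrom_seed <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    out[[i]] <- simulate_trio_chromosome(cfg, chrom_seed = chrom_seed)
  }
  attr(out, "grid") <- grid
  out
}

#' Write a simulated trio to PennCNV-style signal files
#'
#' Writes one signal file per sample (`<prefix>_father.txt`,
#' `_mother.txt`, `_offspring.txt`) and a truth feature table
#' (`<prefix>_truth.txt`) including a `background` row spanning the whole
#' chromosome so the marker space can be reconstructed.
#'
#' @param sim a `sim_trio` object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, a named character vector of the four paths.
#' @export
write_simulated_trio <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_trio"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(father = file.path(dir, paste0(prefix, "_father.txt")),
             mother = file.path(dir, paste0(prefix, "_mother.txt")),
             offspring = file.path(dir, paste0(prefix, "_offspring.txt")),
             truth = file.path(dir, paste0(prefix, "_truth.txt")))
  m <- sim$trio$markers
  for (k in 1:3) {
    tab <- data.frame(Name = m$name, Chr = m$chrom, Position = m$position,
                      lrr = sprintf("%.6f", sim$trio$lrr[, k]),
                      baf = sprintf("%.6f", sim$trio$baf[, k]),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(tab)[4:5] <- c("Log R Ratio", "B Allele Freq")
    utils::write.table(tab, paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  feats <- sim$truth$features
  feats <- rbind(feats,
                 data.frame(type = "background", start = 1L,
                            end = sim$truth$n_markers,
                            size = sim$truth$n_markers, state = "333",
                            chrom = sim$truth$chrom,
                            start_bp = m$position[1L],
                            end_bp = m$position[sim$truth$n_markers],
                            stringsAsFactors = FALSE))
  utils::write.table(feats, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a truth feature table written by [write_simulated_trio()]
#'
#' @param path path to the truth table.
#' @return A `truth_track` object.
#' @export
read_truth <- function(path) {
  feats <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(state = "character"))
  bg <- feats[feats$type == "background", , drop = FALSE]
  if (nrow(bg) != 1L) stop("truth table must contain one background row")
  n <- bg$end
  feats <- feats[feats$type != "background", , drop = FALSE]
  state <- rep("333", n)
  for (j in seq_len(nrow(feats)))
    state[seq.int(feats$start[j], feats$end[j])] <- feats$state[j]
  structure(list(state = state, features = feats, n_markers = n,
                 chrom = bg$chrom),
            class = "truth_track")
}
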