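# Robust mixture emission models for log R ratios and B allele frequencies,
# Baum-Welch parameter estimation, and per-segment trio log-likelihoods.

.SAMPLES <- c("F", "M", "O")

# Genotype clusters are keyed by their reduced B-allele fraction so that
# parameters are shared across copy-number states (e.g. the AB cluster of a
# diploid state and the AABB cluster of a two-copy gain both sit at 1/2).
.BAF_KEYS <- c("0", "1/4", "1/3", "1/2", "2/3", "3/4", "1")
.BAF_FRACS <- c(0, 1 / 4, 1 / 3, 1 / 2, 2 / 3, 3 / 4, 1)

.baf_key <- function(g, cn) {
  if (g == 0L) return("0")
  if (g == cn) return("1")
  gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)
  k <- gcd(g, cn)
  paste0(g / k, "/", cn / k)
}

#' Emission model parameters
#'
#' Parameters of the robust mixture emission models. The log R ratio of a
#' sample in copy-number state s is a normal (state-specific mean and sd)
#' contaminated by a uniform outlier component on `lrr_bounds`; the B allele
#' frequency is a genotype-cluster mixture of truncated normals on \[0, 1\]
#' contaminated by a uniform outlier component (homozygous-null samples emit
#' uniform B allele frequencies). Defaults: log R ratio means
#' (-2, -0.5, 0, 0.4, 0.68) for copy numbers 0--4 on the Illumina scale, sd
#' 0.2, outlier probability 0.01; B allele frequency cluster means at the
#' B-allele fraction, sd 0.03 for homozygous clusters and 0.05 otherwise.
#'
#' @param mu_r,sigma_r 3 x 5 matrices (rows father/mother/offspring, columns
#'   copy numbers 0--4) of log R ratio means and sds.
#' @param eps_r,eps_b length-3 outlier probabilities per sample.
#' @param lrr_bounds support of the uniform log R ratio outlier component.
#' @param mu_b,sigma_b 3 x 7 matrices of B allele frequency cluster means and
#'   sds, columns keyed by B-allele fraction (0, 1/4, 1/3, 1/2, 2/3, 3/4, 1).
#' @param mu_shift_max,sigma_bounds,eps_max constraint set for the Baum-Welch
#'   updates: means stay within `mu_shift_max` of their initial values and
#'   remain nondecreasing in copy number, sds stay in `sigma_bounds`, outlier
#'   probabilities in \[0, `eps_max`\].
#' @return A list of class `emission_params`.
#' @export
emission_params <- function(mu_r = NULL, sigma_r = NULL, eps_r = rep(0.01, 3L),
                            lrr_bounds = c(-5, 3),
                            mu_b = NULL, sigma_b = NULL,
                            eps_b = rep(0.01, 3L),
                            mu_shift_max = 0.3, sigma_bounds = c(0.05, 1.0),
                            eps_max = 0.1) {
  dim_r <- list(.SAMPLES, as.character(0:4))
  dim_b <- list(.SAMPLES, .BAF_KEYS)
  if (is.null(mu_r))
    mu_r <- matrix(rep(c(-2, -0.5, 0, 0.4, 0.68), each = 3L), 3L, 5L)
  if (is.null(sigma_r)) sigma_r <- matrix(0.2, 3L, 5L)
  if (is.null(mu_b)) mu_b <- matrix(rep(.BAF_FRACS, each = 3L), 3L, 7L)
  if (is.null(sigma_b))
    sigma_b <- matrix(rep(ifelse(.BAF_FRACS %in% c(0, 1), 0.03, 0.05),
                          each = 3L), 3L, 7L)
  dimnames(mu_r) <- dimnames(sigma_r) <- dim_r
  dimnames(mu_b) <- dimnames(sigma_b) <- dim_b
  stopifnot(all(sigma_r > 0), all(sigma_b > 0), lrr_bounds[1L] < lrr_bounds[2L],
            all(eps_r >= 0), all(eps_r <= 1), all(eps_b >= 0), all(eps_b <= 1))
  structure(list(mu_r = mu_r, sigma_r = sigma_r, eps_r = eps_r,
                 lrr_bounds = lrr_bounds, mu_b = mu_b, sigma_b = sigma_b,
                 eps_b = eps_b, mu_shift_max = mu_shift_max,
                 sigma_bounds = sigma_bounds, eps_max = eps_max),
            class = "emission_params")
}

#' Genotype model for B allele frequencies
#'
#' For a sample with copy number c, the possible genotypes carry 0..c B
#' alleles with cluster means at the B-allele fraction; the genotype prior is
#' binomial in the number of A alleles with the population A-allele frequency
#' `p_A`.
#'
#' @param p_A population A-allele frequency: a scalar applied to all markers,
#'   or a named vector (marker names) as from [read_allele_freqs()]; unnamed
#'   markers default to 0.5.
#' @return A list of class `genotype_model`.
#' @export
genotype_model <- function(p_A = 0.5) {
  stopifnot(all(p_A >= 0), all(p_A <= 1))
  structure(list(p_A = p_A), class = "genotype_model")
}

.marker_pA <- function(geno, marker_names, n) {
  p <- geno$p_A
  if (length(p) == 1L && is.null(names(p))) return(rep(p, n))
  out <- rep(0.5, n)
  hit <- match(marker_names, names(p))
  out[!is.na(hit)] <- p[hit[!is.na(hit)]]
  out
}

.sample_index <- function(k) {
  if (is.character(k)) match(k, .SAMPLES) else as.integer(k)
}

#' Log R ratio emission density
#'
#' Normal plus uniform-outlier mixture:
#' `(1 - eps) * N(r; mu, sigma) + eps * U(r; l, u)`.
#'
#' @param r log R ratio value(s).
#' @param cn copy number state in 0--4.
#' @param k sample: `"F"`, `"M"`, `"O"` or index 1--3.
#' @param params an [emission_params()] object.
#' @return Density value(s).
#' @export
lrr_density <- function(r, cn, k, params = emission_params()) {
  k <- .sample_index(k)
  s <- as.character(as.integer(cn))
  sigma <- params$sigma_r[k, s]
  if (sigma <= 0) stop("sigma_r must be positive")
  l <- params$lrr_bounds[1L]; u <- params$lrr_bounds[2L]
  eps <- params$eps_r[k]
  (1 - eps) * stats::dnorm(r, params$mu_r[k, s], sigma) +
    eps * stats::dunif(r, l, u)
}

.dtnorm01 <- function(b, mu, sigma) {
  z <- stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma)
  stats::dnorm(b, mu, sigma) / z
}

#' B allele frequency emission density
#'
#' For positive copy numbers, a genotype-cluster mixture of truncated normals
#' on \[0, 1\] plus a uniform outlier component; the homozygous-null state
#' (copy number 0) emits uniform \[0, 1\] values.
#'
#' @param b B allele frequency value(s) in \[0, 1\].
#' @param cn copy number state in 0--4.
#' @param k sample: `"F"`, `"M"`, `"O"` or index 1--3.
#' @param geno a [genotype_model()] object.
#' @param params an [emission_params()] object.
#' @param p_A optional numeric vector of per-value A-allele frequencies
#'   overriding `geno` (recycled to `length(b)`).
#' @return Density value(s).
#' @export
baf_density <- function(b, cn, k, geno = genotype_model(),
                        params = emission_params(), p_A = NULL) {
  if (any(b < 0 | b > 1, na.rm = TRUE)) stop("BAF values must lie in [0, 1]")
  cn <- as.integer(cn)
  if (cn == 0L) return(rep(1, length(b)))
  k <- .sample_index(k)
  if (is.null(p_A)) {
    p_A <- if (length(geno$p_A) == 1L && is.null(names(geno$p_A)))
      geno$p_A else 0.5
  }
  p_A <- rep_len(p_A, length(b))
  eps <- params$eps_b[k]
  dens <- rep(0, length(b))
  for (g in 0:cn) {
    key <- .baf_key(g, cn)
    prior <- stats::dbinom(cn - g, cn, p_A)
    dens <- dens + prior * .dtnorm01(b, params$mu_b[k, key],
                                     params$sigma_b[k, key])
  }
  (1 - eps) * dens + eps * 1
}

# n x 5 matrix of per-marker log emission densities (LRR x BAF) for sample k.
.log_emissions <- function(lrr, baf, k, params, geno, p_A) {
  n <- length(lrr)
  logem <- matrix(0, n, 5L)
  for (cn in 0:4) {
    logem[, cn + 1L] <- log(lrr_density(lrr, cn, k, params)) +
      log(baf_density(baf, cn, k, geno, params, p_A = p_A))
  }
  logem
}

# Truncated-normal M-step on [0, 1]: choose (mu, sigma) whose truncated mean
# and variance match the responsibility-weighted sample moments (the exact
# MLE, since the truncated normal with fixed support is an exponential
# family). Fixed-point iteration on the standard truncated-moment identities.
.tn_fit <- function(m1, v, mu, sigma) {
  for (it in 1:50) {
    a <- (0 - mu) / sigma
    b <- (1 - mu) / sigma
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (!is.finite(z) || z < 1e-12) break
    pa <- stats::dnorm(a); pb <- stats::dnorm(b)
    r <- (pa - pb) / z
    varfac <- 1 + (a * pa - b * pb) / z - r^2
    if (!is.finite(varfac) || varfac <= 1e-6) break
    sigma_new <- sqrt(max(v / varfac, 1e-8))
    mu_new <- m1 - sigma_new * r
    if (!is.finite(mu_new) || !is.finite(sigma_new)) break
    conv <- abs(mu_new - mu) < 1e-10 && abs(sigma_new - sigma) < 1e-10
    mu <- min(max(mu_new, -1), 2)
    sigma <- min(max(sigma_new, 1e-4), 2)
    if (conv) break
  }
  c(mu, sigma)
}

.project_params <- function(params, init) {
  for (k in 1:3) {
    mu <- pmin(pmax(params$mu_r[k, ], init$mu_r[k, ] - init$mu_shift_max),
               init$mu_r[k, ] + init$mu_shift_max)
    params$mu_r[k, ] <- cummax(mu)  # nondecreasing in copy number
    # truncated-normal location parameters may sit outside [0, 1]; only the
    # drift from the theoretical cluster fraction is constrained
    params$mu_b[k, ] <- pmin(pmax(params$mu_b[k, ],
                                  .BAF_FRACS - init$mu_shift_max),
                             .BAF_FRACS + init$mu_shift_max)
  }
  params$sigma_r[] <- pmin(pmax(params$sigma_r, init$sigma_bounds[1L]),
                           init$sigma_bounds[2L])
  params$sigma_b[] <- pmin(pmax(params$sigma_b, 0.01), init$sigma_bounds[2L])
  params$eps_r <- pmin(pmax(params$eps_r, 0), init$eps_max)
  params$eps_b <- pmin(pmax(params$eps_b, 0), init$eps_max)
  params
}

#' Estimate emission parameters by the Baum-Welch algorithm
#'
#' Runs EM per sample on a marker-level five-state chain (transition 1/2 to
#' the same state, 1/8 otherwise; uniform initial distribution) with the
#' [lrr_density()] / [baf_density()] emissions. The E-step computes state
#' responsibilities by forward-backward; the M-step updates means, sds and
#' outlier probabilities as responsibility-weighted moments and projects them
#' onto the constraint set (means within `mu_shift_max` of their initial
#' values and nondecreasing in copy number; sds and outlier probabilities
#' within bounds). The marker-level chain is used solely to estimate emission
#' parameters; segment classification remains the job of [posterior_table()].
#'
#' @param trio a `trio_signals` object with at least 500 markers (otherwise
#'   `init` is returned unchanged).
#' @param init initial [emission_params()].
#' @param max_iter maximum EM iterations (0 returns `init`).
#' @param tol stop when the log-likelihood improves by less than `tol`.
#' @param geno a [genotype_model()].
#' @return An `emission_params` object with an attribute `loglik` holding the
#'   per-sample log-likelihood trajectories.
#' @export
fit_emission_params <- function(trio, init = emission_params(),
                                max_iter = 10L, tol = 1e-3,
                                geno = genotype_model()) {
  stopifnot(inherits(trio, "trio_signals"))
  n <- nrow(trio$markers)
  if (n < 500L || max_iter == 0L) return(init)
  p_A <- .marker_pA(geno, trio$markers$name, n)
  params <- init
  trajectories <- vector("list", 3L)
  for (k in 1:3) {
    lrr <- trio$lrr[, k]; baf <- trio$baf[, k]
    ll_trace <- numeric(0)
    prev_ll <- -Inf
    for (iter in seq_len(max_iter)) {
      logem <- .log_emissions(lrr, baf, k, params, geno, p_A)
      fb <- .hmm_fb(logem, rep(0.2, 5L), 0.5)
      if (!is.finite(fb$loglik))
        stop("non-finite likelihood in Baum-Welch at iteration ", iter)
      ll_trace <- c(ll_trace, fb$loglik)
      gamma <- fb$gamma

      # LRR updates: within-state split of normal vs. uniform outlier
      unif_dens <- stats::dunif(lrr, params$lrr_bounds[1L],
                                params$lrr_bounds[2L])
      eps_num <- 0
      for (cn in 0:4) {
        s <- as.character(cn)
        norm_part <- (1 - params$eps_r[k]) *
          stats::dnorm(lrr, params$mu_r[k, s], params$sigma_r[k, s])
        out_part <- params$eps_r[k] * unif_dens
        tau <- norm_part / (norm_part + out_part)
        w <- gamma[, cn + 1L] * tau
        sw <- sum(w)
        if (sw > 1e-8) {
          mu <- sum(w * lrr) / sw
          params$mu_r[k, s] <- mu
          params$sigma_r[k, s] <- sqrt(sum(w * (lrr - mu)^2) / sw)
        }
        eps_num <- eps_num + sum(gamma[, cn + 1L] * (1 - tau))
      }
      params$eps_r[k] <- eps_num / n

      # BAF updates: cluster responsibilities pooled across states sharing a
      # B-allele fraction; the homozygous-null state is uniform and
      # contributes to neither the clusters nor the outlier probability.
      wsum <- bsum <- b2sum <- stats::setNames(rep(0, 7L), .BAF_KEYS)
      eps_num_b <- 0; eps_den_b <- 0
      for (cn in 1:4) {
        comp <- matrix(0, n, cn + 2L)  # clusters then outlier
        for (g in 0:cn) {
          key <- .baf_key(g, cn)
          comp[, g + 1L] <- (1 - params$eps_b[k]) *
            stats::dbinom(cn - g, cn, p_A) *
            .dtnorm01(baf, params$mu_b[k, key], params$sigma_b[k, key])
        }
        comp[, cn + 2L] <- params$eps_b[k]
        tot <- rowSums(comp)
        g_state <- gamma[, cn + 1L]
        for (g in 0:cn) {
          key <- .baf_key(g, cn)
          w <- g_state * comp[, g + 1L] / tot
          wsum[key] <- wsum[key] + sum(w)
          bsum[key] <- bsum[key] + sum(w * baf)
          b2sum[key] <- b2sum[key] + sum(w * baf^2)
        }
        eps_num_b <- eps_num_b + sum(g_state * comp[, cn + 2L] / tot)
        eps_den_b <- eps_den_b + sum(g_state)
      }
      for (key in .BAF_KEYS[wsum > 1e-8]) {
        m1 <- bsum[key] / wsum[key]
        v <- max(b2sum[key] / wsum[key] - m1^2, 1e-8)
        tn <- .tn_fit(m1, v, params$mu_b[k, key], params$sigma_b[k, key])
        params$mu_b[k, key] <- tn[1L]
        params$sigma_b[k, key] <- tn[2L]
      }
      if (eps_den_b > 0) params$eps_b[k] <- eps_num_b / eps_den_b

      params <- .project_params(params, init)
      if (abs(fb$loglik - prev_ll) < tol) break
      prev_ll <- fb$loglik
    }
    trajectories[[k]] <- ll_trace
  }
  attr(params, "loglik") <- stats::setNames(trajectories, .SAMPLES)
  params
}

# Per-sample, per-copy-number log-likelihood sums over a marker index range.
.state_loglik_matrix <- function(idx, trio, params, geno) {
  p_A <- .marker_pA(geno, trio$markers$name[idx], length(idx))
  out <- matrix(0, 3L, 5L, dimnames = list(.SAMPLES, as.character(0:4)))
  for (k in 1:3) {
    lrr <- trio$lrr[idx, k]; baf <- trio$baf[idx, k]
    for (cn in 0:4) {
      out[k, cn + 1L] <- sum(log(lrr_density(lrr, cn, k, params))) +
        sum(log(baf_density(baf, cn, k, geno, params, p_A = p_A)))
    }
  }
  out
}

#' Log-likelihood of a trio state over a segment
#'
#' Sum over the three samples and the segment's markers of the log emission
#' densities (log R ratio and B allele frequency), each sample evaluated at
#' its copy number under `state`. Log R ratios and B allele frequencies are
#' treated as conditionally independent given the copy-number states.
#'
#' @param seg segment: a list/one-row data frame with `start_index` and
#'   `end_index` (1-based inclusive marker indices into `trio`), or an
#'   integer vector of length 2.
#' @param state three-character trio state code (e.g. "332").
#' @param trio a `trio_signals` object.
#' @param params an [emission_params()] object.
#' @param geno a [genotype_model()].
#' @return Log-likelihood (scalar).
#' @export
segment_loglik <- function(seg, state, trio, params = emission_params(),
                           geno = genotype_model()) {
  if (is.numeric(seg) && length(seg) == 2L)
    seg <- list(start_index = seg[1L], end_index = seg[2L])
  idx <- seq.int(seg$start_index, seg$end_index)
  stopifnot(all(idx >= 1L), all(idx <= nrow(trio$markers)))
  cns <- symbol_cn(as.integer(strsplit(as.character(state), "")[[1L]]))
  mat <- .state_loglik_matrix(idx, trio, params, geno)
  sum(mat[cbind(1:3, cns + 1L)])
}
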