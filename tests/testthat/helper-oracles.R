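# Independent oracles and small fixture builders used across the suite.

# brute-force Mendelian transmission: enumerate the 2 x 2 homolog choices
oracle_mendelian <- function(f_cn, m_cn, o_cn) {
  homologs <- function(cn) c(ceiling(cn / 2), floor(cn / 2))
  hits <- 0L
  for (tf in homologs(f_cn)) for (tm in homologs(m_cn))
    if (min(tf + tm, 4L) == o_cn) hits <- hits + 1L
  hits / 4
}

# brute-force circular max t-statistic over every admissible window
oracle_cbs_max <- function(x) {
  n <- length(x)
  sigma <- stats::sd(x)
  best <- -Inf
  for (a in 1:n) for (b in a:n) {
    L <- b - a + 1L
    if (L == n) next
    w <- x[a:b]; r <- x[-(a:b)]
    stat <- abs(mean(w) - mean(r)) / (sigma * sqrt(1 / L + 1 / (n - L)))
    if (stat > best) best <- stat
  }
  best
}

# naive per-marker, per-state posterior evaluator, written independently of
# the package's vectorized path (densities spelled out inline)
oracle_posterior <- function(idx, prev_state, trio, params, geno,
                             p_mendelian = 1 - 1.5e-6) {
  states <- enumerate_states()$states
  cn_of <- c(`1` = 0L, `2` = 1L, `3` = 2L, `5` = 3L, `6` = 4L)
  dtn <- function(b, mu, sd)
    dnorm(b, mu, sd) / (pnorm(1, mu, sd) - pnorm(0, mu, sd))
  baf_key <- function(g, cn) {
    if (g == 0) return("0")
    if (g == cn) return("1")
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    k <- gcd(g, cn)
    paste0(g / k, "/", cn / k)
  }
  lp <- sapply(states, function(code) {
    syms <- as.integer(strsplit(code, "")[[1]])
    cns <- unname(cn_of[as.character(syms)])
    ll <- 0
    for (k in 1:3) {
      cn <- cns[k]
      for (i in idx) {
        r <- trio$lrr[i, k]; b <- trio$baf[i, k]
        s <- as.character(cn)
        dr <- (1 - params$eps_r[k]) *
          dnorm(r, params$mu_r[k, s], params$sigma_r[k, s]) +
          params$eps_r[k] *
            dunif(r, params$lrr_bounds[1], params$lrr_bounds[2])
        if (cn == 0) {
          db <- 1
        } else {
          db <- 0
          for (g in 0:cn) {
            key <- baf_key(g, cn)
            db <- db + dbinom(cn - g, cn, 0.5) *
              dtn(b, params$mu_b[k, key], params$sigma_b[k, key])
          }
          db <- (1 - params$eps_b[k]) * db + params$eps_b[k]
        }
        ll <- ll + log(dr) + log(db)
      }
    }
    pm <- oracle_mendelian(cns[1], cns[2], cns[3])
    off <- p_mendelian * pm + (1 - p_mendelian) / 5
    par <- if (is.null(prev_state)) log(0.2) + log(0.2)
    else {
      ps <- as.integer(strsplit(prev_state, "")[[1]])
      sum(log(ifelse(ps[1:2] == syms[1:2], 0.5, 0.125)))
    }
    unname(ll + log(off) + par)
  })
  names(lp) <- states
  lse <- max(lp) + log(sum(exp(lp - max(lp))))
  exp(lp - lse)
}

# deterministic small trio with diploid-like signals
make_toy_trio <- function(n = 40, chrom = 1L, seed = 7L) {
  set.seed(seed)
  markers <- data.frame(name = sprintf("m%03d", seq_len(n)), chrom = chrom,
                        position = seq_len(n) * 1000L,
                        stringsAsFactors = FALSE)
  lrr <- matrix(rnorm(3 * n, 0, 0.15), n, 3)
  baf <- matrix(pmin(pmax(sample(c(0, 0.5, 1), 3 * n, replace = TRUE) +
                            rnorm(3 * n, 0, 0.02), 0), 1), n, 3)
  trio_signals(markers, lrr, baf)
}

# deterministic sample_signals object (optionally a subset of the markers)
make_sample <- function(n = 10, keep = seq_len(n), seed = 5L) {
  set.seed(seed)
  lrr <- round(rnorm(n, 0, 0.15), 4)
  baf <- round(pmin(pmax(sample(c(0, .5, 1), n, TRUE) +
                           rnorm(n, 0, .02), 0), 1), 4)
  structure(list(markers = data.frame(name = sprintf("m%02d", seq_len(n)),
                                      chrom = 1L,
                                      position = seq_len(n) * 1000L,
                                      stringsAsFactors = FALSE)[keep, ],
                 lrr = lrr[keep], baf = baf[keep], sample = "s"),
            class = "sample_signals")
}

# write a PennCNV-style signal file from vectors
write_signal_fixture <- function(path, name, chr, pos, lrr, baf,
                                 label = NULL) {
  lrr_col <- if (is.null(label)) "Log R Ratio"
             else paste0(label, ".Log R Ratio")
  baf_col <- if (is.null(label)) "B Allele Freq"
             else paste0(label, ".B Allele Freq")
  tab <- data.frame(Name = name, Chr = chr, Position = pos, lrr = lrr,
                    baf = baf, stringsAsFactors = FALSE, check.names = FALSE)
  names(tab)[4:5] <- c(lrr_col, baf_col)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# simulate marker-level data from the per-sample five-state emission chain
# (used for Baum-Welch recovery checks)
sim_emission_chain <- function(n, params, k = 1L, seed = 1L) {
  set.seed(seed)
  states <- integer(n)
  states[1] <- sample(5L, 1L)
  for (i in 2:n)
    states[i] <- if (runif(1) < 0.5) states[i - 1] else
      sample(setdiff(1:5, states[i - 1]), 1L)
  cn <- states - 1L
  lrr <- numeric(n); baf <- numeric(n)
  fracs <- c(`0` = 0, `1/4` = 1/4, `1/3` = 1/3, `1/2` = 1/2, `2/3` = 2/3,
             `3/4` = 3/4, `1` = 1)
  baf_key <- function(g, c) {
    if (g == 0) return("0")
    if (g == c) return("1")
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    d <- gcd(g, c)
    paste0(g / d, "/", c / d)
  }
  rtn <- function(mu, sd)
    qnorm(runif(1, pnorm(0, mu, sd), pnorm(1, mu, sd)), mu, sd)
  for (i in 1:n) {
    s <- as.character(cn[i])
    lrr[i] <- if (runif(1) < params$eps_r[k])
      runif(1, params$lrr_bounds[1], params$lrr_bounds[2])
    else rnorm(1, params$mu_r[k, s], params$sigma_r[k, s])
    if (cn[i] == 0) {
      baf[i] <- runif(1)
    } else if (runif(1) < params$eps_b[k]) {
      baf[i] <- runif(1)
    } else {
      g <- rbinom(1, cn[i], 0.5)
      key <- baf_key(g, cn[i])
      baf[i] <- rtn(params$mu_b[k, key], params$sigma_b[k, key])
    }
  }
  list(states = states, cn = cn, lrr = lrr, baf = baf)
}

# wrap single-sample vectors into a trio whose other two samples are diploid
chain_as_trio <- function(lrr, baf, seed = 2L) {
  set.seed(seed)
  n <- length(lrr)
  markers <- data.frame(name = sprintf("m%05d", 1:n), chrom = 1L,
                        position = (1:n) * 1000L, stringsAsFactors = FALSE)
  other <- function() list(lrr = rnorm(n, 0, 0.2),
                           baf = pmin(pmax(sample(c(0, .5, 1), n, TRUE) +
                                             rnorm(n, 0, 0.03), 0), 1))
  o1 <- other(); o2 <- other()
  trio_signals(markers, cbind(lrr, o1$lrr, o2$lrr),
               cbind(baf, o1$baf, o2$baf))
}
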