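test_that("LRR density follows the normal + uniform outlier mixture", {
  p <- emission_params(eps_r = rep(0, 3))
  p$sigma_r[, ] <- 0.15
  # peak of a N(mu, 0.15) at its mean
  expect_equal(lrr_density(0, cn = 2, k = "O", p), 1 / (0.15 * sqrt(2 * pi)),
               tolerance = 1e-6)

  p1 <- emission_params(eps_r = rep(1, 3), lrr_bounds = c(-5, 3))
  expect_equal(lrr_density(0, 2, 1, p1), 0.125)  # pure uniform 1/8
  expect_equal(lrr_density(10, 2, 1, p1), 0)     # outside the bounds

  p05 <- emission_params(eps_r = rep(0.05, 3))
  # far outside +-6 sd the normal term vanishes and the outlier floor remains
  expect_equal(lrr_density(2.9, 0, 2, p05), 0.05 / 8, tolerance = 1e-8)

  bad <- emission_params()
  bad$sigma_r[1, 1] <- -1
  expect_error(lrr_density(0, 0, 1, bad), "positive")
})

test_that("BAF density mixes genotype clusters and handles the null state", {
  p <- emission_params()
  geno <- genotype_model()
  b <- seq(0, 1, by = 0.05)
  expect_equal(baf_density(b, cn = 0, k = 1, geno, p), rep(1, length(b)))
  expect_error(baf_density(1.2, 2, 1, geno, p), "\\[0, 1\\]")

  # diploid, eps = 0: manual three-cluster mixture with binomial (1/4,1/2,1/4)
  p0 <- emission_params(eps_b = rep(0, 3))
  dtn <- function(b, mu, sd)
    dnorm(b, mu, sd) / (pnorm(1, mu, sd) - pnorm(0, mu, sd))
  manual <- 0.25 * dtn(b, 0, 0.03) + 0.5 * dtn(b, 0.5, 0.05) +
    0.25 * dtn(b, 1, 0.03)
  expect_equal(baf_density(b, 2, 1, geno, p0), manual, tolerance = 1e-12)

  # a skewed allele frequency reweights the clusters
  d_skew <- baf_density(0.02, 2, 1, genotype_model(p_A = 0.9), p0)
  manual_skew <- dbinom(2, 2, 0.9) * dtn(0.02, 0, 0.03) +
    dbinom(1, 2, 0.9) * dtn(0.02, 0.5, 0.05) +
    dbinom(0, 2, 0.9) * dtn(0.02, 1, 0.03)
  expect_equal(d_skew, manual_skew)
})

test_that("both emission densities integrate to one for every state", {
  p <- emission_params(eps_r = rep(0.05, 3), eps_b = rep(0.04, 3))
  geno <- genotype_model()
  for (cn in 0:4) {
    for (k in 1:3) {
      int_r <- integrate(function(r) lrr_density(r, cn, k, p), -8, 6,
                         rel.tol = 1e-9)$value
      expect_equal(int_r, 1, tolerance = 1e-6)
      int_b <- integrate(function(b) baf_density(b, cn, k, geno, p), 0, 1,
                         rel.tol = 1e-9)$value
      expect_equal(int_b, 1, tolerance = 1e-6)
    }
  }
})

test_that("segment log-likelihood is a sum of per-marker log densities", {
  trio <- make_toy_trio(10, seed = 21)
  p <- emission_params()
  geno <- genotype_model()
  ll <- segment_loglik(c(3, 3), "332", trio, p, geno)
  cns <- c(2, 2, 1)
  direct <- sum(vapply(1:3, function(k)
    log(lrr_density(trio$lrr[3, k], cns[k], k, p)) +
      log(baf_density(trio$baf[3, k], cns[k], k, geno, p)), numeric(1)))
  expect_equal(ll, direct, tolerance = 1e-12)

  # additivity over adjacent half-segments
  whole <- segment_loglik(c(1, 10), "333", trio, p, geno)
  expect_equal(whole,
               segment_loglik(c(1, 5), "333", trio, p, geno) +
                 segment_loglik(c(6, 10), "333", trio, p, geno),
               tolerance = 1e-10)
})

test_that("diploid data favors 333 over 332 increasingly with coverage", {
  margin <- vapply(c(10, 100), function(n) {
    set.seed(100 + n)
    sim <- sim_emission_chain(n, emission_params(), k = 3, seed = 100 + n)
    # force diploid: regenerate as a pure CN2 stretch
    lrr <- rnorm(n, 0, 0.2)
    g <- rbinom(n, 2, 0.5)
    baf <- pmin(pmax(g / 2 + rnorm(n, 0, 0.04), 0), 1)
    trio <- chain_as_trio(lrr, baf, seed = n)
    segment_loglik(c(1, n), "333", trio) -
      segment_loglik(c(1, n), "332", trio)
  }, numeric(1))
  expect_true(all(margin > 0))
  expect_gt(margin[2], margin[1])
})

test_that("Baum-Welch recovers emission parameters from simulated data", {
  truth <- emission_params()
  sim <- sim_emission_chain(25000, truth, k = 1, seed = 31)
  trio <- chain_as_trio(sim$lrr, sim$baf, seed = 32)
  fit <- fit_emission_params(trio, emission_params(), max_iter = 10)
  expect_true(all(abs(fit$mu_r[1, ] - truth$mu_r[1, ]) < 0.05))
  expect_true(all(abs(fit$sigma_r[1, ] - truth$sigma_r[1, ]) < 0.02))

  # likelihood trace is nondecreasing (EM ascent)
  ll <- attr(fit, "loglik")[["F"]]
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))

  # too few markers or zero iterations: initial values pass through
  small <- make_toy_trio(50)
  expect_identical(fit_emission_params(small, truth), truth)
  expect_identical(fit_emission_params(trio, truth, max_iter = 0), truth)
})
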