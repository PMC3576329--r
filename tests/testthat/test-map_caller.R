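test_that("posterior table is a proper distribution over the 121 states", {
  trio <- make_toy_trio(30, seed = 13)
  post <- posterior_table(c(5, 20), NULL, trio)
  expect_length(post, 121L)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_true(all(post >= 0))
  expect_setequal(names(post), enumerate_states()$states)
})

test_that("with a flat likelihood the posterior follows the trio-state prior", {
  # identical emission parameters across states make the likelihood constant
  # over every state that involves no homozygous-null sample
  p <- emission_params()
  p$mu_r[, ] <- 0; p$sigma_r[, ] <- 0.2
  p$mu_b[, ] <- 0.5; p$sigma_b[, ] <- 0.2
  trio <- make_toy_trio(12, seed = 17)
  post <- posterior_table(c(1, 12), NULL, trio, params = p)
  sp <- enumerate_states()$states
  no_null <- sp[!grepl("1", sp)]
  prior <- vapply(no_null, function(code) {
    s <- as.integer(strsplit(code, "")[[1]])
    offspring_conditional(s[1], s[2], s[3]) / 25
  }, numeric(1))
  # posterior restricted to these states is proportional to the prior
  ratio <- post[no_null] / prior
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("posterior table matches the naive per-marker evaluator", {
  for (s in 1:3) {
    set.seed(s)
    n <- sample(10:100, 1)
    trio <- make_toy_trio(n, seed = 50 + s)
    p <- emission_params(eps_r = rep(0.02, 3), eps_b = rep(0.03, 3))
    prev <- if (s == 1) NULL else "333"
    post <- posterior_table(c(1, n), prev, trio, params = p)
    naive <- oracle_posterior(1:n, prev, trio, p, genotype_model())
    expect_equal(unname(post[names(naive)]), unname(naive),
                 tolerance = 1e-9)
  }
})

test_that("a diploid-only trio yields no de novo calls", {
  ok <- 0L
  for (s in 1:3) {
    cfg <- sim_config(n_markers = 4000, rho = 0.2, sigma_r = 0.2,
                      de_novo_sizes = integer(0),
                      transmitted_sizes = integer(0),
                      homozygosity_sizes = integer(0))
    sim <- simulate_trio_chromosome(cfg, chrom_seed = 600 + s)
    fit <- call_trio(sim$trio, seg_params(n_perm = 500, seed = s))
    if (all(fit$calls$state == "333") && !any(fit$calls$is_de_novo))
      ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})

test_that("a planted de novo deletion is called 332 over the feature", {
  cfg <- sim_config(n_markers = 5000, rho = 0.2, sigma_r = 0.15,
                    de_novo_sizes = 100L, transmitted_sizes = integer(0),
                    homozygosity_sizes = integer(0))
  sim <- simulate_trio_chromosome(cfg, chrom_seed = 77)
  fit <- call_trio(sim$trio, seg_params(n_perm = 1000, seed = 7))
  feat <- sim$truth$features
  dn <- fit$calls[fit$calls$state == "332", , drop = FALSE]
  expect_gte(nrow(dn), 1L)
  overlap <- sum(pmin(dn$end_index, feat$end) -
                   pmax(dn$start_index, feat$start) + 1)
  expect_gte(overlap / feat$size, 0.5)
  expect_true(all(dn$is_de_novo))
  expect_true(all(dn$log10_odds_vs_diploid > 0))
})

test_that("parental deletions with a diploid offspring are not de novo", {
  # positive minimum distance arises, but the absolute copy numbers resolve
  # the region as 223 (both parents hemizygous, offspring diploid)
  set.seed(88)
  n <- 3000; idx <- 1001:1100
  markers <- data.frame(name = sprintf("m%04d", 1:n), chrom = 1L,
                        position = (1:n) * 1000L, stringsAsFactors = FALSE)
  lrr <- matrix(rnorm(3 * n, 0, 0.15), n, 3)
  lrr[idx, 1:2] <- lrr[idx, 1:2] - 0.5
  g <- matrix(rbinom(3 * n, 2, 0.5), n, 3)
  baf <- pmin(pmax(g / 2 + rnorm(3 * n, 0, 0.03), 0), 1)
  # hemizygous parents: single-allele BAF near 0 or 1
  baf[idx, 1:2] <- pmin(pmax(rbinom(2 * length(idx), 1, 0.5) +
                               rnorm(2 * length(idx), 0, 0.03), 0), 1)
  trio <- trio_signals(markers, lrr, baf)
  fit <- call_trio(trio, seg_params(n_perm = 1000, seed = 5))
  hit <- fit$calls[fit$calls$start_index <= 1050 &
                     fit$calls$end_index >= 1050, ]
  expect_equal(hit$state, "223")
  expect_false(hit$is_de_novo)
  expect_gt(mean(minimum_distance(trio)$d[idx]), 0.3)
})

test_that("ranking orders de novo calls by posterior odds, invariantly", {
  calls <- data.frame(chrom = c(1L, 2L, 1L, 3L),
                      start_bp = c(100L, 5L, 900L, 20L),
                      end_bp = c(200L, 50L, 990L, 80L),
                      start_index = 1:4, end_index = 2:5,
                      n_markers = c(10L, 50L, 10L, 30L),
                      state = c("332", "333", "335", "331"),
                      map_posterior = rep(0.9, 4),
                      log10_odds_vs_diploid = c(6, 0, 2, 6),
                      is_de_novo = c(TRUE, FALSE, TRUE, TRUE),
                      stringsAsFactors = FALSE)
  ranked <- rank_calls(calls)
  expect_equal(ranked$log10_odds_vs_diploid, c(6, 6, 2))
  # odds tie broken by coverage
  expect_equal(ranked$n_markers[1:2], c(30L, 10L))
  expect_equal(rank_calls(calls[1, ])$state, "332")
  for (s in 1:10) {
    set.seed(s)
    expect_identical(rank_calls(calls[sample(4), ]), ranked)
  }
})
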