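test_that("simulated moments match the configured noise model", {
  sim <- simulate_trio_chromosome(sim_config(rho = 0, sigma_r = 0.15),
                                  chrom_seed = 101)
  dip <- sim$truth$state == "333"
  dip[unlist(lapply(which(sim$truth$features$type == "homozygosity_wave"),
                    function(j) seq(sim$truth$features$start[j],
                                    sim$truth$features$end[j])))] <- FALSE
  for (k in 1:3)
    expect_lt(abs(mad_lrr(sim$trio$lrr[dip, k]) - 0.15), 0.01)
  cors <- cor(sim$trio$lrr[dip, ])[lower.tri(diag(3))]
  expect_true(all(abs(cors) < 0.02))

  sim5 <- simulate_trio_chromosome(sim_config(rho = 0.5, sigma_r = 0.2),
                                   chrom_seed = 102)
  dip5 <- sim5$truth$state == "333"
  cors5 <- cor(sim5$trio$lrr[dip5, ])[lower.tri(diag(3))]
  expect_true(all(abs(cors5 - 0.5) < 0.03))
})

test_that("the truth track lists the configured features consistently", {
  sim <- simulate_trio_chromosome(sim_config(), chrom_seed = 103)
  feats <- sim$truth$features
  expect_equal(sum(feats$type == "de_novo_del"), 4L)
  expect_equal(sum(feats$type == "transmitted_del"), 4L)
  expect_equal(sum(feats$type == "homozygosity_wave"), 3L)
  expect_setequal(feats$size[feats$type == "de_novo_del"],
                  c(10L, 25L, 50L, 100L))
  expect_setequal(feats$size[feats$type == "homozygosity_wave"],
                  c(50L, 100L, 500L))

  # marker-level truth reconstructs from the feature list
  rebuilt <- rep("333", sim$truth$n_markers)
  for (j in seq_len(nrow(feats)))
    rebuilt[feats$start[j]:feats$end[j]] <- feats$state[j]
  expect_identical(rebuilt, sim$truth$state)

  # features separated by at least the diploid buffer
  gaps <- feats$start[-1] - feats$end[-nrow(feats)] - 1L
  expect_true(all(gaps >= 200L))
})

test_that("offspring BAF loses its heterozygous cluster in de novo deletions", {
  sim <- simulate_trio_chromosome(sim_config(sigma_r = 0.15),
                                  chrom_seed = 104)
  feats <- sim$truth$features
  dn_idx <- unlist(lapply(which(feats$type == "de_novo_del"),
                          function(j) seq(feats$start[j], feats$end[j])))
  baf_dn <- sim$trio$baf[dn_idx, "O"]
  expect_lt(mean(baf_dn > 0.4 & baf_dn < 0.6), 0.01)
  # while diploid regions show all three clusters
  dip_idx <- which(sim$truth$state == "333")[1:2000]
  baf_dip <- sim$trio$baf[dip_idx, "O"]
  expect_gt(mean(baf_dip > 0.4 & baf_dip < 0.6), 0.3)
})

test_that("shared waves leave the minimum distance flat in wave regions", {
  sim <- simulate_trio_chromosome(sim_config(sigma_r = 0.15),
                                  chrom_seed = 105)
  feats <- sim$truth$features
  md <- minimum_distance(sim$trio)
  for (j in which(feats$type == "homozygosity_wave")) {
    idx <- seq(feats$start[j], feats$end[j])
    # within sampling noise of zero (|d| has sd ~ 0.18 here), and far from
    # tracking the -0.2 trough depth
    se <- mad_lrr(md$d) / sqrt(length(idx))
    expect_lt(abs(mean(md$d[idx])), max(3 * se, 0.03))
    # yet the offspring's own log R ratio does dip in the trough
    expect_lt(mean(sim$trio$lrr[idx, "O"]), -0.05)
  }
})

test_that("the study grid is complete and bit-reproducible", {
  sims <- simulate_study(n_chromosomes = 1L, seed = 9L, n_markers = 4000L)
  expect_length(sims, 12L)
  grid <- attr(sims, "grid")
  expect_equal(nrow(unique(grid[, c("rho", "sigma_r")])), 12L)

  again <- simulate_study(n_chromosomes = 1L, seed = 9L, n_markers = 4000L)
  expect_identical(sims[[5]]$trio, again[[5]]$trio)
  expect_identical(sims[[12]]$truth, again[[12]]$truth)

  other <- simulate_study(n_chromosomes = 1L, seed = 10L, n_markers = 4000L)
  expect_false(identical(sims[[1]]$trio$lrr, other[[1]]$trio$lrr))
})

test_that("simulated trios survive a disk round-trip", {
  dir <- withr::local_tempdir()
  sim <- simulate_trio_chromosome(sim_config(n_markers = 4000L),
                                  chrom_seed = 106)
  paths <- write_simulated_trio(sim, dir, "t1")
  expect_true(all(file.exists(paths)))
  trio <- assemble_trio(read_signal_file(paths["father"]),
                        read_signal_file(paths["mother"]),
                        read_signal_file(paths["offspring"]))
  expect_equal(nrow(trio$markers), 4000L)
  expect_equal(trio$lrr[, "F"], round(sim$trio$lrr[, 1], 6))
  truth <- read_truth(paths["truth"])
  expect_identical(truth$state, sim$truth$state)
  expect_equal(truth$n_markers, 4000L)
})
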