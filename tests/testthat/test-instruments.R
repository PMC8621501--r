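test_that("clumping keeps independent variants and prunes dominated ones", {
  stats <- summary_stats(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
    pos = c(1000L, 2000L, 3000L), effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.01,
    pvalue = c(1e-10, 1e-9, 1e-8), n = 1e5, stringsAsFactors = FALSE))
  ld0 <- ld_matrix(stats$snp_id, diag(3), stats$pos)
  expect_equal(clump(stats, ld0, 0.2, 250000)$snp_id, stats$snp_id)

  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.9
  ld <- ld_matrix(stats$snp_id, r2, stats$pos)
  kept <- clump(stats[1:2, ], ld, 0.2, 250000)
  expect_identical(kept$snp_id, "rs1")
  # outside the distance window the correlated pair survives
  far <- stats
  far$pos <- c(1000L, 400000L, 3000L)
  ld_far <- ld_matrix(far$snp_id, r2, far$pos)
  expect_setequal(clump(far[1:2, ], ld_far, 0.2, 250000)$snp_id,
                  c("rs1", "rs2"))
  expect_error(clump(stats, ld_matrix("rs9", diag(1), 1L), 0.2, 1e5),
               "missing from LD")
})

test_that("greedy clumping matches the brute-force oracle on random instances", {
  for (seed in 1:50) {
    inst <- random_clump_instance(sample(5:20, 1), seed)
    for (preset in list(c(0.001, 1e7), c(0.2, 250000))) {
      got <- clump(inst$stats, inst$ld, preset[1], preset[2])$snp_id
      want <- clump_oracle(inst$stats, inst$ld, preset[1], preset[2])
      expect_setequal(got, want)
    }
  }
})

test_that("clump output preserves the input ordering of retained variants", {
  inst <- random_clump_instance(15, 77)
  got <- clump(inst$stats, inst$ld, 0.2, 250000)
  expect_identical(got$snp_id,
                   inst$stats$snp_id[inst$stats$snp_id %in% got$snp_id])
})

test_that("the F-statistic is the squared z of the exposure association", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.02), 0)
  f <- f_statistic(0.0316, 0.01)
  expect_equal(f, 9.9856, tolerance = 1e-6)
  expect_lt(f, 10)  # excluded at the weak-instrument bound
  expect_error(f_statistic(0.1, 0), "se > 0")
})

test_that("variance explained follows the 2p(1-p)beta^2 formula", {
  one <- data.frame(eaf = 0.5, beta = 0.1)
  expect_equal(variance_explained(one), 0.005)
  expect_equal(variance_explained(one[0, ]), 0)
  expect_error(variance_explained(data.frame(eaf = NA_real_, beta = 0.1)),
               "missing eaf")
})

test_that("variance explained tracks the simulated truth at large n", {
  cfg <- recovery_config(31)
  sim <- simulate_pair(cfg)
  truth_ve <- sum(2 * sim$exposure$eaf * (1 - sim$exposure$eaf) *
                    sim$truth$gamma^2)
  est_ve <- variance_explained(sim$exposure[sim$truth$is_instrument, ])
  expect_lt(abs(est_ve - truth_ve) / truth_ve, 0.1)
})

test_that("selection applies every filter in order and logs exclusions", {
  set.seed(41)
  m <- 30
  ex <- summary_stats(data.frame(
    snp_id = sprintf("rs%02d", 1:m), chrom = "1", pos = (1:m) * 1e6,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.05, se = 0.005,
    pvalue = c(rep(1e-12, 25), rep(0.5, 5)), n = 1e5,
    stringsAsFactors = FALSE), trait_name = "exp")
  ou_p <- rep(0.5, m); ou_p[1] <- 1e-9   # rs01 is outcome-associated
  ou_b <- rep(0.01, m)
  ou <- summary_stats(data.frame(
    snp_id = sprintf("rs%02d", 1:m), chrom = "1", pos = (1:m) * 1e6,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = ou_b, se = 0.02, pvalue = ou_p, n = 1e5,
    stringsAsFactors = FALSE), trait_name = "out", trait_type = "binary")
  ld <- ld_matrix(ex$snp_id, diag(m), ex$pos)

  inst <- suppressMessages(select_instruments(ex, ou, ld))
  expect_false("rs01" %in% inst$variants$snp_id)
  log <- inst$selection_log
  expect_equal(log$reason[log$snp_id == "rs01"], "outcome_associated")
  expect_equal(sum(log$reason == "exposure_not_significant"), 5)
  expect_equal(nrow(inst$variants), 24)
  # retained set is a subset of the p-significant set
  expect_true(all(inst$variants$snp_id %in% ex$snp_id[ex$pvalue < 5e-8]))
  # every retained variant clears the F bound
  expect_true(all(inst$f > 10))

  # filters off: p threshold 1 and no LD keeps all minus the F filter
  all_in <- suppressMessages(select_instruments(
    ex, ou, ld, p_exp_threshold = 1, p_out_threshold = 1e-30,
    f_threshold = 0))
  expect_equal(nrow(all_in$variants), m)
})

test_that("selection survives an empty result with a diagnostic", {
  ex <- random_stats(10, 51, "e")
  ou <- random_stats(10, 52, "o")
  ld <- ld_matrix(ex$snp_id, diag(10), ex$pos)
  expect_message(inst <- select_instruments(ex, ou, ld), "no instruments")
  expect_equal(nrow(inst$variants), 0)
  expect_equal(inst$r2_explained, 0)
})

test_that("simulated selection recovers close to the planted instrument count", {
  hits <- integer(20)
  for (r in seq_len(20)) {
    cfg <- sim_config(m_variants = 100, prop_instruments = 0.9,
                      sigma_gamma = 0.12, n_exp = 2e6, theta = 0,
                      seed = 600 + r)
    sim <- simulate_pair(cfg)
    inst <- suppressMessages(select_instruments(sim$exposure, sim$outcome,
                                                sim$ld))
    hits[r] <- nrow(inst$variants)
  }
  # 90 planted strong instruments: retained count within +/-10% on average
  expect_gt(mean(hits), 81)
  expect_lt(mean(hits), 99)
})
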