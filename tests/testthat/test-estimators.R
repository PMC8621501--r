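test_that("the Wald ratio divides outcome by exposure association", {
  h <- h_df(bx = 0.1, by = 0.05, sx = 0.01, sy = 0.1)
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 1.0)
  h0 <- h_df(bx = 0.1, by = 0, sx = 0.01, sy = 0.1)
  expect_equal(wald_ratio(h0)$beta, 0)
  # p agrees with the normal CDF at z = 1.96
  h96 <- h_df(bx = 1, by = 1.96, sx = 0.01, sy = 1)
  expect_equal(wald_ratio(h96)$pvalue, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_error(wald_ratio(h_df(0, 0.1, 0.01, 0.1)), "undefined")
})

test_that("IVW is exact under homogeneity and refuses a single variant", {
  h <- h_df(bx = c(0.1, 0.2), by = c(0.05, 0.10), sx = 0.01, sy = 0.02)
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(est$het$Q, 0)
  expect_equal(est$het$i2, 0)
  expect_equal(est$or_, exp(est$beta))
  expect_error(mr_ivw(h[1, ]), "wald_ratio")
})

test_that("IVW and Egger agree with the weighted least squares oracle", {
  for (seed in 1:25) {
    h <- random_h(sample(5:50, 1), seed)
    est <- mr_ivw(h)
    expect_equal(est$beta, wls_oracle(h$beta_exp, h$beta_out, h$se_out),
                 tolerance = 1e-10)
    eg <- mr_egger(h)
    flip <- h$beta_exp < 0
    co <- wls_oracle(abs(h$beta_exp), ifelse(flip, -h$beta_out, h$beta_out),
                     h$se_out, intercept = TRUE)
    expect_equal(eg$egger_intercept, co[1], tolerance = 1e-10)
    expect_equal(eg$beta, co[2], tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact linear law and tests its intercept", {
  bx <- seq(0.05, 0.5, length.out = 10)
  h <- h_df(bx = bx, by = 0.02 + 0.4 * bx, sx = 0.01, sy = 0.05)
  est <- mr_egger(h)
  expect_equal(est$beta, 0.4, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("the weighted median interpolates the ratio at half weight", {
  h <- h_df(bx = c(1, 1, 1), by = c(0.2, 0.4, 0.6), sx = 0.01, sy = 1)
  est <- mr_weighted_median(h, n_boot = 0)
  expect_equal(est$beta, 0.4)
  # all ratios equal -> the common ratio with a small bootstrap SE
  hc <- h_df(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15),
             sx = 1e-4, sy = 1e-4)
  est_c <- mr_weighted_median(hc, n_boot = 200, seed = 4)
  expect_equal(est_c$beta, 0.5, tolerance = 1e-6)
  expect_lt(est_c$se, 0.01)
})

test_that("the weighted mode finds the dominant ratio cluster", {
  h1 <- h_df(bx = rep(0.2, 4), by = rep(0.06, 4), sx = 0.01, sy = 0.02)
  expect_equal(mr_weighted_mode(h1, n_boot = 0)$beta, 0.3)
  set.seed(6)
  bx <- rep(0.2, 20)
  ratios <- c(rnorm(14, 0.4, 0.01), rnorm(6, 1.2, 0.01))
  h2 <- h_df(bx = bx, by = ratios * bx, sx = 0.005, sy = 0.02)
  est <- mr_weighted_mode(h2, n_boot = 0)
  expect_lt(abs(est$beta - 0.4), 0.05)
  # grid refinement changes the estimate by less than the grid step
  fine <- mr_weighted_mode(h2, n_boot = 0, grid_n = 100000)
  step <- diff(range(ratios)) * 11 / 10000
  expect_lt(abs(fine$beta - est$beta), step)
})

test_that("bootstrap standard errors are bit-for-bit seed-reproducible", {
  h <- random_h(10, 91)
  a <- mr_weighted_median(h, n_boot = 100, seed = 17)
  b <- mr_weighted_median(h, n_boot = 100, seed = 17)
  expect_identical(a, b)
  m1 <- mr_weighted_mode(h, n_boot = 50, seed = 17)
  m2 <- mr_weighted_mode(h, n_boot = 50, seed = 17)
  expect_identical(m1, m2)
  expect_false(identical(a$se, mr_weighted_median(h, n_boot = 100,
                                                  seed = 18)$se))
})

test_that("estimators are equivariant under sign changes", {
  h <- random_h(12, 33)
  neg_both <- h; neg_both$beta_exp <- -h$beta_exp
  neg_both$beta_out <- -h$beta_out
  neg_out <- h; neg_out$beta_out <- -h$beta_out
  for (f in list(function(x) mr_ivw(x)$beta,
                 function(x) mr_egger(x)$beta,
                 function(x) mr_weighted_median(x, n_boot = 0)$beta)) {
    expect_equal(f(neg_both), f(h), tolerance = 1e-10)
    expect_equal(f(neg_out), -f(h), tolerance = 1e-10)
  }
})

test_that("a duplicated variant pair reproduces its own Wald ratio via IVW", {
  h <- h_df(bx = 0.1, by = 0.04, sx = 0.01, sy = 0.05)
  pair <- rbind(h, h)
  pair$snp_id <- c("rs1", "rs2")
  expect_equal(mr_ivw(pair)$beta, wald_ratio(h)$beta, tolerance = 1e-12)
})

test_that("multivariable IVW reduces to IVW at k = 1 and flags collinearity", {
  cfg <- sim_config(m_variants = 80, theta = 0.3, prop_instruments = 1,
                    seed = 55)
  sim <- simulate_multi_exposure(cfg, 1, matrix(1, 1, 1))
  names(sim$exposures) <- "x1"
  mv <- mr_mvivw(sim$exposures, sim$outcome, p_threshold = 5e-8)
  sig <- sim$exposures[[1]][sim$exposures[[1]]$pvalue < 5e-8, ]
  h <- suppressMessages(harmonize(sig, sim$outcome))
  # rebuild the univariable fit on the identical instrument set
  uni <- mr_ivw(h, "random")
  expect_equal(mv[[1]]$beta, uni$beta, tolerance = 1e-10)
  expect_equal(mv[[1]]$se, uni$se, tolerance = 1e-10)

  # duplicated exposure column is rank-deficient
  two <- list(x1 = sim$exposures[[1]], x2 = sim$exposures[[1]])
  expect_error(suppressWarnings(mr_mvivw(two, sim$outcome)), "collinear")
})

test_that("near-perfect exposure-effect correlation trips the condition flag", {
  cfg <- sim_config(m_variants = 100, prop_instruments = 1, n_exp = 2e6,
                    theta = 0.3, seed = 77)
  sim <- simulate_multi_exposure(cfg, 2, matrix(c(1, 0.99999, 0.99999, 1), 2))
  names(sim$exposures) <- c("x1", "x2")
  expect_warning(mr_mvivw(sim$exposures, sim$outcome, p_threshold = 1e-4),
                 "ill-conditioned")
})

test_that("odds-ratio conversion matches the closed form and its symmetry", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or_, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)
  o3 <- to_odds_ratio(0.3, 0.1)
  expect_equal(o3$or_, 1.349859, tolerance = 1e-6)
  expect_equal(o3$ci_low, exp(0.3 - qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(o3$ci_low, 1.1096, tolerance = 1e-4)
  expect_equal(o3$ci_high, 1.6421, tolerance = 1e-4)
  expect_equal(to_odds_ratio(-0.3, 0.1)$or_, 1 / o3$or_, tolerance = 1e-12)
})

test_that("multivariable IVW recovers correlated multi-exposure effects", {
  theta <- c(0.3, 0, 0.2)
  corr <- matrix(0.5, 3, 3); diag(corr) <- 1
  reps <- 100
  cover <- matrix(NA, reps, 3)
  z <- qnorm(0.975)
  for (r in seq_len(reps)) {
    cfg <- sim_config(m_variants = 150, prop_instruments = 0.6,
                      theta = theta, sigma_gamma = 0.048, seed = 80000 + r)
    sim <- simulate_multi_exposure(cfg, 3, corr)
    names(sim$exposures) <- c("x1", "x2", "x3")
    mv <- mr_mvivw(sim$exposures, sim$outcome)
    for (j in 1:3) {
      cover[r, j] <- (mv[[j]]$beta - z * mv[[j]]$se) <= theta[j] &&
        theta[j] <= (mv[[j]]$beta + z * mv[[j]]$se)
    }
  }
  # direct effects of all three exposures, including the null one, are
  # covered by their 95% CIs in at least 90% of replicates
  expect_true(all(colMeans(cover) >= 0.90))
})

test_that("all estimators converge to the same effect with valid instruments", {
  reps <- 50
  diffs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(m_variants = 200, prop_instruments = 1, theta = 0.3,
                      sigma_gamma = 0.048, n_exp = 5e5, n_out = 5e5,
                      case_fraction = 0.5, seed = 90000 + r)
    sim <- simulate_pair(cfg)
    h <- sim_harm(sim)
    ests <- c(mr_ivw(h)$beta, mr_egger(h)$beta,
              mr_weighted_median(h, n_boot = 0)$beta,
              mr_weighted_mode(h, n_boot = 0)$beta)
    diffs[r] <- max(dist(ests))
  }
  expect_lt(mean(diffs), 0.02)
  expect_lt(max(diffs), 0.05)
})
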