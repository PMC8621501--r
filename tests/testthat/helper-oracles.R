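# Independent oracles and fixture builders shared across tests.

# build a harmonized-format data.frame directly from effect vectors
h_df <- function(bx, by, sx, sy, ids = sprintf("rs%04d", seq_along(bx)),
                 pos = seq_along(bx) * 1000L, eaf = 0.3) {
  structure(data.frame(
    snp_id = ids, chrom = "1", pos = pos,
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = sx, p_exp = 2 * pnorm(-abs(bx / sx)),
    eaf_exp = eaf,
    beta_out = by, se_out = sy, p_out = 2 * pnorm(-abs(by / sy)),
    eaf_out = eaf, palindromic = FALSE, flipped = FALSE,
    stringsAsFactors = FALSE
  ), class = c("harmonized_data", "data.frame"))
}

# random harmonized instance for estimator oracle checks
random_h <- function(n, seed) {
  set.seed(seed)
  h_df(bx = rnorm(n, 0.1, 0.05) + 0.02,
       by = rnorm(n, 0.05, 0.05),
       sx = runif(n, 0.005, 0.02),
       sy = runif(n, 0.01, 0.1))
}

# random summary_stats fixture
random_stats <- function(m, seed, trait = "x") {
  set.seed(seed)
  summary_stats(data.frame(
    snp_id = sprintf("rs%04d", seq_len(m)), chrom = "1",
    pos = sort(sample.int(5e7, m)),
    effect_allele = sample(c("A", "C"), m, TRUE),
    other_allele = "G",
    eaf = runif(m, 0.05, 0.95),
    beta = rnorm(m, 0, 0.05), se = runif(m, 0.005, 0.05),
    pvalue = runif(m), n = 10000, stringsAsFactors = FALSE
  ), trait_name = trait)
}

# independent re-execution of the greedy clumping definition: written
# naively with explicit repeated scans, no shared code with mrpipe::clump
clump_oracle <- function(stats, ld, r2_threshold, window_bp) {
  remaining <- stats$snp_id
  kept <- character()
  while (length(remaining) > 0) {
    sub <- stats[stats$snp_id %in% remaining, ]
    sub <- sub[order(sub$pvalue, sub$pos, sub$snp_id), ]
    best <- sub$snp_id[1]
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    drop <- character()
    for (s in remaining) {
      r2 <- ld$r2[match(s, ld$snp_ids), match(best, ld$snp_ids)]
      dist <- abs(stats$pos[stats$snp_id == s] -
                    stats$pos[stats$snp_id == best])
      if (r2 >= r2_threshold && dist <= window_bp) drop <- c(drop, s)
    }
    remaining <- setdiff(remaining, drop)
  }
  stats$snp_id[stats$snp_id %in% kept]
}

# random clumping instance: m SNPs with a random block r2 structure
random_clump_instance <- function(m, seed) {
  set.seed(seed)
  pos <- sort(sample.int(2e7, m))
  z <- matrix(rnorm(m * 3), m, 3)
  cc <- stats::cov2cor(tcrossprod(z) + diag(m) * 0.5)
  r2 <- cc^2
  stats <- summary_stats(data.frame(
    snp_id = sprintf("rs%03d", seq_len(m)), chrom = "1", pos = pos,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = rnorm(m, 0, 0.1), se = 0.01,
    pvalue = 10^-runif(m, 1, 12), n = 1e5, stringsAsFactors = FALSE))
  list(stats = stats, ld = ld_matrix(stats$snp_id, r2, pos))
}

# weighted least squares oracle via lm(): returns coefficients
wls_oracle <- function(bx, by, sy, intercept = FALSE) {
  w <- 1 / sy^2
  if (intercept) {
    unname(coef(lm(by ~ bx, weights = w)))
  } else {
    unname(coef(lm(by ~ 0 + bx, weights = w)))
  }
}

# simulation scenarios used by calibration / robustness acceptance checks.
# Chosen a priori (see the methods vignette): the null/recovery regime
# mirrors a lipid GWAS (n ~ 190k) against a rare-outcome population cohort
# (n ~ 400k, case fraction 1%); the pleiotropy-power regime mirrors a
# case-control outcome GWAS (10,754 cases / 306,882 controls).
null_config <- function(seed) {
  sim_config(m_variants = 100, prop_instruments = 1, theta = 0,
             prop_invalid = 0, sigma_gamma = 0.048,
             n_exp = 190000, n_out = 400000, case_fraction = 0.01,
             seed = seed)
}

recovery_config <- function(seed, theta = 0.3) {
  sim_config(m_variants = 150, prop_instruments = 0.6, theta = theta,
             prop_invalid = 0, sigma_gamma = 0.048,
             n_exp = 190000, n_out = 400000, case_fraction = 0.01,
             seed = seed)
}

# 40% of instruments carry a directional direct effect (mean 0.02 on the
# exposure-raising orientation); the outcome is a balanced case-control
# GWAS so the per-variant outcome SE (~0.006) leaves the estimators'
# contrast identifiable (see the methods vignette for the power analysis)
pleiotropy_config <- function(seed, theta = 0.3) {
  sim_config(m_variants = 100, prop_instruments = 1, theta = theta,
             prop_invalid = 0.4, mu_alpha = 0.02, sigma_alpha = 0.005,
             sigma_gamma = 0.048, n_exp = 190000,
             n_out = 300000, case_fraction = 0.5, seed = seed)
}

# single-outlier injection regime: a pleiotropic direct effect of 8x the
# outcome SE planted on the most influential (largest-effect) instrument,
# where pleiotropy distorts IVW the most
injection_config <- function(seed) {
  sim_config(m_variants = 15, prop_instruments = 1, theta = 0.3,
             sigma_gamma = 0.048, n_exp = 190000, n_out = 400000,
             case_fraction = 0.01, seed = seed)
}

inject_outlier <- function(h, times_se = 8) {
  j <- which.max(abs(h$beta_exp))
  h$beta_out[j] <- h$beta_out[j] + times_se * h$se_out[j]
  attr(h, "outlier_id") <- h$snp_id[j]
  h
}

# harmonize a simulated pair without the message chatter
sim_harm <- function(sim) suppressMessages(harmonize(sim$exposure, sim$outcome))
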