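#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments.
#' For each variant the leave-one-out IVW slope is computed; the observed
#' statistic is the weighted residual sum of squares
#' `RSS_obs = sum_j w_j (beta_out_j - b_(-j) beta_exp_j)^2`,
#' `w_j = 1/se_out_j^2`. `n_sim` datasets are then simulated under the
#' no-pleiotropy model (`beta_exp* ~ N(beta_exp, se_exp)`,
#' `beta_out* ~ N(b_(-j) beta_exp_j, se_out)`) and processed identically:
#'
#' * **global test** — empirical p of `RSS_obs` against the simulated RSS
#'   distribution, `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`;
#' * **outlier test** — per-variant empirical p of the observed squared
#'   weighted residual against its simulated distribution, Bonferroni-
#'   multiplied by the number of variants; variants with adjusted
#'   `p < outlier_alpha` are flagged;
#' * **distortion test** — the shift `b_without_outliers - b_all` compared
#'   (two-sided) against the empirical distribution of the same shift over
#'   `n_sim` random variant subsets of the same size, drawn without
#'   replacement.
#'
#' All empirical p-values use the `(1 + count)/(1 + n_sim)` convention and
#' therefore lie in (0, 1].
#'
#' @param variants [harmonize]d data.frame with `>= 4` rows.
#' @param n_sim Number of simulated datasets (default 1000, minimum 100).
#' @param outlier_alpha Significance level applied to Bonferroni-adjusted
#'   per-variant p-values (default 0.05).
#' @param seed Seed; the full result is reproducible from it.
#' @return A `presso_result` list: `rss_obs`, `global_p`, `outlier_p`
#'   (named, adjusted), `outlier_ids`, `beta_raw` and `beta_corrected`
#'   (random-effects IVW before/after outlier removal; `beta_corrected` is
#'   `NULL` when nothing is flagged), `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso <- function(variants, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1L) {
  .check_harmonized(variants, 4, "mr_presso")
  stopifnot(n_sim >= 100)
  bx <- variants$beta_exp; by <- variants$beta_out
  sx <- variants$se_exp; sy <- variants$se_out
  ids <- variants$snp_id
  n <- length(bx)
  w <- 1 / sy^2

  set.seed(seed)
  s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
  b_loo <- (s1 - w * bx * by) / (s2 - w * bx^2)
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  # simulated datasets under the no-pleiotropy expectation (n_sim x n)
  bxs <- matrix(stats::rnorm(n_sim * n, rep(bx, each = n_sim),
                             rep(sx, each = n_sim)), n_sim, n)
  bys <- matrix(stats::rnorm(n_sim * n, rep(b_loo * bx, each = n_sim),
                             rep(sy, each = n_sim)), n_sim, n)
  wm <- matrix(w, n_sim, n, byrow = TRUE)
  s1s <- rowSums(wm * bxs * bys)
  s2s <- rowSums(wm * bxs^2)
  b_loo_s <- (s1s - wm * bxs * bys) / (s2s - wm * bxs^2)
  res_sim <- wm * (bys - b_loo_s * bxs)^2
  rss_sim <- rowSums(res_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) /
    (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * n)
  names(outlier_p) <- ids
  outlier_ids <- ids[outlier_p < outlier_alpha]
  if (length(outlier_ids) == n) {
    stop("all variants flagged as outliers: correction degenerate",
         call. = FALSE)
  }

  beta_raw <- mr_ivw(variants, "random")
  beta_corrected <- NULL
  distortion_p <- NA_real_
  if (length(outlier_ids) > 0) {
    keep <- !(ids %in% outlier_ids)
    beta_corrected <- mr_ivw(variants[keep, , drop = FALSE], "random")
    d_obs <- beta_corrected$beta - beta_raw$beta
    n_keep <- sum(keep)
    d_sim <- vapply(seq_len(n_sim), function(i) {
      idx <- sample.int(n, n_keep)
      .ivw_slope(bx[idx], by[idx], sy[idx]) - beta_raw$beta
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(list(
    rss_obs = rss_obs, global_p = global_p,
    outlier_p = outlier_p, outlier_ids = outlier_ids,
    beta_raw = beta_raw, beta_corrected = beta_corrected,
    distortion_p = distortion_p, n_sim = n_sim, seed = seed
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outlier_ids) > 0) {
    cat(sprintf("  outliers: %s; distortion p = %.4g\n",
                paste(x$outlier_ids, collapse = ", "), x$distortion_p))
    cat(sprintf("  IVW raw beta = %.4g, corrected beta = %.4g\n",
                x$beta_raw$beta, x$beta_corrected$beta))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
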