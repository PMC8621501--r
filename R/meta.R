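#' Heterogeneity-gated fixed/random-effects meta-analysis
#'
#' Pools cohort-level MR estimates on the log-odds scale. The fixed-effects
#' pool uses weights `1/se^2`; Cochran's Q, I-squared and the
#' DerSimonian-Laird between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' are computed from the fixed fit. The random-effects model
#' (weights `1/(se^2 + tau2)`) is used only when heterogeneity is
#' significant under the gating rule `p_Q < q_alpha` **and**
#' `I2 > i2_threshold`; otherwise the fixed-effects pool is reported.
#'
#' @param estimates List of `mr_estimate` objects (or any lists with `beta`
#'   and `se`), one per cohort. A single estimate is passed through with a
#'   warning (`model_used = "fixed"`).
#' @param q_alpha Heterogeneity p-value gate (default 0.1).
#' @param i2_threshold I-squared gate in percent (default 50).
#' @return A `meta_result` list: `pooled_beta`, `pooled_se`, `pooled_p`,
#'   `or_`, `ci_low`, `ci_high`, `Q`, `p_q`, `i2`, `tau2`, `model_used`,
#'   `k_studies`.
#' @export
meta_mr <- function(estimates, q_alpha = 0.1, i2_threshold = 50) {
  beta <- vapply(estimates, `[[`, numeric(1), "beta")
  se <- vapply(estimates, `[[`, numeric(1), "se")
  stopifnot(all(se > 0))
  k <- length(beta)
  if (k < 2) {
    warning("single study: passthrough, no pooling", call. = FALSE)
    or <- to_odds_ratio(beta, se)
    return(structure(list(
      pooled_beta = beta, pooled_se = se,
      pooled_p = 2 * stats::pnorm(-abs(beta / se)),
      or_ = or$or_, ci_low = or$ci_low, ci_high = or$ci_high,
      Q = 0, p_q = NA_real_, i2 = 0, tau2 = 0,
      model_used = "fixed", k_studies = 1L
    ), class = "meta_result"))
  }
  w <- 1 / se^2
  beta_fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - beta_fixed)^2)
  df <- k - 1
  p_q <- stats::pchisq(Q, df, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))

  use_random <- p_q < q_alpha && i2 > i2_threshold
  if (use_random) {
    wr <- 1 / (se^2 + tau2)
    pooled_beta <- sum(wr * beta) / sum(wr)
    pooled_se <- sqrt(1 / sum(wr))
  } else {
    pooled_beta <- beta_fixed
    pooled_se <- sqrt(1 / sum(w))
  }
  or <- to_odds_ratio(pooled_beta, pooled_se)
  structure(list(
    pooled_beta = pooled_beta, pooled_se = pooled_se,
    pooled_p = 2 * stats::pnorm(-abs(pooled_beta / pooled_se)),
    or_ = or$or_, ci_low = or$ci_low, ci_high = or$ci_high,
    Q = Q, p_q = p_q, i2 = i2, tau2 = tau2,
    model_used = if (use_random) "random" else "fixed",
    k_studies = as.integer(k)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Meta-analysis (%d studies, %s effects): OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$k_studies, x$model_used, x$or_, x$ci_low, x$ci_high, x$pooled_p))
  cat(sprintf("  Q = %.3f (p = %.3g), I2 = %.1f%%, tau2 = %.4g\n",
              x$Q, x$p_q, x$i2, x$tau2))
  invisible(x)
}

#' Bonferroni significance threshold for an analysis grid
#'
#' `alpha / (n_exposures * n_outcomes)`; e.g. 0.05 over 4 exposures and 7
#' outcomes gives 0.001786, conventionally reported as 0.0018 after
#' rounding to two significant figures.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_exposures,n_outcomes Grid dimensions.
#' @return The per-test threshold (unrounded).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_exposures, n_outcomes) {
  stopifnot(alpha > 0, n_exposures >= 1, n_outcomes >= 1)
  alpha / (n_exposures * n_outcomes)
}

#' Classify an association p-value against a Bonferroni screen
#'
#' `"significant"` when `p < threshold`; `"suggestive"` when
#' `threshold <= p < nominal`; `"null"` otherwise.
#'
#' @param p P-value(s).
#' @param threshold Bonferroni-corrected threshold (e.g.
#'   [bonferroni_threshold()]).
#' @param nominal Nominal level (default 0.05).
#' @return Character vector of classifications.
#' @export
classify_association <- function(p, threshold, nominal = 0.05) {
  stopifnot(threshold > 0, threshold < nominal)
  ifelse(p < threshold, "significant",
         ifelse(p < nominal, "suggestive", "null"))
}
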