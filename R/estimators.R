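#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Standard error (`>= 0`).
#' @return List with `or_`, `ci_low`, `ci_high`
#'   (`exp(beta +/- 1.959964 se)`).
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(all(is.na(se) | se >= 0))
  z <- stats::qnorm(0.975)
  list(or_ = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

.het_stats <- function(Q, df) {
  structure(list(
    Q = Q, df = df,
    p_q = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    i2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  ), class = "het_stats")
}

.mr_estimate <- function(method, beta, se, pvalue, n_snps, het = NULL, ...) {
  or <- to_odds_ratio(beta, se)
  structure(c(list(method = method, beta = beta, se = se, pvalue = pvalue,
                   or_ = or$or_, ci_low = or$ci_low, ci_high = or$ci_high,
                   n_snps = n_snps, het = het), list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]: beta = %.4g (se %.4g), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, n_snps = %d\n",
              x$method, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pvalue,
              x$n_snps))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4g (se %.4g), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  if (!is.null(x$het)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$het$Q, x$het$df, x$het$p_q, x$het$i2))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, beta = x$beta, se = x$se, pvalue = x$pvalue,
    or_ = x$or_, ci_low = x$ci_low, ci_high = x$ci_high, n_snps = x$n_snps,
    egger_intercept = x$egger_intercept %||% NA_real_,
    egger_intercept_p = x$egger_intercept_p %||% NA_real_,
    Q = if (is.null(x$het)) NA_real_ else x$het$Q,
    p_q = if (is.null(x$het)) NA_real_ else x$het$p_q,
    i2 = if (is.null(x$het)) NA_real_ else x$het$i2,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_harmonized <- function(variants, min_n, method) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) < min_n) {
    stop(sprintf("%s requires at least %d variant(s), got %d%s",
                 method, min_n, nrow(variants),
                 if (min_n >= 2 && nrow(variants) == 1)
                   " (use wald_ratio for a single variant)" else ""),
         call. = FALSE)
  }
  if (any(variants$beta_exp == 0)) {
    stop("zero exposure effect: Wald ratio undefined", call. = FALSE)
  }
}

#' Wald ratio causal estimate from a single variant
#'
#' `beta = beta_out / beta_exp`, the outcome association divided by the
#' exposure association, with the first-order standard error
#' `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param variants One-row [harmonize]d data.frame.
#' @param second_order Use the second-order SE, which propagates the
#'   exposure SE as well (default `FALSE`, the conventional first-order
#'   approximation).
#' @return An `mr_estimate` (method `"wald"`).
#' @export
wald_ratio <- function(variants, second_order = FALSE) {
  .check_harmonized(variants, 1, "wald_ratio")
  v <- variants[1, ]
  beta <- v$beta_out / v$beta_exp
  se <- if (second_order) {
    sqrt(v$se_out^2 / v$beta_exp^2 +
           v$beta_out^2 * v$se_exp^2 / v$beta_exp^4)
  } else {
    v$se_out / abs(v$beta_exp)
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("wald", beta, se, p, 1L)
}

# weighted regression of beta_out on beta_exp through the origin,
# weights 1/se_out^2; shared by ivw and presso internals
.ivw_slope <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of the outcome associations on the exposure
#' associations through the origin with weights `1/se_out^2`
#' (equivalently, the inverse-variance-weighted mean of per-variant Wald
#' ratios). The fixed-effects SE is `sqrt(1/sum(w beta_exp^2))`; the
#' random-effects model is the multiplicative-overdispersion one, inflating
#' the SE by `max(1, sqrt(Q/(n-1)))` so precision never exceeds
#' fixed-effects. Cochran's Q is computed on the Wald-ratio scale.
#'
#' @param variants [harmonize]d data.frame with `>= 2` rows.
#' @param effects_model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` (method `"ivw_re"` or `"ivw_fe"`) whose `het`
#'   element holds Q, df, p and I-squared.
#' @export
mr_ivw <- function(variants, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  .check_harmonized(variants, 2, "mr_ivw")
  bx <- variants$beta_exp; by <- variants$beta_out; sy <- variants$se_out
  n <- length(bx)
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)  # == sum((ratio-beta)^2 / se_wald^2)
  het <- .het_stats(Q, n - 1L)
  se <- if (effects_model == "random") {
    se_fixed * max(1, sqrt(Q / (n - 1)))
  } else se_fixed
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate(if (effects_model == "random") "ivw_re" else "ivw_fe",
               beta, se, p, n, het = het)
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome associations on the exposure
#' associations *with* an intercept (weights `1/se_out^2`), after orienting
#' every variant so its exposure effect is positive. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect, and its test against zero is the Egger
#' pleiotropy test. SEs carry the multiplicative-overdispersion inflation
#' `max(1, sqrt(RSS_w/(n-2)))`; p-values use the t-distribution with
#' `n - 2` degrees of freedom.
#'
#' @param variants [harmonize]d data.frame with `>= 3` rows.
#' @return An `mr_estimate` (method `"egger"`) with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p` fields and heterogeneity in
#'   `het` (Q = weighted RSS about the Egger fit, df `n - 2`).
#' @export
mr_egger <- function(variants) {
  .check_harmonized(variants, 3, "mr_egger")
  flip <- variants$beta_exp < 0
  bx <- abs(variants$beta_exp)
  by <- ifelse(flip, -variants$beta_out, variants$beta_out)
  sy <- variants$se_out
  n <- length(bx)
  w <- 1 / sy^2

  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swy - slope * swx) / sw
  rss <- sum(w * (by - intercept - slope * bx)^2)
  infl <- max(1, sqrt(rss / (n - 2)))
  se_slope <- sqrt(sw / denom) * infl
  se_int <- sqrt(swxx / denom) * infl
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = n - 2)
  .mr_estimate("egger", slope, se_slope, p_slope, n,
               het = .het_stats(rss, n - 2L),
               egger_intercept = intercept, egger_intercept_se = se_int,
               egger_intercept_p = p_int)
}

.wald_ratios <- function(variants) {
  r <- variants$beta_out / variants$beta_exp
  se <- variants$se_out / abs(variants$beta_exp)
  list(ratio = r, se = se, w = 1 / se^2)
}

.weighted_median_est <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

.boot_se <- function(variants, estimator, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  set.seed(seed)
  n <- nrow(variants)
  est <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(n, variants$beta_exp, variants$se_exp)
    by <- stats::rnorm(n, variants$beta_out, variants$se_out)
    est[b] <- estimator(bx, by, variants$se_exp, variants$se_out)
  }
  stats::sd(est)
}

#' Weighted median MR estimate
#'
#' The weighted median of the per-variant Wald ratios (weights equal to the
#' inverse variance of each ratio), obtained by linear interpolation of the
#' ratio at standardized cumulative weight 0.5. Consistent when at least
#' half the total weight comes from valid instruments. The SE comes from a
#' parametric bootstrap: exposure and outcome associations are resampled
#' from normals centred on their estimates with their reported SEs.
#'
#' @param variants [harmonize]d data.frame with `>= 3` rows.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the bootstrap
#'   and reports `NA` SE and p).
#' @param seed Seed for the bootstrap generator.
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(variants, n_boot = 1000, seed = 1L) {
  .check_harmonized(variants, 3, "mr_weighted_median")
  wr <- .wald_ratios(variants)
  beta <- .weighted_median_est(wr$ratio, wr$w)
  se <- .boot_se(variants, function(bx, by, sx, sy) {
    r <- by / bx
    .weighted_median_est(r, bx^2 / sy^2)
  }, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("weighted_median", beta, se, p, nrow(variants))
}

.weighted_mode_est <- function(ratio, w, phi, grid_n) {
  s <- stats::sd(ratio)
  m <- stats::mad(ratio)  # 1.4826 * raw MAD == raw MAD / 0.6745
  h <- phi * 0.9 * min(s, if (m > 0) m else s) * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h == 0) return(ratio[1])  # all ratios identical
  grid <- seq(mean(ratio) - 5 * s, mean(ratio) + 5 * s, length.out = grid_n)
  w <- w / sum(w)
  dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / h)) / h
  grid[which.max(dens)]
}

#' Weighted mode MR estimate
#'
#' The mode of the weighted kernel density of per-variant Wald ratios
#' (Gaussian kernel, bandwidth `phi * 0.9 * min(sd, mad) * n^(-1/5)` where
#' `mad` is the scaled median absolute deviation), maximized on a fixed
#' grid spanning the ratio mean plus or minus 5 SD. Consistent when the
#' largest group of similar single-variant estimates comes from valid
#' instruments. SE by parametric bootstrap as in [mr_weighted_median()].
#'
#' @param variants [harmonize]d data.frame with `>= 3` rows.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot,seed Bootstrap replicates and seed.
#' @param grid_n Grid resolution for the point estimate (default 10000).
#' @param boot_grid_n Coarser grid used inside the bootstrap (default 512;
#'   the discretization error is negligible relative to bootstrap noise).
#' @return An `mr_estimate` (method `"weighted_mode"`).
#' @export
mr_weighted_mode <- function(variants, phi = 1, n_boot = 1000, seed = 1L,
                             grid_n = 10000, boot_grid_n = 512) {
  .check_harmonized(variants, 3, "mr_weighted_mode")
  stopifnot(phi > 0)
  wr <- .wald_ratios(variants)
  beta <- .weighted_mode_est(wr$ratio, wr$w, phi, grid_n)
  se <- .boot_se(variants, function(bx, by, sx, sy) {
    r <- by / bx
    .weighted_mode_est(r, bx^2 / sy^2, phi, boot_grid_n)
  }, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("weighted_mode", beta, se, p, nrow(variants))
}

#' Multivariable IVW MR
#'
#' Jointly regresses the outcome associations on several exposures'
#' associations (no intercept, weights `1/se_out^2`), giving each
#' exposure's direct effect adjusted for the others. Instruments are the
#' union of variants genome-wide significant for at least one exposure;
#' every exposure and the outcome are aligned to a common effect allele
#' before fitting. SEs carry multiplicative overdispersion scaling
#' `max(1, sqrt(RSS_w/(n-k)))` (the unscaled SEs are attached as
#' `se_unscaled`).
#'
#' @param exposures Named list of [summary_stats] objects (`k >= 1`).
#' @param outcome A [summary_stats] object.
#' @param p_threshold Significance threshold defining the instrument union
#'   (default 5e-8; use 1 to keep all shared variants).
#' @param palindromic_policy Passed to [harmonize()].
#' @param condition_warn Condition-number threshold of the weighted design
#'   above which a collinearity warning is raised (default 30).
#' @return List of `mr_estimate` objects (method `"mvmr_ivw"`), one per
#'   exposure, with attributes `condition_number` and `n_snps`.
#' @export
mr_mvivw <- function(exposures, outcome, p_threshold = 5e-8,
                     palindromic_policy = "infer_by_eaf",
                     condition_warn = 30) {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  k <- length(exposures)
  nms <- names(exposures)
  if (is.null(nms)) nms <- vapply(exposures, attr, "", "trait_name")

  union_ids <- unique(unlist(lapply(exposures, function(e)
    e$snp_id[e$pvalue < p_threshold])))
  if (length(union_ids) == 0) stop("no genome-wide-significant instruments",
                                   call. = FALSE)
  harms <- lapply(exposures, function(e) {
    suppressMessages(harmonize(.subset_stats(e, e$snp_id %in% union_ids),
                               outcome, palindromic_policy = palindromic_policy))
  })
  common <- Reduce(intersect, lapply(harms, `[[`, "snp_id"))
  if (length(common) <= k) stop("too few shared instruments for multivariable fit",
                                call. = FALSE)
  # express every exposure effect on the outcome's reported allele, so the
  # outcome column is shared across exposures
  bx <- vapply(harms, function(h) {
    h <- h[match(common, h$snp_id), ]
    ifelse(h$flipped, -h$beta_exp, h$beta_exp)
  }, numeric(length(common)))
  h1 <- harms[[1]][match(common, harms[[1]]$snp_id), ]
  by <- ifelse(h1$flipped, -h1$beta_out, h1$beta_out)
  sy <- h1$se_out
  fit <- .mvivw_fit(bx, by, sy, nms, condition_warn)
  fit
}

.mvivw_fit <- function(bx, by, sy, nms, condition_warn = 30) {
  bx <- as.matrix(bx)
  n <- nrow(bx); k <- ncol(bx)
  w <- 1 / sy^2
  xw <- bx * sqrt(w)
  sv <- svd(xw, nu = 0, nv = 0)$d
  if (min(sv) <= max(sv) * 1e-10) {
    offenders <- if (!is.null(nms)) paste(nms, collapse = ", ") else "design"
    stop("collinear exposure effects (rank-deficient design): ", offenders,
         call. = FALSE)
  }
  kappa <- max(sv) / min(sv)
  if (kappa > condition_warn) {
    warning(sprintf("ill-conditioned multivariable design (condition number %.1f)",
                    kappa), call. = FALSE)
  }
  xtx <- crossprod(xw)
  beta <- unname(drop(solve(xtx, crossprod(bx * w, by))))
  rss <- sum(w * (by - drop(bx %*% beta))^2)
  infl <- max(1, sqrt(rss / (n - k)))
  se0 <- unname(sqrt(diag(solve(xtx))))
  se <- se0 * infl
  out <- lapply(seq_len(k), function(j) {
    est <- .mr_estimate("mvmr_ivw", beta[j], se[j],
                        2 * stats::pnorm(-abs(beta[j] / se[j])), n,
                        exposure = if (!is.null(nms)) nms[j] else paste0("X", j),
                        se_unscaled = se0[j])
    est
  })
  attr(out, "condition_number") <- kappa
  attr(out, "n_snps") <- n
  out
}
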