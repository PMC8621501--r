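# subset a summary_stats object preserving trait attributes
.subset_stats <- function(stats, keep) {
  out <- as.data.frame(stats)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = attr(stats, "trait_name"),
            trait_type = attr(stats, "trait_type"),
            class = c("summary_stats", "data.frame"))
}

#' Greedy LD clumping
#'
#' Selects approximately independent variants: repeatedly retain the
#' remaining variant with the smallest p-value (ties broken by smaller
#' position, then lexicographic `snp_id`) and discard every remaining
#' variant with `r2 >= r2_threshold` *and* distance `<= window_bp` from it.
#' Retained variants are returned in their input order.
#'
#' @param stats A [summary_stats] object.
#' @param ld An [ld_matrix] covering every variant in `stats`.
#' @param r2_threshold Squared-correlation threshold at or above which a
#'   nearby variant is removed (e.g. 0.001 for trait instruments, 0.2 for
#'   cis drug-target instruments).
#' @param window_bp Physical distance threshold in base pairs (e.g. 1e7 or
#'   250000).
#' @return The clumped [summary_stats] subset.
#' @export
clump <- function(stats, ld, r2_threshold, window_bp) {
  stopifnot(inherits(stats, "summary_stats"), inherits(ld, "ld_matrix"),
            r2_threshold > 0, window_bp > 0)
  missing <- setdiff(stats$snp_id, ld$snp_ids)
  if (length(missing) > 0) {
    stop("variant(s) missing from LD matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(stats) == 0) return(stats)
  ord <- order(stats$pvalue, stats$pos, stats$snp_id)
  idx_ld <- match(stats$snp_id, ld$snp_ids)
  alive <- rep(TRUE, nrow(stats))
  keep <- logical(nrow(stats))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    linked <- alive &
      ld$r2[idx_ld, idx_ld[i]] >= r2_threshold &
      abs(stats$pos - stats$pos[i]) <= window_bp
    alive[linked] <- FALSE
  }
  .subset_stats(stats, keep)
}

#' Per-variant instrument-strength F-statistic
#'
#' `F = (beta / se)^2`, the conventional single-variant instrument-strength
#' measure; `F > 10` is the usual weak-instrument bound.
#'
#' @param beta Effect estimate(s), or a data.frame with `beta` and `se`
#'   columns (e.g. a [summary_stats] object).
#' @param se Standard error(s) (ignored when `beta` is a data.frame).
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Variance in a standardized exposure explained by instruments
#'
#' `sum_j 2 eaf_j (1 - eaf_j) beta_j^2` for a standardized (unit-variance)
#' exposure. Accepts a [summary_stats] table (`eaf`, `beta`) or a
#' [harmonize]d table (`eaf_exp`, `beta_exp`).
#'
#' @param instruments data.frame of instruments.
#' @return Fraction of exposure variance explained (0 for an empty set).
#' @export
variance_explained <- function(instruments) {
  if (nrow(instruments) == 0) return(0)
  if ("beta_exp" %in% names(instruments)) {
    eaf <- instruments$eaf_exp
    beta <- instruments$beta_exp
  } else {
    eaf <- instruments$eaf
    beta <- instruments$beta
  }
  if (anyNA(eaf)) stop("missing eaf for variance_explained", call. = FALSE)
  sum(2 * eaf * (1 - eaf) * beta^2)
}

#' Select genetic instruments for a two-sample MR analysis
#'
#' Applies, in order: (1) exposure genome-wide significance
#' (`p < p_exp_threshold`); (2) greedy LD [clump]ing; (3) [harmonize] with
#' the outcome; (4) exclusion of variants associated with the outcome at
#' genome-wide significance (`p_out < p_out_threshold`); (5) exclusion of
#' weak instruments (`F <= f_threshold`). Every exclusion is recorded with
#' its stage and reason in `selection_log`.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param ld [ld_matrix] covering the significant exposure variants.
#' @param p_exp_threshold Exposure significance threshold (default 5e-8).
#' @param clump_r2,clump_window_bp Clumping thresholds (defaults 0.001 and
#'   1e7; the cis drug-target preset is 0.2 and 250000).
#' @param p_out_threshold Outcome-association exclusion threshold
#'   (default 5e-8).
#' @param f_threshold Weak-instrument bound; variants with `F <=` this are
#'   excluded (default 10).
#' @param palindromic_policy Passed to [harmonize()].
#' @return An `instrument_set` list: `exposure_name`, `variants`
#'   (harmonized data.frame), `f` (named per-variant F), `r2_explained`,
#'   `selection_log` (data.frame `snp_id`, `stage`, `reason`). An empty
#'   selection returns a zero-row set with a message, not an error.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               p_exp_threshold = 5e-8,
                               clump_r2 = 0.001, clump_window_bp = 1e7,
                               p_out_threshold = 5e-8, f_threshold = 10,
                               palindromic_policy = "infer_by_eaf") {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  log <- list()
  note <- function(ids, stage, reason) {
    if (length(ids) > 0) {
      log[[length(log) + 1]] <<- data.frame(snp_id = ids, stage = stage,
                                            reason = reason,
                                            stringsAsFactors = FALSE)
    }
  }

  sig <- exposure$pvalue < p_exp_threshold
  note(exposure$snp_id[!sig], "significance", "exposure_not_significant")
  stats <- .subset_stats(exposure, sig)

  if (nrow(stats) > 0) {
    clumped <- clump(stats, ld, clump_r2, clump_window_bp)
    note(setdiff(stats$snp_id, clumped$snp_id), "clump", "ld_clumped")
    stats <- clumped
  }

  harm <- NULL
  if (nrow(stats) > 0) {
    shared <- intersect(stats$snp_id, outcome$snp_id)
    note(setdiff(stats$snp_id, shared), "harmonize", "absent_from_outcome")
    if (length(shared) > 0) {
      harm <- suppressMessages(
        harmonize(stats, outcome, palindromic_policy = palindromic_policy))
      hlog <- attr(harm, "log")
      if (nrow(hlog) > 0) note(hlog$snp_id, "harmonize", hlog$reason)
    }
  }
  if (is.null(harm)) {
    harm <- .harmonized_from_aligned(.subset_stats(exposure, logical(nrow(exposure))),
                                     .subset_stats(outcome, logical(nrow(outcome))))
  }

  out_assoc <- harm$p_out < p_out_threshold
  note(harm$snp_id[out_assoc], "outcome_filter", "outcome_associated")
  harm <- harm[!out_assoc, , drop = FALSE]

  f <- if (nrow(harm) > 0) (harm$beta_exp / harm$se_exp)^2 else numeric()
  weak <- f <= f_threshold
  note(harm$snp_id[weak], "f_filter", "weak_instrument")
  harm <- harm[!weak, , drop = FALSE]
  f <- stats::setNames(f[!weak], harm$snp_id)
  rownames(harm) <- NULL

  selection_log <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(snp_id = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (nrow(harm) == 0) {
    message("no instruments survived selection for ",
            attr(exposure, "trait_name"))
  }
  structure(list(
    exposure_name = attr(exposure, "trait_name"),
    variants = harm,
    f = f,
    r2_explained = if (nrow(harm) > 0) variance_explained(harm) else 0,
    selection_log = selection_log
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "Instrument set for %s: %d variant(s), variance explained %.2f%%\n",
    x$exposure_name, nrow(x$variants), 100 * x$r2_explained))
  invisible(x)
}
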