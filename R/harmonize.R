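.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared variant to the exposure's
#' effect allele, so that the (beta_exp, beta_out) pairs entering the MR
#' estimators refer to the same allele. Outcome effects reported for the
#' opposite allele are sign-flipped (and the effect-allele frequency
#' complemented); alleles reported on the opposite strand are
#' reverse-complemented first. Palindromic variants (A/T or C/G), whose
#' strand cannot be resolved from allele labels, are handled per
#' `palindromic_policy`:
#'
#' * `"infer_by_eaf"` (default): keep the variant when both effect-allele
#'   frequencies are outside \[0.42, 0.58\] and use frequency agreement to
#'   fix the strand (if, after nominal label alignment, the two frequencies
#'   lie on opposite sides of 0.5 the outcome effect is flipped once more);
#'   otherwise (ambiguous frequency or missing EAF) the variant is excluded.
#' * `"drop"`: exclude every palindromic variant.
#' * `"keep"`: assume both studies report the same strand; align by labels.
#'
#' Variants whose allele sets cannot be reconciled at all are excluded.
#' Matching is by `snp_id` only.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param palindromic_policy One of `"infer_by_eaf"`, `"drop"`, `"keep"`.
#' @param eaf_ambiguous Frequency window around 0.5 within which a
#'   palindromic variant is considered unresolvable (default `c(0.42, 0.58)`).
#' @return A `harmonized_data` data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `p_exp`,
#'   `eaf_exp`, `beta_out`, `se_out`, `p_out`, `eaf_out`, `palindromic`,
#'   `flipped`. Exclusions are recorded in the `log` attribute
#'   (data.frame `snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("infer_by_eaf", "drop", "keep"),
                      eaf_ambiguous = c(0.42, 0.58)) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) stop("no shared variants between exposure and outcome",
                                call. = FALSE)
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  n <- length(shared)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  flipped <- rep(FALSE, n)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)

  ea_e <- ex$effect_allele; oa_e <- ex$other_allele
  ea_o <- ou$effect_allele; oa_o <- ou$other_allele
  pal <- unname(.is_palindromic(ea_e, oa_e))

  same <- ea_o == ea_e & oa_o == oa_e
  swap <- ea_o == oa_e & oa_o == ea_e
  ea_oc <- unname(.COMPLEMENT[ea_o]); oa_oc <- unname(.COMPLEMENT[oa_o])
  same_c <- !same & !swap & ea_oc == ea_e & oa_oc == oa_e
  swap_c <- !same & !swap & ea_oc == oa_e & oa_oc == ea_e

  unresolvable <- !(same | swap | same_c | swap_c)
  keep[unresolvable] <- FALSE
  reason[unresolvable] <- "allele_mismatch"

  do_flip <- swap | swap_c
  beta_out[do_flip] <- -beta_out[do_flip]
  eaf_out[do_flip] <- 1 - eaf_out[do_flip]
  flipped[do_flip] <- TRUE

  if (palindromic_policy == "drop") {
    keep[pal] <- FALSE
    reason[pal] <- "palindromic"
  } else if (palindromic_policy == "infer_by_eaf") {
    amb <- pal & keep &
      (is.na(ex$eaf) | is.na(eaf_out) |
         (ex$eaf >= eaf_ambiguous[1] & ex$eaf <= eaf_ambiguous[2]) |
         (eaf_out >= eaf_ambiguous[1] & eaf_out <= eaf_ambiguous[2]))
    keep[amb] <- FALSE
    reason[amb] <- "palindromic_ambiguous"
    # strand fixed by frequency: disagreeing sides of 0.5 imply a strand flip
    fix <- pal & keep & sign(ex$eaf - 0.5) != sign(eaf_out - 0.5)
    beta_out[fix] <- -beta_out[fix]
    eaf_out[fix] <- 1 - eaf_out[fix]
    flipped[fix] <- !flipped[fix]
  }

  out <- data.frame(
    snp_id = shared, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ea_e, other_allele = oa_e,
    beta_exp = ex$beta, se_exp = ex$se, p_exp = ex$pvalue, eaf_exp = ex$eaf,
    beta_out = beta_out, se_out = ou$se, p_out = ou$pvalue, eaf_out = eaf_out,
    palindromic = pal, flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  if (nrow(log) > 0) {
    message(nrow(log), " variant(s) excluded during harmonization")
  }
  structure(out, log = log, class = c("harmonized_data", "data.frame"))
}

# internal: build harmonized_data directly from already-aligned simulated
# exposure/outcome tables (same effect allele by construction)
.harmonized_from_aligned <- function(ex, ou) {
  structure(data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, p_exp = ex$pvalue, eaf_exp = ex$eaf,
    beta_out = ou$beta, se_out = ou$se, p_out = ou$pvalue, eaf_out = ou$eaf,
    palindromic = unname(.is_palindromic(ex$effect_allele, ex$other_allele)),
    flipped = logical(length(ex$snp_id)), stringsAsFactors = FALSE
  ), log = data.frame(snp_id = character(), reason = character()),
  class = c("harmonized_data", "data.frame"))
}
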