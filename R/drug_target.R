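#' Define a drug-target gene region
#'
#' @param gene_symbol Gene symbol (e.g. `"HMGCR"`).
#' @param chrom Chromosome as a string.
#' @param start,end 1-based inclusive gene bounds (`start <= end`).
#' @param flank_bp Window extension on each side (default 100000, the
#'   conventional cis window).
#' @return A `gene_region` list.
#' @export
gene_region <- function(gene_symbol, chrom, start, end, flank_bp = 100000) {
  stopifnot(start <= end, flank_bp >= 0)
  structure(list(gene_symbol = gene_symbol, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end),
                 flank_bp = as.integer(flank_bp)),
            class = "gene_region")
}

#' Load the packaged lipid drug-target gene table
#'
#' Reads a TSV of gene regions (columns `gene_symbol`, `chrom`, `start`,
#' `end`, `lipid_trait`). The packaged default covers the seven
#' lipid-lowering targets: the LDL-C class (HMGCR, NPC1L1, PCSK9, CETP,
#' LDLR) and the TG class (ANGPTL3, LPL), with GRCh37 reference
#' coordinates. The file is an editable fixture, not an annotation-service
#' lookup.
#'
#' @param path Optional alternative TSV with the same columns.
#' @param flank_bp Flank applied to every region (default 100000).
#' @return data.frame with one row per gene plus a `regions` list column of
#'   [gene_region] objects.
#' @export
drug_target_genes <- function(path = NULL, flank_bp = 100000) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_regions.tsv", package = "mrpipe")
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  df$regions <- lapply(seq_len(nrow(df)), function(i)
    gene_region(df$gene_symbol[i], df$chrom[i], df$start[i], df$end[i],
                flank_bp))
  df
}

#' Extract clumped cis instruments for a gene region
#'
#' Keeps variants inside the flanked gene window
#' (`start - flank <= pos <= end + flank`, same chromosome) that reach
#' `p < p_threshold`, then applies greedy LD [clump]ing at the cis preset
#' (`r2 < 0.2` within 250 kb by default). Output is position-sorted.
#'
#' @param stats [summary_stats] for the lipid trait.
#' @param region A [gene_region].
#' @param p_threshold Significance threshold (default 5e-8).
#' @param ld [ld_matrix] covering the window's significant variants.
#' @param clump_r2,clump_window_bp Cis clumping thresholds (defaults 0.2
#'   and 250000).
#' @return Clumped [summary_stats] subset (possibly empty, with a message).
#' @export
extract_cis <- function(stats, region, p_threshold = 5e-8, ld,
                        clump_r2 = 0.2, clump_window_bp = 250000) {
  stopifnot(inherits(stats, "summary_stats"), inherits(region, "gene_region"))
  lo <- region$start - region$flank_bp
  hi <- region$end + region$flank_bp
  keep <- stats$chrom == region$chrom & stats$pos >= lo & stats$pos <= hi &
    stats$pvalue < p_threshold
  sub <- .subset_stats(stats, keep)
  if (nrow(sub) == 0) {
    message("no significant variants in the ", region$gene_symbol, " window")
    return(sub)
  }
  out <- clump(sub, ld, clump_r2, clump_window_bp)
  .subset_stats(out, order(out$pos))
}

#' Drug-target MR estimate in the trait-lowering orientation
#'
#' Estimates the outcome effect of genetically proxied inhibition of a
#' lipid drug target from its cis instruments: random-effects IVW when two
#' or more variants are available, Wald ratio for a single variant. The
#' estimate is reported per 1-SD *reduction* of the lipid trait
#' (`orientation = "lowering"`, the pharmacological direction), i.e. the
#' sign of the per-1-SD-increase estimate is reversed; individual variants'
#' allele orientation is immaterial because the Wald ratio is invariant to
#' joint sign flips.
#'
#' @param variants [harmonize]d cis instruments (exposure = lipid trait,
#'   outcome = disease).
#' @param orientation `"lowering"` (default) or `"raising"`.
#' @param correlated If `TRUE`, account for residual LD among clumped
#'   instruments with generalized weighted least squares using the LD
#'   correlation (requires `ld`); reduces the anti-conservatism of
#'   independence weights when `r2 < 0.2` leaves real correlation.
#' @param ld [ld_matrix] for `correlated = TRUE`. Correlation signs are not
#'   recoverable from r-squared and are taken positive.
#' @return An `mr_estimate` with an `orientation` field.
#' @export
target_mr <- function(variants, orientation = c("lowering", "raising"),
                      correlated = FALSE, ld = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(nrow(variants) >= 1)
  est <- if (nrow(variants) == 1) {
    wald_ratio(variants)
  } else if (correlated) {
    .ivw_correlated(variants, ld)
  } else {
    mr_ivw(variants, "random")
  }
  if (orientation == "lowering") {
    est$beta <- -est$beta
    or <- to_odds_ratio(est$beta, est$se)
    est$or_ <- or$or_; est$ci_low <- or$ci_low; est$ci_high <- or$ci_high
  }
  est$orientation <- orientation
  est
}

# generalized (LD-aware) IVW: slope = x' S^-1 y / x' S^-1 x with
# S = D R D, D = diag(se_out), R = sqrt(r2) taken positive
.ivw_correlated <- function(variants, ld) {
  if (is.null(ld)) stop("correlated IVW requires an ld_matrix", call. = FALSE)
  idx <- match(variants$snp_id, ld$snp_ids)
  if (anyNA(idx)) stop("variant(s) missing from LD matrix", call. = FALSE)
  rr <- sqrt(ld$r2[idx, idx, drop = FALSE])
  sy <- variants$se_out
  sigma <- rr * outer(sy, sy)
  si <- solve(sigma)
  bx <- variants$beta_exp; by <- variants$beta_out
  denom <- drop(t(bx) %*% si %*% bx)
  beta <- drop(t(bx) %*% si %*% by) / denom
  se <- sqrt(1 / denom)
  n <- length(bx)
  # multiplicative overdispersion on the generalized residuals
  r <- by - beta * bx
  q <- drop(t(r) %*% si %*% r)
  se <- se * max(1, sqrt(q / (n - 1)))
  .mr_estimate("ivw_re", beta, se, 2 * stats::pnorm(-abs(beta / se)), n,
               het = .het_stats(q, n - 1L))
}
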