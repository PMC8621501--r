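#' Assemble and validate an analysis-grid configuration
#'
#' Collects every tunable constant of the trait and drug-target grids in
#' one place with the conventional defaults: genome-wide significance
#' 5e-8; trait clumping r2 < 0.001 within 10 Mb (the strict preset; the
#' looser published alternative is r2 < 0.01); cis clumping r2 < 0.2
#' within 250 kb; per-variant F > 10; heterogeneity gate p < 0.1 and
#' I2 > 50%; Bonferroni alpha 0.05 over the grid dimensions.
#'
#' @param exposures Named list of [summary_stats] objects.
#' @param outcomes List of entries `list(name=, cohort=, stats=)`; entries
#'   sharing `name` across cohorts are meta-analyzed.
#' @param ld An [ld_matrix] covering the significant exposure variants.
#' @param selection Overrides for [select_instruments()] arguments
#'   (`p_exp_threshold`, `clump_r2`, `clump_window_bp`, `p_out_threshold`,
#'   `f_threshold`, `palindromic_policy`).
#' @param estimators Overrides: `n_boot` (default 1000), `phi` (1),
#'   `seed` (1).
#' @param presso Overrides: `run` (TRUE), `n_sim` (1000), `outlier_alpha`
#'   (0.05), `seed` (1).
#' @param meta_gate Overrides: `q_alpha` (0.1), `i2_threshold` (50).
#' @param bonferroni Overrides: `alpha` (0.05); `n_exposures` and
#'   `n_outcomes` default to the grid dimensions.
#' @param cis Overrides for the drug-target grid: `p_threshold` (5e-8),
#'   `clump_r2` (0.2), `clump_window_bp` (250000), `flank_bp` (100000).
#' @param primary `"raw"` or `"presso_corrected"`: which IVW estimate is
#'   flagged primary when MR-PRESSO finds outliers.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposures, outcomes, ld,
                            selection = list(), estimators = list(),
                            presso = list(), meta_gate = list(),
                            bonferroni = list(), cis = list(),
                            primary = c("raw", "presso_corrected")) {
  primary <- match.arg(primary)
  stopifnot(is.list(exposures), length(exposures) >= 1,
            !is.null(names(exposures)), is.list(outcomes),
            length(outcomes) >= 1)
  for (e in exposures) stopifnot(inherits(e, "summary_stats"))
  for (o in outcomes) {
    stopifnot(is.list(o), !is.null(o$name), !is.null(o$cohort),
              inherits(o$stats, "summary_stats"))
  }
  merge_opts <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad) > 0) {
      stop("unknown option(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(defaults, user)
  }
  n_outcome_names <- length(unique(vapply(outcomes, `[[`, "", "name")))
  cfg <- list(
    exposures = exposures, outcomes = outcomes, ld = ld,
    selection = merge_opts(list(
      p_exp_threshold = 5e-8, clump_r2 = 0.001, clump_window_bp = 1e7,
      p_out_threshold = 5e-8, f_threshold = 10,
      palindromic_policy = "infer_by_eaf"), selection),
    estimators = merge_opts(list(n_boot = 1000, phi = 1, seed = 1L),
                            estimators),
    presso = merge_opts(list(run = TRUE, n_sim = 1000, outlier_alpha = 0.05,
                             seed = 1L), presso),
    meta_gate = merge_opts(list(q_alpha = 0.1, i2_threshold = 50), meta_gate),
    bonferroni = merge_opts(list(alpha = 0.05,
                                 n_exposures = length(exposures),
                                 n_outcomes = n_outcome_names), bonferroni),
    cis = merge_opts(list(p_threshold = 5e-8, clump_r2 = 0.2,
                          clump_window_bp = 250000, flank_bp = 100000), cis),
    primary = primary
  )
  structure(cfg, class = "analysis_config")
}

.classify_rows <- function(p, threshold, nominal = 0.05) {
  if (threshold >= nominal) {
    return(ifelse(!is.na(p) & p < threshold, "significant", "null"))
  }
  ifelse(is.na(p), NA_character_, classify_association(p, threshold, nominal))
}

.forest_row <- function(exposure, outcome, cohort, method, est = NULL,
                        status = "ok") {
  data.frame(
    exposure = exposure, outcome = outcome, cohort = cohort, method = method,
    beta = est$beta %||% NA_real_, se = est$se %||% NA_real_,
    or_ = est$or_ %||% NA_real_, ci_low = est$ci_low %||% NA_real_,
    ci_high = est$ci_high %||% NA_real_, pvalue = est$pvalue %||% NA_real_,
    n_snps = est$n_snps %||% NA_integer_, status = status,
    stringsAsFactors = FALSE
  )
}

.run_cell_estimators <- function(variants, cfg) {
  rows <- list()
  n <- nrow(variants)
  if (n == 1) {
    rows$wald <- wald_ratio(variants)
  }
  if (n >= 2) {
    rows$ivw_re <- mr_ivw(variants, "random")
  }
  if (n >= 3) {
    rows$egger <- mr_egger(variants)
    rows$weighted_median <- mr_weighted_median(
      variants, n_boot = cfg$estimators$n_boot, seed = cfg$estimators$seed)
    rows$weighted_mode <- mr_weighted_mode(
      variants, phi = cfg$estimators$phi, n_boot = cfg$estimators$n_boot,
      seed = cfg$estimators$seed)
  }
  rows
}

#' Run the exposure-by-outcome two-sample MR grid
#'
#' For every exposure and outcome cohort: select instruments, run
#' MR-PRESSO (reporting, and optionally correcting, pleiotropic outliers),
#' run every applicable estimator, then meta-analyze each outcome across
#' its cohorts (per method, heterogeneity-gated) and classify every
#' p-value against the Bonferroni screen. A failing cell is recorded with
#' its error and the grid continues — partial results are valid output.
#'
#' @param config An [analysis_config].
#' @return data.frame of forest rows (`exposure`, `outcome`, `cohort`
#'   (`"meta"` for pooled rows), `method`, `beta`, `se`, `or_`, `ci_low`,
#'   `ci_high`, `pvalue`, `n_snps`, `status`, `classification`) with
#'   attributes `provenance` (per-cell instrument counts, PRESSO outliers,
#'   seeds, thresholds) and `errors` (per-cell failure manifest).
#' @export
run_trait_grid <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  provenance <- list()
  errors <- list()
  sel <- config$selection

  for (exp_name in names(config$exposures)) {
    exposure <- config$exposures[[exp_name]]
    for (oc in config$outcomes) {
      cell <- paste(exp_name, oc$name, oc$cohort, sep = "|")
      res <- tryCatch({
        inst <- suppressMessages(select_instruments(
          exposure, oc$stats, config$ld,
          p_exp_threshold = sel$p_exp_threshold, clump_r2 = sel$clump_r2,
          clump_window_bp = sel$clump_window_bp,
          p_out_threshold = sel$p_out_threshold,
          f_threshold = sel$f_threshold,
          palindromic_policy = sel$palindromic_policy))
        variants <- inst$variants
        prov <- list(n_instruments = nrow(variants),
                     r2_explained = inst$r2_explained,
                     selection_log = inst$selection_log)
        if (nrow(variants) == 0) {
          provenance[[cell]] <- prov
          return_rows <- .forest_row(exp_name, oc$name, oc$cohort, "none",
                                     status = "no_instruments")
          return_rows
        } else {
          presso_res <- NULL
          if (config$presso$run && nrow(variants) >= 4) {
            presso_res <- mr_presso(variants, n_sim = config$presso$n_sim,
                                    outlier_alpha = config$presso$outlier_alpha,
                                    seed = config$presso$seed)
            prov$presso_global_p <- presso_res$global_p
            prov$presso_outliers <- presso_res$outlier_ids
            if (config$primary == "presso_corrected" &&
                length(presso_res$outlier_ids) > 0) {
              variants <- variants[!variants$snp_id %in% presso_res$outlier_ids,
                                   , drop = FALSE]
            }
          }
          provenance[[cell]] <- prov
          ests <- .run_cell_estimators(variants, config)
          cell_rows <- do.call(rbind, lapply(names(ests), function(m)
            .forest_row(exp_name, oc$name, oc$cohort, ests[[m]]$method,
                        ests[[m]])))
          if (!is.null(presso_res) && !is.null(presso_res$beta_corrected) &&
              config$primary == "raw") {
            cell_rows <- rbind(cell_rows,
                               .forest_row(exp_name, oc$name, oc$cohort,
                                           "ivw_presso_corrected",
                                           presso_res$beta_corrected))
          }
          cell_rows
        }
      }, error = function(e) {
        errors[[cell]] <<- conditionMessage(e)
        .forest_row(exp_name, oc$name, oc$cohort, "none", status = "error")
      })
      rows[[cell]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- rbind(out, .meta_rows(out, config))
  threshold <- bonferroni_threshold(config$bonferroni$alpha,
                                    config$bonferroni$n_exposures,
                                    config$bonferroni$n_outcomes)
  out$classification <- .classify_rows(out$pvalue, threshold)
  attr(out, "provenance") <- provenance
  attr(out, "errors") <- errors
  attr(out, "bonferroni_threshold") <- threshold
  out
}

# pooled rows for every (exposure, outcome, method) observed in >= 2 cohorts
.meta_rows <- function(rows, config) {
  ok <- rows[rows$status == "ok" & !is.na(rows$se) & rows$se > 0, ,
             drop = FALSE]
  if (nrow(ok) == 0) return(ok[0, , drop = FALSE])
  keys <- unique(ok[, c("exposure", "outcome", "method")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    grp <- ok[ok$exposure == keys$exposure[i] & ok$outcome == keys$outcome[i] &
                ok$method == keys$method[i], , drop = FALSE]
    if (nrow(grp) < 2) next
    m <- meta_mr(lapply(seq_len(nrow(grp)), function(j)
      list(beta = grp$beta[j], se = grp$se[j])),
      q_alpha = config$meta_gate$q_alpha,
      i2_threshold = config$meta_gate$i2_threshold)
    row <- .forest_row(keys$exposure[i], keys$outcome[i], "meta",
                       keys$method[i],
                       list(beta = m$pooled_beta, se = m$pooled_se,
                            or_ = m$or_, ci_low = m$ci_low,
                            ci_high = m$ci_high, pvalue = m$pooled_p,
                            n_snps = min(grp$n_snps)))
    row$status <- paste0("meta_", m$model_used)
    out[[i]] <- row
  }
  if (length(out) == 0) return(ok[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the drug-target cis-MR grid
#'
#' For every target gene region and outcome cohort: extract clumped cis
#' instruments from the region's lipid trait ([extract_cis]), harmonize
#' with the outcome, estimate the trait-lowering target effect
#' ([target_mr]), then meta-analyze each outcome across cohorts. Regions
#' duplicated by gene symbol are dropped with a warning; a region with no
#' genome-wide-significant variants yields a `"no_instruments"` row.
#'
#' @param config An [analysis_config] whose `exposures` are keyed by lipid
#'   trait name (e.g. `"LDL-C"`, `"TG"`).
#' @param regions data.frame as returned by [drug_target_genes()]
#'   (columns `gene_symbol`, `chrom`, `start`, `end`, `lipid_trait`).
#' @return data.frame of forest rows as in [run_trait_grid()], with
#'   `exposure` holding the gene symbol and an extra `lipid_trait` column;
#'   estimates are oriented per 1-SD lipid lowering.
#' @export
run_target_grid <- function(config, regions) {
  stopifnot(inherits(config, "analysis_config"), is.data.frame(regions))
  if (anyDuplicated(regions$gene_symbol)) {
    warning("duplicate gene region(s) dropped: ",
            paste(unique(regions$gene_symbol[duplicated(regions$gene_symbol)]),
                  collapse = ", "), call. = FALSE)
    regions <- regions[!duplicated(regions$gene_symbol), , drop = FALSE]
  }
  rows <- list()
  errors <- list()
  for (i in seq_len(nrow(regions))) {
    gene <- regions$gene_symbol[i]
    trait <- regions$lipid_trait[i]
    exposure <- config$exposures[[trait]]
    if (is.null(exposure)) {
      errors[[gene]] <- paste0("no exposure named ", trait)
      next
    }
    region <- gene_region(gene, regions$chrom[i], regions$start[i],
                          regions$end[i], config$cis$flank_bp)
    for (oc in config$outcomes) {
      cell <- paste(gene, oc$name, oc$cohort, sep = "|")
      rows[[cell]] <- tryCatch({
        cis <- suppressMessages(extract_cis(
          exposure, region, p_threshold = config$cis$p_threshold,
          ld = config$ld, clump_r2 = config$cis$clump_r2,
          clump_window_bp = config$cis$clump_window_bp))
        if (nrow(cis) == 0) {
          row <- .forest_row(gene, oc$name, oc$cohort, "none",
                             status = "no_instruments")
        } else {
          harm <- suppressMessages(harmonize(
            cis, oc$stats,
            palindromic_policy = config$selection$palindromic_policy))
          if (nrow(harm) == 0) {
            row <- .forest_row(gene, oc$name, oc$cohort, "none",
                               status = "no_instruments")
          } else {
            est <- target_mr(harm, orientation = "lowering")
            row <- .forest_row(gene, oc$name, oc$cohort, est$method, est)
          }
        }
        row$lipid_trait <- trait
        row
      }, error = function(e) {
        errors[[cell]] <<- conditionMessage(e)
        row <- .forest_row(gene, oc$name, oc$cohort, "none", status = "error")
        row$lipid_trait <- trait
        row
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  meta <- .meta_rows(out[setdiff(names(out), "lipid_trait")], config)
  if (nrow(meta) > 0) {
    meta$lipid_trait <- regions$lipid_trait[match(meta$exposure,
                                                  regions$gene_symbol)]
    out <- rbind(out, meta)
  }
  threshold <- bonferroni_threshold(config$bonferroni$alpha,
                                    config$bonferroni$n_exposures,
                                    config$bonferroni$n_outcomes)
  out$classification <- .classify_rows(out$pvalue, threshold)
  attr(out, "errors") <- errors
  attr(out, "bonferroni_threshold") <- threshold
  out
}

#' Canonical forest-row column order
#'
#' Fixed column order of the tidy result table written by
#' [render_forest()].
#'
#' @format Character vector of length 13.
#' @export
FOREST_COLUMNS <- c("exposure", "outcome", "cohort", "method", "beta", "se",
                    "or_", "ci_low", "ci_high", "pvalue", "n_snps", "status",
                    "classification")

utils::globalVariables(c("or_", "label", "ci_low", "ci_high", "excludes_1",
                         "outcome"))

#' Write forest-plot rows as TSV and render the figure
#'
#' Writes the tidy result table with a fixed, documented column order
#' (see `FOREST_COLUMNS`) and a forest figure: one panel per outcome,
#' log-scaled odds-ratio axis, 95% CI whiskers, with intervals crossing
#' OR = 1 drawn hollow and intervals excluding 1 drawn solid.
#'
#' @param rows Forest rows from [run_trait_grid()] / [run_target_grid()].
#' @param path Output TSV path; the figure goes to the same stem with a
#'   `.pdf` extension.
#' @param methods Methods to draw (default `"ivw_re"`; the TSV always
#'   contains every row).
#' @return `path`, invisibly.
#' @export
render_forest <- function(rows, path, methods = "ivw_re") {
  if (is.null(rows) || nrow(rows) == 0) stop("no rows to render", call. = FALSE)
  extra <- setdiff(names(rows), FOREST_COLUMNS)
  tab <- rows[c(FOREST_COLUMNS, extra)]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.12g", x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)

  plot_rows <- rows[rows$method %in% methods & !is.na(rows$or_), ,
                    drop = FALSE]
  if (nrow(plot_rows) > 0) {
    plot_rows$label <- paste(plot_rows$exposure, plot_rows$cohort)
    plot_rows$excludes_1 <- plot_rows$ci_low > 1 | plot_rows$ci_high < 1
    fig <- ggplot2::ggplot(plot_rows,
                           ggplot2::aes(x = or_, y = label)) +
      ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                          colour = "grey50") +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low, xmax = ci_high),
                              height = 0.2) +
      ggplot2::geom_point(ggplot2::aes(shape = excludes_1), size = 2) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  name = "CI excludes 1") +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~outcome, scales = "free_y") +
      ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
      ggplot2::theme_bw()
    fig_path <- paste0(sub("\\.[^.]+$", "", path), ".pdf")
    grDevices::pdf(fig_path, width = 8, height = 2 + 0.3 * nrow(plot_rows))
    print(fig)
    grDevices::dev.off()
  }
  invisible(path)
}
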