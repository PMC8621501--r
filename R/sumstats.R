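#' Canonical summary-statistic columns
#'
#' Column names of the canonical per-variant GWAS summary-statistic table:
#' one row per variant with identifier, genomic location, alleles,
#' effect-allele frequency, effect size, standard error, p-value and sample
#' size.
#'
#' @format Character vector of length 10.
#' @export
SUMSTATS_COLUMNS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

.VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated summary-statistics object
#'
#' Builds a `summary_stats` object (a data.frame with the canonical columns
#' plus `trait_name` / `trait_type` attributes) from a per-variant table.
#' Rows violating the per-variant invariants (alleles in A/C/G/T and
#' distinct, `se > 0`, `0 < eaf < 1`, `0 < pvalue <= 1`, `pos >= 1`,
#' `n > 0`) are dropped with a message; `eaf` may be `NA` (frequency
#' missing), all other fields must be present.
#'
#' @param df data.frame containing the canonical columns
#'   (see [SUMSTATS_COLUMNS]).
#' @param trait_name Name of the trait the statistics describe.
#' @param trait_type `"continuous"` (beta in SD units) or `"binary"`
#'   (beta on the log-odds scale).
#' @return A `summary_stats` data.frame. The number of dropped rows is
#'   attached as attribute `n_dropped`.
#' @export
summary_stats <- function(df, trait_name = "trait",
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[SUMSTATS_COLUMNS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) df[[col]] <- as.numeric(df[[col]])

  ok <- !is.na(df$snp_id) & !is.na(df$beta) & !is.na(df$se) &
    !is.na(df$pvalue) & !is.na(df$pos) &
    df$effect_allele %in% .VALID_ALLELES &
    df$other_allele %in% .VALID_ALLELES &
    df$effect_allele != df$other_allele &
    df$se > 0 & df$pvalue > 0 & df$pvalue <= 1 &
    df$pos >= 1 & (is.na(df$n) | df$n > 0) &
    (is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for invariant violations")
    df <- df[ok, , drop = FALSE]
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id values: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name, trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variant(s)\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing delimited file, renames columns via `column_map`,
#' validates every row and returns a [summary_stats] object. Rows violating
#' the per-variant invariants are dropped (their count is messaged and kept
#' in the `n_dropped` attribute); duplicate variant identifiers are an error.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical names
#'   (see [SUMSTATS_COLUMNS]) to column names in the file. Canonical names
#'   absent from the map are assumed to appear verbatim in the header.
#' @param trait_name,trait_type Passed to [summary_stats()].
#' @param sep Field separator (default tab).
#' @return A `summary_stats` object.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NULL,
                          trait_type = c("continuous", "binary"),
                          sep = "\t") {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  map <- stats::setNames(SUMSTATS_COLUMNS, SUMSTATS_COLUMNS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMSTATS_COLUMNS)
    if (length(bad) > 0) {
      stop("unknown canonical name(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("mapped column(s) not found in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- stats::setNames(raw[unname(map)], names(map))
  out <- summary_stats(df,
                       trait_name = if (is.null(trait_name)) basename(path) else trait_name,
                       trait_type = trait_type)
  if (nrow(out) == 0) stop("no valid rows in ", path, call. = FALSE)
  out
}

#' Write summary statistics to a tab-delimited file
#'
#' Writes the canonical 10-column table with a header row. Floating-point
#' fields are written with 12 significant digits so a write/read round trip
#' preserves values to at least 10 significant digits.
#'
#' @param stats A [summary_stats] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- as.data.frame(stats)
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- sprintf("%.12g", df[[col]])
    df[[col]][df[[col]] == "NA"] <- "NA"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct an LD matrix object
#'
#' Holds pairwise squared correlations (r-squared) between variants together
#' with their identifiers and positions. The matrix must be symmetric with a
#' unit diagonal and entries in \[0, 1\].
#'
#' @param snp_ids Character vector of variant identifiers.
#' @param r2 Square symmetric matrix of pairwise r-squared values.
#' @param pos Integer vector of 1-based positions, parallel to `snp_ids`.
#' @return An `ld_matrix` object (list with `snp_ids`, `r2`, `pos`).
#' @export
ld_matrix <- function(snp_ids, r2, pos) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  pos <- as.integer(pos)
  m <- length(snp_ids)
  if (!all(dim(r2) == c(m, m)) || length(pos) != m) {
    stop("dimension mismatch between snp_ids, r2 and pos", call. = FALSE)
  }
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2, pos = pos),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d variant(s)\n", length(x$snp_ids)))
  invisible(x)
}

#' Write an LD matrix as TSV
#'
#' Square tab-separated matrix whose header row and first column are the
#' variant identifiers; positions go to a companion two-column file
#' `<path>.pos`.
#'
#' @param ld An [ld_matrix] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- as.data.frame(matrix(sprintf("%.12g", ld$r2), nrow = length(ld$snp_ids)))
  names(df) <- ld$snp_ids
  df <- cbind(snp_id = ld$snp_ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  utils::write.table(data.frame(snp_id = ld$snp_ids, pos = ld$pos),
                     paste0(path, ".pos"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#'
#' @param path Path to the TSV matrix (positions are read from
#'   `<path>.pos`).
#' @return An [ld_matrix] object.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$snp_id)
  r2 <- as.matrix(df[setdiff(names(df), "snp_id")])
  posf <- paste0(path, ".pos")
  pos <- if (file.exists(posf)) {
    p <- utils::read.table(posf, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    p$pos[match(ids, p$snp_id)]
  } else rep(NA_integer_, length(ids))
  ld_matrix(ids, r2, pos)
}
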