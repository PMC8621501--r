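mk_stats <- function(ids, ea, oa, beta, eaf, se = 0.01, pos = NULL,
                     trait = "t") {
  summary_stats(data.frame(
    snp_id = ids, chrom = "1",
    pos = if (is.null(pos)) seq_along(ids) * 100L else pos,
    effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
    se = se, pvalue = 0.5, n = 1000, stringsAsFactors = FALSE),
    trait_name = trait)
}

test_that("matching alleles pass through unchanged", {
  ex <- mk_stats("rs1", "A", "G", 0.10, 0.30)
  ou <- mk_stats("rs1", "A", "G", 0.05, 0.30)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, 0.05)
  expect_false(h$flipped)
})

test_that("swapped outcome alleles flip the sign and the frequency", {
  ex <- mk_stats("rs1", "A", "G", 0.10, 0.30)
  ou <- mk_stats("rs1", "G", "A", 0.05, 0.30)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.70)
  expect_true(h$flipped)
})

test_that("opposite-strand alleles are aligned via reverse complement", {
  ex <- mk_stats("rs1", "A", "G", 0.10, 0.30)
  ou_same <- mk_stats("rs1", "T", "C", 0.05, 0.30)   # complement, same order
  ou_swap <- mk_stats("rs1", "C", "T", 0.05, 0.30)   # complement, swapped
  expect_equal(harmonize(ex, ou_same)$beta_out, 0.05)
  h <- harmonize(ex, ou_swap)
  expect_equal(h$beta_out, -0.05)
  expect_true(h$flipped)
  # unresolvable allele set is excluded and logged
  ou_bad <- mk_stats("rs1", "A", "C", 0.05, 0.30)
  expect_message(h_bad <- harmonize(ex, ou_bad), "excluded")
  expect_equal(nrow(h_bad), 0)
  expect_equal(attr(h_bad, "log")$reason, "allele_mismatch")
})

test_that("palindromic policy decision table is honoured", {
  # enumerate the policy table: (eaf_exp, eaf_out, expected outcome)
  cases <- list(
    list(0.30, 0.30, "keep_same"),    # frequencies agree -> same strand
    list(0.30, 0.70, "keep_flip"),    # frequencies disagree -> strand flip
    list(0.50, 0.30, "drop"),         # ambiguous exposure frequency
    list(0.30, 0.55, "drop"),         # ambiguous outcome frequency
    list(NA, 0.30, "drop")            # missing frequency
  )
  for (cs in cases) {
    ex <- mk_stats("rs1", "A", "T", 0.10, cs[[1]])
    ou <- mk_stats("rs1", "A", "T", 0.05, cs[[2]])
    h <- suppressMessages(harmonize(ex, ou, "infer_by_eaf"))
    if (cs[[3]] == "drop") {
      expect_equal(nrow(h), 0)
    } else {
      expect_equal(nrow(h), 1)
      expect_true(h$palindromic)
      expect_equal(h$beta_out, if (cs[[3]] == "keep_flip") -0.05 else 0.05)
    }
  }
  # the drop policy removes palindromic variants regardless of frequency
  ex <- mk_stats("rs1", "A", "T", 0.10, 0.30)
  ou <- mk_stats("rs1", "A", "T", 0.05, 0.30)
  expect_equal(nrow(suppressMessages(harmonize(ex, ou, "drop"))), 0)
  expect_equal(nrow(harmonize(ex, ou, "keep")), 1)
})

test_that("harmonization is idempotent and a double flip is the identity", {
  set.seed(21)
  m <- 40
  alleles <- cbind(sample(c("A", "C"), m, TRUE), "G")
  ex <- mk_stats(sprintf("rs%02d", 1:m), alleles[, 1], alleles[, 2],
                 rnorm(m, 0, 0.1), runif(m, 0.1, 0.9))
  ou <- mk_stats(sprintf("rs%02d", 1:m), alleles[, 1], alleles[, 2],
                 rnorm(m, 0, 0.1), ex$eaf + rnorm(m, 0, 0.01))
  h1 <- harmonize(ex, ou)
  # re-harmonizing the already-aligned pair changes nothing
  ou_aligned <- mk_stats(h1$snp_id, h1$effect_allele, h1$other_allele,
                         h1$beta_out, h1$eaf_out)
  h2 <- harmonize(ex, ou_aligned)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
  expect_false(any(h2$flipped))

  # flipping the outcome alleles in the input yields identical pairs
  ou_flip <- mk_stats(ou$snp_id, ou$other_allele, ou$effect_allele,
                      -ou$beta, 1 - ou$eaf)
  h3 <- harmonize(ex, ou_flip)
  expect_equal(h3$beta_out, h1$beta_out)
  expect_equal(h3$eaf_out, h1$eaf_out)
})

test_that("record count never exceeds the smaller input; empty overlap errors", {
  ex <- mk_stats(c("rs1", "rs2"), "A", "G", c(0.1, 0.2), 0.3)
  ou <- mk_stats(c("rs2", "rs3"), "A", "G", c(0.1, 0.2), 0.3)
  h <- harmonize(ex, ou)
  expect_lte(nrow(h), 2)
  expect_identical(h$snp_id, "rs2")
  expect_error(harmonize(ex, mk_stats("rs9", "A", "G", 0.1, 0.3)),
               "no shared")
})
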