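# association-set I/O, instrument filtering and harmonization

bmi_rsids <- c("rs10938397", "rs12446632", "rs2947411", "rs3101336",
               "rs543874", "rs7103411", "rs7138803", "rs7514705", "rs8050136")

write_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("reading a valid table round-trips and rejects invalid rows with a report", {
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "C", "G"),
                   other_allele = c("G", "T", "A"),
                   beta = c(0.1, -0.2, 0.05), se = c(0.01, 0.02, 0.01),
                   pval = c(1e-9, 1e-12, 1e-10))
  s <- read_associations(write_tsv(df), column_map = c(pvalue = "pval"))
  expect_s3_class(s, "association_set")
  expect_equal(nrow(s), 3L)
  expect_equal(s$beta, df$beta)
  expect_equal(s$pvalue, df$pval)

  df_bad <- df
  df_bad$se[2] <- 0
  s2 <- read_associations(write_tsv(df_bad), column_map = c(pvalue = "pval"))
  expect_equal(nrow(s2), 2L)
  expect_match(attr(s2, "validation_log"), "rs2", all = FALSE)
  expect_match(attr(s2, "validation_log"), "se not > 0", all = FALSE)

  df_dup <- rbind(df, df[1, ])
  expect_error(read_associations(write_tsv(df_dup)), "rs1")
  expect_error(read_associations(tempfile(), NULL), "not found")
  expect_error(read_associations(write_tsv(df), column_map = c(pvalue = "nope")),
               "nope")
})

test_that("instrument filtering is a strict p-value cut", {
  s <- mk_assoc(c("a", "b"), c("A", "A"), c("G", "G"), c(0.1, 0.1),
                c(0.01, 0.01), pvalue = c(1e-9, 1e-7))
  kept <- filter_instruments(s, 5e-8)
  expect_equal(kept$rsid, "a")
  expect_equal(nrow(filter_instruments(s, 1.0)), 2L)
  expect_error(filter_instruments(s, 1e-12), "no instrument")
})

test_that("excluding the 9 BMI-associated variants from a 116-SNP set leaves 107", {
  set.seed(42)
  rsids <- c(bmi_rsids, sprintf("rs%d", 1:107))
  s <- mk_assoc(rsids, rep("A", 116), rep("G", 116),
                rnorm(116, 0, 0.03), rep(0.005, 116))
  out <- exclude_snps(s, bmi_rsids)
  expect_equal(nrow(out), 107L)
  expect_equal(attr(out, "n_excluded"), 9L)
  expect_false(any(bmi_rsids %in% out$rsid))
  # no-ops
  expect_equal(nrow(exclude_snps(s, character(0))), 116L)
  expect_warning(out2 <- exclude_snps(s, "rs_not_here"), "rs_not_here")
  expect_equal(nrow(out2), 116L)
})

test_that("harmonization aligns swapped alleles by negating the outcome effect", {
  ex <- mk_assoc("rs1", "A", "G", 0.1, 0.01)
  ou <- mk_assoc("rs1", "G", "A", 0.2, 0.02, label = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$beta_x, 0.1)
  expect_equal(h$beta_y, -0.2)
  expect_equal(h$se_y, 0.02)
})

test_that("only overlapping SNPs survive and the deficit is fully accounted for", {
  ex <- mk_assoc(sprintf("rs%d", 1:33), rep("A", 33), rep("G", 33),
                 seq(0.01, 0.33, by = 0.01), rep(0.005, 33))
  ou <- mk_assoc(sprintf("rs%d", 1:23), rep("A", 23), rep("G", 23),
                 rnorm(23, 0, 0.01), rep(0.004, 23), label = "out")
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 23L)
  dr <- attr(h, "drop_report")
  expect_equal(sum(dr$reason == "absent_in_outcome"), 10L)
  expect_equal(nrow(h) + nrow(dr), 33L)
  expect_lte(nrow(h), min(33L, 23L))
})

test_that("palindromic SNPs are flagged, and dropped only on request", {
  ex <- mk_assoc(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                 c(0.1, 0.1), c(0.01, 0.01))
  ou <- mk_assoc(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                 c(0.2, 0.2), c(0.02, 0.02), label = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$palindromic, c(TRUE, FALSE))
  h2 <- harmonize(ex, ou, drop_palindromic = TRUE)
  expect_equal(h2$rsid, "rs2")
  expect_true("rs1" %in% attr(h2, "drop_report")$rsid)
  expect_equal(attr(h2, "drop_report")$reason, "palindromic_dropped")
})

test_that("strand complements are reconciled and true mismatches dropped", {
  ex <- mk_assoc(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "G", "G"),
                 c(0.1, 0.1, 0.1), rep(0.01, 3))
  # rs1 on the other strand (T/C ~ A/G), rs2 other strand swapped, rs3 mismatch
  ou <- mk_assoc(c("rs1", "rs2", "rs3"), c("T", "C", "A"), c("C", "T", "C"),
                 c(0.2, 0.2, 0.2), rep(0.02, 3), label = "out")
  h <- harmonize(ex, ou)
  expect_equal(h$rsid, c("rs1", "rs2"))
  expect_equal(h$beta_y, c(0.2, -0.2))
  expect_setequal(attr(h, "complement_resolved"), c("rs1", "rs2"))
  expect_equal(attr(h, "drop_report")$rsid, "rs3")
  expect_equal(attr(h, "drop_report")$reason, "allele_mismatch")
  # nothing in common at all -> error
  expect_error(harmonize(ex, mk_assoc("rsX", "A", "G", 0.1, 0.01)), "no SNPs")
})

test_that("harmonization is idempotent on already-aligned sets", {
  set.seed(3)
  ex <- mk_assoc(sprintf("rs%d", 1:8), rep("A", 8), rep("G", 8),
                 abs(rnorm(8, 0, 0.03)), rep(0.004, 8))
  ou <- mk_assoc(sprintf("rs%d", 1:8), rep("A", 8), rep("G", 8),
                 rnorm(8, 0, 0.01), rep(0.005, 8), label = "out")
  h1 <- harmonize(ex, ou)
  # rebuild association sets from the harmonized pairs and harmonize again
  ex2 <- mk_assoc(h1$rsid, h1$effect_allele, h1$other_allele, h1$beta_x, h1$se_x)
  ou2 <- mk_assoc(h1$rsid, h1$effect_allele, h1$other_allele, h1$beta_y, h1$se_y,
                  label = "out")
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_x, h1$beta_x)
  expect_equal(h2$beta_y, h1$beta_y)
})

test_that("allele representation of the outcome never changes the estimates", {
  cfg_clean <- sim_config(n_snps = 25, beta_causal = 0.2, seed = 11,
                          randomize_alleles = FALSE)
  cfg_rand <- sim_config(n_snps = 25, beta_causal = 0.2, seed = 11,
                         randomize_alleles = TRUE)
  clean <- simulate_summary(cfg_clean)
  rand <- simulate_summary(cfg_rand)
  h_clean <- harmonize(clean$exposure, clean$outcome)
  h_rand <- harmonize(rand$exposure, rand$outcome)
  expect_equal(mr_ivw(h_rand)$beta, mr_ivw(h_clean)$beta)
  expect_equal(mr_egger(h_rand)$slope$beta, mr_egger(h_clean)$slope$beta)
  expect_equal(mr_egger(h_rand)$intercept$beta, mr_egger(h_clean)$intercept$beta)
  expect_equal(mr_weighted_median(h_rand, b_boot = 0)$beta,
               mr_weighted_median(h_clean, b_boot = 0)$beta)
  expect_equal(cochran_q(h_rand)$q, cochran_q(h_clean)$q)
})

test_that("manually flipping any outcome record leaves estimators unchanged", {
  set.seed(5)
  ex <- mk_assoc(sprintf("rs%d", 1:10), rep("A", 10), rep("G", 10),
                 rnorm(10, 0, 0.03), rep(0.004, 10))
  ou_df <- data.frame(rsid = sprintf("rs%d", 1:10),
                      effect_allele = "A", other_allele = "G",
                      beta = rnorm(10, 0, 0.01), se = rep(0.005, 10))
  flip <- c(2, 5, 9)
  ou_flip <- ou_df
  ou_flip$effect_allele[flip] <- "G"
  ou_flip$other_allele[flip] <- "A"
  ou_flip$beta[flip] <- -ou_flip$beta[flip]
  h1 <- harmonize(ex, association_set(ou_df, "o"))
  h2 <- harmonize(ex, association_set(ou_flip, "o"))
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta, tolerance = 1e-15)
  expect_equal(cochran_q(h2)$q, cochran_q(h1)$q, tolerance = 1e-15)
})

test_that("direction reversal negates, swaps bounds, and is an involution", {
  e <- mr_estimate("ivw_random", 0.256, 0.0437, 23L)
  r <- reverse_direction(e)
  expect_equal(r$beta, -0.256)
  expect_equal(r$ci_lower, -e$ci_upper)
  expect_equal(r$ci_upper, -e$ci_lower)
  expect_equal(r$se, e$se)
  expect_equal(r$pvalue, e$pvalue)
  expect_equal(r$direction, "per-unit-earlier")
  expect_lte(r$ci_lower, r$beta)
  expect_gte(r$ci_upper, r$beta)
  # zero effect: only the flag toggles
  z <- reverse_direction(mr_estimate("ivw_random", 0, 0.1, 5L))
  expect_equal(z$beta, 0)
  expect_equal(z$direction, "per-unit-earlier")
  # involution
  expect_equal(reverse_direction(r), e)
  # must precede OR exponentiation
  expect_error(reverse_direction(to_odds_ratio(e)), "linear scale")
})
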