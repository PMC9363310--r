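test_that("delimited files round-trip through read and write", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
               "rs1\tA\tG\t0.1\t0.02\t5.7e-7",
               "rs2\tt\tc\t-0.25\t0.05\t5.7e-7",
               "rs3\tC\tA\t0.033\t0.01\t0.0009"), f)
  tab <- read_sumstats(f, c(snp_id = "SNP", effect_allele = "EA",
                            other_allele = "OA", beta = "BETA", se = "SE",
                            pval = "P"))
  expect_s3_class(tab, "sumstats")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$effect_allele[2], "T")  # upper-cased
  g <- tempfile(fileext = ".tsv")
  write_sumstats(tab, g)
  back <- read_sumstats(g, c(snp_id = "snp_id", effect_allele = "effect_allele",
                             other_allele = "other_allele", beta = "beta",
                             se = "se", pval = "pval"))
  expect_equal(back$beta, tab$beta)
  expect_equal(back$se, tab$se)
  expect_equal(back$pval, tab$pval)
})

test_that("rows violating record invariants are rejected with reasons", {
  df <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   effect_allele = c("A", "A", "X", "A", "A"),
                   other_allele = c("G", "G", "G", "A", "G"),
                   beta = c(0.1, 0.1, 0.1, 0.1, 0.1),
                   se = c(0.02, 0, 0.02, 0.02, 0.02),
                   pval = c(1e-8, 1e-8, 1e-8, 1e-8, 2))
  tab <- sumstats(df, check_p = FALSE)
  expect_equal(nrow(tab), 1)
  rej <- attr(tab, "rejected")
  expect_setequal(rej$snp_id, c("rs2", "rs3", "rs4", "rs5"))
  expect_equal(rej$reason[rej$snp_id == "rs2"], "se not positive")
  expect_equal(rej$reason[rej$snp_id == "rs3"], "invalid effect allele")
  expect_equal(rej$reason[rej$snp_id == "rs4"], "alleles not distinct")
  expect_equal(rej$reason[rej$snp_id == "rs5"], "pval outside (0, 1]")
})

test_that("unparseable numerics are collected as row errors, not crashes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
               "rs1\tA\tG\tnot_a_number\t0.02\t5.7e-7",
               "rs2\tA\tG\t0.1\t0.02\t5.7e-7"), f)
  tab <- read_sumstats(f, c(snp_id = "SNP", effect_allele = "EA",
                            other_allele = "OA", beta = "BETA", se = "SE",
                            pval = "P"))
  expect_equal(tab$snp_id, "rs2")
  expect_equal(attr(tab, "rejected")$reason, "beta not numeric")
})

test_that("a missing mapped column is a configuration error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP", "rs1\tA\tG\t0.1\t0.02\t1e-8"), f)
  expect_error(read_sumstats(f, c(snp_id = "SNP", effect_allele = "EA",
                                  other_allele = "OA", beta = "BETA",
                                  se = "SE", pval = "PVALUE")),
               "not in file")
  expect_error(read_sumstats(f, c(snp_id = "SNP")), "must map")
})

test_that("reported p far from |beta/se| triggers a validation warning only", {
  df <- data.frame(snp_id = "rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.1, se = 0.02, pval = 0.5)
  expect_warning(tab <- sumstats(df), "inconsistent")
  expect_equal(nrow(tab), 1)  # warning, not rejection
  expect_silent(sumstats(df, check_p = FALSE))
})

test_that("packaged instrument lists have the published epoch structure", {
  counts <- c(birth = 8, infancy = 18, early_childhood = 4,
              later_childhood = 5)
  for (ep in names(counts)) {
    fx <- bmi_ms_instruments(ep)
    expect_equal(nrow(fx$exposure), unname(counts[ep]), label = ep)
    expect_equal(nrow(fx$outcome), unname(counts[ep]), label = ep)
    expect_equal(nrow(attr(fx$exposure, "rejected")), 0)
  }
  all <- bmi_ms_instruments("all")
  expect_equal(nrow(all$exposure), 35)
  # spot-check transcribed values
  inf <- bmi_ms_instruments("infancy")$exposure
  expect_equal(inf$beta[inf$snp_id == "rs2767486"], -0.14325)
  lc <- bmi_ms_instruments("later_childhood")$exposure
  expect_true("rs545608" %in% lc$snp_id)
  expect_equal(lc$effect_allele[lc$snp_id == "rs545608"], "G")
  expect_equal(lc$other_allele[lc$snp_id == "rs545608"], "C")
  expect_error(bmi_ms_instruments("adolescence"))
})

test_that("writing an empty table errors; round-trip is identity on records", {
  canonical_map_for_test <- function() {
    nm <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n", "trait", "timepoint")
    setNames(nm, nm)
  }
  empty <- filter_genomewide(mk_sumstats(3), 1e-300)
  expect_error(write_sumstats(empty, tempfile()), "empty")
  sim <- simulate_two_sample(synth_scenario(n_snp = 1000, seed = 42))
  f <- tempfile(fileext = ".tsv")
  write_sumstats(sim$exposure, f)
  back <- read_sumstats(f, canonical_map_for_test())
  for (cc in c("snp_id", "effect_allele", "other_allele", "eaf", "beta",
               "se", "pval"))
    expect_identical(back[[cc]], sim$exposure[[cc]])
})
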