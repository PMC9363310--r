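test_that("genome-wide filter is strict and order-preserving", {
  tab <- mk_sumstats(4, pval = c(2.10e-08, 5e-8, 4.9999e-8, 0.2))
  kept <- filter_genomewide(tab, 5e-8)
  expect_equal(kept$snp_id, c("rs001", "rs003"))  # 5e-8 exactly is dropped
  # counting matches a direct comparison on random p-values
  set.seed(11)
  p <- runif(100, 0, 1e-6)
  tab2 <- mk_sumstats(100, pval = p)
  expect_equal(nrow(filter_genomewide(tab2, 1e-7)), sum(p < 1e-7))
  expect_identical(filter_genomewide(filter_genomewide(tab2, 1e-7), 1e-7),
                   filter_genomewide(tab2, 1e-7))  # idempotent
})

test_that("MHC exclusion removes chr6:25-35Mb inclusively and only there", {
  tab <- mk_sumstats(4, chrom = c("6", "6", "7", "6"),
                     pos = c(30e6, 24999999, 30e6, 35e6))
  out <- exclude_mhc(tab)
  expect_setequal(out$snp_id, c("rs002", "rs003"))
  expect_setequal(attr(out, "mhc_removed"), c("rs001", "rs004"))
  # missing positions fail loudly, naming the SNP
  expect_error(exclude_mhc(mk_sumstats(2)), "rs001")
  # "chr6" and "6" are the same chromosome
  tab2 <- mk_sumstats(1, chrom = "chr6", pos = 26e6)
  expect_equal(nrow(exclude_mhc(tab2)), 0)
})

test_that("clumping keeps the most significant SNP of each LD block", {
  # two linked SNPs: smaller p wins
  tab <- mk_sumstats(2, pval = c(1e-10, 1e-9), chrom = "1",
                     pos = c(1e6, 1.5e6))
  ld <- ld_matrix(matrix(c(1, .5, .5, 1), 2,
                         dimnames = list(tab$snp_id, tab$snp_id)))
  expect_equal(clump(tab, ld)$snp_id, "rs001")
  # mutually unlinked SNPs all survive
  ld0 <- ld_matrix(diag(2) + 0 * unclass(ld))
  expect_equal(nrow(clump(tab, ld0)), 2)
  # 20 SNPs in 4 blocks: exactly the per-block minimum-p SNP survives
  set.seed(21)
  n <- 20
  block <- rep(1:4, each = 5)
  p <- runif(n, 1e-12, 1e-8)
  tab4 <- mk_sumstats(n, pval = p, chrom = "2",
                      pos = 1e6 + seq_len(n) * 1e4)
  m <- outer(block, block, function(a, b) ifelse(a == b, 0.8, 0))
  diag(m) <- 1
  dimnames(m) <- list(tab4$snp_id, tab4$snp_id)
  got <- clump(tab4, ld_matrix(m))$snp_id
  want <- vapply(1:4, function(b) tab4$snp_id[block == b][
    which.min(p[block == b])], "")
  expect_setequal(got, want)
  expect_equal(nrow(attr(clump(tab4, ld_matrix(m)), "clumped_out")), 16)
})

test_that("clumping respects the distance window and missing-SNP policy", {
  # r2 above threshold but outside the 10Mb window: both kept
  tab <- mk_sumstats(2, pval = c(1e-10, 1e-9), chrom = "1",
                     pos = c(1e6, 12e6))
  ld <- ld_matrix(matrix(c(1, .9, .9, 1), 2,
                         dimnames = list(tab$snp_id, tab$snp_id)))
  expect_equal(nrow(clump(tab, ld, window_kb = 10000)), 2)
  # different chromosomes are never within the window
  tab2 <- mk_sumstats(2, pval = c(1e-10, 1e-9), chrom = c("1", "2"),
                      pos = c(1e6, 1e6))
  dimnames(ld) <- list(tab2$snp_id, tab2$snp_id)
  expect_equal(nrow(clump(tab2, ld_matrix(unclass(ld)))), 2)
  # SNP absent from the matrix: error unless explicitly allowed
  tab3 <- mk_sumstats(3, pval = c(1e-10, 1e-9, 1e-8), chrom = "1",
                      pos = c(1, 2, 3) * 1e6)
  expect_error(clump(tab3, ld), "absent")
  expect_equal(nrow(clump(tab3, ld, allow_missing = TRUE)), 2)
  # asymmetric matrix is rejected
  bad <- matrix(c(1, .2, .6, 1), 2,
                dimnames = list(tab$snp_id, tab$snp_id))
  expect_error(clump(tab, bad), "symmetric")
})

test_that("epoch amalgamation takes each SNP's strongest time point", {
  t3mo <- mk_sumstats(2, snp_id = c("rsA", "rsB"), beta = c(0.05, 0.06),
                      pval = c(1e-9, 1e-10), timepoint = "3mo")
  t1y <- mk_sumstats(2, snp_id = c("rsA", "rsC"), beta = c(0.07, 0.08),
                     pval = c(1e-12, 1e-9), timepoint = "1y")
  out <- amalgamate_epochs(list(`3mo` = t3mo, `1y` = t1y),
                           list(infancy = c("3mo", "1y")))
  inf <- out$infancy
  expect_setequal(inf$snp_id, c("rsA", "rsB", "rsC"))
  expect_equal(inf$beta[inf$snp_id == "rsA"], 0.07)  # 1y beats 3mo
  expect_equal(inf$timepoint[inf$snp_id == "rsA"], "1y")
  # significant at a single time point: those statistics carry through
  expect_equal(inf$timepoint[inf$snp_id == "rsB"], "3mo")
})

test_that("amalgamation equals per-SNP brute-force minimum over time points", {
  set.seed(31)
  tps <- c("2y", "3y", "5y")
  ids <- sprintf("rs%02d", 1:12)
  tabs <- lapply(tps, function(tp)
    mk_sumstats(12, snp_id = ids, beta = rnorm(12, 0.06, 0.01),
                pval = 10^runif(12, -14, -4), timepoint = tp))
  names(tabs) <- tps
  out <- amalgamate_epochs(tabs, list(early = tps), threshold = 5e-8)$early
  # brute force: per SNP, enumerate all significant time points
  for (id in ids) {
    ps <- vapply(tps, function(tp) {
      x <- tabs[[tp]]
      x$pval[x$snp_id == id]
    }, 0)
    sig <- ps[ps < 5e-8]
    if (!length(sig)) expect_false(id %in% out$snp_id, label = id)
    else expect_equal(out$pval[out$snp_id == id], min(sig), label = id)
  }
  # time point in two epochs is a configuration error
  expect_error(amalgamate_epochs(tabs, list(a = c("2y", "3y"),
                                            b = c("3y", "5y"))),
               "more than one epoch")
})
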