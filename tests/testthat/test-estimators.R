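test_that("Wald ratio is the outcome/exposure quotient with scaled SE", {
  # quotient of the published rs11187129 betas
  snp <- data.frame(snp_id = "rs11187129", beta_exp = -0.0471726,
                    se_exp = 0.008338, beta_out = 0.094401, se_out = 0.01739)
  est <- mr_wald_ratio(snp)
  expect_equal(est$beta, 0.094401 / -0.0471726, tolerance = 1e-12)
  expect_equal(round(est$beta, 4), -2.0012)
  expect_equal(est$se, 0.01739 / 0.0471726)
  # zero outcome effect gives a zero ratio; unit exposure passes se through
  expect_equal(mr_wald_ratio(mk_instr(1, 0, sy = 0.2))$beta, 0)
  expect_equal(mr_wald_ratio(mk_instr(1, 0.5, sy = 0.2))$se, 0.2)
  expect_error(mr_wald_ratio(mk_instr(0, 0.1)), "zero")
})

test_that("fixed-effect IVW equals a fixed-effect meta-analysis of Wald ratios", {
  library(metafor)
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    instr <- mk_instr(rnorm(n, 0.08, 0.02), rnorm(n, 0.02, 0.02),
                      sx = runif(n, 0.005, 0.02), sy = runif(n, 0.01, 0.03))
    s <- instr$snps
    fe <- rma(yi = s$beta_out / s$beta_exp, vi = s$se_out^2 / s$beta_exp^2,
              method = "FE")
    got <- mr_ivw(instr, "fixed")
    expect_equal(got$beta, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(got$se, fe$se, tolerance = 1e-10)
    # Q about the IVW estimate matches metafor's QE
    expect_equal(cochran_q(instr)$q, fe$QE, tolerance = 1e-10)
  }
})

test_that("IVW degenerates correctly and MRE never deflates the SE", {
  # identical Wald ratios: estimate is that ratio, Q = 0, MRE se = fixed se
  instr <- mk_instr(c(0.05, 0.10, 0.2), c(0.05, 0.10, 0.2) * 1.7)
  expect_equal(mr_ivw(instr, "fixed")$beta, 1.7, tolerance = 1e-12)
  expect_equal(cochran_q(instr)$q, 0, tolerance = 1e-20)
  expect_equal(mr_ivw(instr, "mre")$se, mr_ivw(instr, "fixed")$se)
  set.seed(102)
  for (rep in 1:10) {
    instr <- mk_instr(rnorm(6, 0.08, 0.02), rnorm(6, 0.02, 0.03))
    expect_gte(mr_ivw(instr, "mre")$se, mr_ivw(instr, "fixed")$se)
  }
  expect_error(mr_ivw(mk_instr(0.1, 0.1)), "wald")
})

test_that("Egger fits an exact line through two equal-weight points", {
  instr <- mk_instr(c(1, 2), c(1, 3), sy = c(1, 1))
  eg <- suppressWarnings(mr_egger(instr))
  expect_equal(eg$estimate$beta, 2, tolerance = 1e-10)
  expect_equal(eg$intercept, -1, tolerance = 1e-10)
})

test_that("Egger slope and intercept match an independent weighted fit", {
  library(metafor)
  set.seed(103)
  s <- mk_instr(abs(rnorm(15, 0.08, 0.02)), rnorm(15, 0.03, 0.03),
                sy = runif(15, 0.01, 0.04))$snps
  # weighted meta-regression of ratios on 1/bx reproduces the Egger fit
  fit <- lm(beta_out ~ beta_exp, data = s, weights = 1 / s$se_out^2)
  eg <- mr_egger(mk_instr(s$beta_exp, s$beta_out, s$se_exp, s$se_out))
  expect_equal(eg$estimate$beta, unname(coef(fit)["beta_exp"]),
               tolerance = 1e-10)
  sm <- summary(fit)
  expect_equal(eg$estimate$se,
               sm$coefficients["beta_exp", "Std. Error"] / min(1, sm$sigma),
               tolerance = 1e-10)
})

test_that("Egger recovers a known directional pleiotropy intercept", {
  set.seed(104)
  hits <- 0
  for (rep in 1:20) {
    n <- 50
    bx_true <- abs(rnorm(n, 0.08, 0.02))
    alpha <- rnorm(n, 0.03, 0.01)   # directional pleiotropy, InSIDE holds
    sx <- rep(0.005, n); sy <- rep(0.01, n)
    instr <- mk_instr(rnorm(n, bx_true, sx),
                      rnorm(n, 0.2 * bx_true + alpha, sy), sx, sy)
    eg <- mr_egger(instr)
    if (abs(eg$intercept - 0.03) <= 2 * eg$intercept_se) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% coverage over 20 replicates
})

test_that("weighted median matches the middle value and a grid-search oracle", {
  # equal weights, ratios {1,2,3}: the middle value
  instr <- mk_instr(c(1, 1, 1), c(1, 2, 3), sx = rep(1e-6, 3))
  expect_equal(mr_weighted_median(instr, n_boot = 200, seed = 1)$beta, 2,
               tolerance = 1e-6)
  # unequal weights: exhaustive cumulative-weight scan written out by hand
  set.seed(105)
  for (rep in 1:5) {
    instr <- mk_instr(abs(rnorm(5, 0.08, 0.03)), rnorm(5, 0.02, 0.03),
                      sx = runif(5, 0.004, 0.01), sy = runif(5, 0.01, 0.04))
    s <- instr$snps
    r <- s$beta_out / s$beta_exp
    v <- s$se_out^2 / s$beta_exp^2 + s$beta_out^2 * s$se_exp^2 / s$beta_exp^4
    o <- order(r)
    rs <- r[o]; ws <- (1 / v)[o] / sum(1 / v)
    # probability assigned to the k-th sorted ratio: weight below it plus
    # half its own; find the bracketing pair around 1/2 and interpolate
    prob <- cumsum(ws) - ws / 2
    k <- max(which(prob < 0.5))
    oracle <- rs[k] + (0.5 - prob[k]) / (prob[k + 1] - prob[k]) *
      (rs[k + 1] - rs[k])
    got <- mr_weighted_median(instr, n_boot = 200, seed = 1)$beta
    expect_equal(got, oracle, tolerance = 1e-10)
    # and it sits between the bracketing order statistics
    expect_gte(got, rs[k])
    expect_lte(got, rs[k + 1])
  }
  expect_error(mr_weighted_median(mk_instr(c(1, 1), c(1, 2))), ">= 3")
  expect_warning(mr_weighted_median(mk_instr(c(1, 1, 1), c(1, 2, 3)),
                                    n_boot = 50, seed = 1), "n_boot")
})

test_that("mode estimators find the dominant ratio cluster", {
  # all ratios identical: both variants return it exactly
  instr <- mk_instr(c(0.05, 0.1, 0.15, 0.2), c(0.05, 0.1, 0.15, 0.2) * 0.7)
  expect_equal(mr_mode(instr, "simple", n_boot = 200, seed = 1)$beta, 0.7,
               tolerance = 1e-3)
  expect_equal(mr_mode(instr, "weighted", n_boot = 200, seed = 1)$beta, 0.7,
               tolerance = 1e-3)
  # 60% of SNPs share ratio 0.3, the rest are dispersed outliers
  set.seed(106)
  n <- 10
  bx <- abs(rnorm(n, 0.1, 0.02))
  ratio <- c(rep(0.3, 6), c(1.2, -0.8, 2.0, -1.5))
  instr2 <- mk_instr(bx, bx * ratio + rnorm(n, 0, 0.001))
  for (v in c("simple", "weighted")) {
    est <- mr_mode(instr2, v, n_boot = 200, seed = 1)$beta
    expect_lt(abs(est - 0.3), 0.1, label = v)
  }
})

test_that("median and mode are invariant to SNP order; seeds fix the SE", {
  set.seed(107)
  instr <- mk_instr(abs(rnorm(8, 0.08, 0.02)), rnorm(8, 0.02, 0.02))
  perm <- instrument_set(instr$snps[sample(8), ], label = "perm")
  a <- mr_weighted_median(instr, n_boot = 300, seed = 9)
  b <- mr_weighted_median(perm, n_boot = 300, seed = 9)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(mr_mode(instr, "weighted", n_boot = 200, seed = 9)$beta,
               mr_mode(perm, "weighted", n_boot = 200, seed = 9)$beta,
               tolerance = 1e-9)
  # bootstrap SE reproducible under the same seed
  expect_identical(a$se, mr_weighted_median(instr, n_boot = 300, seed = 9)$se)
})

test_that("F statistics follow beta^2/se^2 and flag strong instruments", {
  expect_equal(f_statistics(mk_instr(0.1, 0, sx = 0.1))$f$f, 1)
  one <- f_statistics(mk_instr(-0.0471726, 0, sx = 0.008338))
  expect_equal(round(one$f$f, 0), 32)
  for (ep in c("birth", "infancy", "early_childhood", "later_childhood"))
    expect_gt(f_statistics(fixture_instr(ep))$mean_f, 10, label = ep)
})

test_that("Steiger filtering removes reverse-direction SNPs only", {
  # a SNP with far larger outcome z at comparable N is excluded
  instr <- mk_instr(c(0.08, 0.001), c(0.01, 0.30),
                    sx = c(0.008, 0.008), sy = c(0.012, 0.012))
  out <- steiger_filter(instr, n_exp = 30000, n_cases = 15000,
                        n_controls = 27000)
  expect_equal(out$snps$snp_id, "rs001")
  expect_equal(out$excluded$reason, "steiger")
  # borderline SNP agrees with the direct r2 formula on both sides
  st <- attr(out, "steiger")
  z <- c(0.08 / 0.008, 0.001 / 0.008)
  expect_equal(st$r2_exp, z^2 / (z^2 + 30000), tolerance = 1e-12)
  n_eff <- 4 / (1 / 15000 + 1 / 27000)
  zy <- c(0.01, 0.30) / 0.012
  expect_equal(st$r2_out, zy^2 / (zy^2 + n_eff), tolerance = 1e-12)
  expect_error(steiger_filter(instr, n_exp = 30000), "sample sizes")
})

test_that("leave-one-out estimates equal IVW on each reduced set", {
  instr <- fixture_instr("birth")
  lo <- leave_one_out(instr)
  expect_equal(nrow(lo), 7)
  for (i in seq_len(nrow(lo))) {
    sub <- instr$snps[instr$snps$snp_id != lo$omitted[i], ]
    ref <- mr_ivw(sub, "mre")
    expect_equal(lo$beta[i], ref$beta)
    expect_equal(lo$se[i], ref$se)
  }
  # dropping the known outlier moves the birth estimate towards the null
  expect_equal(round(lo$beta[lo$omitted == "rs11187129"], 2), -0.06)
  expect_error(leave_one_out(mk_instr(c(1, 1), c(1, 2))), ">= 3")
})

test_that("Mann-Kendall S matches a brute-force pair count", {
  # strictly increasing: tau = 1
  expect_equal(mann_kendall(1:5)$tau, 1)
  expect_equal(mann_kendall(5:1)$tau, -1)
  set.seed(108)
  for (rep in 1:10) {
    v <- rnorm(8)
    if (rep > 7) v[sample(8, 2)] <- v[1]  # inject ties
    mk <- mann_kendall(v)
    s_brute <- 0
    for (i in 1:7) for (j in (i + 1):8) s_brute <- s_brute + sign(v[j] - v[i])
    expect_equal(mk$s, s_brute)
    expect_equal(mk$tau, s_brute / choose(8, 2))
  }
  # all-equal input: no trend, p = 1
  mk0 <- mann_kendall(rep(2, 5))
  expect_equal(mk0$tau, 0)
  expect_equal(mk0$pval, 1)
  expect_error(mann_kendall(c(1, 2)), "n >= 3")
})

test_that("estimates carry consistent CI and odds-ratio scales", {
  instr <- fixture_instr("infancy")
  est <- mr_ivw(instr)
  expect_equal(est$ci_low, est$beta - 1.96 * est$se)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_low, exp(est$ci_low))
  # duplicated single ratio: IVW returns it exactly
  instr2 <- mk_instr(rep(0.1, 4), rep(0.05, 4))
  expect_equal(mr_ivw(instr2)$beta, 0.5, tolerance = 1e-12)
})
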