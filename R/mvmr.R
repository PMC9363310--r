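#' Assemble multivariable MR instruments
#'
#' Joins a harmonised instrument set with a secondary-exposure summary
#' table (e.g. adult BMI), aligning the secondary effect to the exposure
#' effect allele. SNPs absent from the secondary table are excluded with
#' reason `"not_in_secondary"`; secondary records with incompatible alleles
#' with `"allele_mismatch_secondary"`.
#'
#' @param instr an `instrument_set`.
#' @param secondary a [sumstats] object for the secondary exposure, keyed
#'   by `snp_id`.
#' @return A data frame of class `mvmr_instruments` with columns `snp_id`,
#'   `beta_exp`, `se_exp`, `beta_sec`, `se_sec`, `beta_out`, `se_out`;
#'   exclusions in `attr(, "excluded")`.
#' @export
mvmr_instruments <- function(instr, secondary) {
  stopifnot(inherits(instr, "instrument_set"),
            inherits(secondary, "sumstats"))
  s <- instr$snps
  j <- match(s$snp_id, secondary$snp_id)
  excl <- data.frame(snp_id = character(0), reason = character(0))
  rows <- list()
  for (i in seq_len(nrow(s))) {
    if (is.na(j[i])) {
      excl <- rbind(excl, data.frame(snp_id = s$snp_id[i],
                                     reason = "not_in_secondary"))
      next
    }
    sec <- secondary[j[i], ]
    flip <- NA
    if (sec$effect_allele == s$effect_allele[i] &&
        sec$other_allele == s$other_allele[i]) flip <- FALSE
    else if (sec$effect_allele == s$other_allele[i] &&
             sec$other_allele == s$effect_allele[i]) flip <- TRUE
    else if (!is_palindromic(sec$effect_allele, sec$other_allele)) {
      cea <- unname(COMPLEMENT[sec$effect_allele])
      coa <- unname(COMPLEMENT[sec$other_allele])
      if (cea == s$effect_allele[i] && coa == s$other_allele[i]) flip <- FALSE
      else if (cea == s$other_allele[i] && coa == s$effect_allele[i])
        flip <- TRUE
    }
    if (is.na(flip)) {
      excl <- rbind(excl, data.frame(snp_id = s$snp_id[i],
                                     reason = "allele_mismatch_secondary"))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = s$snp_id[i],
      beta_exp = s$beta_exp[i], se_exp = s$se_exp[i],
      beta_sec = if (flip) -sec$beta else sec$beta, se_sec = sec$se,
      pval_sec = sec$pval,
      beta_out = s$beta_out[i], se_out = s$se_out[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), beta_exp = numeric(0),
               se_exp = numeric(0), beta_sec = numeric(0),
               se_sec = numeric(0), pval_sec = numeric(0),
               beta_out = numeric(0), se_out = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("mvmr_instruments", "data.frame"),
            excluded = excl)
}

check_mvmr <- function(instrs, min_n = 3) {
  instrs <- as.data.frame(instrs)
  need <- c("beta_exp", "se_exp", "beta_sec", "se_sec", "beta_out", "se_out")
  miss <- setdiff(need, names(instrs))
  if (length(miss)) stop("mvmr: missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(instrs) < min_n)
    stop("multivariable MR needs >= ", min_n, " SNPs, got ", nrow(instrs))
  instrs
}

mvmr_result <- function(method, beta, se, n_snp, warning = NULL) {
  structure(list(method = method, beta = beta, se = se,
                 pval = 2 * stats::pnorm(-abs(beta / se)), n_snp = n_snp,
                 or = exp(beta), or_low = exp(beta - 1.96 * se),
                 or_high = exp(beta + 1.96 * se), warning = warning),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("MVMR (%s): beta = %.4g (se %.4g), OR %.2f [%.2f-%.2f], p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$se, x$or, x$or_low, x$or_high, x$pval,
              x$n_snp))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Residual-based multivariable MR
#'
#' Two-step estimate of the direct effect of the primary exposure,
#' conditioning on a secondary exposure: SNP-outcome betas are first
#' regressed on SNP-secondary betas (weighted by `1/se_out^2`, no
#' intercept by default); the residuals — outcome variation not explained
#' by the secondary exposure — are then regressed through the origin on
#' the primary-exposure betas, with the same multiplicative
#' over-dispersion inflation as [mr_ivw()] and a normal p. With all
#' secondary betas zero this reduces exactly to univariable MRE-IVW.
#'
#' @param instrs an `mvmr_instruments` data frame (>= 3 SNPs).
#' @param intercept_step1 include an intercept in the first-step
#'   regression (default `FALSE`, the summary-data MVMR convention).
#' @param collinearity_limit absolute correlation between primary and
#'   secondary betas above which a multicollinearity warning is attached
#'   to the result.
#' @return An `mvmr_result`: `method`, `beta`, `se`, `pval`, `n_snp`, OR
#'   scale, and `warning` (NULL or text).
#' @export
mvmr_residual <- function(instrs, intercept_step1 = FALSE,
                          collinearity_limit = 0.95) {
  s <- check_mvmr(instrs)
  w <- 1 / s$se_out^2
  step1 <- if (all(s$beta_sec == 0)) NULL
    else if (intercept_step1) stats::lm(beta_out ~ beta_sec, data = s,
                                        weights = w)
    else stats::lm(beta_out ~ 0 + beta_sec, data = s, weights = w)
  resid1 <- if (is.null(step1)) s$beta_out else stats::residuals(step1)
  sxx <- sum(s$beta_exp^2 * w)
  beta <- sum(s$beta_exp * resid1 * w) / sxx
  q <- sum(w * (resid1 - beta * s$beta_exp)^2)
  se <- sqrt(1 / sxx) * max(1, sqrt(q / (nrow(s) - 1)))
  warn <- NULL
  if (stats::sd(s$beta_exp) > 0 && stats::sd(s$beta_sec) > 0 &&
      abs(stats::cor(s$beta_exp, s$beta_sec)) > collinearity_limit)
    warn <- sprintf("|cor(beta_exp, beta_sec)| = %.3f: estimates may be unstable",
                    abs(stats::cor(s$beta_exp, s$beta_sec)))
  res <- mvmr_result("residual", beta, se, nrow(s), warn)
  if (!is.null(warn)) warning(warn, call. = FALSE)
  res
}

#' Joint weighted-regression multivariable MR
#'
#' Single weighted multiple regression of SNP-outcome betas on the SNP
#' betas for both exposures, without intercept, weights `1/se_out^2`; the
#' coefficient on the primary exposure is the direct effect. The SE
#' carries the same multiplicative over-dispersion inflation as
#' [mr_ivw()] (residual df n - 2).
#'
#' @param instrs an `mvmr_instruments` data frame (>= 3 SNPs).
#' @return An `mvmr_result` for the primary exposure.
#' @export
mvmr_joint <- function(instrs) {
  s <- check_mvmr(instrs)
  w <- 1 / s$se_out^2
  if (all(s$beta_sec == 0)) {
    # degenerate secondary exposure: the joint fit collapses to the
    # univariable through-origin slope
    uni <- mr_ivw(data.frame(snp_id = s$snp_id, beta_exp = s$beta_exp,
                             se_exp = s$se_exp, beta_out = s$beta_out,
                             se_out = s$se_out), "mre")
    return(mvmr_result("joint", uni$beta, uni$se, nrow(s)))
  }
  X <- cbind(beta_exp = s$beta_exp, beta_sec = s$beta_sec)
  qrx <- qr(sqrt(w) * X)
  if (qrx$rank < 2) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):2]]
    stop("rank-deficient MVMR design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(s$beta_out ~ 0 + X, weights = w)
  sm <- summary(fit)
  beta <- sm$coefficients["Xbeta_exp", "Estimate"]
  se <- sm$coefficients["Xbeta_exp", "Std. Error"] / min(1, sm$sigma)
  mvmr_result("joint", beta, se, nrow(s))
}

#' Restrict instruments by secondary-exposure association
#'
#' Sensitivity analysis complementing MVMR: keep only SNPs whose
#' association with the secondary exposure is weaker than `p_threshold`
#' (default 0.05), so the surviving instrument acts on the primary
#' exposure but shows no detectable effect on the secondary one. SNPs
#' absent from the secondary table are excluded
#' (`"not_in_secondary"`); an empty result is legitimate and signals that
#' every instrument is shared with the secondary exposure.
#'
#' @param instr an `instrument_set`.
#' @param secondary a [sumstats] table for the secondary exposure.
#' @param p_threshold retain SNPs with secondary p strictly greater than
#'   this.
#' @return The restricted `instrument_set` (possibly empty), with
#'   exclusions logged.
#' @export
restrict_by_secondary <- function(instr, secondary, p_threshold = 0.05) {
  stopifnot(inherits(instr, "instrument_set"),
            inherits(secondary, "sumstats"))
  s <- instr$snps
  j <- match(s$snp_id, secondary$snp_id)
  out <- exclude_snps(instr, s$snp_id[is.na(j)], "not_in_secondary")
  s <- out$snps
  j <- match(s$snp_id, secondary$snp_id)
  weak <- secondary$pval[j] > p_threshold
  exclude_snps(out, s$snp_id[!weak], "associated_with_secondary")
}
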