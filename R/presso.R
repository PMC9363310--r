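# Leave-one-out fixed-effect IVW slopes for columns of simulated (or
# observed) beta matrices: slope_(-i) per SNP, vectorised across
# simulations. bx, by are n x m matrices; w a length-n weight vector.
loo_slopes <- function(bx, by, w) {
  sxy <- colSums(bx * by * w)
  sxx <- colSums(bx^2 * w)
  num <- matrix(sxy, nrow(bx), ncol(bx), byrow = TRUE) - bx * by * w
  den <- matrix(sxx, nrow(bx), ncol(bx), byrow = TRUE) - bx^2 * w
  num / den
}

#' MR-PRESSO global pleiotropy test
#'
#' Simulation-based over-dispersion test. The observed statistic is the
#' weighted residual sum of squares of each SNP about its leave-one-out
#' IVW prediction, `RSS = sum_i w_i (by_i - beta_(-i) bx_i)^2` with
#' `w = 1/se_out^2`. Its null distribution is built by `n_sim` parametric
#' simulations of the summary statistics under no pleiotropy
#' (`bx* ~ N(bx, se_exp)`, `by* ~ N(beta_(-i) bx, se_out)`), recomputing
#' the same leave-one-out RSS each time. The p-value uses the +1
#' correction, so it is never exactly zero.
#'
#' @param instr an `instrument_set` with at least four SNPs.
#' @param n_sim number of simulations (>= 1000; default 10,000).
#' @param seed optional integer seed.
#' @return A list of class `presso_global`: `rss_obs`, `global_p`,
#'   `n_sim`, plus the per-SNP observed and simulated residuals reused by
#'   [mr_presso()].
#' @export
presso_global <- function(instr, n_sim = 10000, seed = NULL) {
  s <- get_snps(instr)
  n <- nrow(s)
  if (n < 4) stop("MR-PRESSO is undefined for fewer than 4 SNPs")
  if (n_sim < 1000) stop("n_sim must be >= 1000")
  w <- 1 / s$se_out^2
  b_loo <- drop(loo_slopes(cbind(s$beta_exp), cbind(s$beta_out), w))
  res_obs <- w * (s$beta_out - b_loo * s$beta_exp)^2
  rss_obs <- sum(res_obs)
  sims <- with_seed(seed, {
    bx <- matrix(stats::rnorm(n * n_sim, s$beta_exp, s$se_exp), n)
    by <- matrix(stats::rnorm(n * n_sim, b_loo * s$beta_exp, s$se_out), n)
    slopes <- loo_slopes(bx, by, w)
    w * (by - slopes * bx)^2   # n x n_sim per-SNP simulated residuals
  })
  rss_sim <- colSums(sims)
  structure(list(
    rss_obs = rss_obs,
    global_p = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1),
    n_sim = n_sim,
    res_obs = stats::setNames(res_obs, s$snp_id),
    res_sim = sims), class = "presso_global")
}

#' @export
print.presso_global <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS_obs = %.4g, p %s (%d simulations)\n",
              x$rss_obs,
              if (x$global_p <= 1 / x$n_sim) paste("<", format(1 / x$n_sim))
              else paste("=", format(round(x$global_p, 4))),
              x$n_sim))
  invisible(x)
}

#' MR-PRESSO: global test, outlier test and outlier-corrected estimate
#'
#' Runs the global over-dispersion test, then compares each SNP's observed
#' leave-one-out residual with its own simulated null distribution
#' (Bonferroni-adjusted over SNPs); SNPs with adjusted p below `alpha` are
#' declared outliers and removed, and the corrected causal estimate is the
#' weighted through-origin regression on the remaining SNPs (its p-value
#' from t with n - 1 degrees of freedom, the convention of the original
#' PRESSO implementation). The distortion test compares raw and corrected
#' estimates against a bootstrap of outlier-free estimates.
#'
#' @param instr an `instrument_set` with at least four SNPs.
#' @param n_sim simulations for the global/outlier null (default 10,000).
#' @param seed optional integer seed.
#' @param alpha outlier threshold on the Bonferroni-adjusted per-SNP p
#'   (default 0.05).
#' @param n_boot bootstrap replicates for the distortion test.
#' @return A list of class `mr_presso`: `global` (the
#'   [presso_global()] result, residual matrices dropped), `outlier_p`
#'   (per-SNP adjusted p), `outliers` (character vector), `raw` and
#'   `corrected` (`mr_estimate` rows; `corrected` equals `raw` when no
#'   outlier is found) and `distortion_p` (NA when there is no outlier).
#' @export
#'
#' @examples
#' fx <- bmi_ms_instruments("birth")
#' \donttest{mr_presso(harmonise(fx$exposure, fx$outcome), seed = 1)}
mr_presso <- function(instr, n_sim = 10000, seed = NULL, alpha = 0.05,
                      n_boot = 1000) {
  s <- get_snps(instr)
  n <- nrow(s)
  glob <- presso_global(instr, n_sim, seed)
  exceed <- rowSums(glob$res_sim >= glob$res_obs)
  p_raw <- (1 + exceed) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * n)
  names(p_adj) <- s$snp_id
  outliers <- s$snp_id[p_adj < alpha]
  if (length(outliers) == n)
    stop("every SNP flagged as an outlier; no instruments remain")
  raw <- mr_ivw(instr, "mre")
  keep <- !(s$snp_id %in% outliers)
  corrected <- if (length(outliers))
    presso_corrected(s[keep, , drop = FALSE]) else raw
  distortion_p <- NA_real_
  if (length(outliers)) {
    d_obs <- (corrected$beta - raw$beta) / abs(raw$beta)
    d_null <- with_seed(if (is.null(seed)) NULL else seed + 1, {
      ks <- s[keep, , drop = FALSE]
      wk <- 1 / ks$se_out^2
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nrow(ks), replace = TRUE)
        bb <- sum(ks$beta_exp[i] * ks$beta_out[i] * wk[i]) /
          sum(ks$beta_exp[i]^2 * wk[i])
        (bb - raw$beta) / abs(raw$beta)
      }, 0)
    })
    distortion_p <- mean(abs(d_null) >= abs(d_obs))
  }
  glob$res_sim <- NULL
  structure(list(global = glob, outlier_p = p_adj, outliers = outliers,
                 raw = raw, corrected = corrected,
                 distortion_p = distortion_p, alpha = alpha),
            class = "mr_presso")
}

# Outlier-corrected estimate: weighted through-origin regression with
# t(n-1) p and no floor on the dispersion (plain weighted lm).
presso_corrected <- function(s) {
  w <- 1 / s$se_out^2
  sxx <- sum(s$beta_exp^2 * w)
  beta <- sum(s$beta_exp * s$beta_out * w) / sxx
  nn <- nrow(s)
  sigma2 <- sum(w * (s$beta_out - beta * s$beta_exp)^2) / (nn - 1)
  se <- sqrt(sigma2 / sxx)
  mr_estimate("ivw_corrected", nn, beta, se, df = nn - 1)
}

#' @export
print.mr_presso <- function(x, ...) {
  print(x$global)
  if (length(x$outliers)) {
    cat("outliers (adjusted p <", x$alpha, "):",
        paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("raw beta %.4g (p = %.3g) -> corrected beta %.4g (p = %.3g); distortion p = %.3g\n",
                x$raw$beta, x$raw$pval, x$corrected$beta,
                x$corrected$pval, x$distortion_p))
  } else cat("no outliers detected; corrected estimate equals raw\n")
  invisible(x)
}
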