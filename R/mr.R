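#' @keywords internal
"_PACKAGE"

# Evaluate expr under a temporary seed, leaving the caller's RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# One-row causal-estimate record. p from the normal unless df is given
# (then t with that df). CI fixed at +/- 1.96 se; OR scale is elementwise
# exp. se = NA marks a degenerate fit (e.g. an exact two-point Egger line).
mr_estimate <- function(method, n_snp, beta, se, pval = NULL, df = NULL) {
  stopifnot(is.na(se) || se > 0)
  if (is.null(pval))
    pval <- if (is.na(se)) NA_real_
            else if (is.null(df)) 2 * stats::pnorm(-abs(beta / se))
            else 2 * stats::pt(-abs(beta / se), df)
  out <- data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
                    pval = pval,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se)
  out$or <- exp(out$beta)
  out$or_low <- exp(out$ci_low)
  out$or_high <- exp(out$ci_high)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

get_snps <- function(instr) {
  if (inherits(instr, "instrument_set")) instr$snps
  else as.data.frame(instr)
}

# per-SNP Wald ratios and their delta-method variances
wald_ratios <- function(s, order = 2) {
  r <- s$beta_out / s$beta_exp
  v <- s$se_out^2 / s$beta_exp^2
  if (order == 2) v <- v + s$beta_out^2 * s$se_exp^2 / s$beta_exp^4
  list(ratio = r, var = v)
}

#' Wald ratio estimate
#'
#' Per-SNP causal estimate: the outcome effect divided by the exposure
#' effect, with first-order SE `se_out / |beta_exp|`. Used in place of IVW
#' when a single SNP is available.
#'
#' @param snp a one-row instrument data frame (columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`) or an `instrument_set` with exactly one SNP.
#' @return An `mr_estimate` (one-row data frame).
#' @export
mr_wald_ratio <- function(snp) {
  s <- get_snps(snp)
  if (nrow(s) != 1) stop("mr_wald_ratio expects exactly one SNP")
  if (s$beta_exp == 0) stop("beta_exp is zero; Wald ratio undefined")
  mr_estimate("wald", 1L, s$beta_out / s$beta_exp, s$se_out / abs(s$beta_exp))
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2`:
#' `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`. The fixed-effect SE is
#' `sqrt(1 / sum(bx^2 / sy^2))`; under the multiplicative-random-effects
#' (MRE) model — the primary model here — it is inflated by
#' `max(1, sqrt(Q / (n - 1)))`, so over-dispersion widens the interval but
#' under-dispersion never narrows it. p is two-sided from the standard
#' normal.
#'
#' @param instr an `instrument_set` (or instrument data frame) with at
#'   least two SNPs.
#' @param model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(instr, model = c("mre", "fixed")) {
  model <- match.arg(model)
  s <- get_snps(instr)
  if (nrow(s) < 2)
    stop("IVW needs >= 2 SNPs; use mr_wald_ratio() for a single SNP")
  w <- 1 / s$se_out^2
  sxx <- sum(s$beta_exp^2 * w)
  beta <- sum(s$beta_exp * s$beta_out * w) / sxx
  se <- sqrt(1 / sxx)
  if (model == "mre") {
    q <- sum(w * (s$beta_out - beta * s$beta_exp)^2)
    se <- se * max(1, sqrt(q / (nrow(s) - 1)))
  }
  mr_estimate(paste0("ivw_", model), nrow(s), beta, se)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure betas with a free
#' intercept (weights `1/se_out^2`), after orienting every SNP to a
#' positive exposure effect. The slope is the pleiotropy-adjusted causal
#' estimate; a non-zero intercept indicates directional (unbalanced)
#' horizontal pleiotropy. Slope and intercept SEs carry the multiplicative
#' over-dispersion inflation `max(1, sqrt(Q_egger/(n-2)))` and p-values use
#' t with `n - 2` degrees of freedom.
#'
#' @param instr an `instrument_set` with at least three SNPs for a
#'   meaningful fit (two are accepted and fit exactly).
#' @return A list of class `mr_egger`: `estimate` (an `mr_estimate` for the
#'   slope), `intercept`, `intercept_se`, `intercept_pval`, and the Egger
#'   heterogeneity statistics `q`, `q_df`, `q_pval`.
#' @export
mr_egger <- function(instr) {
  s <- get_snps(instr)
  n <- nrow(s)
  if (n < 2) stop("MR-Egger needs >= 2 SNPs")
  if (n < 3) warning("MR-Egger with 2 SNPs is an exact fit; ",
                     "no residual information")
  flip <- ifelse(s$beta_exp < 0, -1, 1)
  bx <- abs(s$beta_exp)
  by <- s$beta_out * flip
  w <- 1 / s$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  infl <- min(1, sm$sigma)  # dividing by min(1, sigma) floors the inflation
  se_slope <- co["bx", "Std. Error"] / infl
  se_int <- co["(Intercept)", "Std. Error"] / infl
  if (!is.finite(se_slope) || se_slope <= 0) se_slope <- NA_real_
  if (!is.finite(se_int) || se_int <= 0) se_int <- NA_real_
  q <- sum(w * stats::residuals(fit)^2)
  structure(list(
    estimate = mr_estimate("egger", n, co["bx", "Estimate"], se_slope,
                           df = n - 2),
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = se_int,
    intercept_pval = 2 * stats::pt(-abs(co["(Intercept)", "Estimate"] /
                                          se_int), n - 2),
    q = q, q_df = n - 2,
    q_pval = stats::pchisq(q, max(n - 2, 1), lower.tail = FALSE)),
    class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$estimate, ...)
  cat(sprintf("intercept %.4g (se %.4g, p = %.3g); Q = %.3g on %d df\n",
              x$intercept, x$intercept_se, x$intercept_pval, x$q, x$q_df))
  invisible(x)
}

# Interpolated weighted median of x: sort, take cumulative standardised
# weights minus half the own weight, interpolate at probability 1/2.
weighted_median_scan <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The weighted median of the per-SNP Wald ratios, consistent when SNPs
#' contributing at least half the weight are valid instruments. Weights are
#' the inverse second-order (delta-method) Wald-ratio variances
#' `1 / (se_out^2/bx^2 + by^2 se_exp^2 / bx^4)`. The SE comes from a
#' parametric bootstrap: exposure and outcome betas are resampled from
#' normals centred on the observed values and the weighted median
#' recomputed (weights held fixed).
#'
#' @param instr an `instrument_set` with at least three SNPs.
#' @param n_boot bootstrap replicates (default 1000; below 100 draws a
#'   warning).
#' @param seed optional integer seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(instr, n_boot = 1000, seed = NULL) {
  s <- get_snps(instr)
  if (nrow(s) < 3) stop("weighted median needs >= 3 SNPs")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  wr <- wald_ratios(s)
  w <- 1 / wr$var
  beta <- weighted_median_scan(wr$ratio, w)
  se <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(s), s$beta_exp, s$se_exp)
      by <- stats::rnorm(nrow(s), s$beta_out, s$se_out)
      weighted_median_scan(by / bx, w)
    }, 0)
    stats::sd(boots)
  })
  mr_estimate("weighted_median", nrow(s), beta, se)
}

# Kernel-density mode of the Wald ratios with the modified Silverman
# bandwidth of the MBE method, scaled by phi.
ratio_mode <- function(r, w, phi) {
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) / length(r)^(1 / 5)
  h <- max(1e-8, s * phi)
  d <- stats::density(r, weights = w / sum(w), bw = h)
  d$x[which.max(d$y)]
}

#' Mode-based estimate
#'
#' The mode of the smoothed empirical density of per-SNP Wald ratios
#' (normal kernel, modified-Silverman bandwidth scaled by `phi`): the
#' largest cluster of SNPs with the same ratio determines the estimate, so
#' it is consistent when that cluster is made of valid instruments. The
#' `"simple"` variant weighs every ratio equally; the `"weighted"` variant
#' uses inverse delta-method Wald variances. SE by parametric bootstrap as
#' in [mr_weighted_median()]. The bandwidth convention makes the point
#' estimate approximate; treat small differences as within-method noise.
#'
#' @param instr an `instrument_set` with at least three SNPs.
#' @param variant `"simple"` or `"weighted"`.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot,seed bootstrap controls, as in [mr_weighted_median()].
#' @return An `mr_estimate`.
#' @export
mr_mode <- function(instr, variant = c("simple", "weighted"), phi = 1,
                    n_boot = 1000, seed = NULL) {
  variant <- match.arg(variant)
  s <- get_snps(instr)
  if (nrow(s) < 3) stop("mode estimate needs >= 3 SNPs")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable bootstrap SE")
  wr <- wald_ratios(s)
  w <- if (variant == "weighted") 1 / wr$var else rep(1, nrow(s))
  beta <- ratio_mode(wr$ratio, w, phi)
  se <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(s), s$beta_exp, s$se_exp)
      by <- stats::rnorm(nrow(s), s$beta_out, s$se_out)
      ratio_mode(by / bx, w, phi)
    }, 0)
    stats::sd(boots)
  })
  mr_estimate(paste0(variant, "_mode"), nrow(s), beta, se)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (r_i - beta)^2)` over per-SNP Wald ratios `r_i` with
#' first-order weights `w_i = bx_i^2 / se_out_i^2`, referred to chi-square
#' with `n - 1` degrees of freedom (IVW; use `df_adjust = 2` for the Egger
#' residual Q on `n - 2`). Large Q flags per-SNP effect heterogeneity,
#' often a symptom of pleiotropy.
#'
#' @param instr an `instrument_set` with at least two SNPs.
#' @param beta_hat the causal estimate around which residuals are taken;
#'   defaults to the fixed-effect IVW estimate.
#' @param df_adjust subtracted from n to give the df (default 1).
#' @return A list of class `heterogeneity`: `q`, `df`, `pval`.
#' @export
cochran_q <- function(instr, beta_hat = NULL, df_adjust = 1) {
  s <- get_snps(instr)
  if (nrow(s) < 2) stop("Q needs >= 2 SNPs")
  if (is.null(beta_hat)) beta_hat <- mr_ivw(instr, "fixed")$beta
  wr <- wald_ratios(s, order = 1)
  q <- sum((wr$ratio - beta_hat)^2 / wr$var)
  df <- nrow(s) - df_adjust
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' Per-SNP instrument-strength F statistics
#'
#' `F_i = (beta_exp_i / se_exp_i)^2`; a mean F above 10 is the conventional
#' marker of instruments strong enough to avoid weak-instrument bias.
#'
#' @param x an `instrument_set` or a [sumstats] table (then `beta`/`se` are
#'   the exposure columns).
#' @return A list: `f` (data frame `snp_id`, `f`) and `mean_f`.
#' @export
f_statistics <- function(x) {
  if (inherits(x, "instrument_set")) {
    s <- x$snps
    f <- (s$beta_exp / s$se_exp)^2
  } else {
    s <- as.data.frame(x)
    f <- (s$beta / s$se)^2
  }
  list(f = data.frame(snp_id = s$snp_id, f = f), mean_f = mean(f))
}

#' Steiger directionality filter
#'
#' Excludes SNPs that explain more variance in the outcome than in the
#' exposure — such SNPs plausibly act on the exposure *through* the outcome
#' (reverse causation) and violate the exclusion restriction. Variance
#' explained is approximated per side as `r2 = z^2 / (z^2 + N)`, with the
#' binary outcome's N the effective sample size
#' `4 / (1/cases + 1/controls)`.
#'
#' @param instr an `instrument_set`.
#' @param n_exp exposure GWAS sample size.
#' @param n_cases,n_controls outcome GWAS case and control counts.
#' @return The filtered `instrument_set`; removed SNPs are logged with
#'   reason `"steiger"`, and the per-SNP r-squared table is in
#'   `attr(, "steiger")`.
#' @export
steiger_filter <- function(instr, n_exp, n_cases, n_controls) {
  stopifnot(inherits(instr, "instrument_set"))
  if (missing(n_exp) || missing(n_cases) || missing(n_controls) ||
      any(c(n_exp, n_cases, n_controls) <= 0))
    stop("positive exposure and outcome sample sizes are required")
  s <- instr$snps
  n_out <- 4 / (1 / n_cases + 1 / n_controls)
  zx2 <- (s$beta_exp / s$se_exp)^2
  zy2 <- (s$beta_out / s$se_out)^2
  r2_exp <- zx2 / (zx2 + n_exp)
  r2_out <- zy2 / (zy2 + n_out)
  drop <- r2_out > r2_exp
  out <- exclude_snps(instr, s$snp_id[drop], "steiger")
  attr(out, "steiger") <- data.frame(snp_id = s$snp_id, r2_exp = r2_exp,
                                     r2_out = r2_out, excluded = drop)
  out
}

#' Leave-one-out analysis
#'
#' Re-estimates the MRE-IVW effect with each SNP omitted in turn; an
#' estimate that moves materially when one SNP is dropped marks that SNP as
#' an influential (potentially pleiotropic) outlier.
#'
#' @param instr an `instrument_set` with at least three SNPs.
#' @return A data frame of class `mr_loo`: `omitted`, `n_snp`, `beta`,
#'   `se`, `pval`.
#' @export
leave_one_out <- function(instr) {
  s <- get_snps(instr)
  if (nrow(s) < 3) stop("leave-one-out needs >= 3 SNPs")
  rows <- lapply(seq_len(nrow(s)), function(i) {
    est <- mr_ivw(s[-i, , drop = FALSE], "mre")
    data.frame(omitted = s$snp_id[i], n_snp = est$n_snp, beta = est$beta,
               se = est$se, pval = est$pval)
  })
  structure(do.call(rbind, rows), class = c("mr_loo", "data.frame"))
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotone trend in an ordered sequence:
#' `S = sum over i<j of sign(v_j - v_i)` (ties contribute zero),
#' `tau = S / (n(n-1)/2)`, and a two-sided p from the normal approximation
#' with variance `n(n-1)(2n+5)/18` and continuity correction (|S| reduced
#' by 1). Used here to test whether per-time-point MR estimates rise with
#' age.
#'
#' @param values ordered numeric sequence (length >= 3).
#' @return A list of class `mk_trend`: `n`, `s`, `tau`, `pval`.
#' @export
#'
#' @examples
#' mann_kendall(c(1, 2, 3, 5, 4))
mann_kendall <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("Mann-Kendall needs n >= 3")
  if (anyNA(values)) stop("missing values in trend input")
  n <- length(values)
  s <- 0L
  for (i in seq_len(n - 1))
    s <- s + sum(sign(values[(i + 1):n] - values[i]))
  tau <- s / (n * (n - 1) / 2)
  var_s <- n * (n - 1) * (2 * n + 5) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  pval <- if (s == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(n = n, s = as.integer(s), tau = tau, pval = pval),
            class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  cat(sprintf("Mann-Kendall trend: n = %d, S = %d, tau = %.3f, 2-sided p = %.3g\n",
              x$n, x$s, x$tau, x$pval))
  invisible(x)
}
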