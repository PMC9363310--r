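#' Fit the full suite of two-sample MR estimators
#'
#' The central model-fitting function: given a harmonised instrument set it
#' runs the configured estimators and sensitivity statistics and returns a
#' single fitted-model object. With one SNP the Wald ratio is reported in
#' place of everything else; with two SNPs only IVW (and Egger, which is
#' then an exact fit and is skipped by default) are possible; the median
#' and mode estimators need three.
#'
#' @param instr an `instrument_set` from [harmonise()], or a data frame
#'   with columns `snp_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param methods character vector from `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`. Methods whose
#'   SNP-count requirement is not met are silently omitted.
#' @param ivw_model `"mre"` (default) or `"fixed"`; see [mr_ivw()].
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param phi mode bandwidth multiplier.
#' @param seed optional integer seed controlling the bootstraps.
#' @return An object of class `mr_fit` with components `label`,
#'   `estimates` (one row per method: beta, se, p, CI and OR scale),
#'   `heterogeneity` (Cochran's Q about the IVW estimate),
#'   `egger` (the [mr_egger()] fit, when run), `f` (from
#'   [f_statistics()]), and `instruments` (the input set). Methods:
#'   `print`, `summary`, `coef`, `confint`, `residuals`, `plot`.
#' @export
#'
#' @examples
#' fx <- bmi_ms_instruments("infancy")
#' fit <- mr_fit(harmonise(fx$exposure, fx$outcome), seed = 1)
#' fit
#' coef(fit)
mr_fit <- function(instr,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"),
                   ivw_model = c("mre", "fixed"), n_boot = 1000, phi = 1,
                   seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  ivw_model <- match.arg(ivw_model)
  if (!inherits(instr, "instrument_set"))
    instr <- instrument_set(instr)
  n <- nrow(instr$snps)
  if (n == 0) stop("no instruments remain; nothing to fit")
  est <- list()
  egger_fit <- NULL
  het <- NULL
  if (n == 1) {
    est$wald <- mr_wald_ratio(instr)
  } else {
    if ("ivw" %in% methods) est$ivw <- mr_ivw(instr, ivw_model)
    if ("egger" %in% methods && n >= 3) {
      egger_fit <- mr_egger(instr)
      est$egger <- egger_fit$estimate
    }
    if ("weighted_median" %in% methods && n >= 3)
      est$weighted_median <- mr_weighted_median(instr, n_boot, seed = seed)
    if ("simple_mode" %in% methods && n >= 3)
      est$simple_mode <- mr_mode(instr, "simple", phi, n_boot, seed = seed)
    if ("weighted_mode" %in% methods && n >= 3)
      est$weighted_mode <- mr_mode(instr, "weighted", phi, n_boot,
                                   seed = seed)
    het <- cochran_q(instr)
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  structure(list(label = instr$label, estimates = estimates,
                 heterogeneity = het, egger = egger_fit,
                 f = f_statistics(instr), instruments = instr),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit",
      if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", nrow(x$instruments$snps), " SNPs\n", sep = "")
  tab <- x$estimates
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (!is.null(f$heterogeneity))
    cat(sprintf("Heterogeneity: Q = %.4g on %d df, p = %.3g\n",
                f$heterogeneity$q, f$heterogeneity$df,
                f$heterogeneity$pval))
  if (!is.null(f$egger))
    cat(sprintf("Egger intercept: %.4g (se %.4g, p = %.3g)\n",
                f$egger$intercept, f$egger$intercept_se,
                f$egger$intercept_pval))
  cat(sprintf("Mean instrument F: %.1f\n", f$f$mean_f))
  if (nrow(f$instruments$excluded))
    cat("Excluded SNPs:",
        paste(f$instruments$excluded$snp_id, "(",
              f$instruments$excluded$reason, ")", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  out <- cbind(est$beta - z * est$se, est$beta + z * est$se)
  dimnames(out) <- list(est$method,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  s <- object$instruments$snps
  primary <- object$estimates[object$estimates$method %in%
                                c("ivw_mre", "ivw_fixed", "wald"), ][1, ]
  stats::setNames(s$beta_out - primary$beta * s$beta_exp, s$snp_id)
}
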