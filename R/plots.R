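#' Diagnostic plots for an MR fit
#'
#' Base-graphics versions of the standard two-sample MR diagnostics:
#' \describe{
#'   \item{scatter}{per-SNP outcome vs exposure betas with error bars and
#'     one fitted line per estimator (through the origin except Egger).}
#'   \item{forest}{per-SNP Wald ratios with 95% intervals and the summary
#'     estimates below.}
#'   \item{funnel}{per-SNP Wald ratio vs its precision; asymmetry about
#'     the IVW line suggests directional pleiotropy.}
#'   \item{loo}{leave-one-out estimates with the full-set estimate as a
#'     reference line.}
#' }
#'
#' @param x an `mr_fit`.
#' @param type one of `"scatter"`, `"forest"`, `"funnel"`, `"loo"`.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, type = c("scatter", "forest", "funnel", "loo"),
                        ...) {
  type <- match.arg(type)
  s <- x$instruments$snps
  est <- x$estimates
  switch(type,
    scatter = {
      flip <- ifelse(s$beta_exp < 0, -1, 1)
      bx <- abs(s$beta_exp); by <- s$beta_out * flip
      graphics::plot(bx, by, pch = 19,
                     xlim = range(0, bx + s$se_exp),
                     ylim = range(by - 1.96 * s$se_out,
                                  by + 1.96 * s$se_out),
                     xlab = "SNP effect on exposure",
                     ylab = "SNP effect on outcome",
                     main = x$label, ...)
      graphics::segments(bx, by - 1.96 * s$se_out, bx,
                         by + 1.96 * s$se_out, col = "grey60")
      graphics::segments(bx - s$se_exp, by, bx + s$se_exp, by,
                         col = "grey60")
      cols <- stats::setNames(
        grDevices::hcl.colors(nrow(est), "Dark 3"), est$method)
      for (m in est$method) {
        b <- est$beta[est$method == m]
        a <- if (m == "egger") x$egger$intercept else 0
        graphics::abline(a, b, col = cols[[m]], lwd = 2)
      }
      graphics::legend("topleft", legend = est$method, col = cols,
                       lwd = 2, bty = "n", cex = 0.8)
    },
    forest = {
      wr <- wald_ratios(s)
      lab <- c(s$snp_id, paste0("[", est$method, "]"))
      b <- c(wr$ratio, est$beta)
      se <- c(sqrt(wr$var), est$se)
      n <- length(b)
      graphics::plot(b, rev(seq_len(n)), pch = 18,
                     xlim = range(b - 1.96 * se, b + 1.96 * se),
                     yaxt = "n", ylab = "",
                     xlab = "causal estimate (log OR per SD)",
                     main = x$label, ...)
      graphics::axis(2, at = rev(seq_len(n)), labels = lab, las = 1,
                     cex.axis = 0.7)
      graphics::segments(b - 1.96 * se, rev(seq_len(n)), b + 1.96 * se,
                         rev(seq_len(n)))
      graphics::abline(v = 0, lty = 3)
    },
    funnel = {
      wr <- wald_ratios(s)
      prec <- 1 / sqrt(wr$var)
      graphics::plot(wr$ratio, prec, pch = 19,
                     xlab = "Wald ratio", ylab = "precision (1/SE)",
                     main = x$label, ...)
      ivw <- est$beta[grepl("^ivw", est$method)]
      if (length(ivw)) graphics::abline(v = ivw[1], lty = 2)
    },
    loo = {
      lo <- leave_one_out(x$instruments)
      n <- nrow(lo)
      graphics::plot(lo$beta, rev(seq_len(n)), pch = 19,
                     xlim = range(lo$beta - 1.96 * lo$se,
                                  lo$beta + 1.96 * lo$se),
                     yaxt = "n", ylab = "",
                     xlab = "IVW estimate omitting the SNP",
                     main = x$label, ...)
      graphics::axis(2, at = rev(seq_len(n)), labels = lo$omitted,
                     las = 1, cex.axis = 0.7)
      graphics::segments(lo$beta - 1.96 * lo$se, rev(seq_len(n)),
                         lo$beta + 1.96 * lo$se, rev(seq_len(n)))
      full <- est$beta[grepl("^ivw", est$method)]
      if (length(full)) graphics::abline(v = full[1], lty = 2)
      graphics::abline(v = 0, lty = 3)
    })
  invisible(x)
}
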