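#' Define a synthetic two-sample GWAS scenario
#'
#' Generative parameters for simulated exposure/outcome summary statistics
#' under a linear causal model with optional horizontal pleiotropy and,
#' for longitudinal scenarios, correlated per-SNP effects across time
#' points. Defaults mirror the childhood-BMI / MS setting: exposure GWAS
#' of 28,681 individuals, case-control outcome of 14,802 cases and 26,703
#' controls, per-SNP exposure effects of a few percent of an SD.
#'
#' @param n_snp number of instrument SNPs.
#' @param causal_effect true effect of the exposure on the outcome
#'   (log-odds per SD).
#' @param maf_range interval from which effect-allele frequencies are
#'   drawn uniformly.
#' @param exposure_sd SD of the true per-SNP exposure effects (drawn from
#'   a centred normal).
#' @param n_exp exposure GWAS sample size.
#' @param n_cases,n_controls outcome GWAS case/control counts; the
#'   effective outcome size is `4 / (1/n_cases + 1/n_controls)`.
#' @param pleiotropy `"none"`, or `list(type = "balanced", sd = )`, or
#'   `list(type = "directional", mean = , sd = )`: a per-SNP direct effect
#'   on the outcome added to the causal path. The directional mean acts on
#'   the exposure-increasing-allele orientation (the scale on which the
#'   Egger intercept is defined).
#' @param inside_violation correlation in \[-1, 1\] between pleiotropic
#'   effects and true exposure effects (0 satisfies the InSIDE
#'   assumption).
#' @param timepoints optional character vector of time-point labels for
#'   longitudinal simulation.
#' @param timepoint_cor correlation matrix (length(timepoints) square,
#'   positive semi-definite) of per-SNP effects across time points.
#' @param secondary_loading optional scalar: per-SNP effect on a secondary
#'   (adult) exposure as a multiple of the final-time-point effect.
#' @param secondary_effect causal effect of the secondary exposure on the
#'   outcome (used with `secondary_loading`).
#' @param seed integer seed; every simulation from the scenario is fully
#'   reproducible given the seed.
#' @return A validated list of class `synth_scenario`.
#' @export
synth_scenario <- function(n_snp = 50, causal_effect = 0,
                           maf_range = c(0.1, 0.9), exposure_sd = 0.07,
                           n_exp = 28681, n_cases = 14802,
                           n_controls = 26703, pleiotropy = "none",
                           inside_violation = 0, timepoints = NULL,
                           timepoint_cor = NULL, secondary_loading = NULL,
                           secondary_effect = 0, seed = 1) {
  stopifnot(n_snp >= 1, n_exp > 0, n_cases > 0, n_controls > 0,
            exposure_sd > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2],
            abs(inside_violation) <= 1)
  if (identical(pleiotropy, "none")) pleiotropy <- list(type = "none")
  if (!pleiotropy$type %in% c("none", "balanced", "directional"))
    stop("pleiotropy type must be none, balanced or directional")
  if (pleiotropy$type != "none" &&
      (is.null(pleiotropy$sd) || pleiotropy$sd < 0))
    stop("pleiotropy needs a non-negative sd")
  if (pleiotropy$type == "directional" && is.null(pleiotropy$mean))
    stop("directional pleiotropy needs a mean")
  if (!is.null(timepoints)) {
    k <- length(timepoints)
    if (is.null(timepoint_cor)) timepoint_cor <- diag(k)
    timepoint_cor <- as.matrix(timepoint_cor)
    stopifnot(nrow(timepoint_cor) == k, ncol(timepoint_cor) == k)
    if (max(abs(timepoint_cor - t(timepoint_cor))) > 1e-8)
      stop("timepoint correlation matrix must be symmetric")
    if (min(eigen(timepoint_cor, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      stop("timepoint correlation matrix is not positive semi-definite")
  }
  structure(list(n_snp = n_snp, causal_effect = causal_effect,
                 maf_range = maf_range, exposure_sd = exposure_sd,
                 n_exp = n_exp, n_cases = n_cases, n_controls = n_controls,
                 pleiotropy = pleiotropy,
                 inside_violation = inside_violation,
                 timepoints = timepoints, timepoint_cor = timepoint_cor,
                 secondary_loading = secondary_loading,
                 secondary_effect = secondary_effect,
                 seed = as.integer(seed)),
            class = "synth_scenario")
}

# GWAS se of a per-allele effect on a standardised trait
analytic_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

# Directional pleiotropy is defined on the exposure-increasing-allele
# scale (the orientation Egger regression uses), so its mean is carried by
# sign(true effect); balanced pleiotropy is symmetric and unaffected.
draw_pleiotropy <- function(scn, true_x) {
  pl <- scn$pleiotropy
  if (pl$type == "none") return(rep(0, length(true_x)))
  mu <- if (pl$type == "directional") pl$mean else 0
  rho <- scn$inside_violation
  z <- stats::rnorm(length(true_x))
  if (rho != 0 && stats::sd(true_x) > 0) {
    xs <- (true_x - mean(true_x)) / stats::sd(true_x)
    z <- rho * xs + sqrt(1 - rho^2) * z
  }
  mu * ifelse(true_x < 0, -1, 1) + pl$sd * z
}

random_alleles <- function(n) {
  # non-palindromic pairs only, so harmonisation keeps everything
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  i <- sample.int(4, n, replace = TRUE)
  list(ea = pairs[i, 1], oa = pairs[i, 2])
}

sim_table <- function(snp_id, ea, oa, eaf, beta, se, trait, timepoint = NA) {
  sumstats(data.frame(snp_id = snp_id, effect_allele = ea, other_allele = oa,
                      eaf = eaf, beta = beta, se = se,
                      pval = 2 * stats::pnorm(-abs(beta / se)),
                      timepoint = timepoint),
           trait = trait, validate = FALSE)
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws true per-SNP exposure effects, forms true outcome effects
#' `causal_effect * true_x + pleiotropy`, and observes both with normal
#' noise at the analytic GWAS standard errors implied by allele frequency
#' and sample size (`se = 1/sqrt(2 maf (1-maf) n)`, with the effective
#' case-control size on the outcome side). The returned truth record
#' carries every latent quantity.
#'
#' @param scn a [synth_scenario()].
#' @return A list: `exposure` and `outcome` ([sumstats] tables) and
#'   `truth` (data frame of latent values, with the scenario attached as
#'   an attribute).
#' @export
#'
#' @examples
#' sim <- simulate_two_sample(synth_scenario(n_snp = 20,
#'   causal_effect = 0.2, seed = 7))
#' mr_ivw(make_instruments(sim$exposure, sim$outcome))
simulate_two_sample <- function(scn) {
  stopifnot(inherits(scn, "synth_scenario"))
  with_seed(scn$seed, {
    n <- scn$n_snp
    snp_id <- sprintf("rs%06d", seq_len(n))
    al <- random_alleles(n)
    maf <- stats::runif(n, scn$maf_range[1], scn$maf_range[2])
    true_x <- stats::rnorm(n, 0, scn$exposure_sd)
    alpha <- draw_pleiotropy(scn, true_x)
    true_y <- scn$causal_effect * true_x + alpha
    se_x <- analytic_se(maf, scn$n_exp)
    n_out <- 4 / (1 / scn$n_cases + 1 / scn$n_controls)
    se_y <- analytic_se(maf, n_out)
    bx <- stats::rnorm(n, true_x, se_x)
    by <- stats::rnorm(n, true_y, se_y)
    truth <- data.frame(snp_id = snp_id, maf = maf, true_x = true_x,
                        pleiotropy = alpha, true_y = true_y,
                        se_x = se_x, se_y = se_y)
    attr(truth, "scenario") <- scn
    list(exposure = sim_table(snp_id, al$ea, al$oa, maf, bx, se_x,
                              "simulated exposure"),
         outcome = sim_table(snp_id, al$ea, al$oa, maf, by, se_y,
                             "simulated outcome"),
         truth = truth)
  })
}

#' Simulate longitudinal multi-time-point summary statistics
#'
#' Per-SNP true exposure-effect vectors across time points are drawn from
#' a multivariate normal with the scenario's inter-time-point correlation
#' matrix, emulating the shared genetic architecture of a trait measured
#' repeatedly through childhood. The optional secondary (adult) exposure
#' loads on the final time point's effects; the outcome combines a direct
#' effect of the reference (final) time point, the secondary path and any
#' pleiotropy.
#'
#' @param scn a [synth_scenario()] with `timepoints` set.
#' @return A list: `exposure` (named list of per-time-point [sumstats]),
#'   `outcome`, `secondary` (a [sumstats] or NULL), `truth`.
#' @export
simulate_longitudinal <- function(scn) {
  stopifnot(inherits(scn, "synth_scenario"))
  if (is.null(scn$timepoints)) stop("scenario has no timepoints")
  with_seed(scn$seed, {
    n <- scn$n_snp
    k <- length(scn$timepoints)
    snp_id <- sprintf("rs%06d", seq_len(n))
    al <- random_alleles(n)
    maf <- stats::runif(n, scn$maf_range[1], scn$maf_range[2])
    ev <- eigen(scn$timepoint_cor, symmetric = TRUE)
    half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*%
      t(ev$vectors)
    B <- matrix(stats::rnorm(n * k), n, k) %*% half * scn$exposure_sd
    colnames(B) <- scn$timepoints
    ref <- B[, k]
    alpha <- draw_pleiotropy(scn, ref)
    sec <- NULL
    true_sec <- rep(0, n)
    if (!is.null(scn$secondary_loading)) {
      true_sec <- scn$secondary_loading * ref +
        stats::rnorm(n, 0, scn$exposure_sd / 10)
      se_sec <- analytic_se(maf, scn$n_exp)
      sec <- sim_table(snp_id, al$ea, al$oa, maf,
                       stats::rnorm(n, true_sec, se_sec), se_sec,
                       "simulated secondary exposure")
    }
    true_y <- scn$causal_effect * ref + scn$secondary_effect * true_sec +
      alpha
    se_x <- analytic_se(maf, scn$n_exp)
    n_out <- 4 / (1 / scn$n_cases + 1 / scn$n_controls)
    se_y <- analytic_se(maf, n_out)
    exposure <- lapply(seq_len(k), function(j)
      sim_table(snp_id, al$ea, al$oa, maf,
                stats::rnorm(n, B[, j], se_x), se_x,
                "simulated exposure", timepoint = scn$timepoints[j]))
    names(exposure) <- scn$timepoints
    truth <- data.frame(snp_id = snp_id, maf = maf, true_sec = true_sec,
                        pleiotropy = alpha, true_y = true_y)
    truth <- cbind(truth, as.data.frame(B))
    attr(truth, "scenario") <- scn
    list(exposure = exposure,
         outcome = sim_table(snp_id, al$ea, al$oa, maf,
                             stats::rnorm(n, true_y, se_y), se_y,
                             "simulated outcome"),
         secondary = sec, truth = truth)
  })
}

#' Build an instrument set directly from paired summary tables
#'
#' Convenience for simulated (or pre-harmonised) data whose exposure and
#' outcome tables share effect alleles: joins on `snp_id` without any
#' harmonisation step.
#'
#' @param exposure,outcome [sumstats] tables with identical allele coding.
#' @param label set label.
#' @return An `instrument_set`.
#' @export
make_instruments <- function(exposure, outcome, label = "") {
  j <- match(exposure$snp_id, outcome$snp_id)
  keep <- !is.na(j)
  instrument_set(data.frame(
    snp_id = exposure$snp_id[keep],
    effect_allele = exposure$effect_allele[keep],
    other_allele = exposure$other_allele[keep],
    beta_exp = exposure$beta[keep], se_exp = exposure$se[keep],
    pval_exp = exposure$pval[keep], eaf_exp = exposure$eaf[keep],
    beta_out = outcome$beta[j[keep]], se_out = outcome$se[j[keep]],
    pval_out = outcome$pval[j[keep]], eaf_out = outcome$eaf[j[keep]]),
    excluded = data.frame(snp_id = exposure$snp_id[!keep],
                          reason = rep("not_in_outcome", sum(!keep))),
    label = label)
}
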