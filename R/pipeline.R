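#' Assemble an analysis configuration
#'
#' Collects every knob of the end-to-end analysis into one validated
#' object. Inputs may be file paths (delimited summary statistics read via
#' [read_sumstats()]) or in-memory [sumstats] objects, so synthetic and
#' packaged data are interchangeable with real files.
#'
#' @param exposure a [sumstats] table (a `timepoint` column splits it into
#'   analysis units), a named list of tables/paths (one per time point),
#'   or a single file path.
#' @param outcome a [sumstats] table or file path.
#' @param column_map column mapping used for any file paths (see
#'   [read_sumstats()]); defaults to the canonical header.
#' @param epochs named list of epoch definitions used to amalgamate time
#'   points (see [epoch_definitions()]); `NULL` analyses each time point
#'   as its own unit.
#' @param pre_selected if `TRUE`, the exposure tables are already
#'   significance-filtered, clumped and MHC-excluded (as the packaged SNP
#'   lists are) and those stages are skipped.
#' @param p_threshold genome-wide significance threshold.
#' @param ld an [ld_matrix] or path to one; `NULL` skips clumping.
#' @param r2_threshold,window_kb clumping parameters.
#' @param exclude_mhc `"auto"` (apply when chrom/pos are present), `TRUE`
#'   (require positions, error if absent) or `FALSE`.
#' @param palindromic_policy,maf_threshold see [harmonise()].
#' @param estimators methods passed to [mr_fit()].
#' @param n_boot,phi bootstrap size and mode bandwidth for [mr_fit()].
#' @param n_sim MR-PRESSO simulations (PRESSO runs on units with >= 4
#'   SNPs); `0` disables PRESSO.
#' @param steiger `NULL`, or `list(n_exp =, n_cases =, n_controls =)` to
#'   apply [steiger_filter()].
#' @param secondary optional secondary-exposure table or path for
#'   multivariable MR.
#' @param secondary_p_threshold cutoff for [restrict_by_secondary()].
#' @param trend run [mann_kendall()] across the per-unit primary
#'   estimates (default: when there are at least three units).
#' @param seed integer seed governing every stochastic component.
#' @param out_dir if non-NULL, report files are written here.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcome, column_map = canonical_map(),
                            epochs = NULL, pre_selected = FALSE,
                            p_threshold = 5e-8, ld = NULL,
                            r2_threshold = 0.001, window_kb = 10000,
                            exclude_mhc = "auto",
                            palindromic_policy = "strict",
                            maf_threshold = 0.42,
                            estimators = c("ivw", "egger",
                                           "weighted_median", "simple_mode",
                                           "weighted_mode"),
                            n_boot = 1000, phi = 1, n_sim = 10000,
                            steiger = NULL, secondary = NULL,
                            secondary_p_threshold = 0.05, trend = NULL,
                            seed = 1, out_dir = NULL) {
  if (!is.null(steiger)) {
    miss <- setdiff(c("n_exp", "n_cases", "n_controls"), names(steiger))
    if (length(miss)) stop("steiger config needs: ",
                           paste(miss, collapse = ", "))
  }
  if (is.null(seed) && (n_boot > 0 || n_sim > 0))
    stop("a seed is required when bootstrap or PRESSO simulation is enabled")
  structure(list(exposure = exposure, outcome = outcome,
                 column_map = column_map, epochs = epochs,
                 pre_selected = isTRUE(pre_selected),
                 p_threshold = p_threshold, ld = ld,
                 r2_threshold = r2_threshold, window_kb = window_kb,
                 exclude_mhc = exclude_mhc,
                 palindromic_policy = palindromic_policy,
                 maf_threshold = maf_threshold, estimators = estimators,
                 n_boot = n_boot, phi = phi, n_sim = n_sim,
                 steiger = steiger, secondary = secondary,
                 secondary_p_threshold = secondary_p_threshold,
                 trend = trend, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' File keys mirror the arguments of [analysis_config()]; `exposure` may
#' be a mapping of time-point label to file path. Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  for (k in c("outcome", "secondary", "ld"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- resolve(cfg[[k]])
  if (is.character(cfg$exposure)) cfg$exposure <- resolve(cfg$exposure)
  if (is.list(cfg$exposure)) cfg$exposure <- lapply(cfg$exposure, resolve)
  if (!is.null(cfg$column_map)) cfg$column_map <- unlist(cfg$column_map)
  do.call(analysis_config, cfg)
}

load_table <- function(x, column_map, trait = NULL, timepoint = NULL) {
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x) && length(x) == 1)
    return(read_sumstats(x, column_map, trait = trait,
                         timepoint = timepoint))
  stop("expected a sumstats object or a file path")
}

# split a single exposure table into per-unit tables by its timepoint column
split_units <- function(tab) {
  if (all(is.na(tab$timepoint))) return(list(all = tab))
  tps <- unique(tab$timepoint)
  out <- lapply(tps, function(tp) keep_rows(tab, tab$timepoint == tp))
  names(out) <- tps
  out
}

#' Run the full epoch/time-point MR analysis
#'
#' For each analysis unit (age epoch or single time point): instrument
#' selection (significance filter, optional LD clumping and MHC
#' exclusion, unless `pre_selected`), harmonisation, optional Steiger
#' filtering, the configured estimators with heterogeneity, Egger
#' intercept and F statistics, leave-one-out (n >= 3), MR-PRESSO
#' (n >= 4), and optional multivariable MR against a secondary exposure.
#' A Mann-Kendall trend test runs across the per-unit primary estimates
#' when there are at least three units. A unit left with no instruments
#' is reported as empty rather than failing the run: "no SNPs remained"
#' is a legitimate finding. Deterministic given the seed.
#'
#' @param cfg an [analysis_config()].
#' @return An `mr_report`: per-unit results (`fit`, `loo`, `presso`,
#'   `mvmr`, instrument logs), `trend`, and the echoed config. When
#'   `cfg$out_dir` is set, writes `results.tsv` (one row per unit and
#'   method, Table-2 style plus OR columns), `exclusions.tsv`,
#'   `presso.tsv` and `trend.txt` there.
#' @export
run_epoch_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  outcome <- load_table(cfg$outcome, cfg$column_map, trait = "outcome")
  exposure <- cfg$exposure
  if (inherits(exposure, "sumstats")) exposure <- split_units(exposure)
  else if (is.character(exposure) && length(exposure) == 1)
    exposure <- split_units(load_table(exposure, cfg$column_map,
                                       trait = "exposure"))
  else if (is.list(exposure)) {
    if (is.null(names(exposure))) stop("per-time-point exposures must be named")
    exposure <- mapply(function(x, nm) load_table(x, cfg$column_map,
                                                  trait = "exposure",
                                                  timepoint = nm),
                       exposure, names(exposure), SIMPLIFY = FALSE)
  } else stop("unusable exposure input")
  ld <- if (is.character(cfg$ld)) read_ld_matrix(cfg$ld) else cfg$ld

  select <- function(tab) {
    if (cfg$pre_selected) return(tab)
    tab <- filter_genomewide(tab, cfg$p_threshold)
    has_pos <- nrow(tab) == 0 || !any(is.na(tab$chrom) | is.na(tab$pos))
    if (isTRUE(cfg$exclude_mhc) ||
        (identical(cfg$exclude_mhc, "auto") && has_pos))
      tab <- exclude_mhc(tab)
    if (!is.null(ld) && nrow(tab) > 1)
      tab <- clump(tab, ld, cfg$r2_threshold, cfg$window_kb)
    tab
  }

  units <- if (!is.null(cfg$epochs) && length(exposure) > 1) {
    amalgamate_epochs(lapply(exposure, select), cfg$epochs,
                      if (cfg$pre_selected) 1 else cfg$p_threshold)
  } else lapply(exposure, select)

  secondary <- if (!is.null(cfg$secondary))
    load_table(cfg$secondary, cfg$column_map, trait = "secondary")

  results <- list()
  for (u in names(units)) {
    tab <- units[[u]]
    res <- list(label = u, n_input = nrow(tab))
    if (nrow(tab) == 0) {
      res$empty <- TRUE
      res$message <- "no SNPs remained"
      results[[u]] <- res
      next
    }
    instr <- harmonise(tab, outcome, policy = cfg$palindromic_policy,
                       maf_threshold = cfg$maf_threshold, label = u)
    if (!is.null(cfg$steiger))
      instr <- steiger_filter(instr, cfg$steiger$n_exp,
                              cfg$steiger$n_cases, cfg$steiger$n_controls)
    res$instruments <- instr
    n <- nrow(instr$snps)
    if (n == 0) {
      res$empty <- TRUE
      res$message <- "no SNPs remained after harmonisation"
      results[[u]] <- res
      next
    }
    res$empty <- FALSE
    res$fit <- mr_fit(instr, methods = cfg$estimators, n_boot = cfg$n_boot,
                      phi = cfg$phi, seed = cfg$seed)
    if (n >= 3) res$loo <- leave_one_out(instr)
    if (n >= 4 && cfg$n_sim > 0)
      res$presso <- mr_presso(instr, n_sim = cfg$n_sim, seed = cfg$seed)
    if (!is.null(secondary) && n >= 3) {
      mv <- mvmr_instruments(instr, secondary)
      res$mvmr <- list(instruments = mv)
      if (nrow(mv) >= 3) {
        res$mvmr$residual <- mvmr_residual(mv)
        res$mvmr$joint <- mvmr_joint(mv)
      }
      restricted <- restrict_by_secondary(instr, secondary,
                                          cfg$secondary_p_threshold)
      res$mvmr$restricted <- restricted
      if (nrow(restricted$snps) >= 2)
        res$mvmr$restricted_fit <- mr_fit(restricted,
                                          methods = "ivw",
                                          seed = cfg$seed)
    }
    results[[u]] <- res
  }

  primary <- primary_estimates(results)
  do_trend <- if (is.null(cfg$trend)) nrow(primary) >= 3 else
    isTRUE(cfg$trend) && nrow(primary) >= 3
  trend <- if (do_trend) mann_kendall(primary$beta)

  report <- structure(list(units = results, primary = primary,
                           trend = trend, config = cfg,
                           version = as.character(utils::packageVersion("epochmr"))),
                      class = "mr_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# one primary (IVW or Wald) estimate per non-empty unit, in unit order
primary_estimates <- function(results) {
  rows <- lapply(results, function(r) {
    if (isTRUE(r$empty)) return(NULL)
    est <- r$fit$estimates
    pe <- est[est$method %in% c("ivw_mre", "ivw_fixed", "wald"), ][1, ]
    cbind(data.frame(unit = r$label), as.data.frame(pe))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Tabulate every estimate of a report
#'
#' @param report an `mr_report`.
#' @return Data frame with one row per unit and method: `unit`, `method`,
#'   `n_snp`, `beta`, `se`, `pval`, CI and OR columns.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "mr_report"))
  rows <- lapply(report$units, function(r) {
    if (isTRUE(r$empty)) return(NULL)
    cbind(data.frame(unit = r$label), as.data.frame(r$fit$estimates))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report_table(report), file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  excl <- do.call(rbind, lapply(report$units, function(r) {
    if (is.null(r$instruments) || !nrow(r$instruments$excluded)) return(NULL)
    cbind(data.frame(unit = r$label), r$instruments$excluded)
  }))
  if (!is.null(excl))
    utils::write.table(excl, file.path(dir, "exclusions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  pr <- do.call(rbind, lapply(report$units, function(r) {
    if (is.null(r$presso)) return(NULL)
    data.frame(unit = r$label, rss_obs = r$presso$global$rss_obs,
               global_p = r$presso$global$global_p,
               outliers = paste(r$presso$outliers, collapse = ","),
               beta_raw = r$presso$raw$beta,
               beta_corrected = r$presso$corrected$beta,
               pval_corrected = r$presso$corrected$pval,
               distortion_p = r$presso$distortion_p)
  }))
  if (!is.null(pr))
    utils::write.table(pr, file.path(dir, "presso.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$trend)) {
    con <- file(file.path(dir, "trend.txt"), "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report$trend)), con)
  }
  invisible(dir)
}

#' @export
print.mr_report <- function(x, digits = 4, ...) {
  cat("epochmr analysis report (package version ", x$version, ", seed ",
      x$config$seed, ")\n", sep = "")
  if (nrow(x$primary)) {
    tab <- x$primary[c("unit", "method", "n_snp", "beta", "se", "pval",
                       "or", "or_low", "or_high")]
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], signif, digits)
    print(tab, row.names = FALSE)
  }
  empties <- names(Filter(function(r) isTRUE(r$empty), x$units))
  if (length(empties))
    cat("units with no instruments:", paste(empties, collapse = ", "), "\n")
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}
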