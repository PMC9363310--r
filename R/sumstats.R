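#' GWAS summary-statistic tables
#'
#' A `sumstats` object is a data frame with one row per SNP association
#' (per trait and time point), carrying the columns
#' `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`, `trait` and `timepoint`. Exposure betas are on
#' the standardised-trait scale (e.g. SD units of age- and sex-standardised
#' BMI); for a binary outcome the beta is the log odds ratio per copy of the
#' effect allele. `chrom`, `pos`, `eaf` and `n` may be `NA`; operations that
#' require them (e.g. MHC exclusion, Steiger filtering) fail loudly rather
#' than imputing.
#'
#' @param df data frame holding at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`.
#' @param trait trait label applied to rows lacking one.
#' @param validate if `TRUE` (default), rows violating the record invariants
#'   are dropped and reported via the `"rejected"` attribute.
#' @param check_p if `TRUE` (default), warn when a reported p disagrees
#'   with the two-sided normal p implied by `|beta/se|` by more than a
#'   factor of 2. Disable for statistics from conditional or otherwise
#'   non-marginal models, whose p-values legitimately differ from the
#'   marginal beta/SE.
#'
#' @return A `sumstats` object (classed data frame). Rejected rows, if any,
#'   are recorded in `attr(x, "rejected")` as a data frame with a `reason`
#'   column.
#' @export
sumstats <- function(df, trait = NULL, validate = TRUE,
                     check_p = TRUE) {
  stopifnot(is.data.frame(df))
  full <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n", "trait", "timepoint")
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sumstats: missing required columns: ", paste(miss, collapse = ", "))
  for (cc in setdiff(full, names(df))) df[[cc]] <- NA
  df <- df[full]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (cc in c("pos", "eaf", "beta", "se", "pval", "n"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if (!is.null(trait)) df$trait <- ifelse(is.na(df$trait), trait, df$trait)
  df$trait <- as.character(df$trait)
  df$timepoint <- as.character(df$timepoint)
  rejected <- df[0, , drop = FALSE]
  rejected$reason <- character(0)
  if (validate) {
    reason <- validate_records(df)
    bad <- !is.na(reason)
    if (any(bad)) {
      rejected <- df[bad, , drop = FALSE]
      rejected$reason <- reason[bad]
      df <- df[!bad, , drop = FALSE]
    }
    if (check_p) check_pval_consistency(df)
  }
  key <- paste(df$snp_id, df$timepoint, sep = "\r")
  if (anyDuplicated(key))
    stop("sumstats: duplicated snp_id x timepoint: ",
         paste(unique(df$snp_id[duplicated(key)]), collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"), rejected = rejected)
}

BASES <- c("A", "C", "G", "T")

# One reason string per offending row, NA where the row is valid.
validate_records <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  set <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- msg
  }
  set(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  set(!(df$effect_allele %in% BASES), "invalid effect allele")
  set(!(df$other_allele %in% BASES), "invalid other allele")
  set(df$effect_allele == df$other_allele, "alleles not distinct")
  set(is.na(df$beta), "beta not numeric")
  set(is.na(df$se), "se not numeric")
  set(df$se <= 0, "se not positive")
  set(is.na(df$pval), "pval not numeric")
  set(df$pval <= 0 | df$pval > 1, "pval outside (0, 1]")
  set(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")
  reason
}

# |beta/se| should imply a two-sided normal p within a factor of ~2 of the
# reported one; gross disagreement usually signals a mis-mapped column.
# Restricted to p > 1e-12: below that, print rounding of beta/SE moves the
# implied p by more than a factor of 2 on its own.
check_pval_consistency <- function(df, factor = 2) {
  ok <- !is.na(df$beta) & !is.na(df$se) & df$se > 0 & !is.na(df$pval) &
    df$pval > 1e-12
  if (!any(ok)) return(invisible(NULL))
  implied <- 2 * stats::pnorm(-abs(df$beta[ok] / df$se[ok]))
  rat <- pmax(implied / df$pval[ok], df$pval[ok] / pmax(implied, 1e-300))
  off <- which(ok)[rat > factor]
  if (length(off))
    warning("reported p inconsistent with |beta/se| (factor > ", factor,
            ") for: ", paste(utils::head(df$snp_id[off], 5), collapse = ", "),
            if (length(off) > 5) " ..." else "", call. = FALSE)
  invisible(NULL)
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics: ", nrow(x), " SNP records",
      if (!all(is.na(x$trait))) paste0(", trait: ",
        paste(unique(stats::na.omit(x$trait)), collapse = "/")), "\n", sep = "")
  tp <- unique(stats::na.omit(x$timepoint))
  if (length(tp)) cat("time points: ", paste(tp, collapse = ", "), "\n", sep = "")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej))
    cat(nrow(rej), "row(s) rejected at validation\n")
  print(as.data.frame(utils::head(x, 10)), ...)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-delimited (or otherwise delimited) text file with a header row
#' and maps its columns onto the `sumstats` fields. Rows violating the record
#' invariants (non-positive SE, p outside (0, 1], invalid alleles,
#' unparseable numerics) are rejected, not repaired: they are returned in the
#' `"rejected"` attribute together with a per-row reason.
#'
#' @param path path to the delimited text file.
#' @param column_map named character vector mapping `sumstats` field names to
#'   file column names, e.g. `c(snp_id = "SNP", effect_allele = "EA", ...)`.
#'   Fields `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`
#'   are required; `chrom`, `pos`, `eaf`, `n`, `trait`, `timepoint` optional.
#' @param trait,timepoint labels applied to every row (optional; a mapped
#'   column takes precedence).
#' @param sep field delimiter, tab by default.
#'
#' @return A [sumstats] object.
#' @export
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
#'              "rs1\tA\tG\t0.1\t0.02\t5.7e-7"), f)
#' read_sumstats(f, c(snp_id = "SNP", effect_allele = "EA",
#'   other_allele = "OA", beta = "BETA", se = "SE", pval = "P"))
read_sumstats <- function(path, column_map, trait = NULL, timepoint = NULL,
                          sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  column_map <- unlist(column_map)
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(need, names(column_map))
  if (length(miss))
    stop("column_map must map fields: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent))
    stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
  df <- as.data.frame(lapply(column_map, function(cc) raw[[cc]]),
                      stringsAsFactors = FALSE)
  if (!is.null(timepoint) && is.null(df$timepoint)) df$timepoint <- timepoint
  sumstats(df, trait = trait)
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes the canonical header (`snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `trait`, `timepoint`).
#' Numeric fields are written with full precision, so
#' `read_sumstats(write_sumstats(x))` is the identity on records.
#'
#' @param table a [sumstats] object (non-empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) == 0) stop("refusing to write an empty sumstats table")
  out <- as.data.frame(table)
  for (cc in names(out))
    if (is.numeric(out[[cc]]))
      out[[cc]] <- vapply(out[[cc]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17, trim = TRUE,
                                                scientific = NA), "")
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

# column map for the canonical on-disk format
canonical_map <- function() {
  nm <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
          "eaf", "beta", "se", "pval", "n", "trait", "timepoint")
  stats::setNames(nm, nm)
}

#' Childhood-BMI / multiple-sclerosis instrument SNPs
#'
#' The 35 instrument SNP records used in the epoch analysis of standardised
#' childhood BMI (MoBa cohort GWAS, n up to 28,681 children) on multiple
#' sclerosis (IMSGC discovery-stage GWAS, 14,802 cases / 26,703 controls):
#' 8 SNPs for birth--6 weeks, 18 for 3 months--1.5 years, 4 for 2--5 years
#' and 5 for 7--8 years, each with exposure and outcome beta, SE, p and the
#' effect-allele frequency in MoBa. The list is post-selection (already
#' clumped and MHC-filtered, outcome alleles already aligned to the exposure
#' effect allele); chromosome and position are not part of the record.
#' Exposure p-values stem from conditional-and-joint analysis, so the
#' marginal beta/SE consistency check is skipped for them.
#'
#' @param epoch `"birth"`, `"infancy"`, `"early_childhood"`,
#'   `"later_childhood"`, or `"all"`.
#' @return A list with components `exposure` and `outcome`, each a
#'   [sumstats] object keyed by `snp_id` (the epoch label is stored in
#'   `timepoint`).
#' @export
#'
#' @examples
#' fx <- bmi_ms_instruments("birth")
#' nrow(fx$exposure)  # 8
bmi_ms_instruments <- function(epoch = c("all", "birth", "infancy",
                                         "early_childhood",
                                         "later_childhood")) {
  epoch <- match.arg(epoch)
  path <- system.file("extdata", "childhood_bmi_ms_snps.tsv",
                      package = "epochmr", mustWork = TRUE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  if (epoch != "all") {
    raw <- raw[raw$epoch == epoch, , drop = FALSE]
    if (nrow(raw) == 0) stop("unknown epoch: ", epoch)
  }
  common <- raw[c("snp_id", "effect_allele", "other_allele", "eaf")]
  exposure <- sumstats(cbind(common,
    data.frame(beta = raw$beta_exp, se = raw$se_exp, pval = raw$pval_exp,
               timepoint = raw$epoch)),
    trait = "childhood BMI (standardised)", check_p = FALSE)
  outcome <- cbind(common,
    data.frame(beta = raw$beta_out, se = raw$se_out, pval = raw$pval_out,
               timepoint = raw$epoch))
  # the same SNP recurs across epochs with identical outcome statistics
  outcome <- outcome[!duplicated(outcome$snp_id), , drop = FALSE]
  outcome$timepoint <- NA
  outcome <- sumstats(outcome, trait = "multiple sclerosis")

  list(exposure = exposure, outcome = outcome)
}
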