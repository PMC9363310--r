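COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so the strand of the
#' reporting GWAS cannot be resolved from the alleles alone and the effect
#' direction may silently be wrong after harmonisation.
#'
#' @param effect_allele,other_allele single bases (A/C/G/T), distinct.
#' @return Logical (vectorised).
#' @export
#'
#' @examples
#' is_palindromic("C", "G")  # TRUE
#' is_palindromic("A", "G")  # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  bad <- !(effect_allele %in% BASES) | !(other_allele %in% BASES) |
    effect_allele == other_allele
  if (any(bad)) stop("invalid allele pair: ",
                     paste(effect_allele[bad], other_allele[bad],
                           sep = "/", collapse = ", "))
  unname(COMPLEMENT[effect_allele] == other_allele)
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns each outcome record to the exposure effect allele and applies the
#' palindromic-SNP policy, producing an `instrument_set` ready for MR
#' estimation. Exposure SNPs absent from the outcome are excluded with
#' reason `"not_in_outcome"`; outcome records whose alleles match only after
#' swapping have their beta sign flipped and EAF replaced by 1 - EAF
#' (`flipped = TRUE`); alleles that match only after strand complementation
#' are accepted unflipped (complement-then-swap flips); anything else is
#' excluded as `"allele_mismatch"`.
#'
#' Palindromic policies:
#' \describe{
#'   \item{`"strict"` (default)}{every A/T and C/G SNP is excluded. This is
#'     the policy that yields the 7/18/4/4 instrument counts from the
#'     packaged 8/18/4/5 SNP lists.}
#'   \item{`"maf_threshold"`}{a palindromic SNP is excluded only when its
#'     inferred minor-allele frequency exceeds `maf_threshold` (default
#'     0.42) on either side, or when frequency is missing; near-0.5
#'     frequencies leave the strand genuinely ambiguous.}
#' }
#'
#' @param exposure,outcome [sumstats] objects keyed by `snp_id` (one record
#'   per SNP).
#' @param policy `"strict"` or `"maf_threshold"`.
#' @param maf_threshold MAF cutoff for the `"maf_threshold"` policy.
#' @param label label for the resulting instrument set (defaults to the
#'   exposure's time point, if unique).
#' @return An `instrument_set`: list with `label`, `snps` (data frame of
#'   retained SNPs: `snp_id`, `beta_exp`, `se_exp`, `pval_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `pval_out`, `eaf_out`, `palindromic`, `flipped`)
#'   and `excluded` (data frame `snp_id`, `reason`).
#' @export
#'
#' @examples
#' fx <- bmi_ms_instruments("birth")
#' harmonise(fx$exposure, fx$outcome)  # 7 of 8 retained
harmonise <- function(exposure, outcome,
                      policy = c("strict", "maf_threshold"),
                      maf_threshold = 0.42, label = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id))
    stop("harmonise expects one record per snp_id on each side")
  if (!length(intersect(exposure$snp_id, outcome$snp_id)))
    stop("exposure and outcome share no SNPs")
  if (is.null(label)) {
    tp <- unique(stats::na.omit(exposure$timepoint))
    label <- if (length(tp) == 1) tp else ""
  }
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, ]
    j <- match(e$snp_id, outcome$snp_id)
    if (is.na(j)) {
      rows[[i]] <- harmonised_row(e, NULL, excluded = "not_in_outcome")
      next
    }
    rows[[i]] <- harmonise_pair(e, outcome[j, ], policy, maf_threshold)
  }
  all <- do.call(rbind, rows)
  instrument_set(all[!all$excluded, setdiff(names(all),
                                            c("excluded", "reason"))],
                 excluded = data.frame(snp_id = all$snp_id[all$excluded],
                                       reason = all$reason[all$excluded]),
                 label = label)
}

harmonised_row <- function(e, o, excluded = NA_character_,
                           flipped = FALSE, pal = NA) {
  data.frame(
    snp_id = e$snp_id,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf_exp = e$eaf,
    beta_out = if (is.null(o)) NA_real_ else o$beta,
    se_out = if (is.null(o)) NA_real_ else o$se,
    pval_out = if (is.null(o)) NA_real_ else o$pval,
    eaf_out = if (is.null(o)) NA_real_ else o$eaf,
    palindromic = if (is.null(o)) NA else pal,
    flipped = flipped,
    excluded = !is.na(excluded), reason = excluded,
    timepoint = e$timepoint,
    stringsAsFactors = FALSE)
}

# Align one outcome record to the exposure effect allele.
harmonise_pair <- function(e, o, policy, maf_threshold) {
  if (e$snp_id != o$snp_id) stop("snp_id mismatch: ", e$snp_id, " vs ",
                                 o$snp_id)
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  ea <- e$effect_allele; oa <- e$other_allele
  flip <- NA  # NA = incompatible
  if (o$effect_allele == ea && o$other_allele == oa) flip <- FALSE
  else if (o$effect_allele == oa && o$other_allele == ea) flip <- TRUE
  else if (!pal) {
    cea <- unname(COMPLEMENT[o$effect_allele])
    coa <- unname(COMPLEMENT[o$other_allele])
    if (cea == ea && coa == oa) flip <- FALSE
    else if (cea == oa && coa == ea) flip <- TRUE
  }
  if (is.na(flip)) return(harmonised_row(e, o, excluded = "allele_mismatch",
                                         pal = pal))
  if (isTRUE(flip)) {
    o$beta <- -o$beta
    if (!is.na(o$eaf)) o$eaf <- 1 - o$eaf
  }
  if (pal) {
    drop <- if (policy == "strict") TRUE else {
      mafs <- c(e$eaf, o$eaf)
      mafs <- pmin(mafs, 1 - mafs)
      if (all(is.na(mafs))) TRUE else any(mafs > maf_threshold, na.rm = TRUE)
    }
    if (drop) return(harmonised_row(e, o, excluded = "palindromic",
                                    flipped = flip, pal = pal))
  }
  harmonised_row(e, o, flipped = flip, pal = pal)
}

#' Construct an instrument set
#'
#' The unit of all MR estimation: the harmonised, retained SNPs for one
#' epoch or time point, plus the exclusion log.
#'
#' @param snps data frame with at least `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (SEs positive, snp_ids unique).
#' @param excluded data frame (`snp_id`, `reason`), possibly empty.
#' @param label text label.
#' @return An `instrument_set` object.
#' @export
instrument_set <- function(snps, excluded = NULL, label = "") {
  snps <- as.data.frame(snps)
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("instrument_set: missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp_id)) stop("instrument_set: duplicated snp_id")
  if (nrow(snps) && (any(snps$se_exp <= 0) || any(snps$se_out <= 0)))
    stop("instrument_set: SEs must be positive")
  if (is.null(excluded))
    excluded <- data.frame(snp_id = character(0), reason = character(0))
  if (nrow(excluded) && any(is.na(excluded$reason) | excluded$reason == ""))
    stop("every excluded SNP needs a reason")
  rownames(snps) <- NULL
  structure(list(label = label, snps = snps, excluded = excluded),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set", if (nzchar(x$label)) paste0("'", x$label, "'"),
      ": ", nrow(x$snps), " SNPs retained, ", nrow(x$excluded),
      " excluded\n", sep = "")
  if (nrow(x$excluded))
    cat("exclusions: ",
        paste(x$excluded$snp_id, " (", x$excluded$reason, ")",
              sep = "", collapse = ", "), "\n", sep = "")
  print(utils::head(x$snps, 10), ...)
  if (nrow(x$snps) > 10) cat("... and", nrow(x$snps) - 10, "more SNPs\n")
  invisible(x)
}

#' @export
length.instrument_set <- function(x) nrow(x$snps)

# drop SNPs from a set, logging the reason
exclude_snps <- function(instr, ids, reason) {
  stopifnot(inherits(instr, "instrument_set"))
  hit <- instr$snps$snp_id %in% ids
  if (!any(hit)) return(instr)
  instr$excluded <- rbind(instr$excluded,
                          data.frame(snp_id = instr$snps$snp_id[hit],
                                     reason = reason))
  instr$snps <- instr$snps[!hit, , drop = FALSE]
  rownames(instr$snps) <- NULL
  instr
}

#' Write an exclusion audit log
#'
#' @param instr an `instrument_set`.
#' @param path output path for a tab-delimited log (`snp_id`, `reason`,
#'   `action`).
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(instr, path) {
  stopifnot(inherits(instr, "instrument_set"))
  log <- rbind(
    if (nrow(instr$snps))
      data.frame(snp_id = instr$snps$snp_id, reason = "", action = "retained"),
    if (nrow(instr$excluded))
      data.frame(snp_id = instr$excluded$snp_id,
                 reason = instr$excluded$reason, action = "excluded"))
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
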