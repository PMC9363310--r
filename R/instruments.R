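#' Default age-epoch definitions
#'
#' The twelve childhood time points (birth to 8 years) amalgamated into four
#' non-overlapping age epochs chosen to follow the shared genetics of BMI
#' across childhood: birth (birth--6 weeks), infancy (3 months--1.5 years),
#' early childhood (2--5 years) and later childhood (7--8 years).
#'
#' @return Named list mapping epoch label to the ordered character vector of
#'   its time-point labels.
#' @export
epoch_definitions <- function() {
  list(
    birth           = c("birth", "6wk"),
    infancy         = c("3mo", "6mo", "8mo", "1y", "1.5y"),
    early_childhood = c("2y", "3y", "5y"),
    later_childhood = c("7y", "8y")
  )
}

check_epochs <- function(epochs) {
  stopifnot(is.list(epochs), length(epochs) > 0, !is.null(names(epochs)))
  if (any(!vapply(epochs, length, 1L)))
    stop("every epoch needs at least one time point")
  tps <- unlist(epochs, use.names = FALSE)
  if (anyDuplicated(tps))
    stop("time point assigned to more than one epoch: ",
         paste(unique(tps[duplicated(tps)]), collapse = ", "))
  invisible(epochs)
}

#' Retain genome-wide significant associations
#'
#' Keeps records with `pval` strictly below the threshold (conventionally
#' 5e-8), preserving input order. A record with p exactly at the threshold
#' is dropped.
#'
#' @param table a [sumstats] object.
#' @param threshold significance threshold in (0, 1).
#' @return The filtered [sumstats] object (possibly empty).
#' @export
filter_genomewide <- function(table, threshold = 5e-8) {
  stopifnot(inherits(table, "sumstats"),
            is.numeric(threshold), threshold > 0, threshold < 1)
  keep_rows(table, table$pval < threshold)
}

# subset a sumstats without re-validating
keep_rows <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            rejected = attr(table, "rejected"))
}

#' Exclude SNPs in the MHC region
#'
#' Removes records inside the extended major histocompatibility complex,
#' by default chr6:25,000,000--35,000,000 (hg19, 1-based, both ends
#' inclusive). The region's long-range LD and very strong MS associations
#' make its variants unusable as BMI instruments.
#'
#' @param table a [sumstats] object whose records carry `chrom` and `pos`.
#' @param chrom,start,end the region to excise.
#' @return The filtered table; removed SNP ids are in
#'   `attr(, "mhc_removed")`.
#' @export
exclude_mhc <- function(table, chrom = "6", start = 25e6, end = 35e6) {
  stopifnot(inherits(table, "sumstats"))
  missing_pos <- is.na(table$chrom) | is.na(table$pos)
  if (any(missing_pos))
    stop("chrom/pos required for MHC exclusion; missing for: ",
         paste(utils::head(table$snp_id[missing_pos], 5), collapse = ", "))
  chrom <- sub("^chr", "", chrom)
  hit <- table$chrom == chrom & table$pos >= start & table$pos <= end
  out <- keep_rows(table, !hit)
  attr(out, "mhc_removed") <- table$snp_id[hit]
  out
}

#' Read an LD matrix from a delimited file
#'
#' Expects a square matrix of pairwise r-squared values with rsIDs as both
#' header row and first column.
#'
#' @param path file path.
#' @param sep delimiter.
#' @return An `ld_matrix`: a numeric matrix with dimnames, validated for
#'   symmetry, unit diagonal and values in \[0, 1\].
#' @export
read_ld_matrix <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1, check.names = FALSE))
  ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param m square numeric matrix of r-squared values, dimnames = rsIDs.
#' @export
ld_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("LD matrix needs rsID dimnames")
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row/column names differ")
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix is not symmetric")
  if (any(m < 0 | m > 1)) stop("LD r-squared values must lie in [0, 1]")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  structure(m, class = c("ld_matrix", class(m)))
}

#' Greedy LD clumping
#'
#' PLINK-style clumping on summary statistics: repeatedly take the remaining
#' record with the smallest p value as index SNP and discard all remaining
#' records with r-squared above `r2_threshold` to it that lie within
#' `window_kb` of its position. Ties on p are broken by smaller SE, then
#' lexicographic rsID, so the result is deterministic. SNPs on different
#' chromosomes are never within the window; when positions are absent the
#' window is treated as satisfied and LD alone decides.
#'
#' @param table a [sumstats] object.
#' @param ld an [ld_matrix] covering the records (see `allow_missing`).
#' @param r2_threshold LD r-squared above which two SNPs are dependent
#'   (default 0.001).
#' @param window_kb clumping window in kilobases (default 10,000).
#' @param allow_missing if `TRUE`, SNPs absent from `ld` are treated as
#'   unlinked; the default is an error, since silently retaining them would
#'   inflate the instrument.
#' @return The clumped [sumstats]; discarded ids and their index SNP are in
#'   `attr(, "clumped_out")`.
#' @export
clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000,
                  allow_missing = FALSE) {
  stopifnot(inherits(table, "sumstats"))
  ld <- ld_matrix(unclass(ld))
  absent <- setdiff(table$snp_id, rownames(ld))
  if (length(absent) && !allow_missing)
    stop("SNP(s) absent from LD matrix (set allow_missing = TRUE to treat ",
         "as unlinked): ", paste(utils::head(absent, 5), collapse = ", "))
  n <- nrow(table)
  ord <- order(table$pval, table$se, table$snp_id)
  alive <- rep(TRUE, n)
  kept <- logical(n)
  out_log <- data.frame(snp_id = character(0), index = character(0))
  r2_of <- function(i, j) {
    a <- table$snp_id[i]; b <- table$snp_id[j]
    if (!(a %in% rownames(ld)) || !(b %in% rownames(ld))) return(0)
    ld[a, b]
  }
  in_window <- function(i, j) {
    if (is.na(table$chrom[i]) || is.na(table$chrom[j]) ||
        is.na(table$pos[i]) || is.na(table$pos[j])) return(TRUE)
    table$chrom[i] == table$chrom[j] &&
      abs(table$pos[i] - table$pos[j]) <= window_kb * 1000
  }
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (r2_of(i, j) > r2_threshold && in_window(i, j)) {
        alive[j] <- FALSE
        out_log <- rbind(out_log, data.frame(snp_id = table$snp_id[j],
                                             index = table$snp_id[i]))
      }
    }
  }
  out <- keep_rows(table, kept)
  attr(out, "clumped_out") <- out_log
  out
}

#' Amalgamate per-time-point statistics into age epochs
#'
#' Within each epoch, a SNP significant at more than one member time point
#' contributes the statistics of its most strongly associated time point
#' (smallest p; ties broken by smaller SE, then by the epoch's time-point
#' order). SNPs reaching significance at no time point of an epoch are
#' absent from that epoch's table.
#'
#' @param tables named list of [sumstats] objects, one per time point; names
#'   must be covered by `epochs`.
#' @param epochs named list mapping epoch labels to time-point labels, as
#'   from [epoch_definitions()]; time points must be pairwise disjoint.
#' @param threshold significance threshold applied per time point
#'   (default 5e-8).
#' @return Named list of per-epoch [sumstats] objects.
#' @export
amalgamate_epochs <- function(tables, epochs = epoch_definitions(),
                              threshold = 5e-8) {
  check_epochs(epochs)
  stopifnot(is.list(tables), !is.null(names(tables)))
  stray <- setdiff(names(tables), unlist(epochs))
  if (length(stray))
    stop("time point(s) not covered by any epoch: ",
         paste(stray, collapse = ", "))
  out <- list()
  for (ep in names(epochs)) {
    member <- intersect(epochs[[ep]], names(tables))
    if (!length(member)) next
    pooled <- do.call(rbind, lapply(member, function(tp) {
      # threshold >= 1 means the tables are already selection-filtered
      x <- if (threshold < 1)
        as.data.frame(filter_genomewide(tables[[tp]], threshold))
      else as.data.frame(tables[[tp]])
      if (nrow(x)) x$timepoint <- tp
      x
    }))
    if (is.null(pooled) || nrow(pooled) == 0) {
      out[[ep]] <- keep_rows(tables[[member[1]]], FALSE)
      next
    }
    tp_rank <- match(pooled$timepoint, epochs[[ep]])
    pooled <- pooled[order(pooled$snp_id, pooled$pval, pooled$se, tp_rank), ]
    pooled <- pooled[!duplicated(pooled$snp_id), , drop = FALSE]
    rownames(pooled) <- NULL
    out[[ep]] <- structure(pooled, class = c("sumstats", "data.frame"))
  }
  out
}
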