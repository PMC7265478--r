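# Reporting: proportions of mapped unique reads, comparison against a target
# composition, qualitative presence calls and concordance with a reference
# method.

#' Per-category proportions of mapped unique reads
#'
#' The denominator is the total of per-category unique-read counts; discarded
#' and unmapped reads are excluded. Rows are sorted by mapped reads,
#' descending (stable for ties). Percentages are rounded half-up to 2
#' decimals at presentation; the unrounded values are kept in the
#' `proportion_raw` attribute and sum to exactly 100 whenever the denominator
#' is positive.
#'
#' @param counts a [category_counts()] object, or a named numeric vector of
#'   per-category counts.
#' @param keep_zero keep categories with zero mapped reads (default FALSE).
#' @return a data frame of class `identification_result` with columns
#'   `category`, `reads_mapped`, `proportion_pct`, plus attributes
#'   `denominator` and `proportion_raw`.
#' @export
compute_proportions <- function(counts, keep_zero = FALSE) {
  if (inherits(counts, "category_counts")) counts <- counts$counts
  stopifnot(length(counts) == 0L || !is.null(names(counts)))
  counts <- counts[if (keep_zero) TRUE else counts > 0]
  denom <- sum(counts)
  ord <- order(-as.numeric(counts))
  counts <- counts[ord]
  raw <- if (denom > 0) as.numeric(counts) / denom * 100 else
    rep(NA_real_, length(counts))
  res <- data.frame(
    category = names(counts),
    reads_mapped = as.integer(counts),
    proportion_pct = round_half_up(raw, 2L),
    stringsAsFactors = FALSE
  )
  attr(res, "denominator") <- denom
  attr(res, "proportion_raw") <- stats::setNames(raw, names(counts))
  class(res) <- c("identification_result", "data.frame")
  res
}

#' Target composition from DNA concentrations
#'
#' Converts per-category DNA concentrations (ng/uL) into target percentages:
#' `conc / sum(conc) * 100`, rounded half-up to 2 decimals.
#'
#' @param conc named non-negative numeric vector, sum > 0.
#' @return named numeric vector of percentages.
#' @export
target_from_concentrations <- function(conc) {
  stopifnot(!is.null(names(conc)), all(conc >= 0))
  s <- sum(conc)
  if (s <= 0) stop("all concentrations are zero")
  round_half_up(conc / s * 100, 2L)
}

#' Compare measured proportions to a target composition
#'
#' One row per category present in either input, missing side treated as 0.
#' `diff_abs_pct = |target - measured|`; `diff_rel_pct = diff_abs / target *
#' 100`, undefined (NA) when the target is 0. Rounded half-up to 2 decimals.
#'
#' @param result an `identification_result` (its rounded `proportion_pct`
#'   column is used, matching how such tables are printed), or a named
#'   numeric vector of measured percentages.
#' @param target named numeric vector of target percentages.
#' @return data frame with columns `category`, `target_pct`, `measured_pct`,
#'   `diff_abs_pct`, `diff_rel_pct`.
#' @export
compare_to_target <- function(result, target) {
  measured <- if (inherits(result, "identification_result")) {
    stats::setNames(result$proportion_pct, result$category)
  } else {
    stopifnot(!is.null(names(result)))
    result
  }
  cats <- c(names(measured), setdiff(names(target), names(measured)))
  m <- ifelse(cats %in% names(measured), measured[cats], 0)
  t <- ifelse(cats %in% names(target), target[cats], 0)
  diff_abs <- abs(t - m)
  diff_rel <- ifelse(t > 0, diff_abs / t * 100, NA_real_)
  data.frame(
    category = cats,
    target_pct = unname(t),
    measured_pct = unname(m),
    diff_abs_pct = round_half_up(unname(diff_abs), 2L),
    diff_rel_pct = round_half_up(unname(diff_rel), 2L),
    stringsAsFactors = FALSE
  )
}

#' Qualitative presence calls
#'
#' A category is called present (`"+"`) iff its proportion of mapped unique
#' reads is at least `threshold_pct`; categories absent from the result (or
#' below threshold) are `"-"`. The default threshold of 0.5% separates
#' conserved-region false positives at the ~0.1% level from true ~1%
#' components; the method is qualitative, not quantitative.
#'
#' @param result an `identification_result`.
#' @param threshold_pct call threshold in percent (default 0.5).
#' @param sample_id sample identifier recorded in each call.
#' @param categories optional extra category names to include (called `"-"`
#'   unless present above threshold).
#' @return data frame with columns `sample_id`, `category`, `call`,
#'   `threshold_pct`.
#' @export
call_presence <- function(result, threshold_pct = 0.5, sample_id = "sample",
                          categories = NULL) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  prop <- stats::setNames(result$proportion_pct, result$category)
  cats <- c(result$category, setdiff(categories, result$category))
  p <- ifelse(cats %in% names(prop), prop[cats], 0)
  data.frame(
    sample_id = sample_id,
    category = cats,
    call = ifelse(p >= threshold_pct, "+", "-"),
    threshold_pct = threshold_pct,
    stringsAsFactors = FALSE
  )
}

#' Concordance of presence calls against a reference method
#'
#' Per (sample, category) pair: TP when both methods call `+`, FP when only
#' the test method does, FN when only the reference does, TN otherwise.
#' Rates: `tpr = tp/(tp+fn)*100`, `fpr = fp/(fp+tn)*100`,
#' `fnr = fn/(tp+fn)*100`; a rate whose denominator is zero is reported as
#' NA (documented convention for degenerate inputs). Both call sets must
#' cover the same (sample, category) universe.
#'
#' @param test_calls,ref_calls data frames as produced by [call_presence()]
#'   (columns `sample_id`, `category`, `call`).
#' @return list of class `concordance_result` with counts `tp`, `fp`, `fn`,
#'   `tn` and rates `tpr`, `fpr`, `fnr` (percent, 2 decimals).
#' @export
compute_concordance <- function(test_calls, ref_calls) {
  key <- function(x) paste(x$sample_id, x$category, sep = "\r")
  kt <- key(test_calls)
  kr <- key(ref_calls)
  if (anyDuplicated(kt) || anyDuplicated(kr)) {
    stop("duplicated (sample, category) pair in calls")
  }
  if (!setequal(kt, kr)) {
    stop("test and reference calls cover different (sample, category) universes")
  }
  r <- ref_calls$call[match(kt, kr)]
  t <- test_calls$call
  tp <- sum(t == "+" & r == "+")
  fp <- sum(t == "+" & r == "-")
  fn <- sum(t == "-" & r == "+")
  tn <- sum(t == "-" & r == "-")
  rate <- function(num, den) {
    if (den == 0L) NA_real_ else round_half_up(num / den * 100, 2L)
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         tpr = rate(tp, tp + fn), fpr = rate(fp, fp + tn),
         fnr = rate(fn, tp + fn)),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Concordance: TP", x$tp, "FP", x$fp, "FN", x$fn, "TN", x$tn, "\n")
  cat("  TPR", x$tpr, "% FPR", x$fpr, "% FNR", x$fnr, "%\n")
  invisible(x)
}

#' Mean depth of coverage
#'
#' Plain fold-coverage: total aligned bases divided by the region length.
#'
#' @param total_aligned_bases total aligned bases.
#' @param region_length region length in bp, > 0.
#' @return fold coverage (numeric).
#' @export
mean_depth <- function(total_aligned_bases, region_length) {
  stopifnot(all(total_aligned_bases >= 0))
  if (any(region_length <= 0)) stop("region length must be positive")
  total_aligned_bases / region_length
}

#' Write a result table as CSV
#'
#' RFC-4180 CSV with a header row, UTF-8, stable column order; percentage
#' columns are written at their 2-decimal presentation values. Accepts an
#' `identification_result`, a comparison table, presence calls, or a
#' `concordance_result` (written as a one-row table).
#'
#' @param x the object to write.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "concordance_result")) {
    x <- data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
                    tpr = x$tpr, fpr = x$fpr, fnr = x$fnr)
  }
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
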