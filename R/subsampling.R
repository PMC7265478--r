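# Seeded FASTQ subsampling and the throughput/precision (RSD) study.

#' Randomly subsample a FASTQ file
#'
#' Two modes: `"exact"` (default) selects exactly `floor(N * ratio)` reads
#' without replacement; `"bernoulli"` keeps each read independently with
#' probability `ratio`. Original read order is preserved and the same seed
#' always reproduces the same selection.
#'
#' @param infile input FASTQ (plain or gzip).
#' @param ratio fraction of reads to keep, in (0, 1].
#' @param seed integer seed.
#' @param outfile output FASTQ path.
#' @param mode `"exact"` or `"bernoulli"`.
#' @return invisibly, a list with `n_in`, `n_out` and `outfile`.
#' @export
subsample_fastq <- function(infile, ratio, seed, outfile,
                            mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  stopifnot(ratio > 0, ratio <= 1)
  lines <- readLines(infile)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4 in ", infile)
  }
  n <- length(lines) %/% 4L
  keep <- with_seed(seed, {
    if (mode == "exact") {
      m <- floor(n * ratio + 1e-9)
      sort(sample.int(n, m))
    } else {
      which(stats::runif(n) <= ratio)
    }
  })
  line_idx <- rep((keep - 1L) * 4L, each = 4L) + rep(1:4, times = length(keep))
  writeLines(lines[line_idx], outfile)
  invisible(list(n_in = n, n_out = length(keep), outfile = outfile))
}

# Deterministic per-(ratio, replicate) seed below 2^31, via an LCG-style
# integer hash: nearby (seed, ratio, replicate) triples must yield
# well-separated RNG states (naive linear schemes correlate R's
# Mersenne-Twister seeding and inflate between-replicate covariance).
derive_seed <- function(seed, ratio_idx, replicate) {
  h <- 0
  for (x in c(as.numeric(seed) %% 2^31, ratio_idx, replicate, 0, 0)) {
    h <- (h * 69069 + x + 1) %% 2^32
  }
  (h %% 2147483646) + 1
}

#' Subsampling throughput study (mean / Std. Dev. / RSD per category)
#'
#' For each extraction ratio and replicate, subsamples the FASTQ (with a seed
#' derived deterministically from `seed`, the ratio index and the replicate
#' index), classifies the subsample against the database and computes
#' unrounded per-category proportions of mapped unique reads. Replicates are
#' then aggregated into mean, sample (n-1) standard deviation and relative
#' standard deviation `sd / mean * 100` per (ratio, category).
#'
#' @param fastq input FASTQ.
#' @param db a `reference_db`.
#' @param ratios extraction ratios in (0, 1], sorted ascending.
#' @param replicates replicates per ratio (default 4).
#' @param seed base seed for the whole study.
#' @param mode subsampling mode, see [subsample_fastq()].
#' @param min_identity,min_cov mapper thresholds.
#' @return a data frame of class `rsd_table` with one row per
#'   (ratio, category): `ratio`, `category`, `mean_pct`, `sd_pct`, `rsd_pct`
#'   (NA when the mean is 0), `n_reads_mean`.
#' @export
rsd_study <- function(fastq, db, ratios, replicates = 4L, seed = 1L,
                      mode = "exact", min_identity = 0.90, min_cov = 0.80) {
  stopifnot(all(ratios > 0), all(ratios <= 1), replicates >= 1L)
  ratios <- sort(ratios)
  cats <- db_categories(db)
  rows <- list()
  tmp <- tempfile(fileext = ".fastq")
  on.exit(unlink(tmp))
  for (ri in seq_along(ratios)) {
    prop <- matrix(0, nrow = replicates, ncol = length(cats),
                   dimnames = list(NULL, cats))
    nreads <- numeric(replicates)
    for (rep_i in seq_len(replicates)) {
      sub <- subsample_fastq(fastq, ratios[ri],
                             seed = derive_seed(seed, ri, rep_i),
                             outfile = tmp, mode = mode)
      nreads[rep_i] <- sub$n_out
      cc <- classify_fastq(tmp, db, min_identity = min_identity,
                           min_cov = min_cov)
      denom <- sum(cc$counts)
      if (denom > 0) prop[rep_i, ] <- cc$counts[cats] / denom * 100
    }
    mu <- colMeans(prop)
    sdv <- apply(prop, 2L, stats::sd)
    rows[[ri]] <- data.frame(
      ratio = ratios[ri], category = cats, mean_pct = unname(mu),
      sd_pct = unname(sdv),
      rsd_pct = ifelse(mu > 0, unname(sdv / mu * 100), NA_real_),
      n_reads_mean = mean(nreads), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rsd_table", "data.frame")
  out
}
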