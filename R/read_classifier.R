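# Read mapping and the unique-read classification rule: each read is assigned
# to a meat category only when every genome it aligns to belongs to that one
# category; reads hitting several categories are discarded.

#' Map a single read against the reference database
#'
#' Seed-and-extend mapping: every genome sharing at least one exact k-mer
#' seed with the read (either strand) is extended to the best ungapped
#' alignment along the seed diagonal. Hits with identity `>= min_identity`
#' over at least `min_cov` of the read length are reported, at most one
#' (best) hit per genome so multiple hits within one genome cannot masquerade
#' as multi-genome evidence. Gapped alignment is out of scope: amplicon reads
#' are near-full-length matches and indels between related mitogenomes are
#' rare at this scale.
#'
#' @param read a DNA string.
#' @param db a `reference_db`.
#' @param min_identity minimum alignment identity (default 0.90).
#' @param min_cov minimum aligned fraction of the read (default 0.80).
#' @return data frame with columns `accession`, `position` (0-based),
#'   `strand`, `aligned_length`, `matches`, `identity`, `score`.
#' @export
map_read <- function(read, db, min_identity = 0.90, min_cov = 0.80) {
  stopifnot(is.character(read), length(read) == 1L)
  read <- toupper(read)
  if (nchar(read) < db$k) {
    stop("read shorter than the index k-mer size (", db$k, ")")
  }
  h <- map_reads_cpp(db_index(db), read, min_identity, min_cov)
  data.frame(
    accession = db$records$accession[h$genome],
    position = h$pos,
    strand = h$strand,
    aligned_length = h$aligned_length,
    matches = h$matches,
    identity = h$matches / h$aligned_length,
    score = h$matches,
    stringsAsFactors = FALSE
  )
}

#' Classify one read's alignment hits into a category
#'
#' The unique-read rule: `"UNMAPPED"` when there are no hits; otherwise the
#' single category of the hit genomes when they all agree, else
#' `"DISCARDED"`.
#'
#' @param hits a data frame with an `accession` column ([map_read()] output).
#' @param db a `reference_db`.
#' @return a single string: a category name, `"DISCARDED"` or `"UNMAPPED"`.
#' @export
classify_hits <- function(hits, db) {
  if (is.null(hits) || nrow(hits) == 0L) return("UNMAPPED")
  m <- match(hits$accession, db$records$accession)
  if (anyNA(m)) {
    stop("hit(s) to accession(s) absent from the database: ",
         paste(unique(hits$accession[is.na(m)]), collapse = ", "))
  }
  cats <- unique(db$records$category[m])
  if (length(cats) == 1L) cats else "DISCARDED"
}

#' Per-category unique-read counts
#'
#' Container invariant: `sum(counts) + discarded + unmapped == total_reads`.
#'
#' @param counts named integer vector of unique-read counts per category.
#' @param discarded number of multi-category reads.
#' @param unmapped number of reads with no hit.
#' @return an object of class `category_counts`.
#' @export
category_counts <- function(counts, discarded = 0L, unmapped = 0L) {
  counts <- vapply(counts, as.integer, integer(1))
  stopifnot(all(counts >= 0L), discarded >= 0L, unmapped >= 0L)
  total <- sum(counts) + as.integer(discarded) + as.integer(unmapped)
  structure(
    list(counts = counts, discarded = as.integer(discarded),
         unmapped = as.integer(unmapped), total_reads = total),
    class = "category_counts"
  )
}

#' @export
print.category_counts <- function(x, ...) {
  cat("Category counts (", x$total_reads, " reads):\n", sep = "")
  shown <- x$counts[x$counts > 0L]
  if (length(shown)) {
    cat(paste0("  ", names(shown), ": ", shown, collapse = "\n"), "\n")
  }
  cat("  [discarded: ", x$discarded, ", unmapped: ", x$unmapped, "]\n",
      sep = "")
  invisible(x)
}

# Vectorized category decision for a batch of reads given a hit table with
# integer columns read (1-based) and genome.
tally_decisions <- function(n_reads, hit_read, hit_genome, db) {
  assigned <- rep("UNMAPPED", n_reads)
  if (length(hit_read)) {
    cat_of_hit <- db$records$category[hit_genome]
    u <- unique(data.frame(read = hit_read, cat = cat_of_hit,
                           stringsAsFactors = FALSE))
    ncat <- tabulate(u$read, nbins = n_reads)
    assigned[ncat > 1L] <- "DISCARDED"
    single <- u[ncat[u$read] == 1L, , drop = FALSE]
    assigned[single$read] <- single$cat
  }
  assigned
}

decisions_to_counts <- function(assigned, db) {
  cats <- db_categories(db)
  counts <- vapply(cats, function(cc) sum(assigned == cc), integer(1))
  category_counts(counts,
                  discarded = sum(assigned == "DISCARDED"),
                  unmapped = sum(assigned == "UNMAPPED"))
}

#' Classify a FASTQ file of reads into category counts
#'
#' Maps every read with the internal mapper and applies the unique-read rule,
#' tallying per-category unique reads, discarded multi-category reads and
#' unmapped reads. Paired files are processed mate-independently and tallied
#' together. Base qualities are ignored (quality filtering is an upstream
#' concern); reads shorter than `min_length` bp are counted as unmapped and
#' reported via a warning counter.
#'
#' @param path one or more FASTQ paths (plain or gzip).
#' @param db a `reference_db`.
#' @param min_identity,min_cov mapper thresholds, see [map_read()].
#' @param min_length minimum read length considered (default 50).
#' @param per_read also return the per-read decisions.
#' @return a [category_counts()] object; when `per_read = TRUE` it carries a
#'   `per_read` attribute (data frame `id`, `decision`).
#' @export
classify_fastq <- function(path, db, min_identity = 0.90, min_cov = 0.80,
                           min_length = 50L, per_read = FALSE) {
  ids <- character(0)
  seqs <- character(0)
  for (p in path) {
    fq <- read_fastq(p)
    ids <- c(ids, fq$id)
    seqs <- c(seqs, toupper(fq$seq))
  }
  classify_reads(seqs, db, min_identity, min_cov, min_length,
                 ids = ids, per_read = per_read)
}

#' @rdname classify_fastq
#' @param reads character vector of read sequences.
#' @param ids optional read identifiers.
#' @export
classify_reads <- function(reads, db, min_identity = 0.90, min_cov = 0.80,
                           min_length = 50L, ids = NULL, per_read = FALSE) {
  n <- length(reads)
  if (n == 0L) {
    res <- decisions_to_counts(character(0), db)
    if (per_read) {
      attr(res, "per_read") <- data.frame(id = character(0),
                                          decision = character(0))
    }
    return(res)
  }
  reads <- toupper(reads)
  eligible <- nchar(reads) >= max(min_length, db$k)
  n_short <- sum(!eligible)
  if (n_short > 0L) {
    warning(n_short, " read(s) shorter than ", max(min_length, db$k),
            " bp counted as unmapped")
  }
  assigned <- rep("UNMAPPED", n)
  if (any(eligible)) {
    h <- map_reads_cpp(db_index(db), reads[eligible], min_identity, min_cov)
    idx <- which(eligible)
    assigned[eligible] <- tally_decisions(sum(eligible), h$read, h$genome, db)
  }
  res <- decisions_to_counts(assigned, db)
  attr(res, "n_short") <- n_short
  if (per_read) {
    attr(res, "per_read") <- data.frame(
      id = if (is.null(ids)) as.character(seq_len(n)) else ids,
      decision = assigned, stringsAsFactors = FALSE
    )
  }
  res
}

#' Ingest an external SAM alignment into category counts
#'
#' Parses a SAM file line by line, groups all alignment records (primary,
#' secondary and supplementary alike) by read name, and applies the same
#' unique-read rule as [classify_hits()] over each read's hit genomes.
#' Records with the unmapped flag set (0x4) count toward unmapped regardless
#' of other fields; mapping quality is ignored.
#'
#' @param path SAM file path.
#' @param db a `reference_db`; reference names must resolve to database
#'   accessions.
#' @param per_read also return the per-read decisions.
#' @return a [category_counts()] object.
#' @export
ingest_sam <- function(path, db, per_read = FALSE) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) {
    res <- decisions_to_counts(character(0), db)
    if (per_read) {
      attr(res, "per_read") <- data.frame(id = character(0),
                                          decision = character(0))
    }
    return(res)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("malformed SAM record at line ", which(lengths(fields) < 11L)[1L])
  }
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  unknown <- setdiff(unique(rname[mapped]), db$records$accession)
  if (length(unknown)) {
    stop("SAM reference name(s) absent from the database: ",
         paste(unknown, collapse = ", "))
  }
  reads <- unique(qname)
  ridx <- match(qname, reads)
  gidx <- match(rname, db$records$accession)
  assigned <- tally_decisions(length(reads), ridx[mapped], gidx[mapped], db)
  res <- decisions_to_counts(assigned, db)
  if (per_read) {
    attr(res, "per_read") <- data.frame(id = reads, decision = assigned,
                                        stringsAsFactors = FALSE)
  }
  res
}
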