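# In-silico PCR: locate universal-primer binding sites on templates and slice
# the amplicons the sequencing assay would produce.

#' Universal primer presets
#'
#' The three universal primer pairs used for marker amplification: CB1-5/CB3A
#' targeting the mitochondrial CYTB gene (~385 bp product), COIF/COIR
#' targeting COI, and CE CVZV 1/CE CVZV 2 targeting the D-loop. The CYTB
#' preset narrows the product length bounds to 250-500 bp.
#'
#' @param name one of `"cytb"`, `"coi"`, `"dloop"`.
#' @return a list with elements `fwd`, `rev` (each a list with `name` and
#'   `sequence`, 5'->3'), `min_len`, `max_len`.
#' @export
primer_preset <- function(name = c("cytb", "coi", "dloop")) {
  name <- match.arg(name)
  switch(name,
    cytb = list(
      fwd = primer("CB1-5", "CCATCCAACATCTCAGCATGATGAAA"),
      rev = primer("CB3A", "CCCTCAGAATGATATTTGTCCTCA"),
      min_len = 250L, max_len = 500L
    ),
    coi = list(
      fwd = primer("COIF", "AATTGGGGGGTTTGGAAATTG"),
      rev = primer("COIR", "GCTCGTGTATCAACGTCTATTCC"),
      min_len = 100L, max_len = 1000L
    ),
    dloop = list(
      fwd = primer("CE CVZV 1", "GATCACGAGCTTGATCACCA"),
      rev = primer("CE CVZV 2", "AGGAGTGGGCGATTTTAGGT"),
      min_len = 100L, max_len = 1000L
    )
  )
}

#' Define a primer
#'
#' @param name primer name.
#' @param sequence DNA string 5'->3'; IUPAC ambiguity codes allowed.
#' @return a list with class `primer`.
#' @export
primer <- function(name, sequence) {
  sequence <- toupper(sequence)
  stopifnot(nzchar(sequence))
  if (!grepl(DNA_ALPHABET_RE, sequence)) {
    stop("primer ", name, " contains non-IUPAC characters")
  }
  structure(list(name = name, sequence = sequence), class = "primer")
}

# Sliding-window scan of a mask-encoded pattern over a template. Returns
# starts (0-based) and mismatch counts of windows with <= max_mismatch
# mismatches; positions in exact_idx (1-based within pattern) must match.
scan_pattern <- function(tmask, pmask, max_mismatch, exact_idx = integer(0)) {
  L <- length(pmask)
  n <- length(tmask)
  if (L > n) {
    return(data.frame(start = integer(0), mismatches = integer(0)))
  }
  nwin <- n - L + 1L
  mm <- integer(nwin)
  for (j in seq_len(L)) {
    mm <- mm + as.integer(bitwAnd(pmask[j], tmask[j:(j + nwin - 1L)]) == 0L)
  }
  ok <- mm <= max_mismatch
  for (j in exact_idx) {
    ok <- ok & bitwAnd(pmask[j], tmask[j:(j + nwin - 1L)]) > 0L
  }
  data.frame(start = which(ok) - 1L, mismatches = mm[ok])
}

#' Find primer binding sites on a template
#'
#' All ungapped alignments of the primer, and of its reverse complement, with
#' at most `max_mismatch` mismatches, sorted by position. IUPAC codes in the
#' primer match their expansion sets; ambiguity codes in the template
#' (including N) match nothing and count as mismatches. Mimicking
#' amplification chemistry, the 3'-terminal `exact_3prime` bases of the
#' primer must match exactly.
#'
#' @param template DNA string.
#' @param prm a [primer()] (or plain DNA string).
#' @param max_mismatch maximum mismatches (default 3).
#' @param exact_3prime number of 3'-terminal primer bases required to match
#'   (default 2; set 0 to disable).
#' @return data frame with 0-based half-open `start`/`end`, `strand` (`"+"`
#'   if the primer matches the template as written, `"-"` if its reverse
#'   complement does), and `mismatches`.
#' @export
find_primer_sites <- function(template, prm, max_mismatch = 3L,
                              exact_3prime = 2L) {
  if (is.character(prm)) prm <- primer("primer", prm)
  stopifnot(max_mismatch >= 0L)
  template <- toupper(template)
  tmask <- seq_mask(template, template = TRUE)
  p <- prm$sequence
  L <- nchar(p)
  n3 <- min(exact_3prime, L)
  # plus strand: primer 3' end is the window's right end
  plus <- scan_pattern(tmask, seq_mask(p), max_mismatch,
                       exact_idx = if (n3 > 0L) (L - n3 + 1L):L else integer(0))
  # minus strand: scan the reverse complement; the primer 3' end maps to the
  # window's left end
  minus <- scan_pattern(tmask, seq_mask(revcomp(p)), max_mismatch,
                        exact_idx = if (n3 > 0L) 1L:n3 else integer(0))
  out <- rbind(
    if (nrow(plus)) cbind(plus, strand = "+") else NULL,
    if (nrow(minus)) cbind(minus, strand = "-") else NULL
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  out$end <- out$start + L
  out <- out[order(out$start, out$strand), c("start", "end", "strand", "mismatches")]
  rownames(out) <- NULL
  out
}

#' Extract in-silico PCR products
#'
#' Every pairing of a forward-primer site and a reverse-primer site in
#' productive orientation (primers pointing toward each other) whose product
#' length, primers included, lies in `[min_len, max_len]` is reported. The
#' product sequence is given 5'->3' starting at the forward primer. Circular
#' templates (mitogenomes) also yield products spanning the origin; such
#' products have `end > template length`, with `end - start` still the
#' product length.
#'
#' @param template a DNA string, or one row of a [genome_records()] table.
#' @param fwd,rev forward and reverse [primer()]s.
#' @param max_mismatch per-primer mismatch cap (default 3).
#' @param min_len,max_len product length bounds, primers included.
#' @param circular treat the template as circular (default TRUE).
#' @param exact_3prime passed to [find_primer_sites()].
#' @return data frame with columns `start`, `end`, `strand`, `length`,
#'   `fwd_mismatches`, `rev_mismatches`, `sequence`; zero rows when no
#'   productive pair exists.
#' @export
extract_amplicons <- function(template, fwd, rev, max_mismatch = 3L,
                              min_len = 100L, max_len = 1000L,
                              circular = TRUE, exact_3prime = 2L) {
  stopifnot(min_len <= max_len)
  if (is.data.frame(template)) template <- template$sequence[1L]
  template <- toupper(template)
  L <- nchar(template)
  ext <- if (circular) min(L - 1L, max_len) else 0L
  text <- if (ext > 0L) paste0(template, substr(template, 1L, ext)) else template

  fs <- find_primer_sites(text, fwd, max_mismatch, exact_3prime)
  rs <- find_primer_sites(text, rev, max_mismatch, exact_3prime)

  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  rows <- list()
  # forward primer on + strand, reverse primer on - strand, fwd upstream
  fp <- fs[fs$strand == "+" & fs$start < L, , drop = FALSE]
  rm_ <- rs[rs$strand == "-", , drop = FALSE]
  if (nrow(fp) && nrow(rm_)) {
    for (a in seq_len(nrow(fp))) {
      for (b in seq_len(nrow(rm_))) {
        len <- rm_$end[b] - fp$start[a]
        if (rm_$start[b] >= fp$end[a] && len >= min_len && len <= max_len &&
            len <= L) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = fp$start[a], end = fp$start[a] + len, strand = "+",
            length = len, fwd_mismatches = fp$mismatches[a],
            rev_mismatches = rm_$mismatches[b],
            sequence = substr(text, fp$start[a] + 1L, fp$start[a] + len),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  # mirror arrangement: forward primer on - strand, reverse primer on +
  fm <- fs[fs$strand == "-", , drop = FALSE]
  rp <- rs[rs$strand == "+" & rs$start < L, , drop = FALSE]
  if (nrow(fm) && nrow(rp)) {
    for (a in seq_len(nrow(fm))) {
      for (b in seq_len(nrow(rp))) {
        len <- fm$end[a] - rp$start[b]
        if (fm$start[a] >= rp$end[b] && len >= min_len && len <= max_len &&
            len <= L) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = rp$start[b], end = rp$start[b] + len, strand = "-",
            length = len, fwd_mismatches = fm$mismatches[a],
            rev_mismatches = rp$mismatches[b],
            sequence = revcomp(substr(text, rp$start[b] + 1L,
                                      rp$start[b] + len)),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # canonicalize circular duplicates: keep products whose start lies in [0, L)
  key <- paste(out$start %% L, out$length, out$strand)
  out <- out[!duplicated(key), , drop = FALSE]
  out$start <- out$start %% L
  out$end <- out$start + out$length
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Slice a marker amplicon panel from a reference database
#'
#' Runs [extract_amplicons()] on every genome and keeps at most one amplicon
#' per genome: the longest in-bounds product (ties broken by smallest start).
#' Amplicons are labeled `accession|species|category`; genomes yielding no
#' product are reported in the skip list.
#'
#' @param db a `reference_db`.
#' @param fwd,rev primers; defaults to the CYTB preset when both are NULL.
#' @param max_mismatch,min_len,max_len,circular,exact_3prime see
#'   [extract_amplicons()].
#' @param out optional FASTA path for the amplicons.
#' @return list with `amplicons` (named character vector of sequences),
#'   `table` (per-amplicon coordinates) and `skipped` (accessions).
#' @export
slice_marker_panel <- function(db, fwd = NULL, rev = NULL, max_mismatch = 3L,
                               min_len = 250L, max_len = 500L,
                               circular = TRUE, exact_3prime = 2L,
                               out = NULL) {
  stopifnot(inherits(db, "reference_db"))
  if (is.null(fwd) && is.null(rev)) {
    ps <- primer_preset("cytb")
    fwd <- ps$fwd
    rev <- ps$rev
  }
  rec <- db$records
  seqs <- character(0)
  tabs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(rec))) {
    hits <- extract_amplicons(rec$sequence[i], fwd, rev, max_mismatch,
                              min_len, max_len, circular, exact_3prime)
    if (nrow(hits) == 0L) {
      skipped <- c(skipped, rec$accession[i])
      next
    }
    hits <- hits[order(-hits$length, hits$start), , drop = FALSE]
    top <- hits[1L, , drop = FALSE]
    label <- paste(rec$accession[i], rec$species[i], rec$category[i],
                   sep = "|")
    seqs[label] <- top$sequence
    top$accession <- rec$accession[i]
    top$label <- label
    tabs[[length(tabs) + 1L]] <- top
  }
  tab <- if (length(tabs)) do.call(rbind, tabs) else NULL
  if (!is.null(tab)) rownames(tab) <- NULL
  if (!is.null(out)) {
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, out)
  }
  list(amplicons = seqs, table = tab, skipped = skipped)
}
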