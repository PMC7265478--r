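# Shared low-level helpers: IUPAC bitmasks, scoped RNG, presentation rounding,
# plain-text FASTQ I/O.

# Bitmask encoding of IUPAC nucleotide codes (A=1, C=2, G=4, T=8; ambiguity
# codes are unions). Two bases are compatible iff their masks intersect.
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# Templates are matched literally: ambiguity codes (including N) in a template
# match nothing, so they always count as mismatches against a primer base.
TEMPLATE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)

DNA_ALPHABET_RE <- "^[ACGTMRWSYKVHDBN]+$"

seq_mask <- function(x, template = FALSE) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  tab <- if (template) TEMPLATE_MASK else IUPAC_MASK
  m <- unname(tab[ch])
  m[is.na(m)] <- 0L
  m
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps plain
#' character strings as input and output. IUPAC ambiguity codes are handled.
#'
#' @param x a single DNA string.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Round half away from zero at `digits` decimals (presentation rounding; base
# round() is round-half-even). Small epsilon guards against FP representation.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- FASTQ ------------------------------------------------------------------

# Minimal plain/gzip FASTQ reader. Returns list(id, seq). Validates record
# structure and reports the first offending record number.
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: truncated record ", length(lines) %/% 4L + 1L,
         " in ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(list(id = character(0), seq = character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  list(id = ids, seq = seqs)
}

write_fastq <- function(id, seq, path, qual_char = "I") {
  stopifnot(length(id) == length(seq))
  n <- length(id)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", id)
  lines[seq(2L, by = 4L, length.out = n)] <- seq
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- strrep(qual_char, nchar(seq))
  writeLines(lines, path)
  invisible(path)
}

count_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  }
  length(lines) %/% 4L
}
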