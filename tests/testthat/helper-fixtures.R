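# Shared fixtures and independent oracles used across the test files.

rand_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All 0-based occurrences of `pat` as an exact substring of `g` (naive scan).
naive_positions <- function(g, pat) {
  L <- nchar(pat)
  n <- nchar(g)
  if (L > n) return(integer(0))
  hits <- which(vapply(seq_len(n - L + 1L), function(i) {
    substr(g, i, i + L - 1L) == pat
  }, logical(1)))
  hits - 1L
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"), V = c("A", "C", "G"),
  H = c("A", "C", "T"), D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

# Sliding-window Hamming scan with IUPAC expansion in the pattern and literal
# template bases; independent of the package's bitmask scanner.
oracle_scan <- function(template, pattern, max_mismatch) {
  tv <- strsplit(template, "", fixed = TRUE)[[1L]]
  pv <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  L <- length(pv)
  n <- length(tv)
  out <- data.frame(start = integer(0), mismatches = integer(0))
  if (L > n) return(out)
  for (i in 0:(n - L)) {
    mm <- 0L
    for (j in seq_len(L)) {
      tb <- tv[i + j]
      ok <- tb %in% c("A", "C", "G", "T") && tb %in% IUPAC_SETS[[pv[j]]]
      if (!ok) mm <- mm + 1L
    }
    if (mm <= max_mismatch) {
      out <- rbind(out, data.frame(start = i, mismatches = mm))
    }
  }
  out
}

# Match counts of read `r` against genome `g` at every full-overlap offset
# (0-based), via integer codes; vectorized over offsets.
oracle_offset_matches <- function(g, r) {
  code <- function(x) {
    m <- match(strsplit(x, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
    m[is.na(m)] <- 0L
    m
  }
  gv <- code(g)
  rv <- code(r)
  n <- length(gv)
  m <- length(rv)
  if (m > n) return(integer(0))
  noff <- n - m + 1L
  acc <- integer(noff)
  for (j in seq_len(m)) {
    acc <- acc + as.integer(gv[j:(j + noff - 1L)] == rv[j] & rv[j] > 0L)
  }
  acc
}

# Best full-overlap ungapped hit of a read on one genome over both strands:
# list(matches, pos, strand) or NULL if below the identity threshold.
oracle_best_hit <- function(g, read, min_identity = 0.9) {
  m <- nchar(read)
  best <- NULL
  for (st in c("+", "-")) {
    q <- if (st == "+") read else meatseq::revcomp(read)
    sc <- oracle_offset_matches(g, q)
    if (!length(sc)) next
    top <- max(sc)
    if (top / m < min_identity) next
    pos <- which(sc == top)[1L] - 1L
    cand <- list(matches = top, pos = pos, strand = st)
    if (is.null(best) || cand$matches > best$matches ||
        (cand$matches == best$matches && cand$pos < best$pos)) {
      best <- cand
    }
  }
  best
}

# Unique-read rule applied naively to a per-read list of hit categories.
oracle_decision <- function(cats) {
  u <- unique(cats)
  if (length(u) == 0L) "UNMAPPED" else if (length(u) == 1L) u else "DISCARDED"
}

# Minimal SAM writer for fixtures: one line per alignment record.
write_sam <- function(qname, flag, rname, path, refs = unique(rname[rname != "*"])) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", refs, "\tLN:16000"))
  body <- paste(qname, flag, rname, "1", "0", "*", "*", "0", "0", "*", "*",
                sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

small_world <- function(seed = 1, categories = c("pork", "beef", "mutton"),
                        ...) {
  make_world(categories = categories, seed = seed, genome_length = 2000L,
             cassette_at = 500L, ...)
}

# Leaf sets of both sides of every internal edge, by removing the edge and
# flooding the remaining edge list (independent of ape's bipartitions).
oracle_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  edges <- tree$edge
  internal <- which(edges[, 2L] > nt)
  out <- list()
  for (e in internal) {
    keep <- edges[-e, , drop = FALSE]
    # flood from the child node of the removed edge
    comp <- edges[e, 2L]
    repeat {
      grow <- keep[keep[, 1L] %in% comp | keep[, 2L] %in% comp, , drop = FALSE]
      newc <- union(comp, c(grow[, 1L], grow[, 2L]))
      if (length(newc) == length(comp)) break
      comp <- newc
    }
    out[[length(out) + 1L]] <- sort(intersect(comp, seq_len(nt)))
  }
  out
}

# Quartet-based topology oracle: for an additive distance matrix, the
# generating unrooted topology is the unique one whose every quartet split
# pairs the taxa with the strictly smallest four-point sum.
quartet_consistent <- function(topo, dm) {
  labs <- topo$tip.label
  td <- ape::cophenetic.phylo(ape::compute.brlen(topo, 1))
  for (q in utils::combn(labs, 4, simplify = FALSE)) {
    s_dm <- c(dm[q[1], q[2]] + dm[q[3], q[4]],
              dm[q[1], q[3]] + dm[q[2], q[4]],
              dm[q[1], q[4]] + dm[q[2], q[3]])
    s_td <- c(td[q[1], q[2]] + td[q[3], q[4]],
              td[q[1], q[3]] + td[q[2], q[4]],
              td[q[1], q[4]] + td[q[2], q[3]])
    if (which.min(s_dm) != which.min(s_td)) return(FALSE)
  }
  TRUE
}

rand_additive <- function(n, seed) {
  with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 1))
    tr$tip.label <- sample(paste0("t", seq_len(n)))
    tr
  })
}
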