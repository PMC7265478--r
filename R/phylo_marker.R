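# Marker-resolution assessment: pairwise distances between amplicons, a
# neighbor-joining tree and a category monophyly check.

#' Proportion of differing sites between two aligned sequences
#'
#' Sites where either sequence carries a non-ACGT character (gaps, N,
#' ambiguity codes) are excluded; the distance is mismatches over compared
#' sites. The Jukes-Cantor transform `-(3/4) log(1 - 4p/3)` is available as
#' an option (infinite, with a warning, when p >= 0.75).
#'
#' @param a,b DNA strings of equal length.
#' @param model `"p"` (default) or `"jc"`.
#' @return a non-negative distance.
#' @export
p_distance <- function(a, b, model = c("p", "jc")) {
  model <- match.arg(model)
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(av) != length(bv)) {
    stop("sequences must have equal length (align them first)")
  }
  acgt <- c("A", "C", "G", "T")
  use <- av %in% acgt & bv %in% acgt
  if (!any(use)) stop("no comparable (ACGT) sites")
  p <- mean(av[use] != bv[use])
  if (model == "p") return(p)
  if (p >= 0.75) {
    warning("p >= 0.75: Jukes-Cantor distance is infinite")
    return(Inf)
  }
  -0.75 * log(1 - 4 * p / 3)
}

# integer codes for fast offset scoring; non-ACGT -> 0 (never matches)
seq_codes <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  m
}

#' Align near-homologous amplicons by center-star offsets
#'
#' Lightweight alignment for same-locus amplicons of near-equal length: the
#' longest sequence is the center; every other sequence is placed at the
#' ungapped offset maximizing matches to the center (ties: smallest absolute,
#' then smallest offset), and end gaps pad all rows to a common frame.
#' Internal indels are not modeled; a full progressive MSA is out of scope
#' for primer-delimited amplicons.
#'
#' @param seqs named character vector (or `DNAStringSet`) of >= 2 sequences.
#' @param max_shift maximum offset magnitude explored beyond the length
#'   difference (default 25).
#' @return named character vector of equal-length rows padded with `-`.
#' @export
align_amplicons <- function(seqs, max_shift = 25L) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  center_i <- which.max(lens)
  C <- seq_codes(seqs[[center_i]])
  span <- max(abs(max(lens) - lens)) + max_shift
  offs <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    if (i == center_i) next
    S <- seq_codes(seqs[[i]])
    best <- c(score = -1L, off = 0L)
    for (off in -span:span) {
      lo <- max(0L, off)                       # center coords, 0-based
      hi <- min(length(C), length(S) + off)
      if (hi - lo < 1L) next
      sc <- sum(C[(lo + 1L):hi] == S[(lo - off + 1L):(hi - off)] &
                  C[(lo + 1L):hi] > 0L)
      better <- sc > best["score"] ||
        (sc == best["score"] &&
           (abs(off) < abs(best["off"]) ||
              (abs(off) == abs(best["off"]) && off < best["off"])))
      if (better) best <- c(score = sc, off = off)
    }
    offs[i] <- best[["off"]]
  }
  left <- offs - min(offs)
  width <- max(left + lens)
  out <- vapply(seq_along(seqs), function(i) {
    paste0(strrep("-", left[i]), seqs[[i]],
           strrep("-", width - left[i] - lens[i]))
  }, character(1))
  names(out) <- names(seqs)
  out
}

#' Pairwise distance matrix from an alignment
#'
#' Drops columns with more than 50% gaps, then computes [p_distance()] for
#' every pair (per-pair exclusion of remaining non-ACGT sites).
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param model `"p"` or `"jc"`.
#' @return a symmetric labeled matrix with zero diagonal.
#' @export
amplicon_dist <- function(aln, model = c("p", "jc")) {
  model <- match.arg(model)
  stopifnot(length(aln) >= 2L, length(unique(nchar(aln))) == 1L)
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  mat <- mat[, gap_frac <= 0.5, drop = FALSE]
  rows <- apply(mat, 1L, paste, collapse = "")
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(rows[i], rows[j], model = model)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining: iteratively join the pair
#' minimizing the Q-criterion, with branch lengths from the standard
#' three-point formulas. Ties on Q are broken deterministically by the
#' lexicographically smallest label pair (internal nodes are keyed by their
#' smallest leaf label). Negative branch-length estimates are clamped to 0;
#' the total clamped amount is recorded in the `clamped` attribute of the
#' returned tree. The result is the usual unrooted tree with a basal
#' trifurcation.
#'
#' @param dm symmetric distance matrix with labels ([amplicon_dist()]
#'   output), >= 3 taxa.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(dm)
  frags <- labels          # newick fragment per active node
  keys <- labels           # tie-break key: smallest leaf label in the clade
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- clamped + abs(x)
      0
    } else {
      x
    }
  }
  d <- dm
  while (length(frags) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ck <- apply(cand, 1L, function(ij) {
      p <- sort(c(keys[ij[1L]], keys[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(ck)[1L], ]
    i <- pick[[1L]]
    j <- pick[[2L]]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], li, frags[j], lj)
    newkey <- min(keys[i], keys[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    d <- d2
    frags <- c(frags[keep], newfrag)
    keys <- c(keys[keep], newkey)
  }
  # final three-point resolution
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frags[1L], l1, frags[2L], l2, frags[3L], l3)
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# Leaf-index sets (one side of each split) for every internal edge.
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, as.integer)
}

#' Fraction of categories that are monophyletic on a tree
#'
#' For each category, tests whether some edge bipartition of the unrooted
#' tree separates exactly its leaves from all others. Categories with a
#' single leaf (or spanning all leaves) are coherent by convention.
#'
#' @param tree a `phylo` tree.
#' @param category_of optional named character vector mapping leaf labels to
#'   categories; when NULL, categories are taken as the third `|`-separated
#'   field of the leaf labels (`accession|species|category`).
#' @return list with `fraction` and a named logical `per_category`.
#' @export
category_coherence <- function(tree, category_of = NULL) {
  tips <- tree$tip.label
  if (is.null(category_of)) {
    parts <- strsplit(tips, "|", fixed = TRUE)
    if (any(lengths(parts) < 3L)) {
      stop("leaf labels are not 'accession|species|category'; ",
           "supply category_of")
    }
    category_of <- stats::setNames(vapply(parts, `[[`, character(1), 3L), tips)
  }
  cats <- unique(unname(category_of[tips]))
  n <- length(tips)
  splits <- tree_bipartitions(tree)
  split_keys <- vapply(splits, function(s) paste(sort(s), collapse = ","),
                       character(1))
  verdict <- vapply(cats, function(cc) {
    S <- sort(which(category_of[tips] == cc))
    if (length(S) <= 1L || length(S) == n) return(TRUE)
    k1 <- paste(S, collapse = ",")
    k2 <- paste(sort(setdiff(seq_len(n), S)), collapse = ",")
    k1 %in% split_keys || k2 %in% split_keys
  }, logical(1))
  names(verdict) <- cats
  list(fraction = mean(verdict), per_category = verdict)
}
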