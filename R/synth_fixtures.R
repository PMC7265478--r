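# Deterministic synthetic data: category-structured mitogenomes with an
# implanted universal-primer cassette, optional cross-category conserved
# blocks, and error-bearing mixed reads. Everything is reproducible from a
# seed at file-level byte identity.

# substitute each site independently with probability `rate` (to a different
# base); substitution-only, matching the ungapped mapper
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
  }
  paste(ch, collapse = "")
}

splice_in <- function(genome, insert, at) {
  # overwrite genome[at, at + nchar(insert)) (0-based) with insert
  paste0(substr(genome, 1L, at),
         insert,
         substr(genome, at + nchar(insert) + 1L, nchar(genome)))
}

# latinized genus tokens for a category name, e.g. "pork" -> Porkus, Porkella
category_genera <- function(cat) {
  stem <- paste0(toupper(substr(cat, 1L, 1L)),
                 gsub("[^a-z]", "", tolower(substring(cat, 2L))))
  paste0(stem, c("us", "ella"))
}

#' Generate a synthetic reference world
#'
#' Emulates the structure the pipeline faces in practice: one ancestral
#' mitogenome-like sequence, per-category roots diverged from it, species
#' genomes diverged within each category, a universal-primer cassette
#' (forward primer + marker interior + reverse-complemented reverse primer)
#' implanted at a fixed locus of every genome, and optional conserved blocks
#' copied verbatim into all genomes of selected category sets (emulating the
#' near-identical CYTB stretches that make closely related meats
#' confusable). Divergence parameters are pairwise substitution fractions:
#' half is applied on each lineage.
#'
#' @param categories character vector of category names (default: the
#'   13-category scheme).
#' @param n_species species (genomes) per category (default 2).
#' @param between_divergence expected pairwise substitutions/site between
#'   categories (default 0.15, the order of between-genus mitochondrial
#'   divergence at this marker).
#' @param within_divergence expected pairwise substitutions/site within a
#'   category (default 0.02).
#' @param genome_length genome size in bp (default 16000).
#' @param conserved_blocks list of `list(length =, categories =)` entries;
#'   each block is copied verbatim into every genome of the named categories,
#'   inside the marker amplicon so that amplicon reads exercise the
#'   discard rule.
#' @param spacer_length marker interior length between the primers (default
#'   335, giving a 385-bp CYTB-like amplicon).
#' @param cassette_at 0-based implant position of the cassette (default
#'   1000).
#' @param preset primer preset name for the cassette (default `"cytb"`).
#' @param seed integer seed; same seed, same world, byte for byte.
#' @param fasta,config optional output paths for the reference FASTA and the
#'   category config file.
#' @return an object of class `synth_world`: records (a [genome_records()]
#'   table with `category`), the [category_map()], amplicon coordinates
#'   (`amp_start`, `amp_end`, identical across genomes), conserved-block
#'   loci, and the seed.
#' @export
make_world <- function(categories = c("pork", "beef", "mutton", "chicken",
                                      "rabbit", "rat", "venison", "horse",
                                      "camel", "bear", "dog", "cat", "fox"),
                       n_species = 2L, between_divergence = 0.15,
                       within_divergence = 0.02, genome_length = 16000L,
                       conserved_blocks = list(), spacer_length = 335L,
                       cassette_at = 1000L, preset = "cytb", seed = 1L,
                       fasta = NULL, config = NULL) {
  stopifnot(between_divergence >= 0, between_divergence < 0.75,
            within_divergence >= 0, within_divergence < 0.75,
            n_species >= 1L)
  ps <- primer_preset(preset)
  fwd <- ps$fwd$sequence
  rev_rc <- revcomp(ps$rev$sequence)
  cass_len <- nchar(fwd) + spacer_length + nchar(rev_rc)
  if (cassette_at + cass_len > genome_length) {
    stop("primer cassette does not fit in the genome")
  }
  blk_len <- vapply(conserved_blocks, function(b) as.integer(b$length),
                    integer(1))
  if (length(blk_len) && sum(blk_len) + 10L * length(blk_len) > spacer_length) {
    stop("conserved blocks do not fit inside the marker interior")
  }

  world <- with_seed(seed, {
    ancestor <- rand_dna(genome_length)
    blocks <- lapply(blk_len, rand_dna)
    acc <- character(0)
    species <- character(0)
    cat_of <- character(0)
    seqs <- character(0)
    taxa <- character(0)
    cmap_list <- list()
    idx <- 0L
    for (ci in seq_along(categories)) {
      cat <- categories[ci]
      genera <- category_genera(cat)
      cmap_list[[cat]] <- genera
      root <- mutate_seq(ancestor, between_divergence / 2)
      for (si in seq_len(n_species)) {
        idx <- idx + 1L
        g <- mutate_seq(root, within_divergence / 2)
        # implant the primer cassette (primer sites conserved across taxa)
        g <- splice_in(g, fwd, cassette_at)
        g <- splice_in(g, rev_rc, cassette_at + nchar(fwd) + spacer_length)
        # conserved blocks shared verbatim across their category sets
        off <- cassette_at + nchar(fwd) + 5L
        for (bi in seq_along(conserved_blocks)) {
          if (cat %in% conserved_blocks[[bi]]$categories) {
            g <- splice_in(g, blocks[[bi]], off)
          }
          off <- off + blk_len[bi] + 10L
        }
        acc <- c(acc, sprintf("SYN%05d", idx))
        genus <- genera[(si - 1L) %% 2L + 1L]
        species <- c(species, sprintf("%s synthetica%d", genus, si))
        taxa <- c(taxa, genus)
        cat_of <- c(cat_of, cat)
        seqs <- c(seqs, g)
      }
    }
    block_loci <- if (length(conserved_blocks)) {
      starts <- cassette_at + nchar(fwd) + 5L +
        cumsum(c(0L, utils::head(blk_len + 10L, -1L)))
      data.frame(
        block = seq_along(conserved_blocks), start = starts,
        end = starts + blk_len,
        categories = vapply(conserved_blocks, function(b)
          paste(b$categories, collapse = ";"), character(1)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(block = integer(0), start = integer(0), end = integer(0),
                 categories = character(0))
    }
    rec <- genome_records(acc, species, seqs, taxa)
    rec$category <- cat_of
    list(records = rec, cmap = category_map(cmap_list),
         amp_start = cassette_at, amp_end = cassette_at + cass_len,
         blocks = block_loci)
  })
  world$seed <- seed
  class(world) <- "synth_world"
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(world$records$sequence)
    names(ss) <- paste(world$records$accession, world$records$species)
    Biostrings::writeXStringSet(ss, fasta)
  }
  if (!is.null(config)) {
    writeLines(vapply(names(world$cmap), function(nm) {
      paste0(nm, ": ", paste(world$cmap[[nm]], collapse = ", "))
    }, character(1)), config)
  }
  world
}

#' Build a reference database directly from a synthetic world
#'
#' @param world a [make_world()] object.
#' @param k k-mer size.
#' @return a `reference_db`.
#' @export
world_db <- function(world, k = 21L) {
  build_index(world$records, k)
}

#' Simulate mixed amplicon or shotgun reads from a synthetic world
#'
#' Per read: a category is drawn from the mixture, a species uniformly
#' within the category, a fragment either from within the primer-delimited
#' marker amplicon (`"amplicon"` mode, the default) or from a uniform genome
#' position (`"shotgun"` mode), on a random strand, with i.i.d. substitution
#' errors at the stated rate. The truth table records the category, species
#' and position of every read.
#'
#' @param world a [make_world()] object.
#' @param n_reads number of reads.
#' @param mixture named mass-fraction vector over category names (normalized
#'   internally; all names must be world categories).
#' @param read_length read length in bp (default 301, typical of merged
#'   MiSeq 2x300 amplicon reads).
#' @param error_rate per-base substitution error rate (default 0.005).
#' @param seed integer seed.
#' @param mode `"amplicon"` or `"shotgun"`.
#' @param fastq optional output FASTQ path (constant qualities).
#' @param truth optional output CSV path for the truth table.
#' @return list with `reads` (data frame `id`, `seq`), `truth` (data frame
#'   `id`, `category`, `species`, `accession`, `position`, `strand`).
#' @export
simulate_reads <- function(world, n_reads, mixture, read_length = 301L,
                           error_rate = 0.005, seed = 1L,
                           mode = c("amplicon", "shotgun"),
                           fastq = NULL, truth = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(world, "synth_world"), n_reads >= 0L,
            all(mixture >= 0), sum(mixture) > 0)
  if (!all(names(mixture) %in% world$records$category)) {
    stop("mixture categories absent from world: ",
         paste(setdiff(names(mixture), world$records$category),
               collapse = ", "))
  }
  if (mode == "amplicon" &&
      read_length > world$amp_end - world$amp_start) {
    stop("read_length exceeds the amplicon length (",
         world$amp_end - world$amp_start, " bp)")
  }
  rec <- world$records
  out <- with_seed(seed, {
    if (n_reads == 0L) {
      list(id = character(0), seq = character(0),
           category = character(0), species = character(0),
           accession = character(0), position = integer(0),
           strand = character(0))
    } else {
      cat_draw <- sample(names(mixture), n_reads, replace = TRUE,
                         prob = mixture / sum(mixture))
      gidx <- vapply(cat_draw, function(cc) {
        cand <- which(rec$category == cc)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      if (mode == "amplicon") {
        lo <- world$amp_start
        hi <- world$amp_end - read_length
      } else {
        lo <- 0L
        hi <- min(rec$length) - read_length
      }
      pos <- lo + sample.int(hi - lo + 1L, n_reads, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      frag <- substr(rec$sequence[gidx], pos + 1L, pos + read_length)
      nerr <- stats::rbinom(n_reads, read_length, error_rate)
      for (i in which(nerr > 0L)) {
        frag[i] <- local({
          ch <- strsplit(frag[i], "", fixed = TRUE)[[1L]]
          at <- sample.int(read_length, nerr[i])
          for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          paste(ch, collapse = "")
        })
      }
      minus <- strand == "-"
      if (any(minus)) {
        frag[minus] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(frag[minus])))
      }
      list(id = sprintf("read%06d", seq_len(n_reads)), seq = frag,
           category = cat_draw, species = rec$species[gidx],
           accession = rec$accession[gidx], position = pos, strand = strand)
    }
  })
  reads <- data.frame(id = out$id, seq = out$seq, stringsAsFactors = FALSE)
  tt <- data.frame(id = out$id, category = out$category,
                   species = out$species, accession = out$accession,
                   position = out$position, strand = out$strand,
                   stringsAsFactors = FALSE)
  if (!is.null(fastq)) write_fastq(reads$id, reads$seq, fastq)
  if (!is.null(truth)) utils::write.csv(tt, truth, row.names = FALSE)
  list(reads = reads, truth = tt)
}

#' Simulate an H1-like six-component mixture
#'
#' A six-category DNA mixture with target mass fractions 40.38 / 22.70 /
#' 22.40 / 10.83 / 2.54 / 1.08 percent (mutton, beef, rabbit, rat, pork,
#' chicken; normalized internally) at the recommended sequencing throughput
#' of approximately 30,000 reads, with a ~1% minority component probing the
#' qualitative detection limit.
#'
#' @param world a [make_world()] with at least these six categories.
#' @param n_reads number of reads (default 30000).
#' @param read_length,error_rate,seed,fastq,truth see [simulate_reads()].
#' @return see [simulate_reads()].
#' @export
simulate_h1_like <- function(world, n_reads = 30000L, read_length = 301L,
                             error_rate = 0.005, seed = 1L, fastq = NULL,
                             truth = NULL) {
  mixture <- c(mutton = 40.38, beef = 22.70, rabbit = 22.40,
               rat = 10.83, pork = 2.54, chicken = 1.08)
  missing_cats <- setdiff(names(mixture), unique(world$records$category))
  if (length(missing_cats)) {
    stop("world lacks required categories: ",
         paste(missing_cats, collapse = ", "))
  }
  simulate_reads(world, n_reads, mixture, read_length = read_length,
                 error_rate = error_rate, seed = seed, mode = "amplicon",
                 fastq = fastq, truth = truth)
}
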