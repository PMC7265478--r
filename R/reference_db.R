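# Category-curated mitochondrial genome reference database: record container,
# category map, k-mer index and plain-text persistence.

#' Construct a table of reference genome records
#'
#' The basic container for reference mitochondrial genomes: a data frame with
#' one row per genome carrying the accession, species name, taxon labels used
#' for category matching, the sequence and its length.
#'
#' @param accession character vector of unique identifiers.
#' @param species character vector of species names (free text; its
#'   whitespace-separated tokens participate in category matching).
#' @param sequence character vector of DNA sequences (IUPAC codes allowed).
#' @param taxa optional list (or semicolon-separated character vector) of
#'   extra taxon labels per record, e.g. genus or common-group names.
#' @return a data frame with columns `accession`, `species`, `taxa`
#'   (semicolon-separated), `sequence`, `length`.
#' @export
genome_records <- function(accession, species, sequence, taxa = NULL) {
  accession <- as.character(accession)
  species <- as.character(species)
  sequence <- toupper(as.character(sequence))
  n <- length(accession)
  stopifnot(length(species) == n, length(sequence) == n)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  bad <- !grepl(DNA_ALPHABET_RE, sequence)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence of: ",
         paste(accession[bad], collapse = ", "))
  }
  if (is.null(taxa)) {
    taxa <- rep("", n)
  } else if (is.list(taxa)) {
    taxa <- vapply(taxa, function(x) paste(x, collapse = ";"), character(1))
  }
  stopifnot(length(taxa) == n)
  data.frame(
    accession = accession, species = species, taxa = as.character(taxa),
    sequence = sequence, length = nchar(sequence),
    stringsAsFactors = FALSE
  )
}

#' Read reference genomes from a FASTA file
#'
#' Parses a multi-FASTA of mitochondrial genomes into a [genome_records()]
#' table. The first whitespace-delimited token of each header is the
#' accession; the remainder is the species name. Records outside the expected
#' complete-mitogenome length range trigger a warning (they are kept).
#'
#' @param path FASTA file.
#' @param length_gate numeric length-2 vector; records outside
#'   `[length_gate[1], length_gate[2]]` bp raise a warning. The default covers
#'   typical complete animal mitogenomes.
#' @return a genome records data frame.
#' @export
read_genomes <- function(path, length_gate = c(12000, 20500)) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  hdr <- names(ss)
  acc <- sub("\\s.*$", "", hdr)
  species <- trimws(sub("^\\S+\\s*", "", hdr))
  species[!nzchar(species)] <- acc[!nzchar(species)]
  rec <- genome_records(acc, species, as.character(ss))
  out <- rec$length < length_gate[1L] | rec$length > length_gate[2L]
  if (any(out)) {
    warning(sum(out), " record(s) outside the ", length_gate[1L], "-",
            length_gate[2L], " bp complete-mitogenome length range: ",
            paste(utils::head(rec$accession[out], 5L), collapse = ", "))
  }
  rec
}

# --- category map -----------------------------------------------------------

#' Construct a category map
#'
#' Maps meat-category names (the identification unit of the pipeline, e.g.
#' "mutton" spanning the genera Capra/Ovis/Pseudois) to lists of taxon name
#' strings. Order is preserved. A taxon may belong to at most one category;
#' matching later on is case-insensitive, so taxa differing only by case are
#' duplicates.
#'
#' @param categories named list; names are category names, elements are
#'   character vectors of taxon names.
#' @return an object of class `category_map`.
#' @export
category_map <- function(categories) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  nm <- names(categories)
  if (any(!nzchar(nm))) stop("unnamed category in category map")
  if (anyDuplicated(nm)) {
    stop("duplicate category name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  categories <- lapply(categories, function(x) {
    x <- trimws(as.character(x))
    x[nzchar(x)]
  })
  if (any(lengths(categories) == 0L)) {
    stop("category with no taxa: ",
         paste(nm[lengths(categories) == 0L], collapse = ", "))
  }
  all_taxa <- tolower(unlist(categories, use.names = FALSE))
  if (anyDuplicated(all_taxa)) {
    stop("taxon listed under more than one category: ",
         paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ", "))
  }
  structure(categories, class = "category_map")
}

#' Load a category map from a plain-text config file
#'
#' One category per line, `category: taxon1, taxon2, ...`. Blank lines and
#' `#` comments are ignored. Load order is preserved.
#'
#' @param path config file path.
#' @return a [category_map()] object.
#' @export
load_category_map <- function(path) {
  if (!file.exists(path)) stop("category map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty category map file: ", path)
  parts <- regmatches(lines, regexpr(":", lines, fixed = TRUE), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("unparseable category line: ", lines[which(bad)[1L]])
  nm <- vapply(parts, function(p) trimws(p[1L]), character(1))
  taxa <- lapply(parts, function(p) trimws(strsplit(p[2L], ",", fixed = TRUE)[[1L]]))
  names(taxa) <- nm
  category_map(taxa)
}

#' The default 13-category scheme for food-producing and adulteration-related
#' animals
#'
#' Convenience loader for the config shipped with the package: 13 meat
#' categories (pork, beef, mutton, chicken, rabbit, rat, venison, horse,
#' camel, bear, dog, cat, fox) with representative genera. Membership is a
#' starting point and fully user-configurable via [load_category_map()].
#'
#' @return a [category_map()] with 13 categories.
#' @export
default_category_map <- function() {
  load_category_map(system.file("extdata", "categories_13.cfg",
                                package = "meatseq", mustWork = TRUE))
}

# Lower-cased matchable tokens of one record: species-name words plus any
# explicit taxon labels.
record_tokens <- function(species, taxa) {
  tok <- c(strsplit(species, "\\s+")[[1L]],
           strsplit(taxa, ";", fixed = TRUE)[[1L]])
  unique(tolower(tok[nzchar(tok)]))
}

#' Assign reference records to meat categories
#'
#' Keeps exactly the records whose taxon tokens (species-name words plus
#' explicit taxon labels, matched case-insensitively as whole tokens) occur in
#' some category's taxon list, and pairs each with that category. Records
#' matching no category are dropped; a record matching two categories is an
#' error. Input order is preserved.
#'
#' @param records a [genome_records()] data frame.
#' @param cmap a [category_map()].
#' @return the retained records with an added `category` column.
#' @export
filter_records <- function(records, cmap) {
  stopifnot(inherits(cmap, "category_map"))
  if (nrow(records) == 0L) {
    records$category <- character(0)
    return(records)
  }
  cat_taxa <- lapply(cmap, tolower)
  hits <- vapply(seq_len(nrow(records)), function(i) {
    tok <- record_tokens(records$species[i], records$taxa[i])
    m <- names(cmap)[vapply(cat_taxa, function(tx) any(tok %in% tx), logical(1))]
    if (length(m) > 1L) {
      stop("record ", records$accession[i], " matches multiple categories: ",
           paste(m, collapse = ", "))
    }
    if (length(m) == 0L) NA_character_ else m
  }, character(1))
  out <- records[!is.na(hits), , drop = FALSE]
  out$category <- hits[!is.na(hits)]
  rownames(out) <- NULL
  out
}

# --- k-mer index / ReferenceDB ---------------------------------------------

#' Build an indexed reference database
#'
#' Indexes every k-mer of every genome (both strands are queryable) for the
#' internal seed-and-extend read mapper, replacing the external aligner index
#' of the original workflow. IUPAC ambiguity codes are stored literally and
#' never seed a match.
#'
#' @param records a [genome_records()] data frame, normally the output of
#'   [filter_records()] (a `category` column is added as "uncategorized" when
#'   absent).
#' @param k k-mer size, `11 <= k <= 31`; default 21 is specific enough for
#'   ~16-kb mitogenomes while tolerant of errors in 300-bp reads.
#' @return an object of class `reference_db`.
#' @export
build_index <- function(records, k = 21L) {
  k <- as.integer(k)
  if (k < 11L || k > 31L) stop("k must be between 11 and 31")
  if (nrow(records) == 0L) stop("no records to index")
  if (!"category" %in% names(records)) records$category <- "uncategorized"
  short <- records$length < k
  if (any(short)) {
    stop("k = ", k, " exceeds the length of genome(s): ",
         paste(records$accession[short], collapse = ", "))
  }
  db <- structure(
    list(records = records, k = k, cache = new.env(parent = emptyenv())),
    class = "reference_db"
  )
  db$cache$ptr <- kmer_index_build(records$sequence, k)
  db
}

# Return a live index pointer, rebuilding transparently (external pointers do
# not survive serialization).
db_index <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  p <- db$cache$ptr
  if (is.null(p) || !kmer_index_valid(p)) {
    p <- kmer_index_build(db$records$sequence, db$k)
    db$cache$ptr <- p
  }
  p
}

db_categories <- function(db) unique(db$records$category)

#' Look up one k-mer in a reference database
#'
#' Exact lookup on both strands. A minus-strand hit at position `p` means the
#' k-mer's reverse complement occupies forward-strand positions
#' `[p, p + k)`. Positions are 0-based.
#'
#' @param db a `reference_db`.
#' @param kmer a string of length `db$k`.
#' @return data frame with columns `accession`, `position`, `strand`.
#' @export
lookup_kmer <- function(db, kmer) {
  hits <- kmer_index_lookup(db_index(db), toupper(kmer))
  data.frame(
    accession = db$records$accession[hits$genome],
    position = hits$position,
    strand = hits$strand,
    stringsAsFactors = FALSE
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference DB:", nrow(x$records), "genomes,",
      length(db_categories(x)), "categories, k =", x$k, "\n")
  tab <- table(x$records$category)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

DB_FORMAT_VERSION <- "1"

#' Persist / restore a reference database
#'
#' `save_db()` writes a database directory holding the genomes as FASTA, a
#' CSV manifest (accession, species, category, taxa, length) and a metadata
#' file; `load_db()` restores it and rebuilds the k-mer index, reproducing
#' lookup and classification behaviour exactly. All files are plain text.
#'
#' @param db a `reference_db`.
#' @param dir database directory.
#' @return `save_db()` the directory invisibly; `load_db()` a `reference_db`.
#' @export
save_db <- function(db, dir) {
  stopifnot(inherits(db, "reference_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(db$records$sequence)
  names(ss) <- paste(db$records$accession, db$records$species)
  Biostrings::writeXStringSet(ss, file.path(dir, "genomes.fa"))
  utils::write.csv(
    db$records[, c("accession", "species", "category", "taxa", "length")],
    file.path(dir, "manifest.csv"), row.names = FALSE
  )
  writeLines(c(paste0("version: ", DB_FORMAT_VERSION), paste0("k: ", db$k)),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname save_db
#' @export
load_db <- function(dir) {
  need <- file.path(dir, c("genomes.fa", "manifest.csv", "meta.txt"))
  if (!dir.exists(dir)) stop("database directory not found: ", dir)
  if (!all(file.exists(need))) {
    stop("corrupted database directory (missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "), "): ", dir)
  }
  meta <- readLines(file.path(dir, "meta.txt"))
  ver <- sub("^version:\\s*", "", grep("^version:", meta, value = TRUE))
  if (!identical(ver, DB_FORMAT_VERSION)) {
    stop("database format version mismatch: found '", ver,
         "', expected '", DB_FORMAT_VERSION, "'")
  }
  k <- as.integer(sub("^k:\\s*", "", grep("^k:", meta, value = TRUE)))
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(taxa = "character"))
  ss <- Biostrings::readDNAStringSet(file.path(dir, "genomes.fa"))
  acc <- sub("\\s.*$", "", names(ss))
  m <- match(man$accession, acc)
  if (anyNA(m)) stop("corrupted database: manifest/FASTA accession mismatch")
  rec <- genome_records(man$accession, man$species,
                        as.character(ss)[m], man$taxa)
  rec$category <- man$category
  build_index(rec, k)
}

#' Build a reference database in one call
#'
#' Convenience wrapper: read genomes, assign categories, index.
#'
#' @param fasta reference FASTA path.
#' @param cmap a [category_map()] or path to a category config file.
#' @param k k-mer size (see [build_index()]).
#' @return a `reference_db`.
#' @export
build_reference_db <- function(fasta, cmap, k = 21L) {
  if (is.character(cmap)) cmap <- load_category_map(cmap)
  rec <- read_genomes(fasta)
  kept <- filter_records(rec, cmap)
  if (nrow(kept) == 0L) stop("no records match any category")
  build_index(kept, k)
}
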