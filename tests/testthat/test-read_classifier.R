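test_that("map_read: exact substrings, misses, and errored reads vs the offset oracle", {
  set.seed(101)
  rec <- genome_records(paste0("G", 1:3), paste0("Genus", 1:3, " sp"),
                        replicate(3, rand_genome(2000)))
  rec$category <- c("a", "b", "c")
  db <- build_index(rec, 21L)

  # exact 150-bp substring: one perfect hit at the true position
  h <- map_read(substr(rec$sequence[2], 301, 450), db)
  expect_identical(h$accession, "G2")
  expect_identical(h$position, 300L)
  expect_identical(h$identity, 1.0)
  expect_identical(h$aligned_length, 150L)
  expect_identical(h$strand, "+")

  # minus strand
  h2 <- map_read(revcomp(substr(rec$sequence[2], 301, 450)), db)
  expect_identical(h2$position, 300L)
  expect_identical(h2$strand, "-")

  # random read sharing no k-mer: empty
  expect_identical(nrow(map_read(rand_genome(150), db)), 0L)

  expect_error(map_read("ACGT", db), "shorter than")

  # reads with 2 substitutions: position and mismatch count equal the
  # exhaustive-offset Hamming oracle
  for (i in 1:20) {
    g <- sample(3, 1)
    pos <- sample(1800, 1)
    read <- substr(rec$sequence[g], pos, pos + 99)
    at <- sample(100, 2)
    for (p in at) {
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(read, p, p)), 1)
    }
    if (i %% 2 == 0) read <- revcomp(read)
    got <- map_read(read, db, min_identity = 0.9)
    for (gg in 1:3) {
      want <- oracle_best_hit(rec$sequence[gg], read, 0.9)
      have <- got[got$accession == rec$accession[gg], ]
      if (is.null(want)) {
        expect_identical(nrow(have), 0L)
      } else {
        expect_identical(nrow(have), 1L)
        expect_identical(have$position, as.integer(want$pos))
        expect_identical(have$matches, as.integer(want$matches))
      }
    }
  }
})

test_that("classify_hits implements the unique-read rule", {
  w <- small_world(seed = 55)
  db <- world_db(w)
  acc_of <- split(db$records$accession, db$records$category)
  beef3 <- data.frame(accession = rep(acc_of$beef, length.out = 3))
  expect_identical(classify_hits(beef3, db), "beef")
  expect_identical(
    classify_hits(data.frame(accession = c(acc_of$beef[1], acc_of$pork[1])),
                  db),
    "DISCARDED")
  expect_identical(classify_hits(data.frame(accession = character(0)), db),
                   "UNMAPPED")
  expect_error(classify_hits(data.frame(accession = "NOPE"), db),
               "absent from the database")
})

test_that("classify_fastq tallies, conserves and matches a per-read oracle", {
  # high between-category divergence keeps every cross-category alignment far
  # from the identity threshold except inside the conserved block, so the
  # seeded mapper and the unseeded oracle cannot disagree on borderline hits
  w <- small_world(seed = 9, categories = c("pork", "beef", "mutton"),
                   between_divergence = 0.30,
                   conserved_blocks = list(
                     list(length = 120, categories = c("beef", "mutton"))))
  db <- world_db(w)

  # error-free single-category reads, drawn clear of the conserved block
  fq <- withr::local_tempfile(fileext = ".fastq")
  sim <- simulate_reads(w, 100, c(pork = 1), read_length = 120,
                        error_rate = 0, seed = 2, fastq = fq)
  cc <- classify_fastq(fq, db)
  expect_identical(unname(cc$counts["pork"]), 100L)
  expect_identical(cc$discarded, 0L)
  expect_identical(cc$unmapped, 0L)
  expect_identical(cc$total_reads, 100L)

  # empty FASTQ
  writeLines(character(0), fq)
  cc0 <- classify_fastq(fq, db)
  expect_identical(cc0$total_reads, 0L)
  expect_identical(sum(cc0$counts), 0L)

  # mixed reads crossing the conserved block: tallies equal a per-read
  # brute-force oracle
  sim <- simulate_reads(w, 120, c(pork = 0.3, beef = 0.4, mutton = 0.3),
                        read_length = 100, error_rate = 0.005, seed = 3,
                        fastq = fq)
  cc <- classify_fastq(fq, db, per_read = TRUE)
  oracle <- vapply(sim$reads$seq, function(r) {
    cats <- character(0)
    for (g in seq_len(nrow(db$records))) {
      hit <- oracle_best_hit(db$records$sequence[g], r, 0.9)
      if (!is.null(hit)) cats <- c(cats, db$records$category[g])
    }
    oracle_decision(cats)
  }, character(1), USE.NAMES = FALSE)
  expect_identical(attr(cc, "per_read")$decision, oracle)
  for (cat in names(cc$counts)) {
    expect_identical(unname(cc$counts[cat]), sum(oracle == cat))
  }
  expect_identical(cc$discarded, sum(oracle == "DISCARDED"))
  # reads inside the block really are discarded (the rule has teeth here)
  expect_gt(cc$discarded, 0L)

  # conservation + permutation invariance
  expect_identical(sum(cc$counts) + cc$discarded + cc$unmapped, 120L)
  perm <- with_seed(7, sample(120))
  cc_perm <- classify_reads(sim$reads$seq[perm], db)
  expect_identical(cc_perm$counts, cc$counts)

  # malformed FASTQ reports the record number
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), fq)
  expect_error(classify_fastq(fq, db), "record 2|truncated record 2")

  # short reads count as unmapped with a warning
  expect_warning(ccs <- classify_reads(c("ACGTACGT"), db), "unmapped")
  expect_identical(ccs$unmapped, 1L)
})

test_that("no false positives from error-free single-category reads", {
  w <- small_world(seed = 10)
  db <- world_db(w)
  sim <- simulate_reads(w, 300, c(beef = 1), read_length = 150,
                        error_rate = 0, seed = 4)
  cc <- classify_reads(sim$reads$seq, db)
  expect_identical(unname(cc$counts["beef"]) + cc$discarded, 300L)
  expect_true(all(cc$counts[setdiff(names(cc$counts), "beef")] == 0L))
})

test_that("ingest_sam groups records by read and applies the same rule", {
  w <- small_world(seed = 12)
  db <- world_db(w)
  acc <- split(db$records$accession, db$records$category)
  sam <- withr::local_tempfile(fileext = ".sam")

  # one read, one pork alignment
  write_sam("r1", 0L, acc$pork[1], sam)
  cc <- ingest_sam(sam, db)
  expect_identical(unname(cc$counts["pork"]), 1L)
  expect_identical(cc$total_reads, 1L)

  # primary + secondary in two categories: discarded
  write_sam(c("r1", "r1"), c(0L, 256L), c(acc$pork[1], acc$beef[1]), sam)
  cc <- ingest_sam(sam, db)
  expect_identical(cc$discarded, 1L)
  expect_identical(sum(cc$counts), 0L)

  # unmapped flag wins regardless of fields
  write_sam("r9", 4L, acc$pork[1], sam, refs = acc$pork[1])
  cc <- ingest_sam(sam, db)
  expect_identical(cc$unmapped, 1L)

  # unknown reference name
  write_sam("r1", 0L, "NOT_A_REF", sam)
  expect_error(ingest_sam(sam, db), "NOT_A_REF")

  # 200-record synthetic SAM with known truth vs a grouping oracle
  set.seed(77)
  qn <- sprintf("q%03d", sample(60, 200, replace = TRUE))
  rn <- sample(db$records$accession, 200, replace = TRUE)
  fl <- sample(c(0L, 16L, 256L), 200, replace = TRUE)
  unm <- sample(200, 15)
  fl[unm] <- 4L
  rn[unm[1:7]] <- "*"
  write_sam(qn, fl, rn, sam, refs = db$records$accession)
  cc <- ingest_sam(sam, db, per_read = TRUE)
  truth <- tapply(seq_along(qn), qn, function(ix) {
    mapped <- ix[bitwAnd(fl[ix], 4L) == 0L & rn[ix] != "*"]
    oracle_decision(db$records$category[match(rn[mapped],
                                              db$records$accession)])
  })
  for (cat in names(cc$counts)) {
    expect_identical(unname(cc$counts[cat]), sum(truth == cat))
  }
  expect_identical(cc$discarded, sum(truth == "DISCARDED"))
  expect_identical(cc$unmapped, sum(truth == "UNMAPPED"))
  expect_identical(cc$total_reads, length(unique(qn)))
})

test_that("classify_fastq and ingest_sam agree when fed the same hit sets", {
  w <- small_world(seed = 14)
  db <- world_db(w)
  sim <- simulate_reads(w, 150, c(pork = 0.4, beef = 0.3, mutton = 0.3),
                        read_length = 120, error_rate = 0.01, seed = 5)
  cc <- classify_reads(sim$reads$seq, db, ids = sim$reads$id,
                       per_read = TRUE)
  # rebuild a SAM holding exactly the internal mapper's hit genomes
  qn <- character(0); fl <- integer(0); rn <- character(0)
  for (i in seq_len(nrow(sim$reads))) {
    h <- map_read(sim$reads$seq[i], db)
    if (nrow(h) == 0) {
      qn <- c(qn, sim$reads$id[i]); fl <- c(fl, 4L); rn <- c(rn, "*")
    } else {
      qn <- c(qn, rep(sim$reads$id[i], nrow(h)))
      fl <- c(fl, rep(0L, nrow(h)))
      rn <- c(rn, h$accession)
    }
  }
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(qn, fl, rn, sam, refs = db$records$accession)
  cs <- ingest_sam(sam, db)
  expect_identical(cs$counts, cc$counts)
  expect_identical(cs$discarded, cc$discarded)
  expect_identical(cs$unmapped, cc$unmapped)
})
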