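test_that("IUPAC patterns compile with correct degeneracy", {
  expect_equal(compile_pattern("N")$degeneracy, 4)
  expect_equal(compile_pattern("TGASWMAKCN")$degeneracy, 64)
  expect_equal(are_consensus()$pattern, "TGASWMAKCN")
  expect_error(compile_pattern("TGAX"), "X")
  expect_error(compile_pattern(""), "non-empty")
})

test_that("scan_motif finds consensus matches on both strands", {
  hit <- scan_motif("TGACTCAGCA", are_consensus(), strands = "forward")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 10L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$matched_text, "TGACTCAGCA")

  # reverse complement of the previous example: one minus-strand hit
  rc <- scan_motif("TGCTGAGTCA", are_consensus(), strands = "both")
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 0L)
  expect_equal(rc$matched_text, "TGCTGAGTCA")   # forward-strand slice

  # shorter than the pattern: empty result, not an error
  expect_equal(nrow(scan_motif("AAAAAAAAA", are_consensus())), 0L)

  # sequence N matches only pattern N positions
  expect_equal(nrow(scan_motif("TGACTCAGCN", are_consensus())), 1L)
  expect_equal(nrow(scan_motif("NGACTCAGCA", are_consensus())), 0L)

  expect_error(scan_motif("TGAXTCAGCA", are_consensus()), "non-ACGTN")
})

test_that("scan_motif equals the 64-expansion brute-force oracle", {
  for (s in 1:4) {
    seq <- random_dna(500, seed = 1000 + s)
    mine <- scan_motif(seq, are_consensus(), strands = "both")
    ref <- oracle_scan(seq)
    key <- function(d) sort(paste(d$start, d$strand))
    expect_identical(key(mine), key(ref))
  }
})

test_that("strand symmetry: hits on revcomp(S) mirror minus-strand hits on S", {
  seq <- random_dna(800, seed = 77)
  L <- nchar(seq)
  m <- are_consensus()$length
  fwd_on_rc <- scan_motif(reverse_complement(seq), are_consensus(),
                          strands = "forward")
  minus_on_s <- scan_motif(seq, are_consensus(), strands = "both")
  minus_on_s <- minus_on_s[minus_on_s$strand == "-", ]
  expect_setequal(L - fwd_on_rc$start - m, minus_on_s$start)
})

test_that("hit counts on uniform background match the occupancy expectation", {
  # expected hits ~ 2 * (L - 9) * 64 / 4^10 per strand-pair on iid ACGT
  L <- 5000
  n_seq <- 60
  counts <- vapply(seq_len(n_seq), function(i)
    nrow(scan_motif(random_dna(L, seed = 42000 + i), are_consensus())), 0L)
  expected <- 2 * (L - 9) * 64 / 4^10
  se <- sd(counts) / sqrt(n_seq)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("extract_upstream applies strand-aware window arithmetic", {
  seqc <- random_dna(3000, seed = 5)
  plus <- extract_upstream(seqc, list(locus_id = "g1", sequence_id = "c",
                                      start = 1500, end = 3000,
                                      strand = "+"), 1000)
  expect_equal(c(plus$start, plus$end), c(500, 1500))
  expect_false(plus$truncated)
  expect_equal(plus$seq, toupper(substring(seqc, 501, 1500)))

  trunc <- extract_upstream(seqc, list(locus_id = "g2", sequence_id = "c",
                                       start = 300, end = 900,
                                       strand = "+"), 1000)
  expect_equal(c(trunc$start, trunc$end), c(0, 300))
  expect_true(trunc$truncated)

  minus <- extract_upstream(seqc, list(locus_id = "g3", sequence_id = "c",
                                       start = 500, end = 1500,
                                       strand = "-"), 1000)
  expect_equal(c(minus$start, minus$end), c(1500, 2500))
  expect_equal(minus$seq,
               reverse_complement(toupper(substring(seqc, 1501, 2500))))

  expect_error(extract_upstream(seqc, list(locus_id = "g4",
                                           sequence_id = "c", start = 2500,
                                           end = 3500, strand = "+"), 1000),
               "outside")
})

test_that("count_ares recovers planted motifs and keeps zero-hit loci", {
  pr <- generate_promoters(n_seqs = 6, planted_counts = c(3, 2, 0, 1, 2, 3),
                           seed = 42)
  res <- count_ares(pr$sequences, pr$loci)
  expect_equal(nrow(res$counts), 6L)
  expect_true(all(res$counts$n_hits >= c(3, 2, 0, 1, 2, 3)))
  # every planted position is among the reported hits
  planted_keys <- paste(pr$truth$sequence_id, pr$truth$start,
                        pr$truth$strand)
  hit_keys <- paste(res$hits$sequence_id, res$hits$start, res$hits$strand)
  expect_true(all(planted_keys %in% hit_keys))

  # a window of pure C yields no hits
  res0 <- count_ares(c(solo = strrep("C", 1500)),
                     data.frame(sequence_id = "solo", start = 1000,
                                end = 1500, locus_id = "g", strand = "+"))
  expect_equal(res0$counts$n_hits, 0L)
  expect_equal(nrow(res0$hits), 0L)

  # loci sharing a window are scanned independently
  two <- rbind(pr$loci[1, ], transform(pr$loci[1, ], locus_id = "dup"))
  res2 <- count_ares(pr$sequences, two)
  expect_equal(res2$counts$n_hits[1], res2$counts$n_hits[2])

  expect_error(count_ares(pr$sequences,
                          data.frame(sequence_id = "nope", start = 0,
                                     end = 10, locus_id = "g",
                                     strand = "+")),
               "nope")
})

test_that("FASTA and BED round-trip through the standard readers", {
  pr <- generate_promoters(n_seqs = 3, planted_counts = 2, seed = 42)
  d <- withr::local_tempdir()
  synth_write(promoters = pr, dir = d)
  direct <- count_ares(pr$sequences, pr$loci)
  from_files <- count_ares(file.path(d, "promoters.fa"),
                           file.path(d, "loci.bed"))
  expect_equal(from_files$counts, direct$counts)
  expect_equal(from_files$hits, direct$hits)
})
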