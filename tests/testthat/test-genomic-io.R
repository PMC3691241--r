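test_that("FASTA parsing preserves case and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTacgt"), fa)
  seqs <- read_fasta(fa)
  expect_named(seqs, "chr1")
  expect_equal(nchar(seqs), c(chr1 = 8L))
  expect_equal(nchar(gsub("[^acgtn]", "", seqs[["chr1"]])), 4L)

  writeLines(character(0), fa)
  expect_length(read_fasta(fa), 0L)

  writeLines(c(">chr1", "ACXT"), fa)
  expect_error(read_fasta(fa), "line 2", class = "mirtss_validation_error")

  writeLines(c("ACGT"), fa)
  expect_error(read_fasta(fa), "header", class = "mirtss_validation_error")
})

test_that("FASTA round-trip is exact regardless of line wrapping", {
  fa <- withr::local_tempfile(fileext = ".fa")
  set.seed(11)
  seqs <- c(a = rand_masked_window(257), b = rand_masked_window(63))
  write_fasta(seqs, fa, line_width = 17L)
  back <- read_fasta(fa)
  expect_identical(unname(back[names(seqs)]), unname(seqs))
  # features are invariant to wrapping and record order
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rev(seqs), fa2, line_width = 80L)
  back2 <- read_fasta(fa2)
  expect_identical(nmer_features(back[["a"]]), nmer_features(back2[["a"]]))
})

test_that("BED parsing keeps order, validates intervals and strand", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t1100\ts1\t0\t+",
               "chr2\t40\t60\ts2\t0\t-"), bed)
  r <- read_bed(bed)
  expect_equal(r$chrom, c("chr1", "chr2"))
  expect_equal(r$start, c(100L, 40L))
  expect_equal(r$end, c(1100L, 60L))
  expect_equal(r$strand, c("+", "-"))

  writeLines("chr1\t5\t5\ts\t0\t+", bed)
  expect_error(read_bed(bed), class = "mirtss_validation_error")

  writeLines("chr1\t5\t10\ts\t0", bed)
  expect_error(read_bed(bed), class = "mirtss_validation_error")
})

test_that("methylation track reading shifts coordinates and validates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t101\t0.90\t12", tsv)
  tr <- read_methylation_track(tsv, "ctrl01")
  expect_equal(tr$sample_id, "ctrl01")
  expect_equal(tr$sites$pos, 100L)
  expect_equal(tr$sites$p, 0.9)
  expect_equal(tr$sites$r, 12L)

  writeLines("chr1\t101\t1.5\t12", tsv)
  expect_error(read_methylation_track(tsv, "x"), "\\[0,1\\]",
               class = "mirtss_validation_error")

  writeLines(c("chr1\t101\t0.5\t12", "chr1\t101\t0.6\t3"), tsv)
  expect_error(read_methylation_track(tsv, "x"), "101",
               class = "mirtss_validation_error")

  writeLines("chr1\t101\t0.5\t-2", tsv)
  expect_error(read_methylation_track(tsv, "x"), "coverage",
               class = "mirtss_validation_error")
})

test_that("window extraction is strand-aware and bounds-checked", {
  set.seed(7)
  genome <- c(chr1 = rand_dna(2000))
  plus <- extract_window(genome, list(chrom = "chr1", start = 500, end = 501,
                                      strand = "+", name = "p"))
  expect_equal(plus$region$start, 0L)
  expect_equal(plus$region$end, 1000L)
  expect_identical(plus$seq, substr(genome[["chr1"]], 1, 1000))

  minus <- extract_window(genome, list(chrom = "chr1", start = 500, end = 501,
                                       strand = "-", name = "m"))
  expect_equal(minus$region$start, 1L)
  expect_equal(minus$region$end, 1001L)
  expect_identical(minus$seq, naive_revcomp(substr(genome[["chr1"]], 2, 1001)))

  # hand-checked 10 bp toy genome
  toy <- c(c1 = "AAcgTTGCAN")
  w <- extract_window(toy, list(chrom = "c1", start = 4, end = 5, strand = "-"),
                      upstream = 2L, total_len = 6L)
  # genomic span [1, 7) = "AcgTTG"; reverse complement preserving case,
  # with the TSS base (0-based 4) preceded by exactly 2 transcript bases
  expect_identical(w$seq, "CAAcgT")

  expect_error(extract_window(genome, list(chrom = "chr1", start = 100,
                                           end = 101, strand = "+")),
               "exceeds", class = "mirtss_validation_error")
  expect_error(extract_window(genome, list(chrom = "chrX", start = 500,
                                           end = 501, strand = "+")),
               class = "mirtss_validation_error")
})

test_that("plus-strand window plus reverse complement mirrors the minus call", {
  set.seed(21)
  genome <- c(chr1 = rand_dna(400))
  for (pos in c(150L, 200L, 260L)) {
    plus <- extract_window(genome, list(chrom = "chr1", start = pos,
                                        end = pos + 1L, strand = "+"),
                           upstream = 50L, total_len = 100L)
    # the minus-strand locus whose genomic span coincides with the plus window
    mirrored <- extract_window(genome,
                               list(chrom = "chr1",
                                    start = plus$region$end - 51L,
                                    end = plus$region$end - 50L, strand = "-"),
                               upstream = 50L, total_len = 100L)
    expect_identical(mirrored$region$start, plus$region$start)
    expect_identical(mirrored$seq, naive_revcomp(plus$seq))
  }
})
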