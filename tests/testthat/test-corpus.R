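toy_genome <- function() {
  withr::with_seed(5, {
    chr1 <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  })
  genome_source(c(chr1 = chr1, tiny = "ACGTACGT"))
}

test_that("genome access is case-preserving and bounds-checked", {
  g <- genome_source(c(chr1 = "ACGTacgtNn"))
  expect_equal(get_sequence(g, "chr1", 2, 8), "GTacgt")
  expect_error(get_sequence(g, "chr1", -1, 4), "outside bounds")
  expect_error(get_sequence(g, "chr1", 0, 11), "outside bounds")
  expect_error(get_sequence(g, "chrX", 0, 1), "unknown chromosome")
  expect_error(genome_source(c(c1 = "ACGU")), "invalid character")
})

test_that("BED parsing names the offending line", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t360", "chr1\t50", "chr1\t5\t400"), p)
  expect_error(read_bed(p), "line 2")
  writeLines(c("# comment", "chr1\t10\t360", "chr1\tx\t20"), p)
  expect_error(read_bed(p), "line 3")
  writeLines(c("track name=x", "chr1\t10\t360\tpeak1"), p)
  bed <- read_bed(p)
  expect_equal(bed$start, 10L)
  expect_equal(bed$name, "peak1")
})

test_that("windows are center-expanded and center-cropped", {
  g <- toy_genome()
  bed <- tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 1000L, 1000L),
    end = c(1350L, 1200L, 1500L)
  )
  w <- load_windows(bed, g, window = 350L)
  # length-350 interval unchanged
  expect_equal(c(w$start[1], w$end[1]), c(1000L, 1350L))
  # length-200 interval expands symmetrically about the midpoint
  expect_equal(c(w$start[2], w$end[2]), c(925L, 1275L))
  # length-500 interval keeps the central 350 bp
  expect_equal(c(w$start[3], w$end[3]), c(1075L, 1425L))
  expect_true(all(nchar(w$seq) == 350L))
  expect_equal(w$seq[1], get_sequence(g, "chr1", 1000, 1350))
})

test_that("edge-crossing windows are clamped or skipped with warnings", {
  g <- toy_genome()
  bed <- tibble::tibble(chrom = c("chr1", "tiny"), start = c(0L, 0L), end = c(10L, 8L))
  expect_warning(expect_warning(
    w <- load_windows(bed, g, window = 350L),
    "skipped"
  ), "clamped")
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end), c(0L, 350L))
})

test_that("chromosome splits follow the held-out sets", {
  expect_equal(assign_split("chr6"), "val")
  expect_equal(assign_split("chr21"), "val")
  expect_equal(assign_split("chr5"), "test")
  expect_equal(assign_split("chr1"), "train")
  # names with and without the chr prefix resolve identically
  expect_equal(assign_split(c("6", "chr10", "14", "chrX")),
               c("val", "test", "test", "train"))
  expect_error(split_spec(val_chroms = "chr5"), "both")
})

test_that("repeat-run annotation reports maximal runs above the threshold", {
  below <- paste0("AC", strrep("a", 29), "GT")
  at <- paste0("AC", strrep("a", 30), "GT")
  expect_equal(nrow(annotate_repeat_runs(below, 30)), 0L)
  runs <- annotate_repeat_runs(at, 30)
  expect_equal(unname(runs[1, ]), c(2L, 32L))
  expect_equal(nrow(annotate_repeat_runs(strrep("ACGT", 20), 30)), 0L)
  two <- paste0(strrep("a", 35), "ACGT", strrep("g", 40))
  runs2 <- annotate_repeat_runs(two, 30)
  expect_equal(nrow(runs2), 2L)
  expect_equal(unname(runs2[2, ]), c(39L, 79L))
  expect_error(annotate_repeat_runs("ACUG"), "invalid character")
})

test_that("identity augmentation policy returns identical records", {
  g <- toy_genome()
  bed <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1350L)
  corpus <- load_windows(bed, g, window = 350L)
  withr::with_seed(1, {
    out <- augment_corpus(corpus, augmentation_policy(rc_prob = 0, shift_range = c(0L, 0L)), g)
  })
  expect_identical(out$seq, corpus$seq)
  expect_identical(out$start, corpus$start)
})

test_that("reverse complement remaps repeat runs onto lowercase characters", {
  seq <- paste0(strrep("A", 5), strrep("acgt" , 10), strrep("G", 10))
  corpus <- tibble::tibble(
    chrom = "c", start = 0L, end = nchar(seq), seq = seq, split = "train",
    repeat_runs = list(annotate_repeat_runs(seq))
  )
  withr::with_seed(3, {
    out <- augment_corpus(corpus, augmentation_policy(rc_prob = 1, shift_range = c(0L, 0L)))
  })
  expect_equal(out$seq[1], reverse_complement(seq))
  runs <- out$repeat_runs[[1]]
  expect_equal(nrow(runs), 1L)
  chars <- strsplit(out$seq[1], "")[[1]]
  expect_true(all(chars[(runs[1, 1] + 1):runs[1, 2]] %in% c("a", "c", "g", "t")))
  # double reverse complement restores the original record
  withr::with_seed(3, {
    back <- augment_corpus(out, augmentation_policy(rc_prob = 1, shift_range = c(0L, 0L)))
  })
  expect_equal(back$seq[1], seq)
  expect_equal(back$repeat_runs[[1]], corpus$repeat_runs[[1]])
})

test_that("augmentation shifts stay inside the stated range and re-extract", {
  g <- toy_genome()
  bed <- tibble::tibble(chrom = rep("chr1", 50), start = 1000L, end = 1350L)
  corpus <- load_windows(bed, g, window = 350L)
  withr::with_seed(9, {
    out <- augment_corpus(corpus, augmentation_policy(rc_prob = 0), g)
  })
  shifts <- out$start - corpus$start
  expect_true(all(shifts >= -50 & shifts <= 50))
  expect_true(length(unique(shifts)) > 5)
  for (i in seq_len(5)) {
    expect_equal(out$seq[i], get_sequence(g, "chr1", out$start[i], out$end[i]))
  }
})

test_that("corpus FASTA round trip preserves sequence and case exactly", {
  seqs <- c(
    paste0("ACGT", strrep("acgtn", 8), "NNGT"),
    strrep("GAttaca", 10)
  )
  corpus <- tibble::tibble(
    chrom = c("w1", "w2"), start = 0L, end = nchar(seqs), seq = seqs,
    split = c("train", "val"),
    repeat_runs = lapply(seqs, annotate_repeat_runs)
  )
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corpus, fa, tsv)
  back <- read_corpus(fa, tsv)
  expect_identical(back$seq, corpus$seq)
  expect_identical(back$split, corpus$split)
  # writing again is byte-stable
  fa2 <- withr::local_tempfile(fileext = ".fa")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(back, fa2, tsv2)
  expect_identical(readLines(fa), readLines(fa2))
})

test_that("every chromosome maps to exactly one split", {
  chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
  s <- assign_split(chroms)
  expect_true(all(s %in% c("train", "val", "test")))
  expect_equal(sum(s == "val"), 2L)
  expect_equal(sum(s == "test"), 6L)
})
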