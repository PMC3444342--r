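test_that("normalize_sequence uppercases, maps U->T, strips whitespace, handles ambiguity", {
  expect_identical(normalize_sequence("acgu"), "ACGT")
  expect_identical(normalize_sequence("ACGT N"), "ACGTN")
  expect_warning(out <- normalize_sequence("ACRT"), "ambiguity")
  expect_identical(out, "ACNT")
  expect_error(normalize_sequence("ACRT", strict = TRUE), "ambiguity code 'R'",
               class = "period3_format_error")
  expect_error(normalize_sequence("ACGX"), "'X'", class = "period3_format_error")
})

test_that("normalize_sequence is idempotent", {
  set.seed(7)
  for (i in 1:20) {
    raw <- paste(sample(c("a", "c", "G", "t", "u", "n", " ", "\n"), 50, TRUE),
                 collapse = "")
    once <- normalize_sequence(raw)
    expect_identical(normalize_sequence(once), once)
  }
})

test_that("read_fasta parses records in order with normalized residues", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 first record", "acgt", ">s2", "AC", "GTN"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_identical(recs[[1]]$id, "s1")
  expect_identical(recs[[1]]$residues, "ACGT")
  expect_identical(recs[[1]]$length, 4L)
  expect_identical(recs[[2]]$residues, "ACGTN")
})

test_that("read_fasta rejects missing, empty, headerless, and bad-alphabet files", {
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "cannot open")
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_error(read_fasta(f), "empty", class = "period3_format_error")
  writeLines(c("ACGT"), f)
  expect_error(read_fasta(f), "line 1", class = "period3_format_error")
  writeLines(c(">s1", "ACGX"), f)
  expect_error(read_fasta(f), "'X'", class = "period3_format_error")
})

test_that("write_fasta / read_fasta round-trips id and residues", {
  seqs <- list(dna_seq("ACGTACGTNN", id = "a"), dna_seq(random_dna(200, seed = 1), id = "b"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(lapply(back, `[[`, "id"), lapply(seqs, `[[`, "id"))
  expect_identical(lapply(back, `[[`, "residues"), lapply(seqs, `[[`, "residues"))
})

test_that("read_interval_table reads BED3+ as 0-based half-open, in file order", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\texon1", "chr1\t5\t8"), f)
  iv <- read_interval_table(f)
  expect_equal(iv$start, c(10, 5))
  expect_equal(iv$end, c(20, 8))
  expect_identical(iv$label, c("exon1", NA_character_))

  file.create(f2 <- withr::local_tempfile(fileext = ".bed"))
  expect_equal(nrow(read_interval_table(f2)), 0L)

  writeLines("chr1\t20\t10", f)
  expect_error(read_interval_table(f), "line 1", class = "period3_format_error")
})

test_that("write_track emits the documented bedGraph lines and rejects empty tracks", {
  tr <- scan("AAACCC", scan_config(window = 3, anchor = "start"))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_track(tr, f)
  expect_identical(readLines(f),
                   c("seq\t0\t1\t0", "seq\t1\t2\t2", "seq\t2\t3\t2", "seq\t3\t4\t0"))

  one <- period3:::new_power_track("s1", 0, 2.0, scan_config(window = 3, anchor = "start"))
  write_track(one, f)
  expect_identical(readLines(f), "s1\t0\t1\t2")

  empty <- period3:::new_power_track("s1", numeric(0), numeric(0),
                                     scan_config(window = 3, anchor = "start"))
  expect_error(write_track(empty, f), "empty", class = "period3_input_error")
})

test_that("track write/read round-trips anchors and values in both formats", {
  tr <- scan(random_dna(120, seed = 3), scan_config(window = 21, step = 1))
  for (fmt in c("bedgraph", "wig")) {
    f <- withr::local_tempfile()
    write_track(tr, f, format = fmt)
    back <- read_track(f)
    expect_equal(back$positions, tr$positions)
    expect_equal(back$values, tr$values)
  }
})

test_that("bedGraph output partitions coordinates when step = 1", {
  tr <- scan(random_dna(60, seed = 4), scan_config(window = 9))
  f <- withr::local_tempfile()
  write_track(tr, f)
  fields <- do.call(rbind, strsplit(readLines(f), "\t"))
  starts <- as.numeric(fields[, 2])
  ends <- as.numeric(fields[, 3])
  expect_true(all(diff(starts) > 0))
  expect_equal(starts[-1], ends[-length(ends)])  # contiguous, non-overlapping
})

test_that("bedGraph and BED output are readable by rtracklayer", {
  skip_if_not_installed("rtracklayer")
  tr <- scan(random_dna(50, seed = 5), scan_config(window = 9, anchor = "start"))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_track(tr, f)
  gr <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(BiocGenerics::start(gr) - 1L, as.integer(tr$positions))
  expect_equal(gr$score, tr$values)

  b <- withr::local_tempfile(fileext = ".bed")
  write_interval_table(hfe2_exons(), b)
  bed <- rtracklayer::import(b, format = "BED")
  expect_equal(BiocGenerics::start(bed) - 1, hfe2_exons()$start)
  expect_equal(BiocGenerics::end(bed), hfe2_exons()$end)
})
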