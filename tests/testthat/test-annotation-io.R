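test_that("parse_locus_string reproduces printed lengths exactly", {
  loc <- parse_locus_string(c("chr1:48 138 333–48 140 169",
                              "chr1:48 138 680–48 141 264",
                              "chr1:48 138 659–48 141 279"))
  expect_equal(loc$length, c(1836L, 2584L, 2620L))
  expect_equal(loc$chrom, rep("chr1", 3))
  expect_equal(loc$start[1], 48138333L)
  expect_equal(loc$end[1], 48140169L)
  # hyphen instead of en-dash, and no separators, parse identically
  expect_equal(parse_locus_string("chr1:48138333-48140169")$length, 1836L)
  expect_error(parse_locus_string("chr1 48138333 48140169"), "unparseable")
  expect_error(parse_locus_string("chr1:100-50"), "end <= start")
})

test_that("read_bed handles both coordinate conventions and empty input", {
  f0 <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), f0)
  expect_equal(n_records(read_bed(f0)), 0L)

  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t48138333\t48140169\tLOR1a", fb)
  s1 <- read_bed(fb, "bed0_halfopen")
  expect_equal(record_lengths(s1), 1836L)

  fo <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t48138334\t48140169\tLOR1a", fo)
  s2 <- read_bed(fo, "oneinclusive", source_name = s1$source_name)
  expect_equal(record_lengths(s2), 1836L)
  expect_equal(as.data.frame(s1$records), as.data.frame(s2$records))
})

test_that("read_bed rejects malformed lines with a line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\ta", "chr1\tten\t30\tb"), f)
  expect_error(read_bed(f), "line 2.*malformed")
  writeLines(c("chr1\t10\t20\ta", "chr1\t30\t30\tb"), f)
  expect_error(read_bed(f), "line 2.*end <= start")
  writeLines(c("chr1\t10\t20\ta", "chr1\t30\t40\ta"), f)
  expect_error(read_bed(f), "duplicate record_id")
  writeLines("chr1\t10\t20", f)
  expect_error(read_bed(f), "fewer than 4")
})

test_that("write_bed/read_bed round-trips field-for-field", {
  rec <- data.frame(record_id = c("a", "b", "c"), chrom = "chr2",
                    start = c(0L, 100L, 250L), end = c(90L, 200L, 500L),
                    strand = c("+", "-", "*"),
                    family = c("MER31B", NA, "MLT1K"),
                    repeat_class = c("LTR", "LTR", NA),
                    superfamily = c("ERV1", "unassigned", "ERV3"),
                    destruction = c(12.5, NA, 88))
  s <- annotation_set(rec, "demo", "testbuild")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, f)
  s2 <- read_bed(f, "bed0_halfopen", source_name = "demo",
                 genome_build = "testbuild")
  expect_true(annotation_sets_equal(s, s2))

  # empty set -> empty file -> empty set
  e <- mk_set(integer(), integer(), source = "demo")
  write_bed(e, f)
  expect_identical(readLines(f), character())
  expect_equal(n_records(read_bed(f, source_name = "demo")), 0L)
})

test_that("round-trip holds for randomly generated sets", {
  for (seed in c(11, 12, 13)) {
    s <- random_set(100, seed, source = "rt")
    f <- withr::local_tempfile(fileext = ".bed")
    write_bed(s, f)
    s2 <- read_bed(f, source_name = "rt", genome_build = "testbuild")
    expect_true(annotation_sets_equal(s, s2))
  }
})

test_that("record order is deterministic regardless of input order", {
  set.seed(42)
  lines <- sprintf("chr%d\t%d\t%d\tr%03d", sample(1:2, 50, TRUE),
                   st <- sample.int(1000, 50), st + sample.int(300, 50),
                   1:50)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(lines, f1)
  writeLines(rev(lines), f2)
  a <- read_bed(f1, source_name = "x")
  b <- read_bed(f2, source_name = "x")
  expect_equal(as.data.frame(a$records), as.data.frame(b$records))
})

test_that("read_repeatmasker_out parses the standard .out layout", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "",
    "  463  1.3  0.6  1.7  chr1          100     350 (248956072) +  MLT1K          LTR/ERVL-MaLR         1  250    (0)     1",
    "  240 25.1  5.0  1.2  chr1          900    1000 (248955422) C  HERVL-int      LTR/ERVL            (0)  100      1     2"),
    f)
  s <- read_repeatmasker_out(f, source_name = "rm")
  expect_equal(n_records(s), 2L)
  r <- s$records
  expect_equal(r$start, c(99L, 899L))
  expect_equal(r$end, c(350L, 1000L))
  expect_equal(record_lengths(s)[1], 251L)
  expect_equal(r$repeat_class, c("LTR", "LTR"))
  expect_equal(r$family, c("MLT1K", "HERVL-int"))
  expect_equal(r$strand, c("+", "-"))   # 'C' maps to '-'
})

test_that("read_repeatmasker_out handles empty bodies and bad headers", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c("   SW score header", "line2", ""), f)
  expect_equal(n_records(read_repeatmasker_out(f, source_name = "rm")), 0L)
  writeLines(c("chr1\t1\t2\tx"), f)
  expect_error(read_repeatmasker_out(f), "not a RepeatMasker")
})

test_that("filter_ltr_class keeps exactly the requested class", {
  rec <- data.frame(record_id = c("a", "b", "c", "d"), chrom = "chr1",
                    start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
                    repeat_class = c("LTR", "LINE", "LTR", NA))
  s <- annotation_set(rec, "x")
  suppressMessages({
    kept <- filter_ltr_class(s, "LTR")
    expect_equal(sort(kept$records$record_id), c("a", "c"))
    all_ltr <- filter_ltr_class(kept, "LTR")   # identity on pure-LTR sets
    expect_equal(as.data.frame(all_ltr$records), as.data.frame(kept$records))
  })
  expect_message(filter_ltr_class(s, "LTR"), "kept 2 of 4")
})

test_that("read_hervd_tsv converts completeness to destruction", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tfamily\tcompleteness",
               "chr1\t101\t200\tMER31B\t80",
               "chr1\t501\t700\tHERVL-int\t25"), f)
  s <- suppressMessages(read_hervd_tsv(f, "oneinclusive", source_name = "hv"))
  expect_equal(s$records$start, c(100L, 500L))
  expect_equal(s$records$destruction, c(20, 75))
  expect_message(read_hervd_tsv(f, "oneinclusive", source_name = "hv"),
                 "100 - completeness")
})

test_that("annotation_set validates coordinates and destruction range", {
  bad <- data.frame(record_id = "x", chrom = "chr1", start = 10, end = 10)
  expect_error(annotation_set(bad, "s"), "invalid coordinates")
  bad2 <- data.frame(record_id = "x", chrom = "chr1", start = 0, end = 10,
                     destruction = 120)
  expect_error(annotation_set(bad2, "s"), "destruction outside")
  dup <- data.frame(record_id = c("x", "x"), chrom = "chr1",
                    start = c(0, 5), end = c(10, 15))
  expect_error(annotation_set(dup, "s"), "duplicate record_id")
  # identical coordinates + family: kept, but warned about
  twin <- data.frame(record_id = c("x", "y"), chrom = "chr1",
                     start = 0, end = 10, family = "MER31B")
  expect_warning(s <- annotation_set(twin, "s"), "distinct records")
  expect_equal(n_records(s), 2L)
})
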