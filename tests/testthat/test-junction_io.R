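test_that("BED12 junction records convert to intron coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\tj1\t12\t+\t100\t500\t0\t2\t50,50\t0,350",
    "chr1\t100\t500\tj2\t7\t-\t100\t500\t0\t2\t30,20\t0,380"),
    f)
  j <- read_junction_bed(f, dialect = "tophat-bed12")
  expect_equal(j$start, c(150L, 130L))
  expect_equal(j$end, c(450L, 480L))
  expect_equal(j$count, c(12, 7))
  expect_equal(j$strand, c("+", "-"))
})

test_that("BED12 records without exactly two blocks are rejected with a warning", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t500\tj1\t12\t+\t100\t500\t0\t3\t50,20,50\t0,200,350",
    "chr1\t100\t500\tj2\t7\t+\t100\t500\t0\t2\t50,50\t0,350"),
    f)
  expect_warning(j <- read_junction_bed(f, dialect = "tophat-bed12"),
                 "rejected")
  expect_equal(j$id, "j2")
})

test_that("malformed BED lines raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t150\t450\tj1\t12\t+",
               "chr1\txx\t450\tj2\t9\t+"), f)
  expect_error(read_junction_bed(f, "intron-bed6"), "line 2")
  writeLines("chr1\t150\t450\tj1\t12\t?", f)
  expect_error(read_junction_bed(f, "intron-bed6"), "strand")
})

test_that("intron BED6 parses identically and the score doubles as count", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t150\t450\tj1\t12\t+", f)
  j <- read_junction_bed(f, "intron-bed6")
  expect_equal(j$start, 150L)
  expect_equal(j$end, 450L)
  expect_equal(j$count, 12)
})

test_that("BED12 conversion matches a brute-force block-geometry oracle", {
  # build records FROM known introns and random anchoring exon flanks
  set.seed(41)
  f <- withr::local_tempfile(fileext = ".bed")
  a <- sort(sample(1000:100000, 100))
  b <- a + sample(60:5000, 100, replace = TRUE)
  f1 <- sample(10:80, 100, replace = TRUE)
  f2 <- sample(10:80, 100, replace = TRUE)
  lines <- sprintf("chr2\t%d\t%d\tr%d\t%d\t%s\t0\t0\t0\t2\t%d,%d\t0,%d",
                   a - f1, b + f2, seq_len(100), seq_len(100),
                   sample(c("+", "-"), 100, replace = TRUE), f1, f2,
                   (b + f2) - (a - f1) - f2)
  writeLines(lines, f)
  j <- read_junction_bed(f, "tophat-bed12")
  expect_equal(j$start, a)
  expect_equal(j$end, b)
})

test_that("intron BED6 + counts round-trips exactly", {
  co <- default_cohort()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_junction_bed(co$junctions, f)
  back <- read_junction_bed(f, "intron-bed6", sample_sheet = co$samples)
  expect_equal(back$id, co$junctions$id)
  expect_equal(back$start, co$junctions$start)
  expect_equal(back$end, co$junctions$end)
  expect_equal(back$strand, co$junctions$strand)
  expect_equal(count_matrix(back), count_matrix(co$junctions))
})

test_that("acceptor and donor anchors follow the strand conventions", {
  j <- junction_table(c("p", "m"), "chr1", c(150L, 150L), c(450L, 450L),
                      c("+", "-"))
  acc <- acceptor_of(j)
  expect_equal(acc$anchor, c(450L, 149L))
  don <- donor_of(j)
  expect_equal(don$anchor, c(149L, 450L))
  # position -1 (the G of the AG) maps to the last intronic base
  expect_equal(genomic_position(acc[1, ], -1L), 449L)
  expect_equal(genomic_position(acc[2, ], -1L), 150L)
  expect_error(genomic_position(acc[1, ], 0L), "position 0")
})

test_that("extract_window returns transcript-oriented sequence with AG at the junction", {
  g <- toy_genome(chrT = "AACCGGTTACGTACGTAGGC")
  site <- data.frame(chrom = "chrT", strand = "+", anchor = 10L)
  expect_equal(extract_window(g, site, 5, 5), "GTTACGTACG")
  # minus strand equals the reverse complement of the mirrored window
  msite <- data.frame(chrom = "chrT", strand = "-", anchor = 9L)
  plus_mirror <- extract_window(g, data.frame(chrom = "chrT", strand = "+",
                                              anchor = 10L), 5, 5)
  expect_equal(extract_window(g, msite, 5, 5),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(plus_mirror))))
  expect_error(extract_window(g, data.frame(chrom = "chrT", strand = "+",
                                            anchor = 3L), 50, 5), "outside")
  expect_error(extract_window(g, data.frame(chrom = "chrX", strand = "+",
                                            anchor = 10L), 5, 5), "chrT")
})

test_that("minus-strand extraction mirrors plus-strand on cohort loci", {
  co <- default_cohort()
  tr <- co$truth
  for (strand in c("+", "-")) {
    row <- tr[tr$strand == strand, ][1, ]
    site <- data.frame(chrom = row$chrom, strand = strand, anchor = row$can_anchor)
    w <- extract_window(co$genome, site, 50, 2)
    expect_equal(substr(w, 49, 50), "AG")
  }
})

test_that("branchpoint catalogues parse single-base intervals and degenerate inputs", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t1000\tbp1\t.\t+", f)
  cat <- read_branchpoint_catalogue(f)
  expect_equal(cat$pos, 999L)
  writeLines("chr1\t990\t993\tbp1\t.\t+", f)
  expect_warning(cat <- read_branchpoint_catalogue(f), "midpoint")
  expect_equal(cat$pos, 991L)
  writeLines(character(), f)
  expect_equal(nrow(read_branchpoint_catalogue(f)), 0L)
})
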