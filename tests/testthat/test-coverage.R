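frag_df <- function(chrom, start, end, strand, mapq = 60) {
  genomic_intervals(chrom, start, end,
                    name = paste0("r", seq_along(start)),
                    mapq = mapq, strand = strand)
}

test_that("MAPQ filter is strictly greater-than and missing MAPQ passes", {
  fr <- frag_df("chr1", c(0, 100, 200), c(75, 175, 275), "+",
                mapq = c(25, 26, NA))
  out <- filter_fragments(fr)
  expect_equal(out$start, c(100, 200))
  expect_equal(nrow(filter_fragments(fr[0, ])), 0)
})

test_that("duplicates collapse on (chrom, 5' position, strand) and dedup is idempotent", {
  fr <- frag_df("chr1", c(10, 10, 10, 40), c(85, 85, 115, 115),
                c("+", "+", "+", "-"))
  out <- filter_fragments(fr)
  # first two share 5' = 10 on +; third also starts at 10 on + (length differs)
  expect_equal(nrow(out), 2)
  expect_identical(filter_fragments(out), out)
})

test_that("fragments are set to the extension length from their 5' end", {
  fr <- frag_df("chr1", c(10, 300, 50), c(85, 375, 125), c("+", "-", "-"))
  ext <- extend_fragments(fr)
  expect_equal(ext$start, c(10, 175, 0))   # minus strand clipped at 0
  expect_equal(ext$end, c(210, 375, 125))
  # long fragments are truncated to the extension length from the 5' end
  long <- frag_df("chr1", 100, 500, "+")
  expect_equal(extend_fragments(long)$end, 300)
})

test_that("binned mass distributes overlapped bases and conserves total", {
  fr <- frag_df("chr1", 0, 75, "+")
  tr <- build_coverage(fr)
  expect_equal(tr$bins$chr1[1:7], c(rep(32, 6), 8))
  expect_equal(track_mass(tr), 200)

  empty <- build_coverage(fr[0, ], chrom_sizes = c(chr1 = 320))
  expect_equal(track_mass(empty), 0)
  expect_length(empty$bins$chr1, 10)
})

test_that("coverage equals per-base brute force on random toy genomes", {
  set.seed(42)
  for (rep in 1:5) {
    chrom_len <- 9600
    n <- 400
    start <- floor(runif(n, 0, chrom_len - 260))
    fr <- frag_df("chr1", start, start + 75,
                  sample(c("+", "-"), n, replace = TRUE))
    tr <- build_coverage(fr, chrom_sizes = c(chr1 = chrom_len))
    ext <- extend_fragments(fr)
    expect_equal(tr$bins$chr1, oracle_binned_coverage(ext, chrom_len, 32))
    expect_equal(track_mass(tr), sum(interval_length(ext)))
  }
})

test_that("coverage is symmetric under strand flip and coordinate reflection", {
  set.seed(11)
  chrom_len <- 6400
  start <- floor(runif(200, 300, chrom_len - 300))
  strand <- sample(c("+", "-"), 200, replace = TRUE)
  fr <- frag_df("chr1", start, start + 75, strand)
  mirrored <- frag_df("chr1", chrom_len - (start + 75), chrom_len - start,
                      ifelse(strand == "+", "-", "+"))
  tr <- build_coverage(fr, chrom_sizes = c(chr1 = chrom_len))
  tr_m <- build_coverage(mirrored, chrom_sizes = c(chr1 = chrom_len))
  expect_equal(tr_m$bins$chr1, rev(tr$bins$chr1))
})

test_that("bedGraph round trip reproduces nonzero bins", {
  fr <- frag_df("chr1", c(0, 1000), c(75, 1075), "+")
  tr <- build_coverage(fr, chrom_sizes = c(chr1 = 2048))
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  lines <- readLines(f)
  expect_equal(lines[2], "chr1\t0\t32\t32")
  back <- read_bedgraph(f, 32)
  nz <- which(tr$bins$chr1 != 0)
  expect_equal(back$bins$chr1[nz], tr$bins$chr1[nz])
  # all-zero track writes only the header
  empty <- build_coverage(fr[0, ], chrom_sizes = c(chr1 = 320))
  write_bedgraph(empty, f)
  expect_length(readLines(f), 1)
})
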