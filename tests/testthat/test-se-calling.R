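peak_df <- function(chrom, start, end) {
  genomic_intervals(chrom, start, end,
                    name = paste0("p", seq_along(start)), score = 1)
}

uniform_track <- function(n_bins, value = 1, bin_size = 32) {
  structure(list(bins = list(chr1 = rep(value, n_bins)),
                 bin_size = bin_size, total_fragments_used = NA_integer_),
            class = "coverage_track")
}

test_that("blacklist removes >= 1 bp overlaps but not half-open abutment", {
  pk <- peak_df("chr1", c(100, 100), c(200, 200))
  expect_equal(nrow(filter_blacklist(pk, genomic_intervals("chr1", 150, 160))), 0)
  expect_equal(nrow(filter_blacklist(pk, genomic_intervals("chr1", 200, 300))), 2)
  expect_identical(filter_blacklist(pk, NULL), pk)
})

test_that("stitching joins gaps strictly below the stitch distance", {
  pk <- peak_df("chr1", c(100, 13000), c(600, 13500))  # gap 12,400
  expect_equal(nrow(stitch_peaks(pk)), 1)
  pk2 <- peak_df("chr1", c(100, 13100), c(600, 13600))  # gap 12,500
  st <- stitch_peaks(pk2)
  expect_equal(nrow(st), 2)
  expect_equal(st$start, c(100, 13100))
})

test_that("stitching partitions peaks into disjoint hulls matching the closure oracle", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    pk <- random_intervals(n, chroms = c("chr1", "chr2"))
    pk$name <- paste0("p", seq_len(n)); pk$score <- 1
    st <- stitch_peaks(pk)
    # every peak in exactly one region
    members <- sort(unname(unlist(st$members)))
    expect_equal(members, seq_len(n))
    # hulls pairwise disjoint per chromosome
    for (ch in unique(st$chrom)) {
      sub <- st[st$chrom == ch, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
    ora <- oracle_stitch(pk, 12500)
    expect_equal(st[order(st$chrom, st$start), c("chrom", "start", "end")],
                 ora, ignore_attr = TRUE)
  }
})

test_that("raising the stitch distance never increases the region count", {
  set.seed(7)
  pk <- random_intervals(60)
  pk$name <- paste0("p", 1:60); pk$score <- 1
  counts <- vapply(c(0, 100, 1000, 5000, 12500, 50000), function(d)
    nrow(stitch_peaks(pk, se_call_params(stitch_distance = max(d, 1)))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tag quantification is reads-per-million with linear bin proration", {
  tr <- uniform_track(100)             # chr1, 3200 bp, uniform mass
  whole <- quantify_regions(genomic_intervals("chr1", 0, 3200), tr)
  expect_equal(whole$tag_count, 1e6)
  half <- quantify_regions(genomic_intervals("chr1", 0, 1600), tr)
  expect_equal(half$tag_count, 5e5)
  off <- quantify_regions(genomic_intervals("chr2", 0, 100), tr)
  expect_equal(off$tag_count, 0)
  # partial bin: 16 of 32 bases of one uniform bin = half a bin's mass
  part <- quantify_regions(genomic_intervals("chr1", 16, 48), tr)
  expect_equal(part$tag_count, 1e6 / 100)
  zero <- uniform_track(10, value = 0)
  expect_error(quantify_regions(genomic_intervals("chr1", 0, 32), zero),
               "zero-mass")
})

test_that("top-fraction designation flags floor(5% N) with a minimum of one", {
  set.seed(3)
  mk <- function(n, tags) {
    r <- genomic_intervals("chr1", seq(0, by = 2000, length.out = n),
                           seq(1000, by = 2000, length.out = n))
    r$tag_count <- tags
    r
  }
  call <- call_superenhancers(mk(2000, sample(seq_len(2000))))
  expect_equal(call$se_count, 100)
  expect_equal(sum(call$regions$is_super), 100)
  # flagged regions are exactly the 100 highest tag counts
  expect_true(min(call$regions$tag_count[call$regions$is_super]) >
                max(call$regions$tag_count[!call$regions$is_super]))
  expect_true(all(diff(call$regions$tag_count) <= 0))

  expect_equal(call_superenhancers(mk(10, 10:1))$se_count, 1)
  expect_error(call_superenhancers(mk(3, 1:3)[0, ]), "no stitched regions")
})

test_that("all-equal tag counts break ties by length then coordinate", {
  r <- genomic_intervals("chr1", seq(0, by = 10000, length.out = 100),
                         seq(0, by = 10000, length.out = 100) + rep(c(2000, 1000), 50))
  r$tag_count <- rep(5, 100)
  call <- call_superenhancers(r)
  expect_equal(call$se_count, 5)
  flagged <- call$regions[call$regions$is_super, ]
  # longer regions first, then ascending start
  expect_true(all(interval_length(flagged) == 2000))
  expect_equal(flagged$start, seq(0, by = 20000, length.out = 5))
})

test_that("ranks and flags are invariant to track scaling", {
  set.seed(5)
  pk <- random_intervals(40)
  pk$name <- paste0("p", 1:40); pk$score <- 1
  st <- stitch_peaks(pk)
  tr1 <- uniform_track(3200)
  tr1$bins$chr1 <- runif(3200)
  tr2 <- tr1
  tr2$bins$chr1 <- tr1$bins$chr1 * 37.5
  c1 <- call_superenhancers(quantify_regions(st, tr1))
  c2 <- call_superenhancers(quantify_regions(st, tr2))
  expect_equal(c1$regions$start, c2$regions$start)
  expect_equal(c1$regions$is_super, c2$regions$is_super)
  expect_equal(c1$regions$tag_count, c2$regions$tag_count)  # both per-million
})
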