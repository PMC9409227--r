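gene_df <- function(symbol, chrom, start, end, strand) {
  data.frame(symbol = symbol, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

region1 <- genomic_intervals("chr1", 1000, 2000)

test_that("overlap, upstream and downstream relations follow the gene's strand", {
  g_in <- gene_df("A", "chr1", 1500, 3000, "+")
  a <- annotate_region(region1, g_in)
  expect_equal(a$relation, "in gene")
  expect_equal(a$distance, 0)

  g_plus <- gene_df("B", "chr1", 2500, 4000, "+")
  a <- annotate_region(region1, g_plus)
  expect_equal(a$relation, "upstream")   # region sits 5' of the TSS at 2500
  expect_equal(a$distance, 500)

  g_minus <- gene_df("B", "chr1", 2500, 4000, "-")
  a <- annotate_region(region1, g_minus)
  expect_equal(a$relation, "downstream") # TSS at 4000; region lies 3'
  expect_equal(a$distance, 500)

  expect_error(annotate_region(region1, gene_df("C", "chr1", 1, 10, ".")),
               "strand")
})

test_that("flipping a gene's strand swaps upstream and downstream", {
  set.seed(31)
  for (rep in 1:25) {
    gs <- floor(runif(1, 0, 9000)); ge <- gs + floor(runif(1, 100, 3000))
    g <- gene_df("G", "chr1", gs, ge, "+")
    region <- genomic_intervals("chr1", 4000, 4500)
    a_plus <- annotate_region(region, g, annotation_params(window = 1e6))
    g$strand <- "-"
    a_minus <- annotate_region(region, g, annotation_params(window = 1e6))
    if (a_plus$relation == "in gene") {
      expect_equal(a_minus$relation, "in gene")
    } else {
      expect_equal(sort(c(a_plus$relation, a_minus$relation)),
                   c("downstream", "upstream"))
      expect_equal(a_plus$distance, a_minus$distance)
    }
  }
})

test_that("enlarging the window never removes annotations; overlaps ignore it", {
  genes <- gene_df(c("N1", "N2", "OV"), "chr1",
                   c(3000, 60000, 1500), c(5000, 70000, 1800),
                   c("+", "-", "+"))
  small <- annotate_region(region1, genes, annotation_params(window = 2000))
  big <- annotate_region(region1, genes, annotation_params(window = 100000))
  expect_true(all(small$symbol %in% big$symbol))
  expect_true("OV" %in% annotate_region(region1, genes,
                                        annotation_params(window = 0))$symbol)
  # ordering: in gene first, then flanks by distance
  expect_equal(big$symbol, c("OV", "N1", "N2"))
})

test_that("annotate_all fills empty annotation lists and a genes column", {
  regions <- genomic_intervals(c("chr1", "chrX"), c(1000, 1000), c(2000, 2000))
  genes <- gene_df("A", "chr1", 1200, 1800, "+")
  ann <- annotate_all(regions, genes)
  expect_equal(ann$genes, c("A", ""))
  expect_equal(nrow(ann$annotations[[2]]), 0)
  ann0 <- annotate_all(regions, genes[0, ])
  expect_equal(ann0$genes, c("", ""))
})

test_that("published regions annotate their published genes at printed coordinates", {
  # gene spans printed in the genome-browser figure of the source study
  genes <- gene_df(c("C9orf89", "CENPA", "PISD", "TRAF2"),
                   c("chr9", "chr2", "chr22", "chr9"),
                   c(93096217, 26786014, 31618491, 136881933),
                   c(93113283, 26794589, 31662564, 136926621),
                   c("+", "+", "-", "+"))
  fx <- load_table1_fixture()
  hosts <- fx$regions[fx$regions$region_no %in% c(64, 38, 46, 68), ]
  ann <- annotate_all(hosts, genes)
  sym <- lapply(ann$annotations, `[[`, "symbol")
  expect_true("C9orf89" %in% sym[[which(hosts$region_no == 64)]])
  expect_true("CENPA" %in% sym[[which(hosts$region_no == 38)]])
  # overlap is forced by the printed coordinates for PISD and TRAF2
  a_pisd <- ann$annotations[[which(hosts$region_no == 46)]]
  expect_equal(a_pisd$relation[a_pisd$symbol == "PISD"], "in gene")
  a_traf2 <- ann$annotations[[which(hosts$region_no == 68)]]
  expect_equal(a_traf2$relation[a_traf2$symbol == "TRAF2"], "in gene")
})
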