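#' Annotation parameters
#'
#' @param window maximum edge-to-edge distance (bp) from a region to a gene
#'   for the gene to be reported as upstream/downstream flank (default
#'   50,000 bp, a conventional enhancer-to-target assignment span; genes
#'   overlapping the region are always reported as "in gene").
#' @return an `annotation_params` list.
#' @export
annotation_params <- function(window = 50000) {
  stopifnot(window >= 0)
  structure(list(window = window), class = "annotation_params")
}

#' Annotate one region with nearby genes
#'
#' Each gene overlapping the region by >= 1 bp is labelled `in gene` with
#' distance 0. A non-overlapping gene within `window` bp is labelled
#' relative to its own orientation: when the region lies entirely on the
#' 5' (TSS) side of the gene it is `upstream`, otherwise `downstream`;
#' distance is the edge-to-edge gap. Results are ordered by relation
#' priority (in gene, upstream, downstream), then distance.
#'
#' @param region single-row interval table (or list with chrom/start/end).
#' @param genes gene table (see [read_gene_table()]).
#' @param params [annotation_params()].
#' @return data frame: `symbol`, `relation`, `distance`, `strand`.
#' @export
annotate_region <- function(region, genes, params = annotation_params()) {
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad))
    stop("gene with unknown strand: ", genes$symbol[bad[1]])
  empty <- data.frame(symbol = character(0), relation = character(0),
                      distance = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE)
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  overlap <- g$start < region$end & region$start < g$end
  gap <- ifelse(overlap, 0,
                pmax(g$start - region$end, region$start - g$end))
  keep <- overlap | gap <= params$window
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  overlap <- overlap[keep]; gap <- gap[keep]
  region_5prime <- ifelse(g$strand == "+", region$end <= g$start,
                          region$start >= g$end)
  relation <- ifelse(overlap, "in gene",
                     ifelse(region_5prime, "upstream", "downstream"))
  out <- data.frame(symbol = g$symbol, relation = relation, distance = gap,
                    strand = g$strand, stringsAsFactors = FALSE)
  pri <- match(out$relation, c("in gene", "upstream", "downstream"))
  out <- out[order(pri, out$distance, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate all merged gain regions
#'
#' @param regions merged-region table (see [intersect_gains()]).
#' @param genes gene table.
#' @param params [annotation_params()].
#' @return `regions` with an `annotations` list column (one
#'   [annotate_region()] result per region; empty data frame when no gene
#'   is within the window) and a `genes` character column
#'   (semicolon-joined symbols).
#' @export
annotate_all <- function(regions, genes, params = annotation_params()) {
  ann <- lapply(seq_len(nrow(regions)), function(i)
    annotate_region(regions[i, , drop = FALSE], genes, params))
  regions$annotations <- ann
  regions$genes <- vapply(ann, function(a) paste(a$symbol, collapse = ";"),
                          character(1))
  regions
}
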