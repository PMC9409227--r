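#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All region tables in this package use 0-based half-open coordinates
# (BED convention): start is the first base, end is one past the last,
# length == end - start. GRanges (1-based closed) is used only transiently
# for overlap queries, via gi_granges().

#' Construct a genomic interval table
#'
#' The package's common currency for region math: a data frame with columns
#' `chrom`, `start`, `end` in 0-based half-open (BED) coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start >= 0`, `end > start`.
#' @param ... further equal-length columns appended to the table.
#' @return A data frame with validated interval columns.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop(what, " table must have columns chrom, start, end")
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(what, ": missing coordinates")
  if (any(df$start < 0))
    stop(what, ": negative start coordinate")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(what, ": end <= start (zero-length intervals are forbidden) at record ",
         bad[1])
  invisible(df)
}

#' Interval lengths
#' @param x interval data frame.
#' @return numeric vector of `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' Normalize chromosome names to the "chr"-prefixed convention
#'
#' Bare names ("1", "X") gain a "chr" prefix; already-prefixed names pass
#' through unchanged.
#'
#' @param chrom character vector.
#' @return character vector of canonical names.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

# 1-based-closed GRanges view of a 0-based half-open interval table,
# for overlap queries only.
gi_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# Hit pairs (query index, subject index) for >= 1 bp overlap between two
# half-open interval tables.
gi_overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(0), subject = integer(0)))
  hits <- GenomicRanges::findOverlaps(gi_granges(query), gi_granges(subject))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# Logical: does each query interval overlap any subject interval by >= 1 bp?
gi_overlaps_any <- function(query, subject) {
  hit <- rep(FALSE, nrow(query))
  hit[unique(gi_overlap_pairs(query, subject)$query)] <- TRUE
  hit
}
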