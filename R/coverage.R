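#' Coverage parameters
#'
#' Defaults reproduce the ChIP-seq processing rules used throughout:
#' alignments are set to 200 bp from their 5' end, fragments with mapping
#' quality of 25 or below are discarded (strictly-greater-than rule),
#' duplicates (same chromosome, 5' position and strand) are collapsed, and
#' base-level coverage mass is accumulated into 32-nt bins.
#'
#' @param extension_length fragment length after 3' extension, bp.
#' @param bin_size histogram bin width, bp.
#' @param min_mapq exclusive MAPQ threshold; fragments with `mapq > min_mapq`
#'   are kept. Fragments with missing MAPQ are kept.
#' @param deduplicate collapse fragments sharing (chrom, 5' position, strand)?
#' @return A `coverage_params` list.
#' @export
coverage_params <- function(extension_length = 200, bin_size = 32,
                            min_mapq = 25, deduplicate = TRUE) {
  stopifnot(extension_length >= 1, bin_size >= 1)
  structure(list(extension_length = extension_length, bin_size = bin_size,
                 min_mapq = min_mapq, deduplicate = deduplicate),
            class = "coverage_params")
}

five_prime <- function(fragments) {
  ifelse(fragments$strand == "+", fragments$start, fragments$end)
}

#' Filter fragments by mapping quality and duplication
#'
#' @param fragments fragment table from [read_fragments()].
#' @param params [coverage_params()].
#' @return The surviving fragments, original order preserved. Fragments with
#'   `mapq <= min_mapq` are removed (missing MAPQ passes); when
#'   `deduplicate`, only the first fragment at each (chrom, 5' position,
#'   strand) is kept.
#' @export
filter_fragments <- function(fragments, params = coverage_params()) {
  keep <- is.na(fragments$mapq) | fragments$mapq > params$min_mapq
  out <- fragments[keep, , drop = FALSE]
  if (params$deduplicate && nrow(out) > 0) {
    key <- paste(out$chrom, five_prime(out), out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Extend fragments in silico at their 3' ends
#'
#' Each fragment is replaced by an interval of exactly `extension_length` bp
#' anchored at its 5' end (so short fragments grow and long fragments are
#' truncated), clipped at position 0.
#'
#' @param fragments fragment table with a `strand` column.
#' @param params [coverage_params()].
#' @return interval table of extended fragments.
#' @export
extend_fragments <- function(fragments, params = coverage_params()) {
  ext <- params$extension_length
  plus <- fragments$strand == "+"
  start <- ifelse(plus, fragments$start, pmax(0, fragments$end - ext))
  end <- ifelse(plus, fragments$start + ext, fragments$end)
  genomic_intervals(fragments$chrom, start, end)
}

#' Build a binned coverage track from filtered fragments
#'
#' Each extended fragment contributes, to every bin it overlaps, the number
#' of bases by which it overlaps that bin, so total track mass equals the
#' summed extended (clipped) fragment lengths.
#'
#' @param fragments filtered fragment table (see [filter_fragments()]).
#' @param params [coverage_params()].
#' @param chrom_sizes optional named vector of chromosome lengths (bp); when
#'   absent, each chromosome's length is the largest coordinate seen,
#'   rounded up to a bin boundary.
#' @return A `coverage_track`: list with `bins` (named list, one numeric
#'   vector of per-bin mass per chromosome), `bin_size`, and
#'   `total_fragments_used`.
#' @export
build_coverage <- function(fragments, params = coverage_params(),
                           chrom_sizes = NULL) {
  ext <- extend_fragments(fragments, params)
  bs <- params$bin_size
  chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes)
            else sort(unique(ext$chrom))
  bins <- lapply(chroms, function(ch) {
    sub <- ext[ext$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_sizes)) chrom_sizes[[ch]]
           else if (nrow(sub)) max(sub$end) else bs
    len <- as.integer(ceiling(len / bs) * bs)
    if (nrow(sub) == 0) return(numeric(len / bs))
    # difference array -> per-base depth -> fold into bins
    s <- pmin(sub$start, len) + 1
    e <- pmin(sub$end, len) + 1
    delta <- tabulate(s, nbins = len + 1) - tabulate(e, nbins = len + 1)
    depth <- cumsum(delta[1:len])
    colSums(matrix(depth, nrow = bs))
  })
  names(bins) <- chroms
  structure(list(bins = bins, bin_size = bs,
                 total_fragments_used = nrow(fragments)),
            class = "coverage_track")
}

#' Total mass of a coverage track
#' @param track a `coverage_track`.
#' @return numeric scalar: sum of all bin values.
#' @export
track_mass <- function(track) sum(vapply(track$bins, sum, numeric(1)))

#' Write a coverage track as bedGraph
#'
#' One line per nonzero bin, coordinates aligned to bin boundaries.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  bs <- track$bin_size
  for (ch in names(track$bins)) {
    v <- track$bins[[ch]]
    nz <- which(v != 0)
    if (length(nz))
      writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                         format((nz - 1) * bs, scientific = FALSE, trim = TRUE),
                         format(nz * bs, scientific = FALSE, trim = TRUE),
                         format(v[nz], scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into a track
#' @param path bedGraph path.
#' @param bin_size bin width the file was written with.
#' @return a `coverage_track` (with `total_fragments_used = NA`).
#' @export
read_bedgraph <- function(path, bin_size = 32) {
  df <- read_bed(path)
  bins <- lapply(split(df, df$chrom)[unique(df$chrom)], function(sub) {
    v <- numeric(max(sub$end) / bin_size)
    v[sub$start / bin_size + 1] <- as.numeric(sub$name)
    v
  })
  structure(list(bins = bins, bin_size = bin_size,
                 total_fragments_used = NA_integer_),
            class = "coverage_track")
}
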