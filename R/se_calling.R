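#' Super-enhancer calling parameters
#'
#' @param stitch_distance peaks whose gap is strictly less than this many bp
#'   are stitched into one region (default 12,500).
#' @param top_fraction fraction of ranked stitched regions designated
#'   super-enhancers (default 0.05, i.e. the top 5%).
#' @param blacklist optional interval table of artifact regions; peaks
#'   overlapping a blacklist interval by >= 1 bp are dropped before stitching.
#' @return an `se_call_params` list.
#' @export
se_call_params <- function(stitch_distance = 12500, top_fraction = 0.05,
                          blacklist = NULL) {
  stopifnot(stitch_distance >= 0, top_fraction > 0, top_fraction <= 1)
  structure(list(stitch_distance = stitch_distance,
                 top_fraction = top_fraction, blacklist = blacklist),
            class = "se_call_params")
}

#' Remove peaks overlapping a blacklist
#'
#' A peak is removed when it overlaps any blacklist interval by at least
#' 1 bp; half-open abutment is not overlap. Input order is preserved.
#'
#' @param peaks peak table.
#' @param blacklist interval table (or `NULL` / empty for identity).
#' @return filtered peak table.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0 || nrow(peaks) == 0)
    return(peaks)
  out <- peaks[!gi_overlaps_any(peaks, blacklist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stitch peaks into candidate enhancer regions
#'
#' Peaks on the same chromosome are merged by single-linkage chaining:
#' sorted by start, a peak joins the growing region when its start minus
#' the furthest end seen so far is strictly less than `stitch_distance`
#' (overlapping or abutting peaks always merge). The result equals the
#' transitive closure of the pairwise gap-below-threshold relation; each
#' peak belongs to exactly one region and region hulls are pairwise
#' disjoint per chromosome.
#'
#' @param peaks peak table (any order).
#' @param params [se_call_params()].
#' @param chroms optional character vector of allowed chromosome names;
#'   peaks on other chromosomes raise an error.
#' @return region table: `chrom`, `start`, `end` (hull), `n_peaks`, and
#'   `members` (list column of input peak row indices).
#' @export
stitch_peaks <- function(peaks, params = se_call_params(), chroms = NULL) {
  if (!is.null(chroms)) {
    bad <- setdiff(unique(peaks$chrom), chroms)
    if (length(bad)) stop("peaks on undeclared chromosome: ", bad[1])
  }
  if (nrow(peaks) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0),
                             n_peaks = integer(0)))
  d <- params$stitch_distance
  idx <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[idx, , drop = FALSE]
  new_chrom <- c(TRUE, p$chrom[-1] != p$chrom[-nrow(p)])
  # furthest end seen so far within the current chromosome run
  grp_chrom <- cumsum(new_chrom)
  reach <- stats::ave(p$end, grp_chrom, FUN = cummax)
  gap <- c(Inf, p$start[-1] - reach[-nrow(p)])
  breaks <- new_chrom | gap >= d
  region_id <- cumsum(breaks)
  hulls <- lapply(split(seq_len(nrow(p)), region_id), function(rows) {
    list(chrom = p$chrom[rows[1]],
         start = min(p$start[rows]), end = max(p$end[rows]),
         members = idx[rows])
  })
  out <- genomic_intervals(
    vapply(hulls, `[[`, "", "chrom"),
    vapply(hulls, `[[`, numeric(1), "start"),
    vapply(hulls, `[[`, numeric(1), "end"),
    n_peaks = vapply(hulls, function(h) length(h$members), integer(1)))
  out$members <- lapply(hulls, `[[`, "members")
  rownames(out) <- NULL
  out
}

#' Quantify stitched regions against a coverage track
#'
#' Tag count is the track mass overlapping each region, scaled to
#' reads-per-million of the track's total mass; partial bin overlap is
#' prorated linearly.
#'
#' @param regions region table from [stitch_peaks()].
#' @param track a `coverage_track`.
#' @return `regions` with a `tag_count` column added.
#' @export
quantify_regions <- function(regions, track) {
  total <- track_mass(track)
  if (total <= 0) stop("cannot normalize against a zero-mass coverage track")
  bs <- track$bin_size
  regions$tag_count <- vapply(seq_len(nrow(regions)), function(i) {
    v <- track$bins[[regions$chrom[i]]]
    if (is.null(v)) return(0)
    s <- regions$start[i]; e <- min(regions$end[i], length(v) * bs)
    if (e <= s) return(0)
    b1 <- floor(s / bs) + 1; b2 <- floor((e - 1) / bs) + 1
    mass <- sum(v[b1:b2])
    # prorate the flanking partial bins
    mass <- mass - v[b1] * (s - (b1 - 1) * bs) / bs
    mass <- mass - v[b2] * (b2 * bs - e) / bs
    mass * 1e6 / total
  }, numeric(1))
  regions
}

#' Rank stitched regions and designate super-enhancers
#'
#' Regions are ordered by normalized tag count (descending; ties broken by
#' region length descending, then chromosome and start ascending) and the
#' top fraction — `max(1, floor(top_fraction * N))` regions — is flagged.
#'
#' @param regions quantified region table (see [quantify_regions()]).
#' @param params [se_call_params()].
#' @return an `se_call` list: `regions` in rank order with `rank` and
#'   `is_super` columns, `se_count`, and `params`.
#' @export
call_superenhancers <- function(regions, params = se_call_params()) {
  if (nrow(regions) == 0) stop("no stitched regions to rank")
  if (is.null(regions$tag_count)) stop("regions are not quantified")
  ord <- order(-regions$tag_count, -(regions$end - regions$start),
               regions$chrom, regions$start)
  out <- regions[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  se_count <- max(1L, floor(params$top_fraction * nrow(out)))
  out$is_super <- out$rank <= se_count
  rownames(out) <- NULL
  structure(list(regions = out, se_count = se_count, params = params),
            class = "se_call")
}

#' Full super-enhancer call from peaks and a coverage track
#'
#' Convenience wrapper: blacklist filtering, stitching, quantification and
#' top-fraction designation in one step.
#'
#' @inheritParams stitch_peaks
#' @inheritParams quantify_regions
#' @return an `se_call` (see [call_superenhancers()]).
#' @export
call_se_pipeline <- function(peaks, track, params = se_call_params(),
                             chroms = NULL) {
  peaks <- filter_blacklist(peaks, params$blacklist)
  regions <- stitch_peaks(peaks, params, chroms = chroms)
  call_superenhancers(quantify_regions(regions, track), params)
}

#' Super-enhancer regions of a call
#' @param call an `se_call`.
#' @return the flagged (is_super) subset of the call's region table.
#' @export
superenhancers <- function(call) {
  call$regions[call$regions$is_super, , drop = FALSE]
}
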