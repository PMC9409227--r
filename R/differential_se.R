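#' Classify gained, lost and shared super-enhancers between two calls
#'
#' Gain/loss is presence/absence by overlap: a treated super-enhancer with
#' zero bp overlap against every parental super-enhancer is `gained`; a
#' parental super-enhancer with zero overlap against every treated one is
#' `lost` (reported on parental coordinates); any overlap of >= 1 bp makes
#' the pair `shared`.
#'
#' @param treated,parental `se_call` objects on the same genome.
#' @return interval table with columns `status` (gained/lost/shared),
#'   `side` (treated/parental), `tag_count`, and `partner_overlap_bp`
#'   (total bp of overlap with the other call's super-enhancers).
#' @export
classify_gain_loss <- function(treated, parental) {
  t_se <- superenhancers(treated)
  p_se <- superenhancers(parental)
  chrs <- function(x) sub("^chr", "", x)
  if (nrow(t_se) && nrow(p_se)) {
    t_pref <- startsWith(t_se$chrom, "chr")
    p_pref <- startsWith(p_se$chrom, "chr")
    if (any(t_pref) != any(p_pref) && (all(t_pref) || all(p_pref)))
      stop("mismatched chromosome namespaces between treated and parental calls")
  }
  overlap_bp <- function(a, b) {
    out <- numeric(nrow(a))
    if (nrow(a) == 0 || nrow(b) == 0) return(out)
    hits <- gi_overlap_pairs(a, b)
    if (nrow(hits)) {
      w <- pmin(a$end[hits$query], b$end[hits$subject]) -
           pmax(a$start[hits$query], b$start[hits$subject])
      agg <- tapply(w, hits$query, sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  t_ov <- overlap_bp(t_se, p_se)
  p_ov <- overlap_bp(p_se, t_se)
  res <- rbind(
    if (nrow(t_se)) data.frame(
      chrom = t_se$chrom, start = t_se$start, end = t_se$end,
      status = ifelse(t_ov == 0, "gained", "shared"), side = "treated",
      tag_count = t_se$tag_count, partner_overlap_bp = t_ov,
      stringsAsFactors = FALSE),
    if (nrow(p_se) && any(p_ov == 0)) {
      lost <- p_ov == 0
      data.frame(
        chrom = p_se$chrom[lost], start = p_se$start[lost],
        end = p_se$end[lost], status = "lost", side = "parental",
        tag_count = p_se$tag_count[lost],
        partner_overlap_bp = p_ov[lost], stringsAsFactors = FALSE)
    })
  stopifnot(all(res$partner_overlap_bp[res$status != "shared"] == 0))
  rownames(res) <- NULL
  res
}

#' Gained regions of a differential classification
#' @param diff result of [classify_gain_loss()].
#' @return the gained-status rows.
#' @export
gained_regions <- function(diff) {
  out <- diff[diff$status == "gained", , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union-find with path compression; used for transitive overlap grouping
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Intersect gained super-enhancers across two cell lines
#'
#' Gains from line A overlapping (>= 1 bp) gains from line B are grouped by
#' transitive overlap (connected components of the bipartite overlap graph);
#' each group becomes one merged common-gain region whose interval is the
#' union hull of all contributors. Ids are assigned in (chrom, start) order.
#' Gains private to one line produce no merged region.
#'
#' @param gains_a,gains_b interval tables of gained regions (see
#'   [gained_regions()]), one per cell line.
#' @return interval table of merged regions: `merged_region_id`, `chrom`,
#'   `start`, `end`, `length`, `n_contributors_a`, `n_contributors_b`, and
#'   list columns `contributors_a`, `contributors_b` holding the source
#'   intervals.
#' @export
intersect_gains <- function(gains_a, gains_b) {
  empty <- genomic_intervals(character(0), integer(0), integer(0),
                             merged_region_id = integer(0),
                             length = integer(0),
                             n_contributors_a = integer(0),
                             n_contributors_b = integer(0))
  if (nrow(gains_a) == 0 || nrow(gains_b) == 0) return(empty)
  hits <- gi_overlap_pairs(gains_a, gains_b)
  if (nrow(hits) == 0) return(empty)
  n <- nrow(gains_a) + nrow(gains_b)
  parent <- uf_new(n)
  for (k in seq_len(nrow(hits))) {
    ra <- uf_find(parent, hits$query[k])
    rb <- uf_find(parent, nrow(gains_a) + hits$subject[k])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  touched <- c(unique(hits$query), nrow(gains_a) + unique(hits$subject))
  groups <- split(touched, root[touched])
  rows <- lapply(groups, function(g) {
    ia <- g[g <= nrow(gains_a)]
    ib <- g[g > nrow(gains_a)] - nrow(gains_a)
    ca <- gains_a[ia, c("chrom", "start", "end"), drop = FALSE]
    cb <- gains_b[ib, c("chrom", "start", "end"), drop = FALSE]
    all_c <- rbind(ca, cb)
    list(chrom = all_c$chrom[1], start = min(all_c$start),
         end = max(all_c$end), ca = ca, cb = cb)
  })
  out <- genomic_intervals(
    vapply(rows, `[[`, "", "chrom"),
    vapply(rows, `[[`, numeric(1), "start"),
    vapply(rows, `[[`, numeric(1), "end"))
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rows <- rows[ord]
  out$merged_region_id <- seq_len(nrow(out))
  out$length <- out$end - out$start
  out$n_contributors_a <- vapply(rows, function(r) nrow(r$ca), integer(1))
  out$n_contributors_b <- vapply(rows, function(r) nrow(r$cb), integer(1))
  out$contributors_a <- lapply(rows, `[[`, "ca")
  out$contributors_b <- lapply(rows, `[[`, "cb")
  rownames(out) <- NULL
  out
}
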