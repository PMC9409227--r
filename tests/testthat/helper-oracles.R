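# Independent brute-force oracles used to check the package's region
# algebra. These deliberately share no code with the implementation.

# Transitive closure of the pairwise "gap < d" relation between intervals
# on one genome, via connected components of the explicit pairwise graph.
oracle_stitch <- function(peaks, d) {
  n <- nrow(peaks)
  gap <- outer(peaks$start, peaks$end, `-`)  # gap[i, j] = start_i - end_j
  near <- (gap < d & t(gap) < d) &
    outer(peaks$chrom, peaks$chrom, `==`)
  g <- igraph::graph_from_adjacency_matrix(near, mode = "undirected")
  comp <- igraph::components(g)$membership
  hulls <- do.call(rbind, lapply(split(seq_len(n), comp), function(rows)
    data.frame(chrom = peaks$chrom[rows[1]],
               start = min(peaks$start[rows]),
               end = max(peaks$end[rows]))))
  hulls[order(hulls$chrom, hulls$start), , drop = FALSE]
}

# Connected components of the bipartite >= 1 bp overlap graph between two
# gain sets; per-component union hulls, only components with both sides.
oracle_intersect <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ov <- outer(seq_len(na), seq_len(nb), function(i, j)
    a$chrom[i] == b$chrom[j] & a$start[i] < b$end[j] & b$start[j] < a$end[i])
  adj <- matrix(FALSE, na + nb, na + nb)
  adj[seq_len(na), na + seq_len(nb)] <- ov
  adj[na + seq_len(nb), seq_len(na)] <- t(ov)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  all_iv <- rbind(a[, c("chrom", "start", "end")],
                  b[, c("chrom", "start", "end")])
  side <- rep(c("a", "b"), c(na, nb))
  hulls <- do.call(rbind, lapply(split(seq_len(na + nb), comp), function(m) {
    if (length(unique(side[m])) < 2) return(NULL)
    data.frame(chrom = all_iv$chrom[m[1]], start = min(all_iv$start[m]),
               end = max(all_iv$end[m]))
  }))
  if (is.null(hulls))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  hulls[order(hulls$chrom, hulls$start), , drop = FALSE]
}

# Per-base brute-force coverage of extended fragments on a toy genome,
# folded into bins by plain looping.
oracle_binned_coverage <- function(ext, chrom_len, bin_size) {
  depth <- numeric(chrom_len)
  for (i in seq_len(nrow(ext))) {
    s <- ext$start[i] + 1
    e <- min(ext$end[i], chrom_len)
    if (e >= s) depth[s:e] <- depth[s:e] + 1
  }
  n_bins <- ceiling(chrom_len / bin_size)
  vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_size + 1
    sum(depth[lo:min(b * bin_size, chrom_len)])
  }, numeric(1))
}

# Benjamini-Hochberg step-up, written from the closed form
# q_(i) = min_{j >= i} min(1, m * p_(j) / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum of all table probabilities <= that of the observed
# table (with a small tolerance for ties).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_intervals <- function(n, chroms = "chr1", max_pos = 100000,
                             max_len = 8000) {
  start <- floor(runif(n, 0, max_pos))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + floor(runif(n, 1, max_len)),
             stringsAsFactors = FALSE)
}
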