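#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walk down the ranked list; hits advance by |score|^1 (normalized over the
#' set's total), misses by 1/(N - set size). The enrichment score is the
#' signed maximum deviation of the running sum from zero; the walk returns
#' to zero at the end of the list.
#'
#' @param ranked named numeric vector, sorted in decreasing score order.
#' @param set character vector of gene names.
#' @return list with `es` and `running` (the full walk).
#' @export
enrichment_score <- function(ranked, set) {
  hit <- names(ranked) %in% set
  n_hit <- sum(hit)
  if (n_hit == 0 || n_hit == length(ranked))
    stop("gene set must hit a strict, non-empty subset of the ranking")
  w <- abs(ranked)
  denom_hit <- sum(w[hit])
  if (denom_hit == 0) w[hit] <- 1  # all-zero scores: fall back to unweighted
  denom_hit <- sum(w[hit])
  step <- ifelse(hit, w / denom_hit, -1 / (length(ranked) - n_hit))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment (weight exponent 1) with
#' a gene-label permutation null: for each set, `n_perm` random same-size
#' gene sets are drawn from the ranking. The normalized enrichment score
#' divides the observed ES by the mean |null ES| of matching sign; nominal
#' p is the same-sign null tail fraction; FDR is estimated sign-stratified
#' by comparing the null and observed NES distributions.
#'
#' @param ranked named numeric vector of per-gene scores (any order; sorted
#'   internally, ties broken by name for determinism).
#' @param gene_sets named list of character vectors.
#' @param n_perm permutations per set (default 1000).
#' @param seed integer seed for the permutation null.
#' @return data frame: `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `leading_edge` (semicolon-joined genes before/at the ES extremum).
#' @export
preranked_gsea <- function(ranked, gene_sets, n_perm = 1000, seed = 1) {
  stopifnot(!is.null(names(ranked)))
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  n <- length(ranked)
  usable <- vapply(gene_sets, function(s) sum(names(ranked) %in% s) >= 2,
                   logical(1))
  if (any(!usable))
    warning("skipping gene sets with < 2 members in the ranking: ",
            paste(names(gene_sets)[!usable], collapse = ", "))
  gene_sets <- gene_sets[usable]
  if (length(gene_sets) == 0)
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], names(ranked))
    obs <- enrichment_score(ranked, set)
    null_es <- vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(names(ranked), length(set)))$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    p <- if (length(same)) mean(abs(same) >= abs(obs$es)) else 1 / n_perm
    mean_same <- if (length(same)) mean(abs(same)) else NA_real_
    nes <- if (is.na(mean_same) || mean_same == 0) NA_real_
           else obs$es / mean_same
    null_nes <- if (is.na(mean_same)) numeric(0) else null_es / mean_same
    peak <- which.max(abs(obs$running))
    hit <- names(ranked) %in% set
    le <- if (obs$es >= 0) names(ranked)[seq_len(peak)][hit[seq_len(peak)]]
          else names(ranked)[peak:n][hit[peak:n]]
    list(set = nm, size = length(set), es = obs$es, nes = nes, p = p,
         leading_edge = paste(le, collapse = ";"), null_nes = null_nes)
  })
  out <- data.frame(set = vapply(rows, `[[`, "", "set"),
                    size = vapply(rows, `[[`, numeric(1), "size"),
                    es = vapply(rows, `[[`, numeric(1), "es"),
                    nes = vapply(rows, `[[`, numeric(1), "nes"),
                    p = vapply(rows, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  all_null <- unlist(lapply(rows, `[[`, "null_nes"))
  out$fdr <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num_pool <- all_null[all_null >= 0]; obs_pool <- out$nes[out$nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= nes) else 0
      den <- mean(obs_pool >= nes)
    } else {
      num_pool <- all_null[all_null < 0]; obs_pool <- out$nes[out$nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= nes) else 0
      den <- mean(obs_pool <= nes)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  out$leading_edge <- vapply(rows, `[[`, "", "leading_edge")
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("GMT: line ", bad[1], " has fewer than 3 fields")
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, "", 1))
}
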