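#' Run the full prognostic screen
#'
#' Chains the downstream analyses applied to super-enhancer candidate
#' genes: (1) Welch upregulation filter, tumor vs normal; (2) per-gene
#' median-split 5-year overall survival with the log-rank test, on tumor
#' samples; genes passing both (p < alpha each) are the prognostic set;
#' (3) Z >= 0 alteration calls for the prognostic genes; (4) pairwise
#' mutual exclusivity with BH q-values; (5) survival of altered-in-any vs
#' non-altered patients; (6) preranked GSEA of altered-vs-non-altered
#' log2 fold change against user-supplied gene sets.
#'
#' @param expr numeric genes x samples matrix, log2 scale.
#' @param samples data frame with one row per column of `expr`: `sample`,
#'   `is_tumor` (logical), `time` (days), `event` (0/1; may be NA for
#'   normal samples).
#' @param genes_of_interest character vector of candidate gene symbols
#'   (default: all rows of `expr`).
#' @param gene_sets optional named list for GSEA (e.g. [read_gmt()]).
#' @param alpha significance level for both filters (default 0.05).
#' @param horizon survival truncation, days (default 1825).
#' @param n_perm GSEA permutations (default 1000).
#' @param seed seed for the GSEA permutation null.
#' @return list: `per_gene` (upregulation + survival statistics per
#'   candidate), `prognostic_genes`, `alterations`, `exclusivity`,
#'   `altered_vs_not` (log-rank of altered-in-any vs none, plus KM tables),
#'   `gsea`.
#' @export
run_screen <- function(expr, samples, genes_of_interest = rownames(expr),
                       gene_sets = NULL, alpha = 0.05, horizon = 1825,
                       n_perm = 1000, seed = 1) {
  check_expr(expr)
  stopifnot(nrow(samples) == ncol(expr),
            all(c("sample", "is_tumor", "time", "event") %in% names(samples)))
  goi <- intersect(genes_of_interest, rownames(expr))
  if (length(goi) == 0) stop("no genes of interest found in the matrix")
  is_tumor <- samples$is_tumor
  per_gene <- filter_upregulated(expr[goi, , drop = FALSE], is_tumor, alpha)

  tum <- which(is_tumor)
  surv <- truncate_survival(samples$time[tum], samples$event[tum], horizon)
  km_stats <- lapply(goi, function(g) {
    high <- tryCatch(median_split(expr[g, tum]), error = function(e) NULL)
    if (is.null(high)) return(list(p = NA_real_, chisq = NA_real_))
    lr <- tryCatch(logrank_test(surv$time, surv$event, high),
                   error = function(e) NULL)
    if (is.null(lr)) list(p = NA_real_, chisq = NA_real_) else lr
  })
  per_gene$logrank_chisq <- vapply(km_stats, function(x) x$chisq, numeric(1))
  per_gene$logrank_p <- vapply(km_stats, function(x) x$p, numeric(1))
  per_gene$prognostic <- per_gene$upregulated &
    !is.na(per_gene$logrank_p) & per_gene$logrank_p < alpha
  prognostic <- per_gene$symbol[per_gene$prognostic]

  res <- list(per_gene = per_gene, prognostic_genes = prognostic,
              alterations = NULL, exclusivity = NULL,
              altered_vs_not = NULL, gsea = NULL)
  if (length(prognostic) == 0) return(res)

  alt <- alteration_matrix(expr[prognostic, tum, drop = FALSE])
  res$alterations <- alt
  if (length(prognostic) >= 2) res$exclusivity <- mutual_exclusivity(alt)

  altered_any <- colSums(alt) > 0
  if (any(altered_any) && !all(altered_any)) {
    lr <- tryCatch(logrank_test(surv$time, surv$event, altered_any),
                   error = function(e) NULL)
    res$altered_vs_not <- list(
      logrank = lr,
      n_altered = sum(altered_any),
      km_altered = kaplan_meier(surv$time[altered_any],
                                surv$event[altered_any]),
      km_not = kaplan_meier(surv$time[!altered_any],
                            surv$event[!altered_any]))
    if (!is.null(gene_sets)) {
      ranking <- rowMeans(expr[, tum[altered_any], drop = FALSE]) -
        rowMeans(expr[, tum[!altered_any], drop = FALSE])
      res$gsea <- preranked_gsea(ranking, gene_sets, n_perm = n_perm,
                                 seed = seed)
    }
  }
  res
}
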