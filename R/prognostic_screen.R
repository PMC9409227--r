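#' @importFrom stats t.test fisher.test p.adjust pchisq median sd setNames
#' @importFrom survival Surv survfit survdiff
NULL

check_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || any(!nzchar(rownames(expr))))
    stop("expression matrix must have gene names as rownames")
  invisible(expr)
}

#' Genes upregulated in tumors
#'
#' Welch's two-sided t-test per gene on log2 expression, tumor vs normal;
#' a gene passes when p < `alpha` and the tumor mean exceeds the normal
#' mean. No multiplicity correction is applied at this step.
#'
#' @param expr numeric genes x samples matrix (log2 scale).
#' @param is_tumor logical vector over columns: `TRUE` = tumor sample.
#' @param alpha significance level (default 0.05).
#' @return data frame `symbol`, `mean_tumor`, `mean_normal`, `log2_fc`,
#'   `p`, `upregulated`, one row per gene.
#' @export
filter_upregulated <- function(expr, is_tumor, alpha = 0.05) {
  check_expr(expr)
  stopifnot(length(is_tumor) == ncol(expr))
  if (sum(is_tumor) < 2 || sum(!is_tumor) < 2)
    stop("need at least 2 tumor and 2 normal samples for Welch's t-test")
  res <- t(apply(expr, 1, function(v) {
    tt <- stats::t.test(v[is_tumor], v[!is_tumor])
    c(mean(v[is_tumor]), mean(v[!is_tumor]), tt$p.value)
  }))
  data.frame(symbol = rownames(expr),
             mean_tumor = res[, 1], mean_normal = res[, 2],
             log2_fc = res[, 1] - res[, 2], p = res[, 3],
             upregulated = res[, 3] < alpha & res[, 1] > res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Median split of expression values
#'
#' Values strictly above the median go to the high group; values at or
#' below it to the low group.
#'
#' @param values named numeric vector (one gene's expression per sample).
#' @return logical vector, `TRUE` = high group.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("median split needs >= 2 samples")
  m <- stats::median(values)
  high <- values > m
  if (all(high) || !any(high))
    stop("degenerate median split: all values identical")
  high
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate: at each event time, survival is multiplied by
#' (1 - d/n). Computed via [survival::survfit()].
#'
#' @param time follow-up times (days, >= 0).
#' @param event 1 = death, 0 = censored.
#' @return data frame `time`, `n_risk`, `n_event`, `survival` (step values
#'   after each observed time).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test between two survival groups
#'
#' Standard 1-df log-rank chi-square on observed vs expected events,
#' via [survival::survdiff()].
#'
#' @param time,event survival outcome vectors.
#' @param group logical or two-level factor splitting the samples.
#' @return list with `chisq`, `p`, `n`, and observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  if (sum(event) == 0) stop("log-rank test needs at least one event")
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("log-rank test needs exactly two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd$chisq, p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n), observed = sd$obs, expected = sd$exp)
}

#' Truncate survival at a horizon
#'
#' Events after the horizon are administratively censored at the horizon,
#' matching a fixed-term (e.g. 5-year) overall-survival analysis.
#'
#' @param time,event survival outcome vectors.
#' @param horizon days (default 1825 = 5 years); `Inf` disables truncation.
#' @return list with truncated `time` and `event`.
#' @export
truncate_survival <- function(time, event, horizon = 1825) {
  over <- time > horizon
  list(time = pmin(time, horizon), event = ifelse(over, 0, event))
}

#' Binary alteration calls from tumor expression
#'
#' Per gene, Z = (value - cohort mean) / cohort sd over all tumor samples
#' (log2 scale); a sample is called altered when Z >= 0.
#'
#' @param expr numeric genes x tumor-samples matrix (log2 scale).
#' @return binary (0/1) matrix of the same shape.
#' @export
alteration_matrix <- function(expr) {
  check_expr(expr)
  if (ncol(expr) < 2) stop("alteration calls need >= 2 tumor samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene: ", rownames(expr)[which(sds == 0)[1]])
  z <- (expr - rowMeans(expr)) / sds
  (z >= 0) * 1L
}

#' Pairwise mutual exclusivity / co-occurrence of alteration calls
#'
#' For every unordered gene pair, samples are cross-tabulated by altered
#' status; association is scored by a two-sided Fisher exact test and a
#' log2 odds ratio (Haldane 0.5 correction applied when any cell is zero).
#' P-values are Benjamini-Hochberg adjusted across all pairs. Tendency is
#' `co-occurrence` when the (corrected) odds ratio exceeds 1, otherwise
#' `mutual exclusivity`.
#'
#' @param mat binary genes x samples matrix from [alteration_matrix()].
#' @return data frame per pair: `gene_a`, `gene_b`, `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `log2_or`, `p`, `q`, `tendency`.
#' @export
mutual_exclusivity <- function(mat) {
  if (nrow(mat) < 2) stop("mutual exclusivity needs >= 2 genes")
  pairs <- utils::combn(nrow(mat), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- sum(mat[i, ] == 1 & mat[j, ] == 1)
    b <- sum(mat[i, ] == 1 & mat[j, ] == 0)
    cc <- sum(mat[i, ] == 0 & mat[j, ] == 1)
    d <- sum(mat[i, ] == 0 & mat[j, ] == 0)
    tab <- matrix(c(a, cc, b, d), 2)
    p <- stats::fisher.test(tab)$p.value
    if (any(tab == 0)) tab <- tab + 0.5
    l2or <- log2((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
    data.frame(gene_a = rownames(mat)[i], gene_b = rownames(mat)[j],
               n_both = a, n_a_only = b, n_b_only = cc, n_neither = d,
               log2_or = l2or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$tendency <- ifelse(out$log2_or > 0, "co-occurrence",
                         "mutual exclusivity")
  out
}
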