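#' @importFrom tools md5sum
NULL

write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}

#' Materialize a synthetic study to disk
#'
#' Writes every input the pipeline consumes: chrom.sizes, the gene table,
#' per-sample fragment BEDs and peak files for both lines and conditions,
#' the expression and clinical TSVs, the planted-loci truth table, and a
#' small blacklist. Byte-identical across runs with the same config.
#'
#' @param cfg [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, shaped like the input slots of
#'   [pipeline_config()].
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  gg <- make_genome_and_genes(cfg)
  write_tsv(data.frame(chrom = names(gg$chrom_sizes),
                       size = unname(gg$chrom_sizes)),
            p("chrom.sizes"), col.names = FALSE)
  write_tsv(gg$genes, p("genes.tsv"))
  paths <- list(chrom_sizes = p("chrom.sizes"), genes = p("genes.tsv"),
                fragments = list(), peaks = list())
  for (line in c("A", "B")) for (cond in c("parental", "treated")) {
    sim <- simulate_chip(cfg, line, cond)
    key <- paste0(line, "_", cond)
    paths$fragments[[key]] <- p("fragments_", key, ".bed")
    paths$peaks[[key]] <- p("peaks_", key, ".narrowPeak")
    fr <- sim$fragments
    write_tsv(data.frame(fr$chrom, fr$start, fr$end, fr$name,
                         ifelse(is.na(fr$mapq), ".", fr$mapq), fr$strand),
              paths$fragments[[key]], col.names = FALSE)
    pk <- sim$peaks
    np <- data.frame(pk$chrom, pk$start, pk$end, pk$name, pk$score, ".",
                     0, -1, -1, floor((pk$end - pk$start) / 2))
    write_tsv(np, paths$peaks[[key]], col.names = FALSE)
  }
  # artifact exclusion list: two fixed intervals in the unused left margins
  write_bed(genomic_intervals(names(cfg$genome)[1:2], c(0, 0), c(5000, 5000)),
            p("blacklist.bed"))
  paths$blacklist <- p("blacklist.bed")
  cohort <- simulate_cohort(cfg, gg$genes)
  expr_df <- data.frame(symbol = rownames(cohort$expr),
                        round(cohort$expr, 6), check.names = FALSE)
  write_tsv(expr_df, p("expr.tsv"))
  clin <- cohort$samples
  clin$time <- round(clin$time, 3)
  write_tsv(clin, p("clinical.tsv"))
  write_tsv(planted_truth(cfg), p("truth.tsv"))
  write_tsv(data.frame(symbol = cohort$planted_genes), p("planted_genes.tsv"))
  paths$expr <- p("expr.tsv"); paths$clinical <- p("clinical.tsv")
  paths$truth <- p("truth.tsv"); paths$planted_genes <- p("planted_genes.tsv")
  paths
}

#' Pipeline configuration
#'
#' @param inputs named list of input paths: `fragments` and `peaks` (each a
#'   named list with entries `A_parental`, `A_treated`, `B_parental`,
#'   `B_treated`), `chrom_sizes`, `genes`, optional `blacklist`, `expr`,
#'   `clinical`, optional `gmt` — e.g. the return value of
#'   [write_simulation()].
#' @param out_dir output directory.
#' @param coverage [coverage_params()].
#' @param se_call [se_call_params()].
#' @param annotation [annotation_params()].
#' @param alpha screen significance level.
#' @param horizon survival truncation, days.
#' @param n_perm GSEA permutations.
#' @param seed seed for the screen's stochastic steps.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(inputs, out_dir,
                            coverage = coverage_params(),
                            se_call = se_call_params(),
                            annotation = annotation_params(),
                            alpha = 0.05, horizon = 1825,
                            n_perm = 1000, seed = 1) {
  structure(list(inputs = inputs, out_dir = out_dir, coverage = coverage,
                 se_call = se_call, annotation = annotation, alpha = alpha,
                 horizon = horizon, n_perm = n_perm, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: an `inputs` mapping plus optional
#' `out_dir`, `params` (stitch_distance, top_fraction, extension_length,
#' bin_size, min_mapq, window, alpha, horizon, n_perm, seed).
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  pr <- function(name, default) if (is.null(y$params[[name]])) default
                                else y$params[[name]]
  pipeline_config(
    inputs = y$inputs,
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    coverage = coverage_params(extension_length = pr("extension_length", 200),
                               bin_size = pr("bin_size", 32),
                               min_mapq = pr("min_mapq", 25)),
    se_call = se_call_params(stitch_distance = pr("stitch_distance", 12500),
                             top_fraction = pr("top_fraction", 0.05)),
    annotation = annotation_params(window = pr("window", 50000)),
    alpha = pr("alpha", 0.05), horizon = pr("horizon", 1825),
    n_perm = pr("n_perm", 1000), seed = pr("seed", 1))
}

require_input <- function(inputs, field, stage) {
  path <- inputs[[field]]
  if (is.null(path))
    stop("pipeline config is missing input field '", field,
         "' (needed by stage ", stage, ")")
  path
}

check_file <- function(path, field, stage) {
  if (!file.exists(path))
    stop("stage ", stage, ": input file for '", field,
         "' not found: ", path)
  path
}

#' Run the full pipeline
#'
#' Coverage and super-enhancer calls per line and condition, gain/loss
#' classification per line, cross-line intersection into merged common-gain
#' regions, gene annotation, and the prognostic screen on the annotated
#' genes. Every output file is recorded in a manifest with its MD5
#' checksum; a rerun with the same config is byte-identical.
#'
#' @param config [pipeline_config()].
#' @return list: `se_calls`, `differential`, `merged`, `annotated`,
#'   `screen`, `manifest` (data frame of stage, file, md5).
#' @export
run_pipeline <- function(config) {
  inp <- config$inputs
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(config$out_dir, paste0(...))
  written <- list()
  note <- function(stage, path) written[[length(written) + 1]] <<-
    data.frame(stage = stage, file = path, stringsAsFactors = FALSE)

  cs_path <- check_file(require_input(inp, "chrom_sizes", "coverage"),
                        "chrom_sizes", "coverage")
  cs <- utils::read.table(cs_path, sep = "\t", stringsAsFactors = FALSE)
  chrom_sizes <- stats::setNames(cs[[2]], cs[[1]])
  blacklist <- if (!is.null(inp$blacklist))
    read_bed(check_file(inp$blacklist, "blacklist", "se_calling"))
  se_params <- config$se_call
  se_params$blacklist <- blacklist

  samples <- c("A_parental", "A_treated", "B_parental", "B_treated")
  se_calls <- list()
  for (key in samples) {
    fpath <- check_file(require_input(inp$fragments, key, "coverage"),
                        paste0("fragments/", key), "coverage")
    ppath <- check_file(require_input(inp$peaks, key, "se_calling"),
                        paste0("peaks/", key), "se_calling")
    frags <- filter_fragments(read_fragments(fpath), config$coverage)
    track <- build_coverage(frags, config$coverage, chrom_sizes)
    peaks <- read_narrowpeak(ppath)
    call <- call_se_pipeline(peaks, track, se_params,
                             chroms = names(chrom_sizes))
    se_calls[[key]] <- call
    tab <- call$regions[, c("chrom", "start", "end", "n_peaks",
                            "tag_count", "rank", "is_super")]
    f <- outp("se_", key, ".tsv")
    tab$tag_count <- sprintf("%.6f", tab$tag_count)
    write_tsv(tab, f); note("se_calling", f)
    write_bed(genomic_intervals(tab$chrom[call$regions$is_super],
                                tab$start[call$regions$is_super],
                                tab$end[call$regions$is_super],
                                name = paste0("SE", which(call$regions$is_super))),
              outp("se_", key, ".bed"))
    note("se_calling", outp("se_", key, ".bed"))
  }

  diffs <- list(
    A = classify_gain_loss(se_calls$A_treated, se_calls$A_parental),
    B = classify_gain_loss(se_calls$B_treated, se_calls$B_parental))
  for (ln in names(diffs)) {
    f <- outp("differential_", ln, ".tsv")
    d <- diffs[[ln]]
    d$tag_count <- sprintf("%.6f", d$tag_count)
    write_tsv(d, f); note("differential", f)
  }

  merged <- intersect_gains(gained_regions(diffs$A), gained_regions(diffs$B))
  genes <- read_gene_table(check_file(require_input(inp, "genes", "annotation"),
                                      "genes", "annotation"))
  annotated <- annotate_all(merged, genes, config$annotation)
  merged_tab <- data.frame(
    MergedRegion = annotated$merged_region_id,
    Chromosome = annotated$chrom, Start = annotated$start,
    End = annotated$end, Length = annotated$length,
    GeneList = annotated$genes,
    Position = vapply(annotated$annotations,
                      function(a) paste(a$relation, collapse = ";"),
                      character(1)),
    stringsAsFactors = FALSE)
  f <- outp("merged_gain_regions.tsv")
  write_tsv(merged_tab, f); note("intersection", f)

  screen <- NULL
  goi <- unique(unlist(lapply(annotated$annotations, `[[`, "symbol")))
  if (!is.null(inp$expr) && length(goi)) {
    expr_df <- utils::read.table(check_file(inp$expr, "expr", "screen"),
                                 sep = "\t", header = TRUE,
                                 check.names = FALSE, stringsAsFactors = FALSE)
    expr <- as.matrix(expr_df[, -1, drop = FALSE])
    rownames(expr) <- expr_df[[1]]
    clin <- utils::read.table(check_file(inp$clinical, "clinical", "screen"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    gene_sets <- if (!is.null(inp$gmt))
      read_gmt(check_file(inp$gmt, "gmt", "screen"))
    screen <- run_screen(expr, clin, genes_of_interest = goi,
                         gene_sets = gene_sets, alpha = config$alpha,
                         horizon = config$horizon, n_perm = config$n_perm,
                         seed = config$seed)
    f <- outp("screen_per_gene.tsv")
    pg <- screen$per_gene
    for (cn in c("mean_tumor", "mean_normal", "log2_fc", "p",
                 "logrank_chisq", "logrank_p"))
      pg[[cn]] <- sprintf("%.6g", pg[[cn]])
    write_tsv(pg, f); note("screen", f)
    if (!is.null(screen$exclusivity)) {
      f <- outp("screen_exclusivity.tsv")
      ex <- screen$exclusivity
      for (cn in c("log2_or", "p", "q")) ex[[cn]] <- sprintf("%.6g", ex[[cn]])
      write_tsv(ex, f); note("screen", f)
    }
    if (!is.null(screen$gsea)) {
      f <- outp("screen_gsea.tsv")
      gs <- screen$gsea
      for (cn in c("es", "nes", "p", "fdr")) gs[[cn]] <- sprintf("%.6g", gs[[cn]])
      write_tsv(gs, f); note("screen", f)
    }
  }

  manifest <- do.call(rbind, written)
  manifest$md5 <- unname(tools::md5sum(manifest$file))
  mf <- data.frame(stage = c(manifest$stage, "config"),
                   file = c(manifest$file, "seed"),
                   md5 = c(manifest$md5, as.character(config$seed)),
                   stringsAsFactors = FALSE)
  write_tsv(mf, outp("manifest.tsv"))
  list(se_calls = se_calls, differential = diffs, merged = merged,
       annotated = annotated, screen = screen, manifest = mf)
}
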