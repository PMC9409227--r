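#' @importFrom stats runif rnorm rexp rmultinom
NULL

# deterministic sub-seeds so layout (shared), per-line background, per-sample
# fragments and the cohort draw from independent, reproducible streams
sub_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Synthetic-study configuration
#'
#' Defines the simulated study: two cell lines (A, B) in two conditions
#' (parental, treated) on a small two-chromosome genome, with planted
#' super-enhancers — a constitutive set present in every sample, gain loci
#' added in the treated condition only (a subset shared between the lines,
#' the rest private to each), and one boundary-control locus whose member
#' peaks are spaced beyond the stitch distance — plus a tumor/normal
#' expression cohort whose survival hazard depends on planted genes.
#'
#' @param seed integer master seed; every derived dataset is a pure
#'   function of it.
#' @param genome named vector of chromosome lengths, bp.
#' @param n_background_peaks isolated background peaks per cell line
#'   (spaced beyond the stitch distance so each yields one stitched region).
#' @param n_planted_se constitutive planted super-enhancers (present in
#'   both conditions of both lines).
#' @param n_shared_gain treated-only loci planted at identical coordinates
#'   in both lines.
#' @param n_private_gain treated-only loci private to each line.
#' @param se_peak_count inclusive range of member peaks per planted locus.
#' @param se_gap range of gaps (bp) between member peaks; kept below the
#'   12.5 kb stitch distance so every planted locus stitches into one region.
#' @param peak_width range of planted member-peak widths, bp.
#' @param bg_peak_width range of background peak widths, bp.
#' @param control_gap range of member gaps for the boundary-control locus;
#'   above the stitch distance, so its peaks must not merge.
#' @param enrichment fragment-density fold of planted peak windows over
#'   background.
#' @param n_fragments fragments per sample (exact).
#' @param fragment_length read length before 3' extension, bp.
#' @param n_tumor,n_normal cohort sizes.
#' @param n_planted_genes genes given a tumor expression shift and a
#'   survival effect.
#' @param log2_effect tumor-vs-normal shift of planted genes, log2 units.
#' @param hazard_ratio per-gene hazard multiplier for high (above-median)
#'   expression.
#' @param noise_sd expression noise, log2 units.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             genome = c(chr1 = 5e6, chr2 = 5e6),
                             n_background_peaks = 450,
                             n_planted_se = 12,
                             n_shared_gain = 5,
                             n_private_gain = 2,
                             se_peak_count = c(5, 8),
                             se_gap = c(1000, 11000),
                             peak_width = c(800, 1500),
                             bg_peak_width = c(500, 2000),
                             control_gap = c(13000, 15000),
                             enrichment = 10,
                             n_fragments = 200000,
                             fragment_length = 75,
                             n_tumor = 300,
                             n_normal = 30,
                             n_planted_genes = 4,
                             log2_effect = 1.0,
                             hazard_ratio = 2.0,
                             noise_sd = 0.5) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$genome >= 1), cfg$enrichment > 1, cfg$hazard_ratio > 0,
            cfg$n_fragments >= 1, cfg$n_planted_se >= 1,
            cfg$n_shared_gain >= 1, cfg$n_planted_genes >= 1)
  structure(cfg, class = "synthetic_config")
}

runifi <- function(n, range) floor(runif(n, range[1], range[2] + 1))

# Plant the locus skeleton shared by every sample: loci are assigned
# round-robin to chromosomes and placed left-to-right with wide spacing.
se_layout <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 101))
  roles <- c(rep("base", cfg$n_planted_se),
             rep("shared_gain", cfg$n_shared_gain),
             rep("private_gain_A", cfg$n_private_gain),
             rep("private_gain_B", cfg$n_private_gain),
             "control")
  roles <- sample(roles)
  chroms <- rep(names(cfg$genome), length.out = length(roles))
  loci <- list(); peaks <- list()
  cursor <- stats::setNames(rep(50000, length(cfg$genome)), names(cfg$genome))
  for (i in seq_along(roles)) {
    ch <- chroms[i]
    is_control <- roles[i] == "control"
    n_pk <- if (is_control) 3 else runifi(1, cfg$se_peak_count)
    widths <- runifi(n_pk, cfg$peak_width)
    gaps <- runifi(n_pk - 1, if (is_control) cfg$control_gap else cfg$se_gap)
    starts <- cursor[ch] + cumsum(c(0, widths[-n_pk] + gaps))
    ends <- starts + widths
    span_end <- ends[n_pk]
    if (span_end > cfg$genome[[ch]] - 50000)
      stop("genome too small for the requested planted loci")
    loci[[i]] <- data.frame(locus_id = i, chrom = ch, start = starts[1],
                            end = span_end, role = roles[i],
                            stringsAsFactors = FALSE)
    peaks[[i]] <- data.frame(locus_id = i, chrom = ch, start = starts,
                             end = ends, stringsAsFactors = FALSE)
    cursor[ch] <- span_end + runifi(1, c(100000, 200000))
  }
  list(loci = do.call(rbind, loci), member_peaks = do.call(rbind, peaks))
}

# Background peak layout for one line: positions drawn from a 15-kb grid
# restricted to space > 13 kb away from every planted locus, so background
# peaks never stitch with each other or with planted loci.
background_layout <- function(cfg, line) {
  layout <- se_layout(cfg)
  set.seed(sub_seed(cfg$seed, 300 + match(line, c("A", "B"))))
  grid <- 15000
  margin <- 13000
  wmax <- cfg$bg_peak_width[2]
  cand <- do.call(rbind, lapply(names(cfg$genome), function(ch) {
    pos <- seq(10000, cfg$genome[[ch]] - wmax - 10000, by = grid)
    loc <- layout$loci[layout$loci$chrom == ch, , drop = FALSE]
    ok <- rep(TRUE, length(pos))
    for (k in seq_len(nrow(loc)))
      ok <- ok & (pos + wmax <= loc$start[k] - margin |
                  pos >= loc$end[k] + margin)
    data.frame(chrom = ch, pos = pos[ok], stringsAsFactors = FALSE)
  }))
  if (nrow(cand) < cfg$n_background_peaks)
    stop("genome too small for the requested background peaks")
  pick <- sort(sample(nrow(cand), cfg$n_background_peaks))
  widths <- runifi(cfg$n_background_peaks, cfg$bg_peak_width)
  genomic_intervals(cand$chrom[pick], cand$pos[pick],
                    cand$pos[pick] + widths)
}

#' Truth table of planted loci
#'
#' One row per planted locus with its coordinates, role, and the samples
#' it is active in. `shared_gain` loci have identical coordinates in both
#' lines; `private_gain_*` loci are treated-only and line-specific; `base`
#' and `control` loci are active in every sample.
#'
#' @param cfg [synthetic_config()].
#' @return data frame: `locus_id`, `chrom`, `start`, `end`, `role`,
#'   `line` ("A", "B" or "both"), `condition` ("both" or "treated"),
#'   `is_gain`, `is_shared_gain`.
#' @export
planted_truth <- function(cfg) {
  loci <- se_layout(cfg)$loci
  loci$line <- ifelse(loci$role == "private_gain_A", "A",
                      ifelse(loci$role == "private_gain_B", "B", "both"))
  loci$condition <- ifelse(grepl("gain", loci$role), "treated", "both")
  loci$is_gain <- grepl("gain", loci$role)
  loci$is_shared_gain <- loci$role == "shared_gain"
  loci
}

active_loci <- function(cfg, line, condition) {
  truth <- planted_truth(cfg)
  truth[(truth$line %in% c(line, "both")) &
          (truth$condition == "both" | condition == "treated"), ,
        drop = FALSE]
}

#' Simulate one ChIP sample (fragments + peak calls)
#'
#' Background fragments fall uniformly over the genome; planted member-peak
#' windows of the loci active in (line, condition) receive `enrichment`-fold
#' density. The peak table contains the line's background peaks plus the
#' active member-peak windows (the generator emits peak calls directly from
#' truth; no peak caller is modelled). Fragment count is exactly
#' `n_fragments`; MAPQ values include a low-quality minority so the
#' coverage filters are exercised.
#'
#' @param cfg [synthetic_config()].
#' @param line "A" or "B".
#' @param condition "parental" or "treated".
#' @return list: `fragments` (BED6-like table), `peaks` (narrowPeak-like
#'   table), `truth` (active planted loci).
#' @export
simulate_chip <- function(cfg, line = c("A", "B"),
                          condition = c("parental", "treated")) {
  line <- match.arg(line)
  condition <- match.arg(condition)
  layout <- se_layout(cfg)
  act <- active_loci(cfg, line, condition)
  windows <- layout$member_peaks[layout$member_peaks$locus_id %in%
                                   act$locus_id, , drop = FALSE]
  bg <- background_layout(cfg, line)

  set.seed(sub_seed(cfg$seed, 400 + 2 * (match(line, c("A", "B")) - 1) +
                      match(condition, c("parental", "treated"))))
  # components: one uniform background per chromosome + one per window
  comp_w <- c(unname(cfg$genome),
              (cfg$enrichment - 1) * (windows$end - windows$start))
  counts <- as.vector(stats::rmultinom(1, cfg$n_fragments,
                                       comp_w / sum(comp_w)))
  n_chr <- length(cfg$genome)
  frag_chrom <- character(0); frag_start <- numeric(0)
  for (i in seq_len(n_chr)) {
    u <- floor(runif(counts[i], 0, cfg$genome[[i]] - cfg$fragment_length))
    frag_chrom <- c(frag_chrom, rep(names(cfg$genome)[i], counts[i]))
    frag_start <- c(frag_start, u)
  }
  for (j in seq_len(nrow(windows))) {
    k <- n_chr + j
    u <- floor(runif(counts[k], windows$start[j],
                     windows$end[j] - cfg$fragment_length))
    frag_chrom <- c(frag_chrom, rep(windows$chrom[j], counts[k]))
    frag_start <- c(frag_start, u)
  }
  n <- length(frag_start)
  fragments <- genomic_intervals(
    frag_chrom, frag_start, frag_start + cfg$fragment_length,
    name = paste0("frag", seq_len(n)),
    mapq = sample(c(10, 20, 30, 42, 60), n, replace = TRUE,
                  prob = c(0.03, 0.05, 0.12, 0.30, 0.50)),
    strand = sample(c("+", "-"), n, replace = TRUE))

  peaks <- rbind(
    data.frame(chrom = bg$chrom, start = bg$start, end = bg$end,
               stringsAsFactors = FALSE),
    data.frame(chrom = windows$chrom, start = windows$start,
               end = windows$end, stringsAsFactors = FALSE))
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  peaks <- genomic_intervals(peaks$chrom, peaks$start, peaks$end,
                             name = paste0("peak", seq_len(nrow(peaks))),
                             score = 100)
  list(fragments = fragments, peaks = peaks, truth = act)
}

#' Generate the synthetic genome annotation
#'
#' Non-overlapping genes of 5-50 kb tiled along each chromosome with random
#' inter-gene gaps, on both strands; deterministic under the config seed.
#'
#' @param cfg [synthetic_config()].
#' @return list: `chrom_sizes` (named vector) and `genes` (gene table:
#'   `symbol`, `chrom`, `start`, `end`, `strand`).
#' @export
make_genome_and_genes <- function(cfg) {
  set.seed(sub_seed(cfg$seed, 211))
  genes <- do.call(rbind, lapply(names(cfg$genome), function(ch) {
    pos <- 2000
    rows <- list()
    repeat {
      len <- runifi(1, c(5000, 50000))
      if (pos + len > cfg$genome[[ch]] - 2000) break
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = pos, end = pos + len,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      pos <- pos + len + runifi(1, c(2000, 30000))
    }
    do.call(rbind, rows)
  }))
  if (is.null(genes) || nrow(genes) == 0)
    stop("genome too small to place any gene")
  genes$symbol <- sprintf("SYNG%04d", seq_len(nrow(genes)))
  list(chrom_sizes = cfg$genome,
       genes = genes[, c("symbol", "chrom", "start", "end", "strand")])
}

#' Genes lying near the planted shared-gain loci
#'
#' The generator's own annotation of its truth: genes within `window` bp of
#' (or overlapping) a shared-gain locus. The cohort simulator plants its
#' prognostic genes among these, so the expression screen downstream of the
#' ChIP pipeline can recover them.
#'
#' @param cfg [synthetic_config()].
#' @param genes gene table from [make_genome_and_genes()].
#' @param window flank distance, bp (default 50,000).
#' @return character vector of gene symbols.
#' @export
shared_gain_genes <- function(cfg, genes, window = 50000) {
  truth <- planted_truth(cfg)
  shared <- truth[truth$is_shared_gain, , drop = FALSE]
  flank <- genomic_intervals(shared$chrom, pmax(0, shared$start - window),
                             shared$end + window)
  genes$symbol[gi_overlaps_any(genes, flank)]
}

#' Simulate the tumor/normal expression and survival cohort
#'
#' Expression is Normal(per-gene baseline, `noise_sd`) on the log2 scale;
#' planted genes get `+log2_effect` in tumors. Tumor survival times are
#' exponential with the hazard multiplied by `hazard_ratio` for each
#' planted gene whose expression is above the tumor-cohort median, with
#' independent uniform censoring. Deterministic under the config seed.
#'
#' @param cfg [synthetic_config()].
#' @param genes gene table (expression is simulated for every gene).
#' @param planted_genes symbols to plant; defaults to a seeded draw of
#'   `n_planted_genes` from [shared_gain_genes()].
#' @return list: `expr` (genes x samples log2 matrix), `samples` (data
#'   frame `sample`, `is_tumor`, `time`, `event`), `planted_genes`.
#' @export
simulate_cohort <- function(cfg, genes, planted_genes = NULL) {
  set.seed(sub_seed(cfg$seed, 503))
  if (is.null(planted_genes)) {
    pool <- shared_gain_genes(cfg, genes)
    if (length(pool) < cfg$n_planted_genes)
      stop("not enough genes near shared-gain loci to plant")
    planted_genes <- sort(sample(pool, cfg$n_planted_genes))
  }
  stopifnot(all(planted_genes %in% genes$symbol))
  n_s <- cfg$n_tumor + cfg$n_normal
  is_tumor <- c(rep(TRUE, cfg$n_tumor), rep(FALSE, cfg$n_normal))
  baseline <- runif(nrow(genes), 3, 8)
  expr <- matrix(rnorm(nrow(genes) * n_s, mean = baseline, sd = cfg$noise_sd),
                 nrow = nrow(genes),
                 dimnames = list(genes$symbol,
                                 c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                                   sprintf("N%03d", seq_len(cfg$n_normal)))))
  expr[planted_genes, is_tumor] <- expr[planted_genes, is_tumor] +
    cfg$log2_effect
  # per-tumor hazard: baseline x HR^(number of planted genes above median)
  tum <- which(is_tumor)
  n_high <- colSums(do.call(rbind, lapply(planted_genes, function(g)
    expr[g, tum] > stats::median(expr[g, tum]))))
  # baseline median 1200 days for an all-low patient (5-year OS below 50%
  # once typical planted-gene multipliers apply); censoring follow-up of
  # 500-3650 days keeps most events observable inside the 5-year horizon
  lambda0 <- log(2) / 1200
  t_event <- stats::rexp(cfg$n_tumor,
                         rate = lambda0 * cfg$hazard_ratio^n_high)
  t_cens <- runif(cfg$n_tumor, 500, 3650)
  samples <- data.frame(
    sample = colnames(expr),
    is_tumor = is_tumor,
    time = c(pmin(t_event, t_cens), rep(NA_real_, cfg$n_normal)),
    event = c(as.integer(t_event <= t_cens), rep(NA_integer_, cfg$n_normal)),
    stringsAsFactors = FALSE)
  list(expr = expr, samples = samples, planted_genes = planted_genes)
}
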