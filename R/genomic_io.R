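#' @importFrom utils read.table write.table
NULL

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines, lineno, min_fields, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < min_fields)
  if (length(bad))
    stop(what, ": malformed line ", lineno[bad[1]], " (expected >= ",
         min_fields, " tab-separated fields, found ", n[bad[1]], ")")
  fields
}

num_field <- function(fields, i, lineno, what) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(x))
  if (length(bad))
    stop(what, ": non-numeric field ", i, " at line ", lineno[bad[1]])
  x
}

#' Read an ENCODE narrowPeak (or BED6+) peak file
#'
#' Coordinates are kept 0-based half-open exactly as in the file; input
#' ordering is preserved. Lines starting with `track`, `browser` or `#`
#' are skipped.
#'
#' @param path path to a narrowPeak/BED file with 6-10 columns.
#' @return A peak table: `chrom`, `start`, `end`, `name`, `score`, plus
#'   `summit_offset` when a 10th column is present (`NA` otherwise).
#' @export
read_narrowpeak <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0),
                             name = character(0), score = numeric(0),
                             summit_offset = numeric(0)))
  fields <- split_fields(tl$lines, tl$lineno, 6, "narrowPeak")
  nmax <- max(lengths(fields))
  if (nmax > 10) stop("narrowPeak: more than 10 columns")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = num_field(fields, 2, tl$lineno, "narrowPeak"),
    end = num_field(fields, 3, tl$lineno, "narrowPeak"),
    name = vapply(fields, `[[`, "", 4),
    score = num_field(fields, 5, tl$lineno, "narrowPeak"),
    summit_offset = if (all(lengths(fields) >= 10))
      num_field(fields, 10, tl$lineno, "narrowPeak") else NA_real_,
    stringsAsFactors = FALSE)
  if (any(df$score < 0)) stop("narrowPeak: negative peak score")
  validate_intervals(df, "narrowPeak")
  df
}

#' Read aligned fragments from a BED6-like file
#'
#' Returns every record unfiltered — MAPQ and duplicate filtering are the
#' coverage stage's concern. The score column is interpreted as MAPQ when
#' numeric; a `.` or absent score is recorded as `NA` (treated as passing
#' by [filter_fragments()]).
#'
#' @param path path to a 6-column BED file (chrom, start, end, name,
#'   mapq/score, strand).
#' @return fragment table: `chrom`, `start`, `end`, `name`, `mapq`, `strand`.
#' @export
read_fragments <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0),
                             name = character(0), mapq = numeric(0),
                             strand = character(0)))
  fields <- split_fields(tl$lines, tl$lineno, 6, "fragment BED")
  score_raw <- vapply(fields, `[[`, "", 5)
  mapq <- suppressWarnings(as.numeric(score_raw))
  strand <- vapply(fields, `[[`, "", 6)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("fragment BED: missing or invalid strand at line ", tl$lineno[bad[1]])
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = num_field(fields, 2, tl$lineno, "fragment BED"),
    end = num_field(fields, 3, tl$lineno, "fragment BED"),
    name = vapply(fields, `[[`, "", 4),
    mapq = mapq,
    strand = strand,
    stringsAsFactors = FALSE)
  validate_intervals(df, "fragment BED")
  df
}

#' Read a plain BED file as an interval table
#' @param path path to a BED3+ file.
#' @return interval table with `chrom`, `start`, `end` (and `name` if present).
#' @export
read_bed <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0)
    return(genomic_intervals(character(0), integer(0), integer(0)))
  fields <- split_fields(tl$lines, tl$lineno, 3, "BED")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = num_field(fields, 2, tl$lineno, "BED"),
    end = num_field(fields, 3, tl$lineno, "BED"),
    stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 4)) df$name <- vapply(fields, `[[`, "", 4)
  validate_intervals(df, "BED")
  df
}

#' Write an interval table as BED
#'
#' Only `chrom`, `start`, `end` (and `name`, plus any `score`/`strand`
#' columns present) are written; `write_bed()` then [read_bed()] is the
#' identity on the coordinate columns.
#'
#' @param regions interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_intervals(regions)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(regions))
  out <- regions[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Expects a headerless TSV with columns symbol, chrom, start, end, strand
#' (0-based half-open), or a header line naming those columns in any order.
#'
#' @param path path to the gene TSV.
#' @return gene table: `symbol`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("symbol", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, quote = "")
  if (!has_header) {
    if (ncol(df) < 5) stop("gene table: expected 5 columns")
    names(df)[1:5] <- c("symbol", "chrom", "start", "end", "strand")
  }
  df <- df[, c("symbol", "chrom", "start", "end", "strand")]
  df$chrom <- as.character(df$chrom)
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("gene table: unknown strand symbol '", df$strand[bad[1]],
         "' for gene ", df$symbol[bad[1]])
  validate_intervals(df, "gene table")
  df
}

#' Load the packaged table of 68 published common-gain super-enhancer regions
#'
#' The fixture mirrors the published table of merged super-enhancer gain loci
#' shared by two cetuximab-adapted OSCC cell lines: region number, merged
#' region id, coordinates (0-based half-open; `end - start` equals the printed
#' length for every row), and the ordered gene list with position labels
#' (`in gene` / `upstream` / `downstream`) and an upregulated-in-tumor flag.
#' Gene symbols are stored exactly as printed, including LOC/MIR entries,
#' parenthesized aliases (e.g. `C2orf18(SLC35F6)`) and two OCR-garbled LOC
#' identifiers inherited from text extraction; one row of the source lists one
#' more position label than gene symbols, and the orphan label is retained
#' with an `NA` symbol.
#'
#' @return A list with `regions` (68-row interval table with `region_no`,
#'   `merged_region_id`, `length`) and `genes` (one row per gene entry:
#'   `region_no`, `symbol`, `alias`, `upregulated`, `position`).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_superenhancers.tsv",
                      package = "segain", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "")
  bad <- which(df$end - df$start != df$length)
  if (length(bad))
    stop("fixture corrupted: end - start != length at region_no ",
         df$region_no[bad[1]])
  regions <- genomic_intervals(df$chrom, df$start, df$end,
                               region_no = df$region_no,
                               merged_region_id = df$merged_region_id,
                               length = df$length)
  genes <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    syms <- strsplit(df$genes[i], ";", fixed = TRUE)[[1]]
    ups <- strsplit(df$upregulated[i], ";", fixed = TRUE)[[1]] == "1"
    pos <- strsplit(df$positions[i], ";", fixed = TRUE)[[1]]
    n <- max(length(syms), length(pos))
    length(syms) <- n; length(ups) <- n; length(pos) <- n
    alias <- ifelse(grepl("\\(", syms),
                    sub("^.*\\(([^)]*)\\).*$", "\\1", syms), NA_character_)
    data.frame(region_no = df$region_no[i],
               symbol = sub("\\(.*$", "", syms), alias = alias,
               upregulated = ups, position = pos, stringsAsFactors = FALSE)
  }))
  ok <- genes$position %in% c("in gene", "upstream", "downstream")
  if (!all(ok))
    stop("fixture corrupted: bad position label at region_no ",
         genes$region_no[which(!ok)[1]])
  list(regions = regions, genes = genes)
}
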