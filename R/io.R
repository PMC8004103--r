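# Readers and writers. BED is 0-based half-open, GTF 1-based inclusive;
# both are converted to the package-internal 0-based half-open convention
# at this boundary. Count tables are TSV with a unit_id column followed by
# one column per sample named {assay}_{time}_{replicate}.

#' Read genomic intervals from BED or GTF
#'
#' BED (3-6 columns, tab- or space-separated) is validated line by line so
#' parse errors name the offending line; GTF is parsed with rtracklayer and
#' converted to 0-based half-open coordinates.
#'
#' @param path File path.
#' @param format `"bed"` or `"gtf"`.
#' @return Tibble `chrom`, `start`, `end`, `id`, `score`, `strand` (BED) or
#'   `chrom`, `start`, `end`, `strand`, `id`, `gene_type` (GTF).
#' @export
read_intervals <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "bed") return(read_bed(path))
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  out <- gr_to_tbl(gr)
  out$id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else
    sprintf("feature%05d", seq_along(gr))
  out$gene_type <- if ("gene_type" %in% names(mc)) {
    as.character(mc$gene_type)
  } else NA_character_
  out
}

#' @noRd
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort(sprintf("parse error at line %d: fewer than 3 BED fields", i))
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      abort(sprintf("parse error at line %d: non-numeric coordinates", i))
    }
    if (e <= s) {
      abort(sprintf("validation error at line %d: end <= start", i))
    }
    rows[[i]] <- tibble(
      chrom = f[1], start = s, end = e,
      id = if (length(f) >= 4) f[4] else sprintf("interval%05d", i),
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0,
      strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "."
    )
  }
  list_rbind(rows)
}

#' Write intervals as BED6
#'
#' @param df Interval tibble (`chrom`, `start`, `end`; optional `id`,
#'   `score`, `strand`).
#' @param path Output path.
#' @param id_col,score_col Columns used for the BED name and score fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, id_col = "id", score_col = NULL) {
  name <- if (id_col %in% names(df)) df[[id_col]] else "."
  score <- if (!is.null(score_col) && score_col %in% names(df)) {
    df[[score_col]]
  } else 0
  strand <- if ("strand" %in% names(df)) {
    if_else(df$strand %in% c("+", "-"), df$strand, ".")
  } else "."
  bed <- tibble(chrom = df$chrom, start = format_coord(df$start),
                end = format_coord(df$end), name = name, score = score,
                strand = strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

format_coord <- function(x) sprintf("%.0f", x)

#' Write gene annotations as GTF (1-based, inclusive)
#'
#' @param genes Tibble with `id`, `chrom`, `start`, `end`, `strand` and
#'   optional `gene_type`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  gene_type <- if ("gene_type" %in% names(genes)) genes$gene_type else "mRNA"
  lines <- sprintf(
    '%s\tencoop\tgene\t%s\t%s\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
    genes$chrom, format_coord(genes$start + 1), format_coord(genes$end),
    genes$strand, genes$id, gene_type)
  writeLines(lines, path)
  invisible(path)
}

#' Read a count table with an encoded sample design
#'
#' @param path TSV with a `unit_id` column and `{assay}_{time}_{replicate}`
#'   sample columns; all cells nonnegative integers.
#' @return List with `counts` (wide tibble) and `design` (tibble from
#'   [parse_design()]).
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(counts, "unit_id", "count table")
  if (anyDuplicated(counts$unit_id)) {
    abort("validation error: duplicated unit_id in count table")
  }
  sample_cols <- setdiff(names(counts), "unit_id")
  for (col in sample_cols) {
    v <- counts[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != round(v))) {
      abort(sprintf(
        "validation error: column '%s' has negative or non-integer cells",
        col))
    }
  }
  list(counts = counts, design = parse_design(sample_cols))
}

#' Write a complete synthetic dataset to disk
#'
#' Writes every table the pipeline consumes: `genes.gtf` (1-based,
#' inclusive), `tus.bed`, `enhancer_loci.bed`, `tads.bed`, and per-mark,
#' per-time `peaks_{mark}_{time}.bed` (BED6, 0-based half-open, signal in
#' the score field), plus TSVs `counts.tsv`, `activities.tsv`, `peaks.tsv`,
#' `truth.tsv`, `truth_pairs.tsv`, `de_table.tsv`, `size_factors.tsv`,
#' `design.tsv`, and the generator config as `config.yaml`.
#'
#' @param sim An `encoop_sim` bundle from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "encoop_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(mutate(sim$genes, gene_type = "mRNA"), p("genes.gtf"))
  write_bed(sim$tus, p("tus.bed"))
  write_bed(sim$enhancer_loci, p("enhancer_loci.bed"))
  write_bed(mutate(sim$tads, strand = "."), p("tads.bed"), id_col = "tad_id")
  for (key in unique(paste(sim$peaks$mark, sim$peaks$time_hr))) {
    sel <- paste(sim$peaks$mark, sim$peaks$time_hr) == key
    sub <- sim$peaks[sel, ]
    write_bed(mutate(sub, strand = "."),
              p(sprintf("peaks_%s_%g.bed", sub$mark[1], sub$time_hr[1])),
              id_col = "locus_id", score_col = "signal")
  }
  readr::write_tsv(sim$peaks, p("peaks.tsv"))
  readr::write_tsv(sim$counts, p("counts.tsv"))
  readr::write_tsv(sim$activities, p("activities.tsv"))
  readr::write_tsv(sim$truth, p("truth.tsv"))
  readr::write_tsv(sim$truth_pairs, p("truth_pairs.tsv"))
  readr::write_tsv(sim$de_table, p("de_table.tsv"))
  readr::write_tsv(sim$size_factors_true, p("size_factors.tsv"))
  readr::write_tsv(sim$design, p("design.tsv"))
  readr::write_tsv(sim$chrom_sizes, p("chrom_sizes.tsv"))
  cfg <- unclass(sim$config)
  cfg$class_mix <- as.list(cfg$class_mix)
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}

#' Read a synthetic dataset back from disk
#'
#' Inverse of [write_dataset()] for the tables the pipeline consumes.
#'
#' @param dir Dataset directory.
#' @return List with `genes`, `tus`, `enhancer_loci`, `tads`, `peaks`,
#'   `counts`, `design`, `activities`, `de_table`, `truth`, `truth_pairs`,
#'   `size_factors`.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  rt <- function(f) readr::read_tsv(p(f), show_col_types = FALSE,
                                    progress = FALSE)
  genes <- read_intervals(p("genes.gtf"), "gtf") |>
    select("id", "chrom", "start", "end", "strand", "gene_type")
  cnt <- read_count_table(p("counts.tsv"))
  list(
    genes = genes,
    tus = read_intervals(p("tus.bed"), "bed") |>
      select("id", "chrom", "start", "end", "strand"),
    enhancer_loci = read_intervals(p("enhancer_loci.bed"), "bed") |>
      select("id", "chrom", "start", "end", "strand"),
    tads = read_intervals(p("tads.bed"), "bed") |>
      select(tad_id = "id", "chrom", "start", "end"),
    peaks = rt("peaks.tsv"),
    counts = cnt$counts, design = cnt$design,
    activities = rt("activities.tsv"),
    de_table = rt("de_table.tsv"),
    truth = rt("truth.tsv"),
    truth_pairs = rt("truth_pairs.tsv"),
    size_factors = rt("size_factors.tsv")
  )
}
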