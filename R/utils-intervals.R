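# Interval helpers. All tibbles in this package use 0-based half-open
# coordinates (`start`, `end`); conversion to/from the 1-based conventions of
# GRanges and GTF happens only here and at the I/O boundary.

#' Convert an interval tibble to a GRanges object
#'
#' @param df A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand`.
#' @param keep Additional columns to carry along as metadata columns.
#' @return A `GRanges` object (1-based, inclusive internally to GRanges).
#' @keywords internal
#' @noRd
as_gr <- function(df, keep = character()) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[is.na(s) | !s %in% c("+", "-")] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  for (col in keep) S4Vectors::mcols(gr)[[col]] <- df[[col]]
  gr
}

#' @noRd
gr_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

# Gap distance between interval sets: 0 when overlapping or book-ended,
# otherwise the number of bases strictly between the two intervals.
# Returns, for each row of `x`, the minimum gap to any interval in `y`
# (Inf when `y` has nothing on that chromosome).
#' @noRd
min_gap_distance <- function(x, y) {
  if (nrow(y) == 0L) return(rep(Inf, nrow(x)))
  gx <- as_gr(x)
  gy <- as_gr(y)
  hits <- GenomicRanges::distanceToNearest(gx, gy, ignore.strand = TRUE)
  out <- rep(Inf, nrow(x))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

# Single-linkage merge of intervals with gap <= merge_dist, strand-agnostic.
# Returns merged intervals plus the row indices of `df` in each cluster.
#' @noRd
reduce_intervals <- function(df, merge_dist) {
  gr <- as_gr(df)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_dist + 1L,
                               ignore.strand = TRUE, with.revmap = TRUE)
  out <- gr_to_tbl(red)
  out$strand <- NULL
  out$members <- as.list(S4Vectors::mcols(red)$revmap)
  out
}

# Fraction of `x` interval covered overlap etc: pairwise overlap width in bp
# between two single intervals given as (start, end) 0-based half-open.
#' @noRd
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' @noRd
stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
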