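# RNA-class annotation of transcription units (TUs) called from nascent-RNA
# coverage. Positional rules, applied in order of precedence:
#   1. reference (GENCODE-like) class when a TU covers >60% of a reference
#      transcript (max-fraction transcript wins),
#   2. uaRNA / convRNA around mRNA transcription start sites
#      (1000 bp upstream .. 500 bp downstream window, antisense),
#   3. dsRNA within 1 kb downstream of an mRNA 3' end, or within 10 kb with
#      monotonically diminishing signal,
#   4. discard of remaining TUs overlapping >20% of a reference gene,
#   5. eRNA call: remaining ncRNA TUs within 1 kb of both an ATAC and an
#      H3K4me1 peak at any (possibly different) time point.
# All coordinates 0-based half-open; distances are gap lengths (0 = overlap).

#' Assign reference gene classes to transcription units
#'
#' A TU inherits the gene type of the reference transcript for which the
#' overlap fraction exceeds `min_overlap`, taking the transcript with the
#' maximal fraction when several pass.
#'
#' @param tus Tibble of TUs (`id`, `chrom`, `start`, `end`, `strand`).
#' @param reference Tibble of reference transcripts with a `gene_type` column.
#' @param min_overlap Minimal overlap fraction (strict inequality), default 0.6.
#' @param relative_to Whether the fraction is overlap length divided by the
#'   `"reference"` transcript length (default) or the `"tu"` length.
#' @return Character vector of classes per TU (`NA` when no transcript passes).
#' @export
assign_gencode_class <- function(tus, reference, min_overlap = 0.6,
                                 relative_to = c("reference", "tu")) {
  relative_to <- match.arg(relative_to)
  stopifnot_cols(reference, c("chrom", "start", "end", "gene_type"))
  out <- rep(NA_character_, nrow(tus))
  if (nrow(reference) == 0L || nrow(tus) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(as_gr(tus), as_gr(reference),
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ow <- overlap_width(tus$start[qi], tus$end[qi],
                      reference$start[si], reference$end[si])
  denom <- if (relative_to == "reference") {
    reference$end[si] - reference$start[si]
  } else {
    tus$end[qi] - tus$start[qi]
  }
  frac <- ow / denom
  keep <- frac > min_overlap
  if (!any(keep)) return(out)
  best <- tibble(qi = qi[keep], frac = frac[keep],
                 type = reference$gene_type[si[keep]]) |>
    slice_max(.data$frac, n = 1, by = "qi", with_ties = FALSE)
  out[best$qi] <- best$type
  out
}

# strand-aware helpers: position of the 5' end and signed offset downstream
# of a reference point in the orientation of a given strand
tu_5p <- function(tus) if_else(tus$strand == "+", tus$start, tus$end)
tu_3p <- function(tus) if_else(tus$strand == "+", tus$end, tus$start)

#' Classify TSS-proximal and downstream noncoding RNAs
#'
#' Applies the positional rules for upstream antisense RNA (uaRNA),
#' convergent RNA (convRNA), and downstream RNA (dsRNA) relative to
#' classified mRNA TUs. An antisense TU whose 5' end lies within
#' `upstream`/`downstream` bp of an mRNA TSS is uaRNA when it lies upstream
#' of the TSS and convRNA when it overlaps the TSS region from downstream. A
#' same-strand TU starting within `ds_near` bp downstream of an mRNA 3' end
#' is dsRNA; one starting within `ds_far` bp is dsRNA only when its binned
#' signal diminishes 5' to 3' (Spearman of bin index vs signal
#' \eqn{\le} `ds_rho`).
#'
#' @param tus Tibble of unassigned TUs.
#' @param mrnas Tibble of mRNA TUs (classified in the reference pass).
#' @param upstream,downstream TSS window in bp (default 1000 / 500).
#' @param ds_near,ds_far dsRNA distance limits in bp (default 1000 / 10000).
#' @param signal Optional named list of per-TU numeric coverage vectors used
#'   for the `ds_far` diminishing-signal test; TUs without signal are only
#'   eligible under the `ds_near` rule.
#' @param ds_rho Spearman threshold for "diminishing" (default -0.5).
#' @param n_bins Number of bins for the signal test.
#' @return Character vector per TU: `"uaRNA"`, `"convRNA"`, `"dsRNA"`, or `NA`.
#' @export
classify_positional <- function(tus, mrnas, upstream = 1000, downstream = 500,
                                ds_near = 1000, ds_far = 10000,
                                signal = NULL, ds_rho = -0.5, n_bins = 10) {
  out <- rep(NA_character_, nrow(tus))
  if (nrow(mrnas) == 0L || nrow(tus) == 0L) return(out)
  m5 <- tu_5p(mrnas); m3 <- tu_3p(mrnas)
  msign <- if_else(mrnas$strand == "+", 1, -1)
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    same_chrom <- mrnas$chrom == tu$chrom
    if (!any(same_chrom)) next
    p5 <- tu_5p(tu); p3 <- tu_3p(tu)

    # signed offset of the TU 5' end from each mRNA TSS, downstream positive
    off <- (p5 - m5) * msign
    anti <- same_chrom & mrnas$strand != tu$strand
    in_win <- off >= -upstream & off <= downstream
    cand <- which(anti & in_win)
    if (length(cand)) {
      # uaRNA transcribes away from the gene: its whole body upstream of TSS
      body_max_ds <- pmax((tu$start - m5[cand]) * msign[cand],
                          (tu$end - m5[cand]) * msign[cand])
      if (any(off[cand] <= 0 & body_max_ds <= 0)) {
        out[i] <- "uaRNA"; next
      }
      out[i] <- "convRNA"; next
    }

    # dsRNA: same strand, 5' end downstream of the mRNA 3' end
    ds_off <- (p5 - m3) * msign
    same <- same_chrom & mrnas$strand == tu$strand
    if (any(same & ds_off >= 0 & ds_off <= ds_near)) {
      out[i] <- "dsRNA"; next
    }
    if (any(same & ds_off >= 0 & ds_off <= ds_far) && !is.null(signal) &&
        !is.null(signal[[tu$id]])) {
      sig <- signal[[tu$id]]
      if (tu$strand == "-") sig <- rev(sig)
      bins <- tapply(sig, cut(seq_along(sig), breaks = n_bins, labels = FALSE),
                     mean)
      rho <- suppressWarnings(cor(seq_along(bins), as.numeric(bins),
                                  method = "spearman"))
      if (!is.na(rho) && rho <= ds_rho) out[i] <- "dsRNA"
    }
  }
  out
}

#' Discard unassigned TUs that overlap reference genes
#'
#' TUs still unassigned after the reference and positional passes are marked
#' `discarded` when their overlap with any reference gene exceeds `max_frac`
#' of that gene's length.
#'
#' @inheritParams assign_gencode_class
#' @param max_frac Overlap fraction above which a TU is discarded (default 0.2).
#' @return Logical vector: `TRUE` where the TU is to be discarded.
#' @export
discard_overlapping <- function(tus, reference, max_frac = 0.2,
                                relative_to = c("reference", "tu")) {
  relative_to <- match.arg(relative_to)
  out <- rep(FALSE, nrow(tus))
  if (nrow(reference) == 0L || nrow(tus) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(as_gr(tus), as_gr(reference),
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ow <- overlap_width(tus$start[qi], tus$end[qi],
                      reference$start[si], reference$end[si])
  denom <- if (relative_to == "reference") {
    reference$end[si] - reference$start[si]
  } else {
    tus$end[qi] - tus$start[qi]
  }
  hit_frac <- tapply(ow / denom, qi, max)
  out[as.integer(names(hit_frac))] <- hit_frac > max_frac
  out
}

#' Call enhancer RNAs from chromatin support
#'
#' A TU is an eRNA iff it lies within `max_dist` bp of an ATAC peak AND
#' within `max_dist` bp of an H3K4me1 peak, where each condition may be met
#' at any (possibly different) time point. Distance is the gap length, 0 for
#' overlap.
#'
#' @param tus Tibble of retained unclassified ncRNA TUs.
#' @param peaks Tibble of peaks with columns `mark`, `time_hr`, `chrom`,
#'   `start`, `end`; marks `"ATAC"` and `"H3K4me1"` are used.
#' @param max_dist Maximal gap in bp (default 1000).
#' @return Logical vector: `TRUE` where the TU is called eRNA.
#' @export
call_ernas <- function(tus, peaks, max_dist = 1000) {
  if (nrow(tus) == 0L) return(logical(0))
  atac <- filter(peaks, .data$mark == "ATAC")
  k4 <- filter(peaks, .data$mark == "H3K4me1")
  if (nrow(atac) == 0L || nrow(k4) == 0L) {
    warn("empty ATAC or H3K4me1 peak set: no eRNAs can be called")
    return(rep(FALSE, nrow(tus)))
  }
  min_gap_distance(tus, atac) <= max_dist &
    min_gap_distance(tus, k4) <= max_dist
}

#' Merge eRNA TUs into enhancer units
#'
#' Single-linkage, strand-agnostic merge of eRNA intervals with gap
#' `<= merge_dist`; the operation is idempotent and conserves constituents.
#'
#' @param ernas Tibble of eRNA TUs (`id`, `chrom`, `start`, `end`).
#' @param merge_dist Maximal gap in bp for merging (default 1000).
#' @return Tibble of enhancers: `enhancer_id`, `chrom`, `start`, `end`,
#'   `constituent_tu_ids` (list column).
#' @examples
#' ernas <- tibble::tibble(id = c("a", "b"), chrom = "chr1",
#'                         start = c(100, 1500), end = c(600, 2000),
#'                         strand = c("+", "-"))
#' merge_ernas(ernas)  # gap 900 -> one enhancer [100, 2000)
#' @export
merge_ernas <- function(ernas, merge_dist = 1000) {
  if (nrow(ernas) == 0L) {
    return(tibble(enhancer_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  constituent_tu_ids = list()))
  }
  red <- reduce_intervals(ernas, merge_dist)
  red |>
    arrange(.data$chrom, .data$start) |>
    mutate(enhancer_id = sprintf("enh%04d", row_number()),
           constituent_tu_ids = map(.data$members, ~ ernas$id[.x])) |>
    select("enhancer_id", "chrom", "start", "end", "constituent_tu_ids")
}

#' Length-normalized activity of merged enhancers
#'
#' Constituent eRNA counts are size-factor corrected and normalized to each
#' constituent's own length (per kb) before merging; the normalized values
#' are then summed per enhancer:
#' activity = sum over constituents of (count / size_factor) / (length / 1000).
#'
#' @param enhancers Tibble from [merge_ernas()].
#' @param counts Wide count tibble (`unit_id` plus one column per sample).
#' @param lengths Named numeric vector of TU lengths in bp, or a tibble with
#'   `unit_id`, `length_bp`.
#' @param size_factors Named numeric vector of per-sample size factors, or a
#'   tibble with `sample`, `size_factor`; defaults to 1 for every sample.
#' @return Long tibble: `enhancer_id`, `sample`, `activity`.
#' @export
enhancer_activity <- function(enhancers, counts, lengths, size_factors = NULL) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_bp, lengths$unit_id)
  }
  sample_cols <- setdiff(names(counts), "unit_id")
  if (is.null(size_factors)) {
    size_factors <- setNames(rep(1, length(sample_cols)), sample_cols)
  } else if (is.data.frame(size_factors)) {
    size_factors <- setNames(size_factors$size_factor, size_factors$sample)
  }
  all_tus <- unique(unlist(enhancers$constituent_tu_ids))
  missing <- setdiff(all_tus, counts$unit_id)
  if (length(missing)) {
    abort(sprintf("constituent TU(s) missing from counts: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  long <- counts |>
    filter(.data$unit_id %in% all_tus) |>
    pivot_longer(all_of(sample_cols), names_to = "sample",
                 values_to = "count") |>
    mutate(norm = .data$count / size_factors[.data$sample] /
             (lengths[.data$unit_id] / 1000))
  enhancers |>
    select("enhancer_id", "constituent_tu_ids") |>
    unnest_longer(col = "constituent_tu_ids", values_to = "unit_id") |>
    inner_join(long, by = "unit_id", relationship = "many-to-many") |>
    summarise(activity = sum(.data$norm), .by = c("enhancer_id", "sample"))
}

#' Classify transcription units into RNA classes
#'
#' Runs the full classification pass in order of precedence: reference class,
#' uaRNA/convRNA, dsRNA, discard filter, eRNA call. Every TU ends in exactly
#' one class among `mRNA`, `lincRNA` (or any other reference gene type),
#' `dsRNA`, `uaRNA`, `convRNA`, `eRNA`, `unclassified`, `discarded`.
#'
#' @inheritParams assign_gencode_class
#' @inheritParams classify_positional
#' @inheritParams call_ernas
#' @param peaks Peak tibble for the eRNA call (`mark`, `time_hr`, intervals).
#' @param discard_frac Overlap fraction for the discard filter (default 0.2).
#' @return The `tus` tibble with an added `rna_class` column.
#' @export
classify_tus <- function(tus, reference, peaks,
                         min_overlap = 0.6, discard_frac = 0.2,
                         relative_to = c("reference", "tu"),
                         upstream = 1000, downstream = 500,
                         ds_near = 1000, ds_far = 10000, signal = NULL,
                         max_dist = 1000) {
  relative_to <- match.arg(relative_to)
  stopifnot_cols(tus, c("id", "chrom", "start", "end", "strand"))
  cls <- assign_gencode_class(tus, reference, min_overlap, relative_to)
  mrnas <- tus[which(cls == "mRNA"), ]
  open <- is.na(cls)
  if (any(open)) {
    cls[open] <- classify_positional(tus[open, ], mrnas,
                                     upstream = upstream,
                                     downstream = downstream,
                                     ds_near = ds_near, ds_far = ds_far,
                                     signal = signal)
  }
  open <- is.na(cls)
  if (any(open)) {
    drop <- discard_overlapping(tus[open, ], reference, discard_frac,
                                relative_to)
    cls[open][drop] <- "discarded"
  }
  open <- is.na(cls)
  if (any(open)) {
    is_erna <- call_ernas(tus[open, ], peaks, max_dist)
    cls[open][is_erna] <- "eRNA"
  }
  cls[is.na(cls)] <- "unclassified"
  mutate(tus, rna_class = cls)
}
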