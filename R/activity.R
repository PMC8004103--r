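# Count normalization and differential flagging. The canonical in-memory
# activity representation is a long tibble with columns
# unit_id, assay, time_hr, replicate, value (size-factor- and
# length-normalized synthesis level per kb).

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants equalizing sequencing depth: each sample's
#' factor is the median, over units, of the ratio of its count to the unit's
#' geometric mean across samples. Units with a zero count in any sample are
#' excluded from the median.
#'
#' @param counts Wide count tibble: `unit_id` plus one numeric column per
#'   sample (or a numeric matrix with row names).
#' @return Tibble `sample`, `size_factor`.
#' @examples
#' counts <- tibble::tibble(unit_id = c("a", "b", "c"),
#'                          s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' compute_size_factors(counts)  # 1/sqrt(2), sqrt(2)
#' @export
compute_size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  pos <- rowSums(m <= 0) == 0
  if (!any(pos)) {
    abort("normalization error: no unit has nonzero counts in all samples")
  }
  logm <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(x) exp(median(x - loggeo)))
  tibble(sample = colnames(m), size_factor = unname(sf))
}

#' @noRd
counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  stopifnot_cols(counts, "unit_id")
  m <- as.matrix(counts[setdiff(names(counts), "unit_id")])
  rownames(m) <- counts$unit_id
  storage.mode(m) <- "double"
  m
}

#' Parse an assay_time_replicate sample design from column names
#'
#' @param samples Character vector of sample names of the form
#'   `{assay}_{time}_{replicate}`, e.g. `"TTseq_24_2"`.
#' @return Tibble `sample`, `assay`, `time_hr`, `replicate`.
#' @export
parse_design <- function(samples) {
  m <- stringr::str_match(samples, "^([A-Za-z0-9]+)_([0-9.]+)_([0-9]+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad)) {
    abort(sprintf("design error: cannot parse sample name(s): %s",
                  paste(samples[bad], collapse = ", ")))
  }
  tibble(sample = samples, assay = m[, 2],
         time_hr = as.numeric(m[, 3]), replicate = as.integer(m[, 4]))
}

#' Size-factor- and length-normalize a count table
#'
#' value = count / size_factor / (length / 1000), i.e. synthesis level per kb.
#'
#' @param counts Wide count tibble (`unit_id` + sample columns).
#' @param lengths Named numeric vector of unit lengths in bp, or tibble with
#'   `unit_id`, `length_bp`.
#' @param size_factors Tibble `sample`, `size_factor` or named vector;
#'   computed by [compute_size_factors()] when `NULL`.
#' @param design Tibble as from [parse_design()]; parsed from the sample
#'   column names when `NULL`.
#' @return Long activity tibble: `unit_id`, `assay`, `time_hr`, `replicate`,
#'   `value`.
#' @export
normalize_counts <- function(counts, lengths, size_factors = NULL,
                             design = NULL) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length_bp, lengths$unit_id)
  }
  if (any(lengths <= 0, na.rm = TRUE)) abort("unit lengths must be > 0")
  sample_cols <- setdiff(names(counts), "unit_id")
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  if (is.data.frame(size_factors)) {
    size_factors <- setNames(size_factors$size_factor, size_factors$sample)
  }
  if (any(size_factors <= 0)) abort("size factors must be > 0")
  if (is.null(design)) design <- parse_design(sample_cols)
  missing_len <- setdiff(counts$unit_id, names(lengths))
  if (length(missing_len)) {
    abort(sprintf("missing length for unit(s): %s",
                  paste(head(missing_len, 5), collapse = ", ")))
  }
  counts |>
    pivot_longer(all_of(sample_cols), names_to = "sample",
                 values_to = "count") |>
    mutate(value = as.numeric(.data$count / size_factors[.data$sample] /
                                (lengths[.data$unit_id] / 1000))) |>
    inner_join(design, by = "sample") |>
    select("unit_id", "assay", "time_hr", "replicate", "value")
}

#' Replicate-mean activity per unit and time point
#'
#' @param activity Long activity tibble.
#' @return Tibble `unit_id`, `time_hr`, `value` (mean over replicates).
#' @export
replicate_means <- function(activity) {
  activity |>
    summarise(value = mean(.data$value), .by = c("unit_id", "time_hr")) |>
    arrange(.data$unit_id, .data$time_hr)
}

#' Log2 fold change of replicate-mean activity between two time points
#'
#' @param activity Long activity tibble.
#' @param t Time point (hours) of the numerator.
#' @param t0 Reference time point (default 0).
#' @param pseudocount Added to both means before the ratio.
#' @return Tibble `unit_id`, `log2fc`.
#' @export
log2_fold_change <- function(activity, t, t0 = 0, pseudocount = 0) {
  tp <- unique(activity$time_hr)
  if (!t %in% tp || !t0 %in% tp) {
    abort(sprintf("time point %g or %g not in design", t, t0))
  }
  rm <- replicate_means(activity)
  wide <- rm |>
    filter(.data$time_hr %in% c(t, t0)) |>
    pivot_wider(names_from = "time_hr", values_from = "value")
  tibble(unit_id = wide$unit_id,
         log2fc = log2((wide[[as.character(t)]] + pseudocount) /
                         (wide[[as.character(t0)]] + pseudocount)))
}

#' Flag differentially synthesized units
#'
#' A unit is differential when some contrast has both `|log2fc| >` `lfc_thr`
#' (strict) and `fdr <` `fdr_thr` (strict). With a supplied differential
#' table the printed thresholds are applied as-is. Without one, a stand-in
#' is computed from the activity table: per contrast of each time point
#' against `t0`, a Welch test on `log2(value + 1)` across replicates,
#' Benjamini-Hochberg adjusted over units within the contrast. The stand-in
#' approximates a dedicated count-based differential analysis and is not a
#' reimplementation of one.
#'
#' @param de Differential table (`unit_id`, `contrast`, `log2fc`, `fdr`) or
#'   `NULL` to compute the stand-in from `activity`.
#' @param activity Long activity tibble (stand-in mode only).
#' @param units Units to flag; defaults to all units present.
#' @param lfc_thr,fdr_thr Thresholds (default 1 and 0.05, strict).
#' @param t0 Reference time point for the stand-in contrasts.
#' @return Tibble `unit_id`, `is_differential`.
#' @export
flag_differential <- function(de = NULL, activity = NULL, units = NULL,
                              lfc_thr = 1, fdr_thr = 0.05, t0 = 0) {
  if (is.null(de)) {
    if (is.null(activity)) abort("supply either a differential table or activity")
    de <- welch_de_standin(activity, t0 = t0)
  }
  stopifnot_cols(de, c("unit_id", "log2fc", "fdr"))
  flags <- de |>
    summarise(is_differential = any(abs(.data$log2fc) > lfc_thr &
                                      .data$fdr < fdr_thr),
              .by = "unit_id")
  if (!is.null(units)) {
    missing <- setdiff(units, flags$unit_id)
    if (length(missing)) {
      abort(sprintf("unit(s) absent from differential table: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    flags <- flags |> filter(.data$unit_id %in% units)
  }
  flags
}

# Welch-test stand-in for a count-based differential analysis, on
# log2(value+1); zero-variance groups are handled by direct comparison.
#' @noRd
welch_de_standin <- function(activity, t0 = 0) {
  tps <- setdiff(sort(unique(activity$time_hr)), t0)
  logs <- activity |> mutate(lv = log2(.data$value + 1))
  base <- logs |> filter(.data$time_hr == t0)
  out <- list()
  for (t in tps) {
    cur <- logs |> filter(.data$time_hr == t)
    joined <- inner_join(
      summarise(cur, m1 = mean(.data$lv), s1 = sd(.data$lv), n1 = n(),
                .by = "unit_id"),
      summarise(base, m0 = mean(.data$lv), s0 = sd(.data$lv), n0 = n(),
                .by = "unit_id"),
      by = "unit_id")
    p <- pmap_dbl2(joined, function(m1, s1, n1, m0, s0, n0) {
      if ((is.na(s1) || s1 == 0) && (is.na(s0) || s0 == 0)) {
        return(if (isTRUE(all.equal(m1, m0))) 1 else 0)
      }
      se <- sqrt(s1^2 / n1 + s0^2 / n0)
      if (se == 0) return(1)
      tt <- (m1 - m0) / se
      df <- se^4 / ((s1^2 / n1)^2 / max(n1 - 1, 1) +
                      (s0^2 / n0)^2 / max(n0 - 1, 1))
      2 * pt(-abs(tt), df = max(df, 1))
    })
    out[[length(out) + 1L]] <- tibble(
      unit_id = joined$unit_id,
      contrast = sprintf("%g_vs_%g", t, t0),
      log2fc = joined$m1 - joined$m0,
      fdr = p.adjust(p, method = "BH"))
  }
  list_rbind(out)
}

#' @noRd
pmap_dbl2 <- function(df, f) {
  vapply(seq_len(nrow(df)), function(i) {
    do.call(f, as.list(df[i, c("m1", "s1", "n1", "m0", "s0", "n0")]))
  }, numeric(1))
}

#' Spearman rank correlation
#'
#' Pearson correlation of ranks with average ranks for ties. Constant input
#' yields `NA` with a warning (the coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(10, 20, 15, 40))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warn("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
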