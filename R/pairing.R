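# Enhancer-promoter pairing: the neighboring method (host gene for
# intragenic enhancers, nearest active mRNA on each side otherwise), the
# 1 Mb window method, and the TAD-constrained method (both correlation
# filtered). Pairing output is independent of input row order.

#' Units active at one or more time points
#'
#' A unit is "active/transcribed" when its replicate-mean normalized per-kb
#' activity exceeds `floor` at one or more time points.
#'
#' @param activity Long activity tibble.
#' @param floor Activity floor per kb (default 1).
#' @return Character vector of active unit ids.
#' @export
active_units <- function(activity, floor = 1) {
  replicate_means(activity) |>
    summarise(active = any(.data$value > floor), .by = "unit_id") |>
    filter(.data$active) |>
    pull("unit_id")
}

# reference point of a (strandless, merged) enhancer
enhancer_anchor <- function(enhancers, anchor = c("midpoint", "five_prime")) {
  anchor <- match.arg(anchor)
  if (anchor == "midpoint") {
    floor((enhancers$start + enhancers$end) / 2)
  } else {
    # 5'-most constituent start, approximated by the merged interval start
    enhancers$start
  }
}

empty_pairs <- function() {
  tibble(enhancer_id = character(), gene_id = character(),
         method = character(), relation = character(),
         distance = numeric(), rho = numeric())
}

#' Pair enhancers with neighboring target promoters
#'
#' Intragenic enhancers are paired with the mRNA in whose transcribed region
#' they lie; intergenic enhancers with the closest active mRNA on each side
#' (at most two pairs; one at a chromosome edge). Pairs are then restricted
#' to differentially synthesized genes.
#'
#' @param enhancers Enhancer tibble (`enhancer_id`, `chrom`, `start`, `end`).
#' @param genes mRNA tibble (`id`, `chrom`, `start`, `end`, `strand`).
#' @param activity Long activity tibble covering the genes.
#' @param de Differential flags (`unit_id`, `is_differential`), a differential
#'   table accepted by [flag_differential()], or `NULL` to compute the
#'   stand-in from `activity`.
#' @param activity_floor Floor for gene activity (default 1 per kb).
#' @param lfc_thr,fdr_thr Differential thresholds passed on when `de` is a
#'   table or `NULL`.
#' @return Pair tibble: `enhancer_id`, `gene_id`, `method = "neighboring"`,
#'   `relation` (`intragenic`/`upstream`/`downstream`), `distance` (bp),
#'   `rho` (`NA` for this method).
#' @export
pair_neighboring <- function(enhancers, genes, activity, de = NULL,
                             activity_floor = 1, lfc_thr = 1, fdr_thr = 0.05) {
  if (nrow(enhancers) == 0L || nrow(genes) == 0L) return(empty_pairs())
  flags <- resolve_de_flags(de, activity, lfc_thr, fdr_thr)
  act <- active_units(activity, activity_floor)
  genes <- genes |> filter(.data$id %in% act) |> arrange(.data$start)
  if (nrow(genes) == 0L) return(empty_pairs())

  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    e <- enhancers[i, ]
    g <- genes |> filter(.data$chrom == e$chrom)
    if (nrow(g) == 0L) next
    ow <- overlap_width(e$start, e$end, g$start, g$end)
    if (any(ow > 0)) {
      host <- g[which.max(ow), ]
      out[[length(out) + 1L]] <- tibble(
        enhancer_id = e$enhancer_id, gene_id = host$id,
        relation = "intragenic", distance = 0)
      next
    }
    up <- g |> filter(.data$end <= e$start)
    dn <- g |> filter(.data$start >= e$end)
    if (nrow(up)) {
      d <- e$start - up$end
      best <- up[order(d, up$start), ][1, ]
      out[[length(out) + 1L]] <- tibble(
        enhancer_id = e$enhancer_id, gene_id = best$id,
        relation = "upstream", distance = min(d))
    }
    if (nrow(dn)) {
      d <- dn$start - e$end
      best <- dn[order(d, dn$start), ][1, ]
      out[[length(out) + 1L]] <- tibble(
        enhancer_id = e$enhancer_id, gene_id = best$id,
        relation = "downstream", distance = min(d))
    }
  }
  if (!length(out)) return(empty_pairs())
  list_rbind(out) |>
    filter(.data$gene_id %in% flags$unit_id[flags$is_differential]) |>
    mutate(method = "neighboring", rho = NA_real_) |>
    select("enhancer_id", "gene_id", "method", "relation", "distance", "rho") |>
    arrange(.data$enhancer_id, .data$gene_id)
}

#' Pair enhancers with correlated target promoters within a scope
#'
#' Candidate pairs are (enhancer, differential mRNA) with the gene TSS within
#' `window` bp of the enhancer reference point (`scope = "window"`) or with
#' gene TSS and enhancer midpoint inside a common TAD (`scope = "tad"`).
#' Pairs are kept when the enhancer is also differential and the Spearman
#' correlation of the replicate-mean activity profiles across the time
#' course exceeds `rho_min`.
#'
#' @inheritParams pair_neighboring
#' @param scope `"window"` (linear distance) or `"tad"`.
#' @param tads TAD tibble (`chrom`, `start`, `end`, optional `time_hr`);
#'   required for `scope = "tad"`.
#' @param window Window size in bp (default 1e6).
#' @param rho_min Minimal Spearman correlation (strict; default 0.4).
#' @param anchor Enhancer reference point: interval `"midpoint"` (default) or
#'   `"five_prime"` (merged-interval start).
#' @return Pair tibble as in [pair_neighboring()] with `relation = "scoped"`
#'   and the correlation in `rho`.
#' @export
pair_correlated <- function(enhancers, genes, activity, de = NULL,
                            scope = c("window", "tad"), tads = NULL,
                            window = 1e6, rho_min = 0.4,
                            anchor = c("midpoint", "five_prime"),
                            activity_floor = 1, lfc_thr = 1, fdr_thr = 0.05) {
  scope <- match.arg(scope)
  if (scope == "tad" && (is.null(tads) || nrow(tads) == 0L)) {
    abort("config error: TAD scope requested without a TAD set")
  }
  if (nrow(enhancers) == 0L || nrow(genes) == 0L) return(empty_pairs())
  flags <- resolve_de_flags(de, activity, lfc_thr, fdr_thr)
  diff_ids <- flags$unit_id[flags$is_differential]
  act <- active_units(activity, activity_floor)
  genes <- genes |>
    filter(.data$id %in% act, .data$id %in% diff_ids) |>
    mutate(tss = tu_5p(pick(everything())))
  enh <- enhancers |>
    filter(.data$enhancer_id %in% diff_ids) |>
    mutate(ref = enhancer_anchor(pick(everything()), anchor))
  if (nrow(genes) == 0L || nrow(enh) == 0L) return(empty_pairs())

  cand <- inner_join(
    enh |> select("enhancer_id", "chrom", ref = "ref",
                  e_start = "start", e_end = "end"),
    genes |> select(gene_id = "id", "chrom", "tss"),
    by = "chrom", relationship = "many-to-many")
  cand <- if (scope == "window") {
    cand |> filter(abs(.data$tss - .data$ref) <= window)
  } else {
    mid <- floor((cand$e_start + cand$e_end) / 2)
    keep <- same_tad_membership(cand$chrom, mid, cand$chrom, cand$tss, tads)
    cand[keep, ]
  }
  if (nrow(cand) == 0L) return(empty_pairs())

  prof <- profile_matrix(activity, unique(c(cand$enhancer_id, cand$gene_id)))
  cand$rho <- vapply(seq_len(nrow(cand)), function(i) {
    suppressWarnings(spearman_rho(prof[cand$enhancer_id[i], ],
                                  prof[cand$gene_id[i], ]))
  }, numeric(1))
  cand |>
    filter(!is.na(.data$rho), .data$rho > rho_min) |>
    mutate(method = if (scope == "window") "window" else "tad",
           relation = "scoped",
           distance = abs(.data$tss - .data$ref)) |>
    select("enhancer_id", "gene_id", "method", "relation", "distance", "rho") |>
    arrange(.data$enhancer_id, .data$gene_id)
}

# replicate-mean profiles as a units x time matrix
#' @noRd
profile_matrix <- function(activity, units) {
  rm <- replicate_means(activity |> filter(.data$unit_id %in% units))
  wide <- rm |> pivot_wider(names_from = "time_hr", values_from = "value")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$unit_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

# TRUE where point (chrom1, pos1) and (chrom2, pos2) fall inside one common
# TAD at >= 1 time point
#' @noRd
same_tad_membership <- function(chrom1, pos1, chrom2, pos2, tads) {
  tad_sets <- if ("time_hr" %in% names(tads)) {
    split(tads, tads$time_hr)
  } else {
    list(tads)
  }
  out <- rep(FALSE, length(pos1))
  for (ts in tad_sets) {
    for (j in seq_len(nrow(ts))) {
      inside1 <- chrom1 == ts$chrom[j] & pos1 >= ts$start[j] & pos1 < ts$end[j]
      inside2 <- chrom2 == ts$chrom[j] & pos2 >= ts$start[j] & pos2 < ts$end[j]
      out <- out | (inside1 & inside2)
    }
  }
  out
}

#' @noRd
resolve_de_flags <- function(de, activity, lfc_thr, fdr_thr) {
  if (!is.null(de) && "is_differential" %in% names(de)) {
    return(select(de, "unit_id", "is_differential"))
  }
  flag_differential(de, activity, lfc_thr = lfc_thr, fdr_thr = fdr_thr)
}

#' Fraction of pairs whose ends share a TAD
#'
#' The fraction of enhancer-promoter pairs whose enhancer midpoint and gene
#' TSS fall inside one common TAD at one or more time points.
#'
#' @param pairs Pair tibble (`enhancer_id`, `gene_id`).
#' @param enhancers,genes Interval tibbles providing the coordinates.
#' @param tads TAD tibble (`chrom`, `start`, `end`, optional `time_hr`).
#' @return Fraction in \[0, 1\].
#' @export
same_tad_fraction <- function(pairs, enhancers, genes, tads) {
  if (is.null(tads) || nrow(tads) == 0L) abort("tads must be nonempty")
  if (nrow(pairs) == 0L) return(NaN)
  e <- enhancers[match(pairs$enhancer_id, enhancers$enhancer_id), ]
  g <- genes[match(pairs$gene_id, genes$id), ]
  mid <- floor((e$start + e$end) / 2)
  tss <- tu_5p(g)
  mean(same_tad_membership(e$chrom, mid, g$chrom, tss, tads))
}
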