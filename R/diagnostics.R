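# Robustness diagnostics: cross-method class-overlap enrichment,
# strongest-enhancer dominance, dual-target concordance, and the
# eRNA-inflation simulation.

#' Fisher's exact test for a 2x2 table
#'
#' The p-value is computed from the hypergeometric distribution conditional
#' on the table margins; `side = "two_sided"` sums all tables with
#' probability not exceeding the observed one. The odds ratio is the sample
#' odds ratio `a * d / (b * c)`.
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows (a, b) and (c, d).
#' @param side `"greater"` (enrichment of `a`) or `"two_sided"`.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(5, 0, 0, 5, side = "greater")$p_value  # 1/choose(10, 5)
#' @export
fisher_exact <- function(a, b, c, d, side = c("greater", "two_sided")) {
  side <- match.arg(side)
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    abort("domain error: cells must be nonnegative integers")
  }
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p <- if (side == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  list(odds_ratio = (a * d) / (b * c), p_value = min(p, 1))
}

#' Cross-classification overlap of one class between two runs
#'
#' Builds the 2x2 table of membership in `class_of_interest` under two
#' classifications over their shared gene set and tests enrichment
#' (one-sided greater) with [fisher_exact()].
#'
#' @param classes_a,classes_b Tibbles with `gene_id`, `final_class` (e.g.
#'   [classify_all()] output from two pairing methods).
#' @param class_of_interest Class whose overlap is tested (default
#'   `"synergistic"`).
#' @return List with the 2x2 `table` (matrix), `odds_ratio`, `p_value`,
#'   `n_shared`.
#' @export
class_overlap <- function(classes_a, classes_b,
                          class_of_interest = "synergistic") {
  shared <- intersect(classes_a$gene_id, classes_b$gene_id)
  if (length(shared) == 0L) abort("empty intersection of classified genes")
  in_a <- shared %in%
    classes_a$gene_id[classes_a$final_class == class_of_interest]
  in_b <- shared %in%
    classes_b$gene_id[classes_b$final_class == class_of_interest]
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  ft <- fisher_exact(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                     side = "greater")
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       n_shared = length(shared))
}

#' Contribution of the strongest enhancer per gene
#'
#' For each gene, the fraction of the total time-summed eRNA signal of its
#' paired enhancers contributed by the strongest one.
#'
#' @param pairs Pair tibble (`enhancer_id`, `gene_id`).
#' @param activity Long activity tibble covering the enhancers.
#' @param classes Optional classification tibble (`gene_id`, `final_class`)
#'   to join for per-class summaries.
#' @return Tibble `gene_id`, `n_enhancers`, `strongest_fraction` (in (0, 1])
#'   and, when `classes` is given, `final_class`. Genes with zero total
#'   activity are skipped with a warning.
#' @export
strongest_fraction <- function(pairs, activity, classes = NULL) {
  totals <- replicate_means(activity) |>
    summarise(total = sum(.data$value), .by = "unit_id")
  per_gene <- pairs |>
    distinct(.data$gene_id, .data$enhancer_id) |>
    inner_join(totals, by = c(enhancer_id = "unit_id")) |>
    summarise(n_enhancers = n(),
              gene_total = sum(.data$total),
              strongest = max(.data$total), .by = "gene_id")
  zero <- per_gene$gene_total <= 0
  if (any(zero)) {
    warn(sprintf("%d gene(s) with zero total enhancer activity skipped",
                 sum(zero)))
    per_gene <- per_gene[!zero, ]
  }
  out <- per_gene |>
    transmute(.data$gene_id, .data$n_enhancers,
              strongest_fraction = .data$strongest / .data$gene_total)
  if (!is.null(classes)) {
    out <- inner_join(out, select(classes, "gene_id", "final_class"),
                      by = "gene_id")
  }
  out
}

#' Concordance of regulatory class between dual-target enhancers
#'
#' Over enhancers paired with exactly two classified (additive or
#' synergistic) target genes, counts how often the two targets share a
#' class, and tests the count against a binomial null. By default the null
#' concordance probability is derived from the class marginals,
#' `p0 = sum(class frequency^2)` over classified genes.
#'
#' @param pairs Pair tibble (`enhancer_id`, `gene_id`).
#' @param classes Classification tibble (`gene_id`, `final_class`).
#' @param null_p Null concordance probability; computed from class marginals
#'   when `NULL`.
#' @return List `n_dual`, `n_concordant`, `null_p`, `p_value` (one-sided,
#'   `NA` when no dual-target enhancers exist).
#' @export
dual_target_concordance <- function(pairs, classes, null_p = NULL) {
  classes <- classes |>
    filter(.data$final_class %in% c("additive", "synergistic"))
  linked <- pairs |>
    distinct(.data$enhancer_id, .data$gene_id) |>
    inner_join(select(classes, "gene_id", "final_class"), by = "gene_id")
  duals <- linked |>
    summarise(n_targets = n(),
              concordant = n_distinct(.data$final_class) == 1L,
              .by = "enhancer_id") |>
    filter(.data$n_targets == 2L)
  n_dual <- nrow(duals)
  n_conc <- sum(duals$concordant)
  if (is.null(null_p)) {
    freqs <- table(classes$final_class) / nrow(classes)
    null_p <- sum(freqs^2)
  }
  p <- if (n_dual == 0L) NA_real_ else {
    pbinom(n_conc - 1, n_dual, null_p, lower.tail = FALSE)
  }
  list(n_dual = n_dual, n_concordant = n_conc, null_p = unname(null_p),
       p_value = p)
}

#' Robustness of the synergistic set to simulated eRNA inflation
#'
#' Multiplies every enhancer activity by `factor` (or per-enhancer factors),
#' reruns [classify_all()], and returns the fraction of the original
#' synergistic genes still called synergistic.
#'
#' @param pairs Pair tibble.
#' @param activity Long activity tibble.
#' @param factor Global multiplicative factor (> 0).
#' @param factors Optional named per-enhancer factors overriding `factor`.
#' @param seed Seed passed to [classify_all()].
#' @param ... Further arguments to [classify_all()].
#' @return List `overlap` (fraction, `NA` when no synergistic genes before),
#'   `before`, `after` (the two classifications).
#' @export
inflation_robustness <- function(pairs, activity, factor = 2, factors = NULL,
                                 seed = 1L, ...) {
  if (factor <= 0) abort("factor must be > 0")
  before <- classify_all(pairs, activity, seed = seed, ...)
  enh_ids <- unique(pairs$enhancer_id)
  mult <- if (is.null(factors)) {
    setNames(rep(factor, length(enh_ids)), enh_ids)
  } else {
    m <- factors[enh_ids]
    m[is.na(m)] <- factor
    setNames(as.numeric(m), enh_ids)
  }
  inflated <- activity |>
    mutate(value = if_else(.data$unit_id %in% enh_ids,
                           .data$value * unname(mult[.data$unit_id]),
                           .data$value))
  after <- classify_all(pairs, inflated, seed = seed, ...)
  syn_before <- before$gene_id[before$final_class == "synergistic"]
  syn_after <- after$gene_id[after$final_class == "synergistic"]
  overlap <- if (length(syn_before) == 0L) NA_real_ else {
    length(intersect(syn_before, syn_after)) / length(syn_before)
  }
  list(overlap = overlap, before = before, after = after)
}
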