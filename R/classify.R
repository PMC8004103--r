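# Regulatory-mode classification by relative BIC. The relative BIC of a
# competing model is BIC_additive - BIC_competitor: positive values favor
# the competitor. A gene is synergistic when the relative BIC of the
# exponential model exceeds 2, ambiguous in [0, 2], additive below 0. When
# the logistic model has the strictly lowest BIC, the point with the highest
# summed enhancer activity is excluded once and all models are refit on the
# remaining points; a gene still logistic-lowest after the exclusion round
# is classified logistic.

#' Summed enhancer activity per time point for one gene
#'
#' @param gene_id Gene to evaluate.
#' @param pairs Pair tibble (`enhancer_id`, `gene_id`).
#' @param activity Long activity tibble covering the paired enhancers.
#' @return Tibble `time_hr`, `S` (sum over paired enhancers of the
#'   replicate-mean activity).
#' @export
sum_enhancer_activity <- function(gene_id, pairs, activity) {
  eids <- unique(pairs$enhancer_id[pairs$gene_id == gene_id])
  if (length(eids) == 0L) {
    abort(sprintf("gene '%s' has no paired enhancers", gene_id))
  }
  replicate_means(activity |> filter(.data$unit_id %in% eids)) |>
    summarise(S = sum(.data$value), .by = "time_hr") |>
    arrange(.data$time_hr)
}

#' Classify one gene's regulatory mode
#'
#' Fits the additive, exponential, and logistic models to the promoter
#' trajectory `P` as a function of summed enhancer activity `S` and applies
#' the relative-BIC decision rule (see package description). Exactly
#' `max_rounds` logistic-exclusion rounds are allowed (default one); ties in
#' the maximal-S point are broken toward the latest time point.
#'
#' @param S,P Numeric vectors over the time course (typically 7 points).
#' @param time_hr Optional time stamps used for reporting the excluded point.
#' @param relbic_threshold Relative-BIC threshold favoring the synergistic
#'   model (default 2; the interval `[0, threshold]` is ambiguous).
#' @param max_rounds Maximal number of logistic-exclusion rounds.
#' @param seed Seed for the model fits.
#' @param ... Passed to [fit_cooperation_model()].
#' @return Object of class `encoop_gene_fit`: fits per model, retained
#'   points, optional excluded point, relative BIC, and `final_class` among
#'   `additive`, `synergistic`, `logistic`, `ambiguous`, `unfittable`.
#' @examples
#' S <- 1:7
#' classify_gene(S, 2 * S + 3)$final_class  # "additive"
#' @export
classify_gene <- function(S, P, time_hr = NULL, relbic_threshold = 2,
                          max_rounds = 1L, seed = 1L, ...) {
  if (is.null(time_hr)) time_hr <- seq_along(S)
  res <- list(S = S, P = P, time_hr = time_hr, fits = NULL,
              used_idx = seq_along(S), excluded_point = NA_real_,
              relative_bic = NA_real_, final_class = "unfittable")
  class(res) <- "encoop_gene_fit"
  if (length(unique(S)) == 1L || length(unique(P)) == 1L ||
      !all(is.finite(S)) || !all(is.finite(P))) {
    return(res)
  }

  idx <- seq_along(S)
  rounds <- 0L
  repeat {
    fits <- lapply(c("additive", "exponential", "logistic"), function(m) {
      fit_cooperation_model(S[idx], P[idx], m, seed = seed, ...)
    })
    names(fits) <- c("additive", "exponential", "logistic")
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    logistic_lowest <- bics["logistic"] < bics["additive"] &&
      bics["logistic"] < bics["exponential"]
    if (logistic_lowest && rounds < max_rounds && length(idx) > 4L) {
      smax <- which(S[idx] == max(S[idx]))
      drop <- idx[smax[length(smax)]]   # tie -> latest time point
      res$excluded_point <- time_hr[drop]
      idx <- setdiff(idx, drop)
      rounds <- rounds + 1L
      next
    }
    res$fits <- fits
    res$used_idx <- idx
    if (logistic_lowest) {
      res$final_class <- "logistic"
    } else {
      rel <- unname(bics["additive"] - bics["exponential"])
      res$relative_bic <- rel
      res$final_class <- relbic_class(rel, relbic_threshold)
    }
    return(res)
  }
}

# relative-BIC decision buckets: > threshold synergistic, [0, threshold]
# ambiguous (closed interval), < 0 additive
#' @noRd
relbic_class <- function(rel, threshold = 2) {
  if (rel > threshold) "synergistic" else if (rel >= 0) "ambiguous"
  else "additive"
}

#' @export
print.encoop_gene_fit <- function(x, ...) {
  cat(sprintf("<encoop_gene_fit> class=%s relBIC=%.3g excluded=%s (n=%d)\n",
              x$final_class,
              if (is.na(x$relative_bic)) NA else x$relative_bic,
              if (is.na(x$excluded_point)) "none" else
                format(x$excluded_point),
              length(x$used_idx)))
  invisible(x)
}

#' @method tidy encoop_gene_fit
#' @export
tidy.encoop_gene_fit <- function(x, ...) {
  if (is.null(x$fits)) return(tibble())
  list_rbind(lapply(x$fits, function(f) {
    tibble(model = f$model, alpha = f$params$alpha, beta = f$params$beta,
           delta = f$params$delta, rss = f$rss, bic = f$bic, n = f$n)
  }))
}

#' @method glance encoop_gene_fit
#' @export
glance.encoop_gene_fit <- function(x, ...) {
  tibble(final_class = x$final_class, relative_bic = x$relative_bic,
         excluded_point = x$excluded_point, n_points = length(x$used_idx))
}

#' Classify all multi-enhancer genes
#'
#' Restricts to genes paired with `enhancer_range` enhancers, keeps the top
#' `cor_percentile` fraction by Spearman correlation between the summed
#' enhancer activity and the promoter activity, and classifies each retained
#' gene with [classify_gene()].
#'
#' @param pairs Pair tibble from one pairing method.
#' @param activity Long activity tibble covering genes and enhancers.
#' @param enhancer_range Inclusive range of enhancers per gene (default 2-20).
#' @param cor_percentile Fraction of eligible genes retained, ranked by
#'   correlation (default 0.75).
#' @param relbic_threshold,max_rounds,seed Passed to [classify_gene()].
#' @param ... Passed to [fit_cooperation_model()].
#' @return Tibble of class `encoop_classification`: one row per classified
#'   gene with `final_class`, `relative_bic`, `excluded_point`, `rho`,
#'   `n_enhancers`, and per-model parameter/BIC columns.
#' @export
classify_all <- function(pairs, activity, enhancer_range = c(2L, 20L),
                         cor_percentile = 0.75, relbic_threshold = 2,
                         max_rounds = 1L, seed = 1L, ...) {
  if ("method" %in% names(pairs) && length(unique(pairs$method)) > 1L) {
    warn("pairs from several methods supplied; they are pooled")
  }
  counts <- pairs |>
    distinct(.data$gene_id, .data$enhancer_id) |>
    count(.data$gene_id, name = "n_enhancers") |>
    filter(.data$n_enhancers >= enhancer_range[1],
           .data$n_enhancers <= enhancer_range[2])
  if (nrow(counts) == 0L) {
    warn("no genes eligible for classification")
    return(empty_classification())
  }

  prof <- profile_matrix(activity,
                         unique(c(counts$gene_id,
                                  pairs$enhancer_id[pairs$gene_id %in%
                                                      counts$gene_id])))
  tp <- as.numeric(colnames(prof))
  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    gid <- counts$gene_id[i]
    eids <- unique(pairs$enhancer_id[pairs$gene_id == gid])
    S <- colSums(prof[eids, , drop = FALSE])
    P <- prof[gid, ]
    rho <- suppressWarnings(spearman_rho(S, P))
    rows[[i]] <- tibble(gene_id = gid, n_enhancers = counts$n_enhancers[i],
                        rho = rho, S = list(unname(S)), P = list(unname(P)))
  }
  eligible <- list_rbind(rows) |> filter(!is.na(.data$rho))
  n_keep <- floor(nrow(eligible) * cor_percentile + 1e-9)
  kept <- eligible |>
    arrange(desc(.data$rho), .data$gene_id) |>
    slice_head(n = n_keep)

  out <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    g <- classify_gene(kept$S[[i]], kept$P[[i]], time_hr = tp,
                       relbic_threshold = relbic_threshold,
                       max_rounds = max_rounds, seed = seed, ...)
    out[[i]] <- bind_cols(
      tibble(gene_id = kept$gene_id[i], n_enhancers = kept$n_enhancers[i],
             rho = kept$rho[i]),
      glance(g),
      fit_columns(g$fits))
  }
  res <- list_rbind(out) |> arrange(.data$gene_id)
  class(res) <- c("encoop_classification", class(res))
  res
}

#' @noRd
fit_columns <- function(fits) {
  if (is.null(fits)) {
    fits <- list()
  }
  cols <- list()
  for (m in c("additive", "exponential", "logistic")) {
    f <- fits[[m]]
    cols[[paste0(m, "_alpha")]] <- if (is.null(f)) NA_real_ else f$params$alpha
    cols[[paste0(m, "_beta")]] <- if (is.null(f)) NA_real_ else f$params$beta
    if (m == "logistic") {
      cols[["logistic_delta"]] <- if (is.null(f)) NA_real_ else f$params$delta
    }
    cols[[paste0(m, "_rss")]] <- if (is.null(f)) NA_real_ else f$rss
    cols[[paste0(m, "_bic")]] <- if (is.null(f)) NA_real_ else f$bic
  }
  as_tibble(cols)
}

#' @noRd
empty_classification <- function() {
  res <- tibble(gene_id = character(), n_enhancers = integer(),
                rho = numeric(), final_class = character(),
                relative_bic = numeric(), excluded_point = numeric(),
                n_points = integer())
  class(res) <- c("encoop_classification", class(res))
  res
}

#' @method glance encoop_classification
#' @export
glance.encoop_classification <- function(x, ...) {
  lv <- c("additive", "synergistic", "logistic", "ambiguous", "unfittable")
  cnt <- table(factor(x$final_class, levels = lv))
  bind_cols(tibble(n_genes = nrow(x)),
            as_tibble(as.list(setNames(as.integer(cnt), paste0("n_", lv)))))
}

#' Relative BIC of the additive model against a logarithmic control
#'
#' Fits `P = alpha * ln(S + s0) + beta` and the additive model and returns
#' `BIC_additive - BIC_logarithmic`. The logarithmic model has no mechanistic
#' meaning here; a cohort of additively generated genes should essentially
#' never favor it, making it a negative control for the curve-fitting and
#' relative-BIC machinery.
#'
#' @inheritParams classify_gene
#' @param s0 Offset keeping `S + s0 > 0` (default 1).
#' @param ... Passed to [fit_cooperation_model()].
#' @return List with `relative_bic` (`BIC_additive - BIC_logarithmic`) and
#'   the two fits.
#' @export
log_model_control <- function(S, P, s0 = 1, seed = 1L, ...) {
  fa <- fit_cooperation_model(S, P, "additive", seed = seed, ...)
  fl <- fit_cooperation_model(S, P, "logarithmic", seed = seed, s0 = s0, ...)
  list(relative_bic = fa$bic - fl$bic, additive = fa, logarithmic = fl)
}
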