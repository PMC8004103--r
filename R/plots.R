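# ggplot2 graphics for the main result types.

#' Plot observed and fitted promoter activity for one gene
#'
#' Observed promoter activity against summed enhancer activity, with the
#' fitted additive, exponential, and logistic curves overlaid. Excluded
#' points (logistic-exclusion round) are shown as open circles.
#'
#' @param fit An `encoop_gene_fit` from [classify_gene()].
#' @param n_grid Number of grid points for the fitted curves.
#' @return A ggplot object.
#' @export
plot_gene_fit <- function(fit, n_grid = 200) {
  stopifnot(inherits(fit, "encoop_gene_fit"))
  pts <- tibble(S = fit$S, P = fit$P,
                used = seq_along(fit$S) %in% fit$used_idx)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$S, y = .data$P)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "sum of enhancer activities (per kb)",
                  y = "promoter activity (per kb)",
                  subtitle = sprintf("class: %s%s", fit$final_class,
                                     if (!is.na(fit$relative_bic))
                                       sprintf(" (relative BIC %.2f)",
                                               fit$relative_bic) else "")) +
    ggplot2::theme_minimal()
  if (!is.null(fit$fits)) {
    grid <- seq(min(fit$S), max(fit$S), length.out = n_grid)
    curves <- list_rbind(lapply(fit$fits, function(f) {
      par <- c(f$params$alpha, f$params$beta, f$params$delta)
      tibble(model = f$model, S = grid,
             P = model_predict(f$model, par, grid, f$s0))
    }))
    p <- p + ggplot2::geom_line(
      data = curves, ggplot2::aes(color = .data$model), linewidth = 0.6)
  }
  p
}

#' @describeIn classify_all Relative-BIC distribution of a classification,
#'   colored by final class, with the ambiguous band marked.
#' @param object An `encoop_classification`.
#' @param ... Ignored.
#' @method autoplot encoop_classification
#' @export
autoplot.encoop_classification <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$relative_bic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_bic,
                                   fill = .data$final_class)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = c(0, 2), linetype = "dashed") +
    ggplot2::labs(x = "relative BIC (additive - exponential)", y = "genes",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' @describeIn call_superenhancers Ranked signal ("hockey-stick") curve
#'   with the elbow cutoff.
#' @param object An `encoop_superenhancers` tibble.
#' @param ... Ignored.
#' @method autoplot encoop_superenhancers
#' @export
autoplot.encoop_superenhancers <- function(object, ...) {
  df <- as_tibble(object) |> arrange(desc(.data$rank))
  df$order <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$signal,
                                   color = .data$is_super)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = attr(object, "cutoff_signal"),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "region rank (ascending signal)",
                  y = "width-normalized signal", color = "superenhancer") +
    ggplot2::theme_minimal()
}
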