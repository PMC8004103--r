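# End-to-end pipeline: classify TUs -> call/merge enhancers -> normalize ->
# pair -> classify cooperation -> diagnostics. Stage-by-stage record counts
# are logged; every run writes a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects the dataset location, the pairing/classification thresholds, and
#' the random seed. Thresholds default to the values used throughout the
#' analysis: 1 kb eRNA proximity and merge distances, 1 Mb window, 12.5 kb
#' stitching, |log2FC| > 1 and FDR < 0.05 for differential units, Spearman
#' rho > 0.4 for correlated pairing, relative-BIC threshold 2, 2-20
#' enhancers per gene, top 75% correlation percentile, activity floor 1 per
#' kb.
#'
#' @param data_dir Directory holding a dataset as written by
#'   [write_dataset()] (or equivalent files).
#' @param methods Pairing methods to run: subset of `"neighboring"`,
#'   `"window"`, `"tad"`.
#' @param fit_method Pairing method whose pairs feed the cooperation fits
#'   (default: first of `methods`).
#' @param use_activities Use the deposited activity table directly instead
#'   of normalizing counts (the noiseless route; default `FALSE`).
#' @param use_de_table Use the deposited differential table when present
#'   (default `TRUE`); otherwise the Welch stand-in is computed.
#' @param merge_dist,proximity,window,stitch_dist Distances in bp.
#' @param lfc_thr,fdr_thr,rho_min,relbic_threshold,enhancer_range,
#'   cor_percentile,pseudocount,activity_floor Analysis thresholds.
#' @param max_rounds Logistic-exclusion rounds (default 1).
#' @param seed Integer seed.
#' @return List of class `encoop_config`.
#' @export
pipeline_config <- function(data_dir,
                            methods = c("neighboring", "window", "tad"),
                            fit_method = NULL,
                            use_activities = FALSE,
                            use_de_table = TRUE,
                            merge_dist = 1000, proximity = 1000,
                            window = 1e6, stitch_dist = 12500,
                            lfc_thr = 1, fdr_thr = 0.05, rho_min = 0.4,
                            relbic_threshold = 2,
                            enhancer_range = c(2L, 20L),
                            cor_percentile = 0.75,
                            pseudocount = 1, activity_floor = 1,
                            max_rounds = 1L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  thr <- c(merge_dist, proximity, window, stitch_dist, lfc_thr, fdr_thr,
           rho_min, relbic_threshold, cor_percentile, activity_floor)
  if (any(thr <= 0)) abort("config error: thresholds must be positive")
  structure(
    list(data_dir = data_dir, methods = methods,
         fit_method = fit_method %||% methods[1],
         use_activities = isTRUE(use_activities),
         use_de_table = isTRUE(use_de_table),
         merge_dist = merge_dist, proximity = proximity, window = window,
         stitch_dist = stitch_dist, lfc_thr = lfc_thr, fdr_thr = fdr_thr,
         rho_min = rho_min, relbic_threshold = relbic_threshold,
         enhancer_range = as.integer(enhancer_range),
         cor_percentile = cor_percentile, pseudocount = pseudocount,
         activity_floor = activity_floor, max_rounds = as.integer(max_rounds),
         seed = as.integer(seed)),
    class = "encoop_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return List of class `encoop_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config An `encoop_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[encoop] ", fmt), ...))

#' Run the full enhancer-cooperation pipeline
#'
#' Executes, in order: TU classification, eRNA calling and merging,
#' normalization, enhancer-promoter pairing with every requested method,
#' cooperation-model classification, and diagnostics, writing every
#' intermediate table under `out_dir` together with a run manifest.
#'
#' @param config An `encoop_config` from [pipeline_config()] or a path to a
#'   YAML config.
#' @param out_dir Output directory.
#' @param stages Last stage to run: `"annotate"`, `"pair"`, `"fit"`, or
#'   `"diagnose"` (default; runs everything).
#' @return Invisibly, a list with every intermediate result (classified TUs,
#'   enhancers, activity, pairs per method, classification, diagnostics).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("diagnose", "annotate", "pair", "fit")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "encoop_config"))
  stages <- match.arg(stages)
  depth <- match(stages, c("annotate", "pair", "fit", "diagnose"))
  dat <- read_dataset(config$data_dir)
  if ("tad" %in% config$methods &&
      (is.null(dat$tads) || nrow(dat$tads) == 0L)) {
    abort("config error: TAD pairing requested but no TAD set available")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(out_dir, f)
  res <- list(config = config)

  # --- annotate ---------------------------------------------------------
  reference <- mutate(dat$genes,
                      gene_type = dat$genes$gene_type %||% "mRNA")
  classified <- classify_tus(dat$tus, reference, dat$peaks,
                             max_dist = config$proximity)
  stage_log("TU classes: %s",
            paste(names(table(classified$rna_class)),
                  table(classified$rna_class), sep = "=", collapse = " "))
  ernas <- classified |> filter(.data$rna_class == "eRNA")
  enhancers <- merge_ernas(ernas, config$merge_dist)
  stage_log("%d eRNAs merged into %d enhancers", nrow(ernas), nrow(enhancers))
  res$classified_tus <- classified
  res$enhancers <- enhancers
  write_bed(classified |>
              mutate(label = paste(.data$id, .data$rna_class, sep = "|")),
            o("classified_tus.bed"), id_col = "label")
  write_bed(enhancers, o("enhancers.bed"), id_col = "enhancer_id")
  if (depth == 1L) return(finish_run(res, config, o))

  # --- normalize --------------------------------------------------------
  lengths <- tibble(unit_id = dat$tus$id,
                    length_bp = dat$tus$end - dat$tus$start)
  if (config$use_activities) {
    tu_activity <- dat$activities
    size_factors <- NULL
  } else {
    size_factors <- compute_size_factors(dat$counts)
    tu_activity <- normalize_counts(dat$counts, lengths, size_factors,
                                    design = dat$design)
  }
  # merged-enhancer activity: sum of the constituents' per-kb activities
  enh_activity <- enhancers |>
    select("enhancer_id", "constituent_tu_ids") |>
    tidyr::unnest_longer(col = "constituent_tu_ids", values_to = "unit_id") |>
    inner_join(tu_activity, by = "unit_id",
               relationship = "many-to-many") |>
    summarise(value = sum(.data$value),
              .by = c("enhancer_id", "assay", "time_hr", "replicate")) |>
    rename(unit_id = "enhancer_id")
  gene_ids <- dat$genes$id
  activity <- bind_rows(tu_activity |> filter(.data$unit_id %in% gene_ids),
                        enh_activity)
  res$activity <- activity
  res$size_factors <- size_factors
  readr::write_tsv(activity, o("activity.tsv"))

  # --- differential flags ----------------------------------------------
  de <- if (config$use_de_table && !is.null(dat$de_table)) {
    dat$de_table |>
      filter(.data$unit_id %in% gene_ids) |>
      bind_rows(enhancer_de(dat$de_table, enhancers))
  } else {
    NULL
  }
  flags <- flag_differential(de, activity,
                             lfc_thr = config$lfc_thr,
                             fdr_thr = config$fdr_thr)
  stage_log("%d/%d units differential", sum(flags$is_differential),
            nrow(flags))

  # --- pair -------------------------------------------------------------
  genes_tbl <- dat$genes |> select("id", "chrom", "start", "end", "strand")
  pairs <- list()
  for (m in config$methods) {
    pairs[[m]] <- switch(m,
      neighboring = pair_neighboring(enhancers, genes_tbl, activity, flags,
                                     activity_floor = config$activity_floor),
      window = pair_correlated(enhancers, genes_tbl, activity, flags,
                               scope = "window", window = config$window,
                               rho_min = config$rho_min,
                               activity_floor = config$activity_floor),
      tad = pair_correlated(enhancers, genes_tbl, activity, flags,
                            scope = "tad", tads = dat$tads,
                            rho_min = config$rho_min,
                            activity_floor = config$activity_floor))
    stage_log("method %s: %d pairs", m, nrow(pairs[[m]]))
  }
  res$pairs <- pairs
  readr::write_tsv(list_rbind(pairs), o("pairs.tsv"))
  if (depth == 2L) return(finish_run(res, config, o))

  # --- fit --------------------------------------------------------------
  fit_pairs <- pairs[[config$fit_method]]
  classification <- classify_all(
    fit_pairs, activity, enhancer_range = config$enhancer_range,
    cor_percentile = config$cor_percentile,
    relbic_threshold = config$relbic_threshold,
    max_rounds = config$max_rounds, seed = config$seed)
  stage_log("cooperation classes (%s): %s", config$fit_method,
            paste(names(table(classification$final_class)),
                  table(classification$final_class), sep = "=",
                  collapse = " "))
  res$classification <- classification
  readr::write_tsv(as_tibble(classification), o("classifications.tsv"))
  if (depth == 3L) return(finish_run(res, config, o))

  # --- diagnose ---------------------------------------------------------
  diag <- list()
  if (!is.null(dat$tads) && nrow(dat$tads) > 0L && nrow(fit_pairs) > 0L) {
    diag$same_tad_fraction <- same_tad_fraction(fit_pairs, enhancers,
                                                genes_tbl, dat$tads)
  }
  dom <- strongest_fraction(fit_pairs, activity, classification)
  readr::write_tsv(dom, o("dominance.tsv"))
  diag$dominance_median <- dom |>
    summarise(median_strongest = median(.data$strongest_fraction),
              .by = "final_class")
  conc <- dual_target_concordance(fit_pairs, classification)
  readr::write_tsv(as_tibble(conc[c("n_dual", "n_concordant", "null_p",
                                    "p_value")]),
                  o("concordance.tsv"))
  diag$concordance <- conc
  if ("signal" %in% names(dat$peaks) && nrow(enhancers) > 0L) {
    se <- call_superenhancers(dat$peaks, enhancers,
                              stitch_dist = config$stitch_dist,
                              proximity = config$proximity)
    write_bed(se, o("superenhancers.bed"), id_col = "region_id",
              score_col = "signal")
    diag$superenhancers <- se
  }
  if (length(config$methods) >= 2L && depth >= 4L) {
    others <- setdiff(config$methods, config$fit_method)
    ov <- list()
    for (m in others) {
      cl2 <- classify_all(pairs[[m]], activity,
                          enhancer_range = config$enhancer_range,
                          cor_percentile = config$cor_percentile,
                          relbic_threshold = config$relbic_threshold,
                          max_rounds = config$max_rounds, seed = config$seed)
      if (nrow(cl2) && length(intersect(cl2$gene_id,
                                        classification$gene_id))) {
        co <- class_overlap(classification, cl2)
        ov[[m]] <- tibble(method_a = config$fit_method, method_b = m,
                          both = co$table[1, 1], a_only = co$table[1, 2],
                          b_only = co$table[2, 1], neither = co$table[2, 2],
                          odds_ratio = co$odds_ratio, p_value = co$p_value)
      }
    }
    if (length(ov)) {
      readr::write_tsv(list_rbind(ov), o("overlap_tables.tsv"))
      diag$overlap <- list_rbind(ov)
    }
  }
  res$diagnostics <- diag
  finish_run(res, config, o)
}

# expand a per-TU differential table to merged enhancers (an enhancer is
# differential when one of its constituent eRNA TUs is)
#' @noRd
enhancer_de <- function(de_table, enhancers) {
  if (nrow(enhancers) == 0L) return(de_table[0, ])
  enhancers |>
    select("enhancer_id", "constituent_tu_ids") |>
    tidyr::unnest_longer(col = "constituent_tu_ids", values_to = "unit_id") |>
    inner_join(de_table, by = "unit_id", relationship = "many-to-many") |>
    summarise(log2fc = .data$log2fc[which.max(abs(.data$log2fc))],
              fdr = min(.data$fdr),
              .by = c("enhancer_id", "contrast")) |>
    rename(unit_id = "enhancer_id")
}

#' @noRd
finish_run <- function(res, config, o) {
  manifest <- list(
    package = "encoop",
    version = as.character(utils::packageVersion("encoop")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(res)
}
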