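# Synthetic-data generator. Produces a desk-scale genome with known
# regulatory ground truth: stranded gene and eRNA transcription units, TADs,
# time-stamped ATAC/H3K4me1 peak sets, smooth enhancer activity ramps, gene
# promoter trajectories generated from an additive, exponential, or logistic
# function of summed enhancer activity, and negative-binomial count tables.
# Every generator is deterministic given the config seed.

sim_seed <- function(config, offset) set.seed(config$seed + offset)

#' Generate a synthetic genome annotation
#'
#' Lays out genes, enhancer loci, and TADs on a small multi-chromosome
#' genome. Each gene owns a genomic block; its true enhancers are placed
#' intragenically (so the host-gene pairing rule recovers the ground-truth
#' links exactly), decoy loci are intergenic, and TADs tile each chromosome
#' at block boundaries so a gene and its enhancers always share a TAD.
#'
#' @param config An [sim_config()] object.
#' @return A list with tibbles `genes`, `enhancer_loci`, `tads`,
#'   `chrom_sizes`. Coordinates are 0-based half-open. `enhancer_loci` carries
#'   `role` (`"true"`/`"decoy"`) and `target_gene_id` (NA for decoys).
#' @examples
#' ann <- gen_annotation(sim_config(n_genes = 6, n_enhancers = 20, seed = 1))
#' ann$genes
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "encoop_sim_config"))
  sim_seed(config, 0L)
  n_chrom <- config$n_chromosomes
  n_genes <- config$n_genes
  kmin <- config$enhancers_per_gene[1]
  kmax <- config$enhancers_per_gene[2]

  n_true <- round(config$n_enhancers * (1 - config$decoy_fraction))
  n_decoy <- config$n_enhancers - n_true
  if (config$n_enhancers > 0 &&
      (n_true < n_genes * kmin || n_true > n_genes * kmax)) {
    abort(sprintf(
      paste0("capacity error: %d true enhancer loci cannot be split over %d ",
             "genes with %d-%d enhancers each"),
      n_true, n_genes, kmin, kmax))
  }

  # enhancers per gene, adjusted to hit the total exactly
  if (config$n_enhancers == 0) {
    k <- rep(0L, n_genes)
  } else {
    k <- sample(seq(kmin, kmax), n_genes, replace = TRUE)
    while (sum(k) > n_true) {
      idx <- which(k > kmin)
      i <- idx[sample.int(length(idx), 1L)]
      k[i] <- k[i] - 1L
    }
    while (sum(k) < n_true) {
      idx <- which(k < kmax)
      i <- idx[sample.int(length(idx), 1L)]
      k[i] <- k[i] + 1L
    }
  }

  genes_per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  chrom_names <- paste0("chr", seq_len(n_chrom))
  chrom_sizes <- tibble(chrom = chrom_names,
                        length = round(config$chrom_length))

  margin <- 5000
  genes <- list(); loci <- list(); tads <- list()
  gi <- 0L
  for (ci in seq_len(n_chrom)) {
    n_blk <- genes_per_chrom[ci]
    if (n_blk == 0L) next
    bounds <- round(seq(0, config$chrom_length, length.out = n_blk + 1))
    tads[[ci]] <- tibble(chrom = chrom_names[ci],
                         start = bounds[-length(bounds)],
                         end = bounds[-1],
                         tad_id = sprintf("%s_tad%02d", chrom_names[ci],
                                          seq_len(n_blk)))
    for (bi in seq_len(n_blk)) {
      gi <- gi + 1L
      kg <- k[gi]
      b0 <- bounds[bi]; b1 <- bounds[bi + 1]
      gene_len <- 8000 + 4500 * kg + round(runif(1, 0, 4000))
      if (gene_len + 2 * margin + 10000 > (b1 - b0)) {
        abort(sprintf("capacity error: gene block of %d bp cannot hold a %d bp gene",
                      b1 - b0, gene_len))
      }
      gstart <- b0 + margin +
        round(runif(1, 0, max(0, 0.2 * (b1 - b0 - gene_len - 2 * margin))))
      gend <- gstart + gene_len
      gene_id <- sprintf("gene%03d", gi)
      genes[[gi]] <- tibble(
        id = gene_id, chrom = chrom_names[ci],
        start = gstart, end = gend,
        strand = sample(c("+", "-"), 1L),
        n_enhancers = kg
      )
      if (kg > 0L) {
        # intragenic slots, >= 1.2 kb apart so 1 kb merging keeps them distinct
        int0 <- gstart + 2500; int1 <- gend - 2500
        w <- (int1 - int0) / kg
        len <- round(runif(kg, 500, 1500))
        s <- int0 + (seq_len(kg) - 1) * w +
          round(runif(kg, 0, pmax(1, w - len - 2700)))
        loci[[length(loci) + 1L]] <- tibble(
          id = sprintf("%s_e%02d", gene_id, seq_len(kg)),
          chrom = chrom_names[ci],
          start = round(s), end = round(s) + len,
          strand = sample(c("+", "-"), kg, replace = TRUE),
          role = "true", target_gene_id = gene_id
        )
      }
    }
  }
  genes <- list_rbind(genes)
  tads <- list_rbind(tads)

  if (n_decoy > 0L) {
    host <- rep(seq_len(n_genes), length.out = n_decoy)
    dl <- round(runif(n_decoy, 500, 1500))
    dstart <- numeric(n_decoy)
    per_gene_rank <- stats::ave(host, host, FUN = seq_along)
    for (i in seq_len(n_decoy)) {
      g <- genes[host[i], ]
      blk_end <- tads$end[tads$chrom == g$chrom & tads$start <= g$start &
                            tads$end >= g$end][1]
      r0 <- g$end + 6000 + (per_gene_rank[i] - 1) * 6000
      r1 <- blk_end - 3000 - dl[i]
      if (r1 <= r0) abort("capacity error: no intergenic room for decoy loci")
      dstart[i] <- r0 + round(runif(1, 0, min(r1 - r0, 3000)))
    }
    decoys <- tibble(
      id = sprintf("decoy%03d", seq_len(n_decoy)),
      chrom = genes$chrom[host],
      start = round(dstart), end = round(dstart) + dl,
      strand = sample(c("+", "-"), n_decoy, replace = TRUE),
      role = "decoy", target_gene_id = NA_character_
    )
  } else {
    decoys <- tibble(id = character(), chrom = character(),
                     start = numeric(), end = numeric(), strand = character(),
                     role = character(), target_gene_id = character())
  }
  enhancer_loci <- bind_rows(list_rbind(loci), decoys)

  list(genes = genes, enhancer_loci = enhancer_loci, tads = tads,
       chrom_sizes = chrom_sizes)
}

# normalized logistic-in-time ramp: 0 at t_first, 1 at t_last, monotone
ramp01 <- function(t, onset, slope) {
  g <- plogis(slope * (t - onset))
  (g - g[1]) / (g[length(g)] - g[1])
}

#' Generate ground-truth activity trajectories
#'
#' Gives every enhancer locus a smooth monotone activity ramp over the time
#' course and every gene a promoter trajectory computed from its generating
#' model (additive, exponential, or logistic) applied to the sum of its
#' paired enhancers' activities. Replicate observations carry multiplicative
#' log-normal noise with coefficient of variation `config$noise_cv`.
#'
#' @param annotation Output of [gen_annotation()].
#' @param config An [sim_config()] object.
#' @return A list with:
#'   * `activities`: long tibble (`unit_id`, `assay`, `time_hr`, `replicate`,
#'     `value`) of noisy per-kb synthesis levels,
#'   * `trajectories`: noiseless per-unit trajectories,
#'   * `truth`: per-gene generating class and parameters,
#'   * `truth_pairs`: ground-truth (gene, enhancer locus) links,
#'   * `enhancer_truth`: per-locus ramp parameters.
#' @export
gen_activities <- function(annotation, config) {
  stopifnot(inherits(config, "encoop_sim_config"))
  sim_seed(config, 1L)
  tp <- config$time_points_hr
  genes <- annotation$genes
  loci <- annotation$enhancer_loci

  # per-gene generating class, proportions as configured
  mix <- config$class_mix
  n_g <- nrow(genes)
  n_per <- floor(mix * n_g)
  rest <- n_g - sum(n_per)
  extra <- rep(names(mix), length.out = max(rest, 0))
  classes <- sample(c(rep(names(mix), n_per), extra))

  # coherent direction per gene so eRNA and mRNA profiles correlate
  gene_dir <- sample(c("up", "down"), n_g, replace = TRUE)
  dir_of <- setNames(gene_dir, genes$id)

  et <- loci |>
    mutate(
      direction = if_else(.data$role == "true",
                          dir_of[.data$target_gene_id],
                          sample(c("up", "down"), n(), replace = TRUE)),
      onset_hr = runif(n(), 18, 72),
      slope = runif(n(), 0.1, 0.25),
      base = runif(n(), 20, 80),
      amplitude = runif(n(), 150, 500)
    )

  enh_traj <- et |>
    rowwise() |>
    reframe(unit_id = .data$id, time_hr = tp,
            value_true = {
              g <- ramp01(tp, .data$onset_hr, .data$slope)
              if (.data$direction == "down") g <- 1 - g
              .data$base + .data$amplitude * g
            })

  s_wide <- enh_traj |>
    inner_join(select(et, "id", "target_gene_id"),
               by = c(unit_id = "id")) |>
    filter(!is.na(.data$target_gene_id)) |>
    summarise(S = sum(.data$value_true),
              .by = c("target_gene_id", "time_hr"))

  truth <- tibble(gene_id = genes$id, true_class = classes,
                  alpha = NA_real_, beta = NA_real_, delta = NA_real_)
  gene_traj <- vector("list", n_g)
  for (i in seq_len(n_g)) {
    S <- s_wide$S[s_wide$target_gene_id == genes$id[i]]
    S <- S[order(s_wide$time_hr[s_wide$target_gene_id == genes$id[i]])]
    if (length(S) == 0L) S <- rep(0, length(tp))
    rng <- max(S) - min(S)
    p <- switch(classes[i],
      additive = {
        a <- runif(1, 0.3, 1); b <- runif(1, 5, 30)
        list(alpha = a, beta = b, delta = NA_real_, P = a * S + b)
      },
      exponential = {
        r <- runif(1, 2, 3.5); a <- r / rng
        b <- log(runif(1, 5, 20)) - a * min(S)
        list(alpha = a, beta = b, delta = NA_real_, P = exp(a * S + b))
      },
      logistic = {
        d <- runif(1, 100, 600); a <- runif(1, 6, 9) / rng
        mid <- min(S) + runif(1, 0.45, 0.6) * rng
        b <- -a * mid
        list(alpha = a, beta = b, delta = d,
             P = d / (1 + exp(-(a * S + b))))
      },
      abort(sprintf("unknown generating model '%s' in class_mix", classes[i]))
    )
    truth$alpha[i] <- p$alpha; truth$beta[i] <- p$beta; truth$delta[i] <- p$delta
    gene_traj[[i]] <- tibble(unit_id = genes$id[i], time_hr = tp,
                             value_true = p$P)
  }
  trajectories <- bind_rows(enh_traj, list_rbind(gene_traj))

  # replicate observations with multiplicative log-normal noise
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  reps <- seq_len(config$n_replicates)
  activities <- trajectories |>
    cross_join(tibble(replicate = reps)) |>
    mutate(assay = "TTseq",
           value = .data$value_true *
             if (sdlog > 0) exp(rnorm(n(), 0, sdlog)) else 1) |>
    select("unit_id", "assay", "time_hr", "replicate", "value")

  list(
    activities = activities,
    trajectories = trajectories,
    truth = truth,
    truth_pairs = loci |> filter(.data$role == "true") |>
      transmute(gene_id = .data$target_gene_id, locus_id = .data$id),
    enhancer_truth = et |>
      select("id", "role", "target_gene_id", "direction", "onset_hr",
             "slope", "base", "amplitude")
  )
}

#' Generate integer count tables from activities
#'
#' The observation layer: expected count = activity (per kb) x unit length
#' (kb) x per-sample size factor; counts are negative-binomially distributed
#' with dispersion `config$nb_dispersion` (Poisson at dispersion 0).
#'
#' @param activities Long activity tibble as produced by [gen_activities()]
#'   (`unit_id`, `time_hr`, `replicate`, `value`), values nonnegative.
#' @param annotation Output of [gen_annotation()]; supplies unit lengths.
#' @param config An [sim_config()] object.
#' @return A list with `counts` (wide tibble: `unit_id` then one
#'   `TTseq_{time}_{rep}` column per sample) and `size_factors`
#'   (`sample`, `size_factor`; geometric mean 1).
#' @export
gen_counts <- function(activities, annotation, config) {
  stopifnot(inherits(config, "encoop_sim_config"))
  if (any(activities$value < 0)) abort("activities must be nonnegative")
  sim_seed(config, 2L)
  lengths <- bind_rows(
    annotation$genes |> select("id", "start", "end"),
    annotation$enhancer_loci |> select("id", "start", "end")
  ) |> transmute(unit_id = .data$id, length_bp = .data$end - .data$start)

  samples <- activities |>
    distinct(.data$time_hr, .data$replicate) |>
    arrange(.data$time_hr, .data$replicate) |>
    mutate(sample = sprintf("TTseq_%g_%d", .data$time_hr, .data$replicate))
  sf <- exp(rnorm(nrow(samples), 0, 0.25))
  sf <- sf / exp(mean(log(sf)))
  size_factors <- tibble(sample = samples$sample, size_factor = sf)

  long <- activities |>
    inner_join(samples, by = c("time_hr", "replicate")) |>
    inner_join(lengths, by = "unit_id") |>
    inner_join(size_factors, by = "sample") |>
    mutate(mu = .data$value * (.data$length_bp / 1000) * .data$size_factor,
           count = if (config$nb_dispersion == 0) {
             rpois(n(), .data$mu)
           } else {
             rnbinom(n(), mu = .data$mu, size = 1 / config$nb_dispersion)
           })
  counts <- long |>
    select("unit_id", "sample", "count") |>
    pivot_wider(names_from = "sample", values_from = "count") |>
    arrange(match(.data$unit_id, lengths$unit_id))
  list(counts = counts, size_factors = size_factors)
}

#' Generate ATAC and H3K4me1 peak sets
#'
#' Every true enhancer locus receives both an ATAC and an H3K4me1 peak
#' overlapping it at one or more time points; a configurable fraction of
#' decoy loci receives a single mark only (the rest receive none), so the
#' two-mark eRNA predicate rejects all decoys.
#'
#' @param annotation Output of [gen_annotation()].
#' @param config An [sim_config()] object.
#' @return Tibble of peaks: `mark`, `time_hr`, `chrom`, `start`, `end`,
#'   `signal`, `locus_id`.
#' @export
gen_peaks <- function(annotation, config) {
  stopifnot(inherits(config, "encoop_sim_config"))
  sim_seed(config, 3L)
  tp <- config$time_points_hr
  loci <- annotation$enhancer_loci
  if (nrow(loci) == 0L) {
    return(tibble(mark = character(), time_hr = numeric(), chrom = character(),
                  start = numeric(), end = numeric(), signal = numeric(),
                  locus_id = character()))
  }

  peaks_for <- function(locus, mark) {
    present <- runif(length(tp)) < 0.7
    if (!any(present)) present[sample(length(tp), 1L)] <- TRUE
    t_here <- tp[present]
    tibble(
      mark = mark, time_hr = t_here, chrom = locus$chrom,
      start = pmax(0, locus$start - round(runif(length(t_here), 0, 300))),
      end = locus$end + round(runif(length(t_here), 0, 300)),
      signal = exp(rnorm(length(t_here), log(20), 0.6)),
      locus_id = locus$id
    )
  }

  out <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    if (locus$role == "true") {
      out[[length(out) + 1L]] <- peaks_for(locus, "ATAC")
      out[[length(out) + 1L]] <- peaks_for(locus, "H3K4me1")
    } else if (runif(1) < config$decoy_single_mark) {
      out[[length(out) + 1L]] <- peaks_for(locus, sample(c("ATAC", "H3K4me1"), 1L))
    }
  }
  list_rbind(out)
}

#' Simulate a complete synthetic dataset
#'
#' Runs [gen_annotation()], [gen_activities()], [gen_counts()], and
#' [gen_peaks()] and assembles the bundle every downstream stage consumes:
#' transcription units, a GENCODE-like reference, peaks, TADs, counts, and a
#' differential table derived from the noiseless trajectories.
#'
#' @param config An [sim_config()] object.
#' @param pseudocount Pseudocount for the truth-derived log2 fold changes.
#' @return A list of class `encoop_sim`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 6, n_enhancers = 20, seed = 1))
#' names(sim)
#' @export
simulate_dataset <- function(config = sim_config(), pseudocount = 1) {
  ann <- gen_annotation(config)
  act <- gen_activities(ann, config)
  cnt <- gen_counts(act$activities, ann, config)
  peaks <- gen_peaks(ann, config)

  tus <- bind_rows(
    ann$genes |> select("id", "chrom", "start", "end", "strand"),
    ann$enhancer_loci |> select("id", "chrom", "start", "end", "strand")
  )
  reference <- ann$genes |>
    select("id", "chrom", "start", "end", "strand") |>
    mutate(gene_type = "mRNA")

  # truth-derived differential table (stands in for an ingested DE analysis)
  t0 <- config$time_points_hr[1]
  de_table <- act$trajectories |>
    mutate(v0 = .data$value_true[.data$time_hr == t0][1],
           .by = "unit_id") |>
    filter(.data$time_hr != t0) |>
    transmute(unit_id = .data$unit_id,
              contrast = sprintf("%g_vs_%g", .data$time_hr, t0),
              log2fc = log2((.data$value_true + pseudocount) /
                              (.data$v0 + pseudocount)),
              fdr = if_else(abs(.data$log2fc) > 0.1, 1e-9, 1))

  design <- act$activities |>
    distinct(.data$assay, .data$time_hr, .data$replicate) |>
    mutate(sample = sprintf("%s_%g_%d", .data$assay, .data$time_hr,
                            .data$replicate))

  structure(
    list(config = config, genes = ann$genes,
         enhancer_loci = ann$enhancer_loci, tads = ann$tads,
         chrom_sizes = ann$chrom_sizes, tus = tus, reference = reference,
         activities = act$activities, trajectories = act$trajectories,
         truth = act$truth, truth_pairs = act$truth_pairs,
         enhancer_truth = act$enhancer_truth,
         counts = cnt$counts, size_factors_true = cnt$size_factors,
         peaks = peaks, de_table = de_table, design = design),
    class = "encoop_sim"
  )
}

#' @export
print.encoop_sim <- function(x, ...) {
  cat("<encoop_sim>\n")
  cat(sprintf("  %d genes, %d enhancer loci (%d true), %d TADs\n",
              nrow(x$genes), nrow(x$enhancer_loci),
              sum(x$enhancer_loci$role == "true"), nrow(x$tads)))
  cat(sprintf("  %d samples, %d count rows\n",
              nrow(x$design), nrow(x$counts)))
  cat(sprintf("  true classes: %s\n",
              paste(names(table(x$truth$true_class)),
                    table(x$truth$true_class), sep = "=", collapse = " ")))
  invisible(x)
}
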