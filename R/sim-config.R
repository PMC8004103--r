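#' Configuration for the synthetic-data generator
#'
#' Bundles the genome layout, experimental design, and noise model used by
#' [simulate_dataset()] and the `gen_*` functions. Defaults describe a
#' desk-scale genome (2 chromosomes of 10 Mb, 60 genes, 200 enhancer loci)
#' observed with the seven-time-point, two-replicate TT-seq design of the
#' transdifferentiation time course the pipeline targets.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of protein-coding genes.
#' @param n_enhancers Total number of enhancer loci (true regulatory loci plus
#'   intergenic decoys).
#' @param time_points_hr Sampling times in hours, strictly increasing.
#' @param n_replicates Replicates per time point.
#' @param class_mix Named proportions over the generating models
#'   `additive`, `exponential`, `logistic`; must sum to 1.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   replicate noise applied to synthesis levels (0 = noiseless).
#' @param nb_dispersion Negative-binomial dispersion of the count layer
#'   (0 = Poisson).
#' @param enhancers_per_gene Integer range `c(min, max)` of true enhancers
#'   assigned per gene (the cooperation analysis considers 2--20).
#' @param decoy_fraction Fraction of `n_enhancers` that are decoy loci:
#'   transcribed but not regulating any gene.
#' @param decoy_single_mark Fraction of decoy loci receiving only one
#'   chromatin mark (so the two-mark eRNA predicate rejects them); the rest
#'   receive none.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A list of class `encoop_sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$time_points_hr
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 10e6,
                       n_genes = 60L,
                       n_enhancers = 200L,
                       time_points_hr = c(0, 12, 24, 30, 36, 72, 96),
                       n_replicates = 2L,
                       class_mix = c(additive = 1 / 3, exponential = 1 / 3,
                                     logistic = 1 / 3),
                       noise_cv = 0.1,
                       nb_dispersion = 0.05,
                       enhancers_per_gene = c(2L, 5L),
                       decoy_fraction = 0.15,
                       decoy_single_mark = 0.5,
                       seed = 1L) {
  known <- c("additive", "exponential", "logistic")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% known)) {
    abort(paste0("class_mix must be named with models among: ",
                 paste(known, collapse = ", ")))
  }
  if (abs(sum(class_mix) - 1) > 1e-9) abort("class_mix must sum to 1")
  if (any(diff(time_points_hr) <= 0)) {
    abort("time_points_hr must be strictly increasing")
  }
  counts <- c(n_chromosomes, n_genes, n_replicates)
  if (any(counts < 1)) abort("n_chromosomes, n_genes, n_replicates must be >= 1")
  if (n_enhancers < 0) abort("n_enhancers must be >= 0")
  if (noise_cv < 0 || nb_dispersion < 0) {
    abort("noise_cv and nb_dispersion must be >= 0")
  }
  if (length(enhancers_per_gene) != 2L ||
      enhancers_per_gene[1] < 1L ||
      enhancers_per_gene[2] < enhancers_per_gene[1]) {
    abort("enhancers_per_gene must be c(min, max) with 1 <= min <= max")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.numeric(chrom_length),
      n_genes = as.integer(n_genes),
      n_enhancers = as.integer(n_enhancers),
      time_points_hr = as.numeric(time_points_hr),
      n_replicates = as.integer(n_replicates),
      class_mix = class_mix[known][!is.na(class_mix[known])],
      noise_cv = as.numeric(noise_cv),
      nb_dispersion = as.numeric(nb_dispersion),
      enhancers_per_gene = as.integer(enhancers_per_gene),
      decoy_fraction = as.numeric(decoy_fraction),
      decoy_single_mark = as.numeric(decoy_single_mark),
      seed = as.integer(seed)
    ),
    class = "encoop_sim_config"
  )
}

#' @export
print.encoop_sim_config <- function(x, ...) {
  cat("<encoop_sim_config>\n")
  cat(sprintf("  genome: %d x %.1f Mb, %d genes, %d enhancer loci\n",
              x$n_chromosomes, x$chrom_length / 1e6, x$n_genes, x$n_enhancers))
  cat(sprintf("  design: %d time points (%s hr) x %d replicates\n",
              length(x$time_points_hr),
              paste(x$time_points_hr, collapse = ","), x$n_replicates))
  cat(sprintf("  class mix: %s\n",
              paste(sprintf("%s=%.2f", names(x$class_mix), x$class_mix),
                    collapse = " ")))
  cat(sprintf("  noise_cv=%.3g nb_dispersion=%.3g seed=%d\n",
              x$noise_cv, x$nb_dispersion, x$seed))
  invisible(x)
}
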