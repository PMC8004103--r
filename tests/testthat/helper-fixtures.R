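# Fixture builders shared across test files. Everything is generated in
# code; coordinates are 0-based half-open.

tu_row <- function(id, chrom, start, end, strand = "+") {
  tibble::tibble(id = id, chrom = chrom, start = start, end = end,
                 strand = strand)
}

peak_rows <- function(mark, time_hr, chrom, start, end, signal = 10) {
  tibble::tibble(mark = mark, time_hr = time_hr, chrom = chrom,
                 start = start, end = end, signal = signal)
}

# long activity tibble from a units x time matrix of replicate-mean values
# (both replicates identical unless jitter is supplied)
activity_from_profiles <- function(profiles, time_hr, n_replicates = 2,
                                   jitter = NULL) {
  out <- list()
  for (u in rownames(profiles)) {
    for (r in seq_len(n_replicates)) {
      v <- profiles[u, ]
      if (!is.null(jitter)) v <- v * jitter(length(v))
      out[[length(out) + 1L]] <- tibble::tibble(
        unit_id = u, assay = "TTseq", time_hr = time_hr, replicate = r,
        value = as.numeric(v))
    }
  }
  dplyr::bind_rows(out)
}

truth_pairs_tbl <- function(sim) {
  dplyr::transmute(sim$truth_pairs, enhancer_id = locus_id, gene_id,
                   method = "truth", relation = "truth",
                   distance = 0, rho = NA_real_)
}

# per-class recovery, ambiguous excluded from denominators
recovery_rates <- function(classification, truth) {
  target <- c(additive = "additive", exponential = "synergistic",
              logistic = "logistic")
  m <- dplyr::inner_join(tibble::as_tibble(classification), truth,
                         by = "gene_id")
  m <- m[m$final_class != "ambiguous", ]
  vapply(names(target), function(cl) {
    sub <- m[m$true_class == cl, ]
    if (nrow(sub) == 0L) NA_real_ else mean(sub$final_class == target[[cl]])
  }, numeric(1))
}

# hand-enumerable 10-gene toy annotation for the pairing tests: genes g01..g10
# on two chromosomes, all 10 kb long, with known activity/differential status
toy_pairing_fixture <- function() {
  starts <- c(1e5, 6e5, 12e5, 30e5, 52e5,    # chrA
              1e5, 6e5, 12e5, 24e5, 52e5)    # chrB
  genes <- tibble::tibble(
    id = sprintf("g%02d", 1:10),
    chrom = rep(c("chrA", "chrB"), each = 5),
    start = starts,
    end = starts + 1e4,
    strand = rep(c("+", "-"), 5)
  )
  enhancers <- tibble::tibble(
    enhancer_id = c("eA", "eB", "eC", "eD", "eE"),
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrB"),
    # eA intragenic in g01; eB between g02/g03; eC beyond g05 (chromosome
    # edge); eD between g07/g08; eE between g08/g09 near the TAD boundary
    start = c(1.02e5, 8e5, 56e5, 8e5, 19e5),
    end = c(1.03e5, 8.01e5, 56.01e5, 8.01e5, 19.01e5)
  )
  tp <- c(0, 12, 24, 30, 36, 72, 96)
  up <- c(10, 12, 20, 40, 80, 150, 160)     # strongly increasing
  flat <- rep(10, 7)                        # active but not differential
  wig <- c(50, 60, 70, 10, 20, 30, 40)      # differential, rho vs up = -0.5
  prof <- rbind(
    g01 = up, g02 = up, g03 = up, g04 = flat, g05 = up,
    g06 = up, g07 = wig, g08 = up, g09 = up, g10 = up,
    eA = up, eB = up, eC = up, eD = up, eE = up)
  activity <- activity_from_profiles(prof, tp)
  de <- tibble::tibble(
    unit_id = rownames(prof),
    is_differential = !rownames(prof) %in% c("g04"))
  tads <- tibble::tibble(
    chrom = c("chrA", "chrA", "chrB", "chrB"),
    start = c(0, 20e5, 0, 20e5),
    end = c(20e5, 60e5, 20e5, 60e5))
  list(genes = genes, enhancers = enhancers, activity = activity, de = de,
       tads = tads, time_hr = tp)
}
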