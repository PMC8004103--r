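# Robustness diagnostics and the superenhancer caller.

test_that("Fisher exact p-values match the hypergeometric enumeration and fisher.test", {
  ft <- fisher_exact(5, 0, 0, 5, side = "greater")
  expect_equal(ft$p_value, 1 / choose(10, 5))
  ft <- fisher_exact(5, 5, 5, 5, side = "greater")
  expect_equal(ft$odds_ratio, 1)
  expect_gt(ft$p_value, 0.5)
  expect_error(fisher_exact(-1, 2, 3, 4), "domain error")

  # brute-force oracle over all tables with the observed margins
  brute_p <- function(a, b, c, d, side) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(m, k)
    probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
    if (side == "greater") sum(probs[xs >= a])
    else sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:200) {
    cells <- as.integer(stats::rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)))
    for (side in c("greater", "two_sided")) {
      expect_equal(
        fisher_exact(cells[1], cells[2], cells[3], cells[4], side)$p_value,
        min(brute_p(cells[1], cells[2], cells[3], cells[4], side), 1),
        tolerance = 1e-12)
    }
    # independent cross-check against stats::fisher.test
    tab <- matrix(cells, 2, byrow = TRUE)
    expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4],
                              "greater")$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4],
                              "two_sided")$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("class overlap builds the 2x2 table over shared genes and tests enrichment", {
  a <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                      final_class = rep(c("synergistic", "additive"),
                                        each = 10))
  # identical classifications: off-diagonals zero, minimal p for the margins
  ov <- class_overlap(a, a)
  expect_equal(ov$table[1, 2], 0)
  expect_equal(ov$table[2, 1], 0)
  expect_equal(ov$p_value,
               fisher_exact(10, 0, 0, 10, "greater")$p_value)
  # known 33/57-style overlap reproduced by hand count
  b <- a
  b$final_class[1:4] <- "additive"   # 4 of the 10 synergistic flip
  ov <- class_overlap(a, b)
  expect_equal(unname(ov$table[1, ]), c(6, 4))
  expect_equal(unname(ov$table[2, ]), c(0, 10))
  # independent random labels: no enrichment on a fixed seed
  set.seed(5)
  r1 <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                       final_class = sample(c("synergistic", "additive"),
                                            200, TRUE))
  r2 <- dplyr::mutate(r1, final_class = sample(final_class))
  expect_gt(class_overlap(r1, r2)$p_value, 0.01)
  expect_error(class_overlap(a, dplyr::mutate(a, gene_id = paste0("x",
                                                                  gene_id))),
               "empty intersection")
})

test_that("strongest-enhancer fractions follow the arithmetic of summed trajectories", {
  tp <- c(0, 12, 24)
  prof <- rbind(e1 = c(10, 10, 10), e2 = c(5, 5, 0),
                e3 = c(2, 2, 2), e4 = c(2, 2, 2), z1 = c(0, 0, 0))
  act <- activity_from_profiles(prof, tp)
  pairs <- tibble::tibble(
    enhancer_id = c("e1", "e2", "e3", "e4", "z1"),
    gene_id = c("gA", "gA", "gB", "gB", "gC"))
  fr <- strongest_fraction(pairs[1:4, ], act)
  expect_equal(fr$strongest_fraction[fr$gene_id == "gA"], 30 / 40)
  expect_equal(fr$strongest_fraction[fr$gene_id == "gB"], 0.5)
  # single enhancer -> 1.0
  fr1 <- strongest_fraction(pairs[1, ], act)
  expect_equal(fr1$strongest_fraction, 1.0)
  expect_warning(fr0 <- strongest_fraction(pairs, act), "zero total")
  expect_false("gC" %in% fr0$gene_id)
})

test_that("dual-target concordance counts and binomial test behave as specified", {
  classes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40),
    final_class = rep(c("additive", "synergistic"), 20))
  # 20 enhancers, each pairing two genes of the same class -> all concordant
  pairs <- tibble::tibble(
    enhancer_id = rep(sprintf("e%02d", 1:20), each = 2),
    gene_id = sprintf("g%02d", c(rbind(seq(1, 40, 2), seq(1, 40, 2) + 2))))
  pairs$gene_id[pairs$gene_id == "g41"] <- "g01"  # wrap last pair
  res <- dual_target_concordance(pairs, classes, null_p = 0.5)
  expect_equal(res$n_dual, 20L)
  expect_equal(res$n_concordant, 20L)
  expect_equal(res$p_value, 0.5^20)
  # at the null expectation the tail probability is >= ~0.5
  half <- res
  pairs_disc <- pairs
  flip <- pairs_disc$gene_id[seq(2, 40, 4)]
  pairs_disc$gene_id[seq(2, 40, 4)] <-
    sprintf("g%02d", (as.integer(sub("g", "", flip)) %% 40) + 1)
  res2 <- dual_target_concordance(pairs_disc, classes, null_p = 0.5)
  expect_gte(res2$p_value, 0.4)
  # no dual-target enhancers -> counts reported, p undefined
  res3 <- dual_target_concordance(pairs[1, ], classes)
  expect_equal(res3$n_dual, 0L)
  expect_true(is.na(res3$p_value))
  # null from class marginals: frequencies (0.5, 0.5) -> p0 = 0.5
  expect_equal(dual_target_concordance(pairs, classes)$null_p, 0.5)
})

test_that("eRNA inflation by a global factor leaves the synergistic set unchanged", {
  sim <- simulate_dataset(sim_config(n_genes = 10, n_enhancers = 36,
                                     seed = 23))
  pairs <- truth_pairs_tbl(sim)
  res <- inflation_robustness(pairs, sim$activities, factor = 1, seed = 1)
  expect_equal(res$overlap, 1.0)
  res2 <- inflation_robustness(pairs, sim$activities, factor = 2, seed = 1)
  expect_equal(res2$overlap, 1.0)
  expect_error(inflation_robustness(pairs, sim$activities, factor = 0),
               "> 0")
})

test_that("stitching keeps enhancer-proximal peaks and merges within 12.5 kb", {
  enh <- tibble::tibble(enhancer_id = c("E", "E2"), chrom = "chr1",
                        start = c(500, 5200), end = c(900, 5600))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 5000, 40000), end = c(1000, 6000, 41000),
    signal = c(10, 30, 99))
  # third peak is 2 kb+ from any enhancer -> dropped; first two merge (gap 4 kb)
  st <- stitch_regions(peaks, enh)
  expect_equal(nrow(st), 1L)
  expect_equal(st$start, 0)
  expect_equal(st$end, 6000)
  expect_equal(st$signal, (10 + 30) / 2000)
  # 12.5 kb stitch boundary: gap 12500 merges, 12501 (13 kb case) splits
  enh2 <- dplyr::bind_rows(enh[1, ], tibble::tibble(enhancer_id = "E3",
                                                    chrom = "chr1",
                                                    start = 19500,
                                                    end = 19900))
  peaks2 <- tibble::tibble(chrom = "chr1", start = c(0, 13500),
                           end = c(1000, 20000), signal = c(5, 6))
  expect_equal(nrow(stitch_regions(peaks2, enh2)), 1L)
  peaks3 <- tibble::tibble(chrom = "chr1", start = c(0, 13501),
                           end = c(1000, 20000), signal = c(5, 6))
  expect_equal(nrow(stitch_regions(peaks3, enh2)), 2L)
  # order invariance and signal conservation
  set.seed(17)
  starts <- sort(sample.int(2e5, 30)) * 3
  peaks_r <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + 500, signal = runif(30, 1, 50))
  enh_r <- tibble::tibble(enhancer_id = sprintf("e%d", 1:30), chrom = "chr1",
                          start = starts, end = starts + 100)
  s1 <- stitch_regions(peaks_r, enh_r)
  s2 <- stitch_regions(peaks_r[sample(30), ], enh_r[sample(30), ])
  expect_equal(s1, s2)
  expect_equal(sum(s1$signal * vapply(seq_len(nrow(s1)), function(i) {
    sum(peaks_r$end[peaks_r$start >= s1$start[i] &
                      peaks_r$end <= s1$end[i]] -
          peaks_r$start[peaks_r$start >= s1$start[i] &
                          peaks_r$end <= s1$end[i]])
  }, numeric(1))), sum(peaks_r$signal))
})

test_that("the elbow cutoff flags regions above the unit-slope crossing", {
  # quadratic curve: slope crosses 1 between scaled ranks 5 and 6
  eb <- elbow_cutoff((0:10)^2)
  expect_equal(eb$cutoff_signal, 25)
  expect_equal(sum(eb$is_super), 5L)
  expect_equal(which(eb$is_super), 7:11)
  # linear ramp: slope never exceeds 1, nothing flagged
  eb <- elbow_cutoff(seq(2, 20, by = 2))
  expect_false(any(eb$is_super))
  # one extreme outlier over a flat base: only the outlier flagged
  eb <- elbow_cutoff(c(rep(1, 9) + seq(0, 0.08, by = 0.01), 1000))
  expect_equal(sum(eb$is_super), 1L)
  expect_true(eb$is_super[10])
  # flagged set is downward-closed in rank order
  set.seed(29)
  for (i in 1:10) {
    s <- sort(rlnorm(50, 0, 1.5))
    eb <- elbow_cutoff(s)
    flagged <- which(eb$is_super)
    if (length(flagged)) expect_equal(flagged, (50 - length(flagged) + 1):50)
  }
  expect_warning(eb <- elbow_cutoff(rep(3, 5)), "constant")
  expect_false(any(eb$is_super))
  expect_error(elbow_cutoff(c(1, 2)), ">= 3")
})

test_that("superenhancer calls are not enriched for synergistic targets on the fixture", {
  sim <- simulate_dataset(sim_config(seed = 37))
  pairs <- truth_pairs_tbl(sim)
  cl <- classify_all(pairs, sim$activities, seed = 37)
  enh <- sim$enhancer_loci |>
    dplyr::transmute(enhancer_id = id, chrom, start, end)
  se <- call_superenhancers(sim$peaks, enh)
  expect_s3_class(se, "encoop_superenhancers")
  # map superenhancer regions to target genes via the loci they contain
  se_regions <- se[se$is_super, ]
  if (nrow(se_regions) > 0L && sum(cl$final_class == "synergistic") > 0L) {
    loci <- sim$enhancer_loci
    in_se <- vapply(seq_len(nrow(loci)), function(i) {
      any(se_regions$chrom == loci$chrom[i] &
            se_regions$start <= loci$start[i] &
            se_regions$end >= loci$end[i])
    }, logical(1))
    se_genes <- unique(loci$target_gene_id[in_se & loci$role == "true"])
    tab <- table(
      se = cl$gene_id %in% se_genes,
      syn = cl$final_class == "synergistic")
    if (all(dim(tab) == c(2, 2))) {
      p <- fisher_exact(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1],
                        side = "greater")$p_value
      expect_gt(p, 0.05)
    }
  }
})
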