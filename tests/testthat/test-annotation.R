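# RNA-class annotation rules, eRNA calling, merging, and enhancer activity.

test_that("reference class assignment uses the >60% overlap rule with max-fraction ties", {
  reference <- tibble::tibble(
    chrom = "chr1", start = c(1000, 5000), end = c(2000, 6000),
    strand = c("+", "+"), gene_type = c("mRNA", "lincRNA"))
  # TU covering 70% of the mRNA transcript
  tus <- tu_row("t1", "chr1", 1000, 1700)
  expect_equal(assign_gencode_class(tus, reference), "mRNA")
  # 50% of every overlapping transcript -> none
  tus <- tu_row("t2", "chr1", 1000, 1500)
  expect_true(is.na(assign_gencode_class(tus, reference)))
  # 60% exactly is not enough (strict inequality)
  tus <- tu_row("t3", "chr1", 1000, 1600)
  expect_true(is.na(assign_gencode_class(tus, reference)))
  # 65% of an mRNA and 90% of a lincRNA -> lincRNA (max fraction wins)
  ref2 <- tibble::tibble(
    chrom = "chr1", start = c(1000, 1500), end = c(2000, 2500),
    strand = "+", gene_type = c("mRNA", "lincRNA"))
  tus <- tu_row("t4", "chr1", 1350, 2400)  # 650/1000 vs 900/1000
  expect_equal(assign_gencode_class(tus, ref2), "lincRNA")
  # fraction relative to the TU is selectable
  tus <- tu_row("t5", "chr1", 1100, 1500)  # 100% of TU, 40% of reference
  expect_true(is.na(assign_gencode_class(tus, reference)))
  expect_equal(assign_gencode_class(tus, reference, relative_to = "tu"),
               "mRNA")
})

test_that("TSS-proximal and downstream positional rules classify uaRNA, convRNA, dsRNA", {
  # + strand mRNA with TSS at 10000, 3' end at 20000
  mrnas <- tu_row("m1", "chr1", 10000, 20000, "+")
  # antisense TU, 5' end 300 bp upstream, body upstream -> uaRNA
  ua <- tu_row("u1", "chr1", 9000, 9700, "-")
  expect_equal(classify_positional(ua, mrnas), "uaRNA")
  # antisense TU overlapping the TSS from inside the gene -> convRNA
  conv <- tu_row("c1", "chr1", 9500, 10400, "-")
  expect_equal(classify_positional(conv, mrnas), "convRNA")
  # 5' end outside the [-1000, +500] window -> unclassified
  far <- tu_row("f1", "chr1", 7000, 8500, "-")
  expect_true(is.na(classify_positional(far, mrnas)))
  # window boundaries: exactly -1000 and +500 are inside
  edge_up <- tu_row("e1", "chr1", 8500, 9000, "-")
  expect_equal(classify_positional(edge_up, mrnas), "uaRNA")
  edge_dn <- tu_row("e2", "chr1", 9800, 10500, "-")
  expect_equal(classify_positional(edge_dn, mrnas), "convRNA")
  # same-strand TU starting 400 bp after the 3' end -> dsRNA
  ds <- tu_row("d1", "chr1", 20400, 21000, "+")
  expect_equal(classify_positional(ds, mrnas), "dsRNA")
  # 1 kb boundary: 1000 in, 1001 out (without signal support)
  expect_equal(classify_positional(tu_row("d2", "chr1", 21000, 21500, "+"),
                                   mrnas), "dsRNA")
  expect_true(is.na(classify_positional(tu_row("d3", "chr1", 21001, 21500,
                                               "+"), mrnas)))
  # within 10 kb it needs monotonically diminishing signal
  far_ds <- tu_row("d4", "chr1", 25000, 27000, "+")
  decaying <- list(d4 = seq(100, 10, length.out = 50))
  rising <- list(d4 = seq(10, 100, length.out = 50))
  expect_equal(classify_positional(far_ds, mrnas, signal = decaying), "dsRNA")
  expect_true(is.na(classify_positional(far_ds, mrnas, signal = rising)))
  expect_true(is.na(classify_positional(far_ds, mrnas)))
  # the same rules mirror on a - strand mRNA (TSS at the interval end)
  mrnas_m <- tu_row("m2", "chr2", 10000, 20000, "-")
  ua_m <- tu_row("u2", "chr2", 20300, 21000, "+")  # 5' end 300 bp upstream
  expect_equal(classify_positional(ua_m, mrnas_m), "uaRNA")
  ds_m <- tu_row("d5", "chr2", 9000, 9600, "-")    # 5' end 400 bp downstream
  expect_equal(classify_positional(ds_m, mrnas_m), "dsRNA")
})

test_that("the discard filter removes unassigned TUs overlapping >20% of a reference gene", {
  reference <- tibble::tibble(chrom = "chr1", start = 0, end = 10000,
                              strand = "+", gene_type = "mRNA")
  expect_true(discard_overlapping(tu_row("x", "chr1", 0, 2500), reference))
  expect_false(discard_overlapping(tu_row("x", "chr1", 0, 1000), reference))
  expect_false(discard_overlapping(tu_row("x", "chr1", 0, 2000), reference))
})

test_that("eRNA calling requires both marks within 1 kb, at any time point", {
  tus <- dplyr::bind_rows(
    tu_row("near_both", "chr1", 10000, 10500),
    tu_row("atac_only", "chr1", 50000, 50500),
    tu_row("too_far", "chr1", 90000, 90500))
  peaks <- dplyr::bind_rows(
    peak_rows("ATAC", 24, "chr1", 11300, 11600),      # gap 800 at t=24
    peak_rows("H3K4me1", 0, "chr1", 10200, 10400),    # overlap at t=0
    peak_rows("ATAC", 0, "chr1", 50400, 50700),
    peak_rows("ATAC", 0, "chr1", 91501, 91800),       # gap 1001 from too_far
    peak_rows("H3K4me1", 0, "chr1", 91501, 91800))
  expect_equal(call_ernas(tus, peaks), c(TRUE, FALSE, FALSE))
  # gap exactly 1000 qualifies
  peaks2 <- dplyr::bind_rows(peak_rows("ATAC", 0, "chr1", 91500, 91800),
                             peak_rows("H3K4me1", 0, "chr1", 91500, 91800))
  expect_true(call_ernas(tu_row("t", "chr1", 90000, 90500), peaks2))
  expect_warning(res <- call_ernas(tus, peaks[peaks$mark == "ATAC", ]),
                 "empty")
  expect_false(any(res))
})

test_that("eRNA merging is strand-agnostic single linkage with a 1 kb gap, idempotent", {
  ernas <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100, 1500, 3000, 100), end = c(600, 2000, 3400, 300),
    strand = c("+", "-", "+", "+"))
  # gap a-b = 900 (merged, opposite strands), b-c = 1000 (merged)
  m <- merge_ernas(ernas)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start[m$chrom == "chr1"], 100)
  expect_equal(m$end[m$chrom == "chr1"], 3400)
  expect_setequal(m$constituent_tu_ids[m$chrom == "chr1"][[1]],
                  c("a", "b", "c"))
  # boundary: gap 1001 stays split
  ernas2 <- tibble::tibble(id = c("a", "b"), chrom = "chr1",
                           start = c(100, 1601), end = c(600, 2000),
                           strand = "+")
  expect_equal(nrow(merge_ernas(ernas2)), 2L)
  ernas3 <- dplyr::mutate(ernas2, start = c(100, 1600))
  expect_equal(nrow(merge_ernas(ernas3)), 1L)
  # idempotence and constituent conservation on random fixtures
  set.seed(42)
  for (rep in 1:5) {
    starts <- sort(sample.int(50000, 40))
    rnd <- tibble::tibble(id = sprintf("r%02d", 1:40), chrom = "chr1",
                          start = starts, end = starts + 200,
                          strand = sample(c("+", "-"), 40, TRUE))
    m1 <- merge_ernas(rnd)
    expect_equal(sort(unlist(m1$constituent_tu_ids)), sort(rnd$id))
    remerged <- merge_ernas(
      dplyr::transmute(m1, id = enhancer_id, chrom, start, end,
                       strand = "."))
    expect_equal(remerged[c("chrom", "start", "end")],
                 m1[c("chrom", "start", "end")])
    gaps <- diff(m1$start) - (m1$end[-nrow(m1)] - m1$start[-nrow(m1)])
    expect_true(all(m1$start[-1] - m1$end[-nrow(m1)] > 1000))
  }
})

test_that("enhancer activity sums per-kb-normalized constituent counts", {
  enh <- tibble::tibble(enhancer_id = "E1", chrom = "chr1", start = 0,
                        end = 2000, constituent_tu_ids = list(c("t1", "t2")))
  counts <- tibble::tibble(unit_id = c("t1", "t2"),
                           TTseq_0_1 = c(50, 100), TTseq_0_2 = c(0, 0))
  lengths <- c(t1 = 500, t2 = 1000)
  act <- enhancer_activity(enh, counts, lengths)
  expect_equal(act$activity[act$sample == "TTseq_0_1"], 50 / 0.5 + 100 / 1)
  expect_equal(act$activity[act$sample == "TTseq_0_2"], 0)
  # single constituent, 30 counts over 1 kb -> 30
  enh1 <- tibble::tibble(enhancer_id = "E2", chrom = "chr1", start = 0,
                         end = 1000, constituent_tu_ids = list("t2"))
  counts1 <- tibble::tibble(unit_id = "t2", TTseq_0_1 = 30)
  expect_equal(enhancer_activity(enh1, counts1, lengths)$activity, 30)
  # scales as 1/size_factor
  sf <- tibble::tibble(sample = c("TTseq_0_1", "TTseq_0_2"),
                       size_factor = c(2, 1))
  act_sf <- enhancer_activity(enh, counts, lengths, sf)
  expect_equal(act_sf$activity[act_sf$sample == "TTseq_0_1"], 200 / 2)
  expect_error(enhancer_activity(enh, counts[1, ], lengths), "missing")
})

test_that("classification is a partition and recovers all true enhancers on the fixture", {
  sim <- simulate_dataset(sim_config(n_genes = 8, n_enhancers = 30,
                                     decoy_fraction = 0.3, seed = 5))
  classified <- classify_tus(sim$tus, sim$reference, sim$peaks)
  expect_equal(nrow(classified), nrow(sim$tus))
  expect_true(all(classified$rna_class %in%
                    c("mRNA", "lincRNA", "dsRNA", "uaRNA", "convRNA", "eRNA",
                      "unclassified", "discarded")))
  truth <- sim$enhancer_loci
  called <- classified$id[classified$rna_class == "eRNA"]
  expect_setequal(called, truth$id[truth$role == "true"])  # recall 1, FPR 0
  expect_true(all(classified$rna_class[classified$id %in% sim$genes$id] ==
                    "mRNA"))
})
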