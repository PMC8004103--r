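# encoop

Enhancer cooperation analysis from nascent-transcription time courses.

Mammalian genes are typically controlled by several enhancers at once, and a
central question in regulatory genomics is whether those enhancers combine
*additively* — each contributing its share of transcription — or
*synergistically*, with the whole exceeding the sum of the parts. `encoop`
implements a complete, testable pipeline for answering that question from
time-course nascent-RNA (TT-seq) data, as produced for example during a
B-cell-to-macrophage transdifferentiation experiment sampled at 0, 12, 24,
30, 36, 72, and 96 hours in duplicate. It is aimed at computational
biologists who have transcription-unit calls, count tables, chromatin peak
sets, and TAD intervals, and who want per-gene regulatory-mode calls with
the surrounding robustness checks.

## What it computes

1. **RNA-class annotation.** Transcription units (TUs) are classified by
   positional rules: a TU inherits a reference (GENCODE-like) gene type if
   it covers more than 60% of the annotated transcript; remaining TUs become
   uaRNA/convRNA if antisense within the `[TSS − 1000, TSS + 500]` bp window
   of an mRNA start, dsRNA if within 1 kb (or 10 kb with decaying signal)
   downstream of an mRNA end; TUs overlapping more than 20% of a reference
   gene are discarded; and the rest are **eRNAs** when both an ATAC and an
   H3K4me1 peak lie within 1 kb at any time point. eRNAs within 1 kb of each
   other are merged, strand-agnostically, into enhancers whose activity is
   the sum of the constituents' size-factor- and length-normalized counts.

2. **Enhancer–promoter pairing** by three methods: *neighboring* (intragenic
   enhancers pair with their host gene, intergenic ones with the nearest
   active mRNA on each side, restricted to differential genes), a *1 Mb
   window*, and a *TAD* scope (the latter two requiring both ends
   differential — |log2FC| > 1, FDR < 0.05 — and Spearman ρ > 0.4 between
   the eRNA and mRNA time profiles).

3. **Cooperation-mode classification.** For each gene with 2–20 paired
   enhancers (top 75% by correlation), promoter activity *P* is fit as a
   function of the summed enhancer activity *S* under three models:

   - additive: `P = α·S + β`
   - synergistic (exponential): `P = exp(α·S + β)`
   - logistic: `P = δ / (1 + exp(−(α·S + β)))`

   by bounded global least squares (differential evolution + local
   refinement). Fits are compared with `BIC = n·ln(RSS/n) + (k+1)·ln(n)`.
   If the logistic model has the lowest BIC, the point with the highest *S*
   is excluded once and all models are refit. Otherwise the **relative BIC**
   `BIC_additive − BIC_exponential` decides: > 2 synergistic, in [0, 2]
   ambiguous, < 0 additive. A logarithmic model `P = α·ln(S + 1) + β` with
   no mechanistic meaning serves as a negative control for the machinery.

4. **Diagnostics:** cross-method class-overlap enrichment (Fisher's exact
   test from the hypergeometric distribution), strongest-enhancer dominance,
   dual-target concordance (binomial test against a marginal-frequency
   null), a simulated eRNA-inflation robustness check, and an
   occupancy-based superenhancer caller (peaks within 1 kb of enhancers
   stitched at 12.5 kb, width-normalized signal, rank-curve elbow cutoff).

5. **A synthetic-data generator** (`simulate_dataset()`) that produces a
   desk-scale genome with known ground truth — gene and eRNA TUs, TADs,
   time-stamped peak sets, logistic-in-time enhancer ramps, promoter
   trajectories generated from each model, and negative-binomial counts —
   so that every stage of the pipeline is testable end to end.

## Worked example

```r
library(encoop)

sim <- simulate_dataset(sim_config(n_genes = 12, n_enhancers = 40, seed = 1))
sim
#> <encoop_sim>
#>   12 genes, 40 enhancer loci (34 true), 12 TADs
#>   14 samples, 52 count rows
#>   true classes: additive=4 exponential=4 logistic=4

pairs <- dplyr::transmute(sim$truth_pairs, enhancer_id = locus_id, gene_id)
cl <- classify_all(pairs, sim$activities, seed = 1)
glance(cl)
#> # A tibble: 1 × 6
#>   n_genes n_additive n_synergistic n_logistic n_ambiguous n_unfittable
#>     <int>      <int>         <int>      <int>       <int>        <int>
#> 1       9          2             3          4           0            0

dplyr::select(cl[cl$final_class == "synergistic", ][1, ],
              gene_id, n_enhancers, rho, final_class, relative_bic)
#> # A tibble: 1 × 5
#>   gene_id n_enhancers   rho final_class relative_bic
#>   <chr>         <int> <dbl> <chr>              <dbl>
#> 1 gene001           2 0.964 synergistic         37.8
```

Nine of the twelve genes have 2–20 paired enhancers and survive the
correlation filter; `gene001` is called synergistic because the exponential
fit beats the additive one by 37.8 BIC units — far above the threshold of 2.
`autoplot(cl)` shows the relative-BIC distribution;
`plot_gene_fit(classify_gene(S, P))` overlays the three fitted curves on the
observed trajectory.

The full file-based pipeline (classify → pair → fit → diagnose, writing
every intermediate table plus a run manifest) runs with:

```r
write_dataset(sim, "data_dir")
res <- run_pipeline(pipeline_config(data_dir = "data_dir", seed = 1), "out_dir")
```

or from a shell via `inst/scripts/encoop
simulate|annotate|pair|fit|diagnose|run --config cfg.yaml --out out_dir`.

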