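# coexrank

Guide-gene co-expression ranking and permutation-based gene-set
enrichment for bulk transcriptome cohorts.

## What it does

Studies of the aging human brain often anchor a whole-transcriptome
analysis on one transcript of interest — a *guide gene*, such as the
astrocyte-enriched neuropeptide precursor *ENHO* — and ask which genes and
pathways track it, and whether that co-expression structure differs
between cohort strata (dementia vs. no dementia, sexes, age groups).
`coexrank` implements that workflow for an expression matrix (FPKM/TPM-like
units), a sample-metadata table and a GMT pathway collection:

1. **Rank.** Within a stratum, Pearson-correlate the guide against every
   other gene on the `log2(x + 1)` scale, order by `r` (ties broken by
   gene id), and z-score the correlation vector:
   `z_i = (r_i - mean(r)) / sd(r)`. The signed `z` is the pre-ranked
   statistic, so guide-depleted pathways score negative.
2. **Enrich.** For each gene set `H` (size `k`, list length `N`), the
   enrichment score is the signed extremum of the running sum
   `P_hit(i) - P_miss(i)` with `P_hit` accumulating `|z|^w` over members
   and `P_miss` accumulating `1/(N-k)` over non-members. The null is
   gene-label permutation (`K` random same-size sets);
   `NES = ES / mean(|same-sign permutation ES|)`, p-values carry the +1
   correction, and Benjamini–Hochberg FDR runs across all retained sets.
3. **Compare.** Venn overlaps and overlap-coefficient similarity
   (`|A∩B| / min(|A|,|B|)`) of top gene lists between strata;
   Mann–Whitney/Welch tests on top-list correlation distributions;
   median-split (Lo/Hi guide expression) comparisons of continuous
   pathology markers; bivariate guide–marker correlation.
4. **Simulate.** A latent-factor cohort generator plants co-expression
   modules at exact target guide correlations
   `rho = beta / sqrt((1 + tau_g^2)(beta^2 + tau^2))`, with strata of
   differing coupling strength, guide-linked markers and decoy gene
   sets — the ground truth used to validate every step.

See `vignettes/guide-coexpression-enrichment.Rmd` for the full model
description, parameter meanings and design rationale.

## Worked example

A synthetic two-stratum cohort (50 donors x 4 samples, three planted
modules coupled more strongly in the D stratum, 20 decoy sets):

```r
library(coexrank)

cfg <- synth_config(n_donors_per_stratum = 25, samples_per_donor = 4,
                    n_background_genes = 2000, n_decoy_sets = 20,
                    decoy_set_size = 40, seed = 42)
cohort <- generate_cohort(cfg)
cohort$truth
#> SyntheticTruth: guide ENHO, 3 planted modules, seed 42
#>      D  ND
#> M1 0.6 0.4
#> M2 0.7 0.5
#> M3 0.8 0.6

expr <- log_transform(cohort$expression)
prof_d <- center_scale(guide_correlation_profile(
  expr, "ENHO", cohort$metadata, c(dementia = "D")))
head(prof_d$entries, 5)
#>   gene_id         r        z rank
#> 1 M3_G039 0.8537834 4.396623    1
#> 2 M3_G004 0.8298870 4.268336    2
#> 3 M3_G019 0.8252626 4.243510    3
#> 4 M3_G009 0.8243736 4.238737    4
#> 5 M3_G026 0.8207717 4.219400    5
```

The strongest-coupled planted module (true `rho = 0.8` in D) tops the
ranking at `r ~ 0.82-0.85`. Enrichment against the planted + decoy
collection recovers exactly the three planted sets:

```r
sets <- generate_gene_sets(cohort$truth, cfg)
enr <- run_enrichment(prof_d, sets,
                      enrichment_config(n_permutations = 2000, seed = 42))
head(as.data.frame(enr)[, 1:6], 5)
#>     set_name size_measured         ES       NES    p_nominal  p_adjusted
#> 1 PLANTED_M1            40  0.8918919  1.955227 0.0005120328 0.003925585
#> 2 PLANTED_M2            40  0.9297297  2.038176 0.0005120328 0.003925585
#> 3 PLANTED_M3            40  0.9851351  2.159637 0.0005120328 0.003925585
#> 4  DECOY_004            40 -0.3824465 -1.525738 0.0408163265 0.093877551
#> 5  DECOY_006            40 -0.4041641 -1.612378 0.0408163265 0.093877551
```

All three planted pathways sit at the permutation floor
(`p_adjusted ~ 0.004`, positive NES); no decoy passes the 0.05 FDR line.
Cross-stratum comparisons reproduce the designed contrast — the top-1%
correlations are higher in the stronger-coupled stratum, and the
guide-linked markers separate the Hi/Lo median-split groups:

```r
prof_nd <- center_scale(guide_correlation_profile(
  expr, "ENHO", cohort$metadata, c(dementia = "ND")))
sel_d  <- select_genes(prof_d, "top_fraction", 0.01)
sel_nd <- select_genes(prof_nd, "top_fraction", 0.01)
venn_overlap(list(D = sel_d, ND = sel_nd))
#> OverlapReport: D / ND
#> A_only B_only     AB
#>     10     10     11

r_top <- function(p, f = 0.01) p$entries$r[seq_len(floor(f * nrow(p$entries)))]
compare_r_distributions(r_top(prof_d), r_top(prof_nd))[c("p_value", "median_difference")]
#>           p_value median_difference
#>      3.125400e-08      2.160107e-01

ms <- marker_tests(median_split(expr$values["ENHO", ], cohort$metadata,
                                c(dementia = "ND")),
                   cohort$metadata, c("AT8", "pTau", "TNFa"))
ms$tests[, c("marker", "mean_lo", "mean_hi", "p_value")]
#>   marker   mean_lo  mean_hi      p_value
#> 1    AT8  9.363404 10.75632 2.698176e-08
#> 2   pTau  9.207110 10.60370 9.954266e-10
#> 3   TNFa 10.114818 10.04104 7.111192e-01
```

The guide-coupled markers (AT8, pTau; planted slopes 1 and 0.8) are
significantly higher in the Hi group, the uncoupled marker (TNFa, slope 0)
is not — the expected pattern for pathology markers tracking guide
expression.

A whole study (preprocessing, per-stratum profiles, selections,
enrichment, comparison plan, manifest) runs from one configuration via
`run_study(config, output_dir)` or the CLI wrapper
(`inst/exec/coexrank run-all --config study.yaml`); both are deterministic
given the configured seed.

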