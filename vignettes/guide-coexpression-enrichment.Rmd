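---
title: "Guide-gene co-expression ranking and pathway enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-gene co-expression ranking and pathway enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexrank)
```

## The analytical problem

A recurring design in transcriptome studies of the aging brain asks: which
genes, and which biological pathways, rise and fall together with a single
transcript of interest — a *guide gene* such as the astrocyte-enriched
neuropeptide precursor *ENHO* — and does that co-expression structure
differ between clinically defined groups (dementia vs. no dementia, males
vs. females, young vs. old-old)? The data are bulk expression matrices
(FPKM/TPM-like units, tens of thousands of genes, hundreds of postmortem
samples from around a hundred donors), sample metadata with stratum labels
and continuous immunohistochemistry markers of pathology, and a pathway
collection in GMT format.

`coexrank` implements that workflow end to end:

1. **Preprocess**: `log2(x + 1)` transform of linear-scale expression;
   optional mean-expression, counts-per-million and fold-change/p filters;
   per-donor averaging and age binning for cohort summaries.
2. **Rank**: Pearson correlation of the guide against every other gene
   within a metadata-defined stratum; order by `r` descending; z-score the
   correlation vector to obtain the pre-ranked statistic.
3. **Enrich**: weighted running-sum enrichment score per gene set, a
   gene-permutation null, normalized enrichment scores, and
   Benjamini–Hochberg FDR across sets.
4. **Compare**: Venn overlaps and overlap-coefficient similarity of top
   gene lists across strata; two-sample tests on correlation
   distributions; median-split (Lo/Hi guide expression) marker
   comparisons; bivariate guide–marker correlation.
5. **Simulate**: a latent-factor cohort generator with planted modules and
   full ground truth, used to validate every step above.

## The ranking statistic

Within a stratum with samples $j = 1..n$ ($n \ge 3$), the per-gene
statistic starts from the Pearson coefficient
$r_i = \mathrm{cor}(g, x_i)$ between the guide profile $g$ and gene $i$,
computed on the log scale. Genes are ordered by $r$ descending (ties broken
by gene identifier, so the ordering is reproducible across platforms), and
the vector is centred and scaled:

$$z_i = \frac{r_i - \bar r}{\mathrm{sd}(r)}$$

with the sample ($n-1$) standard deviation. The signed $z$ — not the
integer rank — is the statistic fed to enrichment. This choice preserves
the sign structure of the profile: pathways whose members concentrate at
the bottom of the list receive negative enrichment scores, which is what
"depleted with the guide" means here. Using centred integer ranks instead
is available via `statistic = "rank"`.

Three details are deliberate:

* The guide gene is excluded from its own ranking ($r = 1$ with itself
  would distort any set containing it).
* Genes with zero variance in the stratum have undefined $r$; they are
  excluded with a recorded reason rather than assigned $r = 0$.
* Pearson, not Spearman, throughout; rank correlation is not offered as a
  drop-in because selection cutoffs (`r > 0.7`) are conventionally quoted
  on the Pearson scale in this literature.

## The enrichment score and its null

For a ranked list of $N$ genes with statistics $s_1 \ge \dots \ge s_N$ and
a set $H$ of $k$ member positions, the running sum after position $i$ is

$$P_{hit}(i) = \frac{\sum_{j \le i,\, j \in H} |s_j|^w}
                    {\sum_{j \in H} |s_j|^w},
  \qquad
  P_{miss}(i) = \frac{|\{j \le i,\, j \notin H\}|}{N - k},$$

and the enrichment score ES is the value of $P_{hit} - P_{miss}$ at its
maximum absolute deviation, signed. The default weight is $w = 1$; $w = 0$
gives the unweighted Kolmogorov–Smirnov-like statistic. The *leading edge*
is the set members at or before the extremum (at or after it for negative
ES). When the positive and negative extreme magnitudes tie to within
$10^{-12}$ relative, the ES is defined as 0 with an empty leading edge;
this matches the convention of reference implementations and keeps the
score exactly antisymmetric under list reversal at $w = 0$. Because the
running sum is piecewise linear between member positions, the
implementation evaluates it only at hits, which makes the permutation loop
cheap; tests verify equality with the literal full-list evaluation for
every proper subset of a 10-gene list.

**Null model.** The null is gene-label permutation: $K$ sets of the same
measured size drawn uniformly without replacement from the restricted
ranked list (default $K = 10\,000$; tests and the bundled study
configurations use smaller $K$, stated per run in the output manifest).
This matches the tool family the workflow is built around and keeps
enrichment independent of sample-level data. Normalization and p-values
are signed-side:

$$\mathrm{NES} = \frac{ES}{\mathrm{mean}\,|ES^{perm}_{\text{same sign}}|},
  \qquad
  p = \frac{1 + \#\{|ES^{perm}_{\text{same sign}}| \ge |ES|\}}
           {1 + \#\{ES^{perm}_{\text{same sign}}\}},$$

with the +1 correction keeping $p \in (0, 1]$. If no permutation lands on
the observed sign, the result is flagged and $p$ reported at its floor.
BH adjustment runs across all retained sets; the conventional selection is
`p_adjusted <= 0.05`.

**Restriction.** Before scoring, sets are intersected with the ranked
genes, sets outside the size window (default 15–500 measured genes) are
dropped with a log entry, and the ranked list is restricted to genes
appearing in at least one retained set — the same two-sided restriction
applied in the published analyses this workflow reproduces.

**Determinism.** Inside `run_enrichment()` one permutation pool is shared
per distinct set size (as reference implementations do), and each pool's
RNG substream is derived from `(seed, size)`. Results are therefore
invariant to the order sets appear in the GMT and bit-identical across
reruns. `permutation_null()` called directly draws its own fresh $K$
permutations; the type-I calibration test uses that route because it needs
independence across sets.

## Comparative analyses

* `venn_overlap()` / `similarity_matrix()`: exact region counts by set
  arithmetic and the overlap coefficient
  $|A \cap B| / \min(|A|, |B|)$ plus Jaccard. The overlap coefficient is
  the package's similarity score between strata; the annotation that
  values above 0.1 indicate substantial overlap is retained from the
  conventions this replaces, but it is a reporting threshold, not a test.
* `compare_r_distributions()`: two-sided Mann–Whitney by default (Welch t
  as an option) on the correlation values of two top-list selections, with
  the difference of medians as the effect size. The underlying published
  figures do not state their test; both options are exposed.
* `median_split()`: Lo = guide expression below the stratum median, Hi =
  above; values exactly at the median go to Lo. This tie rule is
  deterministic and conservative for the typical "is pathology higher in
  the Hi group" comparison. With an even number of distinct values the
  halves are exactly equal.
* `marker_tests()`: per-marker two-sided Welch t (default) or
  Mann–Whitney between Lo and Hi, missing values dropped pairwise, groups
  with fewer than 3 observed values flagged rather than tested.
* `guide_marker_correlation()`: Pearson by default (the published
  scatterplots show linear fits), Spearman as an option.

## The synthetic cohort generator

`generate_cohort()` draws, per sample $j$, a standard-normal latent factor
$f_j$. The guide latent is $g_j = f_j + \varepsilon$ (sd $\tau_g$), each
gene of planted module $m$ is $x_{ij} = \beta_{m,s(j)} f_j + \varepsilon$
(sd $\tau_m$) with the loading depending on the sample's stratum $s(j)$,
and background genes are independent noise. The population guide–gene
correlation is then

$$\rho = \frac{\beta}{\sqrt{(1 + \tau_g^2)(\beta^2 + \tau^2)}},$$

implemented as `rho_theoretical()` with inverse `beta_for_rho()`, so
cohorts can be planted at exact target correlations. Latents map to
strictly positive linear units through $2^{(5 + x)}$, chosen so that the
pipeline's `log2(x + 1)` approximately recovers the latent Gaussian scale
(at the offset of 5 the `+1` perturbs values by under 3% of a log2 unit).
Markers are $10 + \gamma g_j + \varepsilon$, floored at zero; the offset
keeps the floor inactive in practice so the planted linear relationship
survives.

Defaults emulate the structure of the old-old postmortem cohort the
pipeline targets: two dementia-status strata of 50 donors with 4 samples
each (about 400 samples), donor ages 77–102, three planted modules of 40
genes with stronger coupling in the D stratum
($\rho_D = 0.6/0.7/0.8$ vs. $\rho_{ND} = 0.4/0.5/0.6$, $\tau = 1$,
$\tau_g = 0.5$), 5000 background genes as a desk-scale stand-in for a
~50 000-gene transcriptome, and markers coupled to the guide. Three fixed
RNG substreams (expression, markers, decoy sets) are derived from the
master seed, so adding a marker never perturbs expression draws.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: count-level sampling noise and
library-size effects, batch structure, donor-level random effects beyond
the stratum label (samples within a donor are exchangeable here),
non-Gaussian expression tails, and missing expression values. The
generator validates the *inference machinery*, not the biology.

## Numerical and design choices

* Strict inequalities at every filter threshold (`> 10` mean expression,
  `> 1.5` fold change, `< 0.05` p, `r > cutoff`): boundary values are
  excluded, matching the conventions quoted in the analyses this package
  reproduces.
* The counts-per-million filter keeps genes above threshold in at least
  `min(group size) - 1` samples, the grouped-design reading of the
  usual edgeR-style rule, floored at one sample so never-expressed genes
  cannot survive degenerate group sizes.
* Per-donor averaging operates on whatever scale the matrix carries;
  in the standard workflow the transform precedes averaging.
* Age bins are half-open `[k·w, (k+1)·w)`; an optional open-ended final
  bin (e.g. `30+`) reproduces terminal bins like ">30 y".
* Ties in `r` break by gene identifier ascending; selections at a tied
  boundary are therefore deterministic.
* All tabular output is UTF-8 TSV with floats at fixed significant-digit
  precision; ranked profiles serialize at 17 significant digits, which
  round-trips doubles exactly — this is what makes a staged run
  (`correlate` to file, then `gsea` from file) bit-identical to the
  in-memory pipeline.
* `run_study()` reruns are byte-identical for all result files; the
  manifest and log record wall times and are the only files that differ
  between identical runs.

## Problem sizes used in the bundled validations

The package's own validation suite runs on simulated cohorts sized for a
desk machine, chosen once: 10-gene exhaustive enrichment-score checks
(all 1022 proper subsets); type-I calibration with 200 random sets against
a 1000-gene null list at $K = 1000$; planted-pathway recovery on
200-sample cohorts with 5000 background genes, 50 decoy sets and
$K = 2000$ over 20 seeded replicates; correlation recovery at 1000
samples; and the stratum-contrast comparison over 100 replicates of
200-sample two-stratum cohorts. The acceptance script
(`scripts/acceptance.R`) recomputes exactly these quantities from scratch.

## Known limitations

* The gene-permutation null conditions on the restricted universe. Gene
  sets that systematically avoid the planted (high-statistic) genes — such
  as pure-background decoy sets — are genuinely depleted relative to
  random same-size draws, so their depletion p-values are mildly
  anti-conservative; in validation this surfaces as an occasional decoy
  just under the 0.05 FDR line (roughly one replicate in twenty). Real
  pathway collections, which tile most of the transcriptome, dilute this
  effect.
* No multilevel/adaptive p-value refinement: the smallest achievable
  nominal p is bounded by the same-sign permutation count, so very strong
  enrichments saturate at the floor and are distinguished by NES, not p.
* No phenotype-label permutation, covariate adjustment, partial
  correlations, or network/module detection beyond the guide-centred
  ranking.
* Semi-quantitative neuropathology scales (CERAD/Braak-like ordinal
  scores) are out of scope; markers are treated as continuous.
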