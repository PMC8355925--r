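# enhancertrain

Exercise training remodels the regulatory genome of human skeletal
muscle: the activity of enhancers — distal elements marked by H3K4me1
and activated ones additionally by H3K27ac — shifts between the
untrained and trained state, and those shifts propagate to the
expression of the genes the enhancers contact. Because most
disease-associated GWAS variants fall in non-coding regulatory DNA,
training-responsive enhancers are natural candidates for mediating part
of the health benefit of exercise.

`enhancertrain` implements that full analysis as a tested R pipeline,
together with a seeded synthetic-data generator that emulates every
input, so each stage can be validated end to end without any external
download:

1. **Enhancer identification** — coverage-based consensus peaks from
   per-sample H3K27ac and H3K4me1 calls; an enhancer is an H3K27ac
   consensus peak overlapping an H3K4me1 consensus peak by at least one
   nucleotide (BED 0-based half-open arithmetic throughout).
2. **Paired differential testing** — per-feature negative binomial
   log-linear models `log mu = participant + beta * training +
   log(library size)` fit to the 8 pre/post pairs; the natural-log fold
   change is the fitted training coefficient `beta`, tested by a
   likelihood-ratio statistic with Cox–Reid-adjusted profile-ML
   dispersion, and discoveries called at Benjamini–Hochberg FDR < 0.1.
   The same model serves H3K27ac counts on enhancers and RNA-seq gene
   counts (`~participant` vs `~participant + training`).
3. **Enhancer–gene integration** — scored EpiMap-style links attached
   by single-nucleotide overlap; promoters grouped as
   None/Up/Down/Both by the regulation of their linked enhancers;
   two-sample Kolmogorov–Smirnov comparison of lnFC ECDFs between
   groups; Pearson correlation of enhancer vs strongest-linked-gene
   fold changes.
4. **GWAS enrichment** — genome-wide significant catalog SNPs
   (p < 5×10⁻⁸, haplotypes excluded), greedy LD clumping at R² ≥ 0.5,
   1:2 covariate-matched control SNPs (MAF ± 0.05; gene density,
   nearest-gene distance, LD buddies ± 50%), per-category control
   de-duplication, tag expansion at R² = 1 with block-collapsed
   overlap, and a logistic regression per disease/trait category:
   `logit P(overlap) = b0 + b1 * is_GWAS`, reported as
   OR = exp(b1) with 95% Wald intervals.

## Worked example

The logistic enrichment test on a reference overlap table — 332 of
12,955 GWAS SNPs and 421 of 23,454 matched control SNPs falling inside
training-responsive enhancers:

```r
library(enhancertrain)
flags <- function(k, n) c(rep(1L, k), rep(0L, n - k))
enrichment_test(flags(332, 12955), flags(421, 23454))
#>   n_case n_case_overlap n_control n_control_overlap or_estimate ci_low ci_high
#> 1  12955            332     23454               421        1.44   1.24    1.66
#>          p degenerate
#> 1 9.46e-07      FALSE
```

GWAS SNPs have 1.44-fold higher odds (2.6% vs 1.8% overlap rates) of
falling in a responsive enhancer than their matched controls.

A small synthetic study through the whole pipeline:

```r
cfg <- simulation_config(seed = 1, n_regions = 400, n_genes = 300,
                         n_snps = 2000)
res <- run_pipeline(cfg)
nrow(res$enhancers)          # 300 dual-mark enhancers (75% of regions)
length(res$regulated$down)   # 30 enhancers losing H3K27ac at FDR < 0.1
res$concordance$r            # 0.48: enhancer/gene logFC correlation
head(res$enrichment, 2)
#>         category enhancer_set n_case n_case_overlap n_control
#> 1       combined    regulated   2000             42      2782
#> 2 anthropometric    regulated    106              4       208
#>   n_control_overlap or_estimate ci_low ci_high     p
#> 1                45       1.305 0.8534    1.99 0.219
#> 2                 3       2.680 0.5886   12.20 0.202
```

Under the generator's default null planting (per-category OR = 1) the
confidence intervals cover 1, as they should; planting a 1.44-fold
enrichment recovers it (see the acceptance script below).

A shell entry point with `simulate`, `enhancers`, `expression`,
`links`, `gwas`, and `pipeline` subcommands is installed at
`inst/cli/enhancertrain.R`.

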