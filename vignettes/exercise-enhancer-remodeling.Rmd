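---
title: "Methods: differential enhancer activity and GWAS variant enrichment in paired training designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enhancer activity and GWAS variant enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## The scientific setting

Skeletal muscle biopsies are taken from the same participants before
and after an endurance-training programme. Two chromatin marks are
profiled by ChIP-seq — H3K4me1, which marks enhancer regions regardless
of their activity, and H3K27ac, whose level tracks enhancer *activity*
— along with RNA-seq of the same biopsies. The analysis asks three
questions: which enhancers change activity after training; whether
those changes propagate to the expression of linked genes; and whether
disease-associated GWAS variants are over-represented inside the
training-responsive enhancers relative to covariate-matched control
variants.

## Interval conventions

All coordinates inside the package are BED-style: 0-based starts,
exclusive ends, strand ignored. Two intervals overlap when they share
at least one base (`a.start < b.end && b.start < a.end`); abutting
half-open intervals do not. One-based inclusive external
representations — browser spans, SNP table positions — are converted at
the parser boundary (`browser_span_to_interval()`,
`read_snp_table()`), so only one arithmetic convention exists
internally.

## Consensus peaks and enhancer identification

Replicate peak calls disagree at their edges. `consensus_peaks()`
partitions the genome by the union of all per-sample peaks and keeps
the maximal runs of bases covered by at least `min_support` samples
(default: a majority, `ceiling(n/2)`), intersected back to union-peak
extents. This is a deterministic coverage rule playing the role of a
reproducibility filter; it deliberately replaces pseudo-replicate
reproducibility machinery (IDR-style) with something self-contained and
exactly testable — identical inputs give the interval back unchanged,
and staggered inputs give precisely the doubly-covered run.

An enhancer is then an H3K27ac consensus peak overlapping at least one
H3K4me1 consensus peak by a single nucleotide; the H3K27ac peak is the
enhancer unit and its coordinates pass through unchanged.

## The paired negative binomial test

For each feature (enhancer H3K27ac counts, or gene RNA counts) the
model is a negative binomial GLM with log link:

$$\log \mu_{is} = \alpha_{p(s)} + \beta\, t_s + \log L_s$$

with participant fixed effects $\alpha$, training indicator $t_s \in
\{0,1\}$, and the library size $L_s$ as offset. Normalisation is by
library size only; CPM is the descriptive quantity reported alongside.
The natural-log fold change is the fitted $\beta$ (a `log2_fc` flag
converts). The null model drops $\beta$ (`~participant`).

Three numerical choices matter at $n = 8$ pairs (16 samples, 9
coefficients):

* **Dispersion** is estimated per feature by profile maximum likelihood
  with the Cox–Reid adjustment $-\tfrac12 \log\det(X^TWX)$, floored at
  $10^{-4}$. Plain ML dispersion is biased low when the participant
  block absorbs half the residual degrees of freedom, which makes the
  test anticonservative.
* **The reference distribution** for the likelihood-ratio statistic of
  $\beta = 0$ is $F(1, n - p)$ rather than $\chi^2_1$: the F reference
  absorbs the remaining uncertainty of the estimated dispersion, in the
  spirit of quasi-likelihood F-tests. With both choices the measured
  type-I error at $p < 0.05$ under a simulated global null is 0.049
  (band checked by the test suite: 0.03–0.07); with neither it is 0.09.
* **Degenerate features**: all-zero rows are excluded from testing and
  reported with `NA` p and q, so multiplicity is paid only for testable
  features.

Discoveries are called at Benjamini–Hochberg FDR < 0.1 (Bonferroni is
available as a flag for gene-level reporting, since family-wise
corrected q-values are sometimes preferred there; which convention a
given published gene count used is not always decidable, so both are
exposed and neither is asserted). Up/down sets split significant
features by the sign of $\beta$; the non-regulated contrast set takes
the $n$ features with the largest q (ties: larger p, then smaller id) —
the least training-responsive enhancers.

## Enhancer–gene links

Scored links (EpiMap-style: enhancer interval, gene, interaction
score) attach to enhancers by single-nucleotide overlap; all
overlapping links are kept and duplicate (enhancer, gene) pairs
collapse only where a statistic requires it. Promoters classify by
their linked enhancers: `Both` (at least one up- and one
down-regulated), `Up`/`Down` (at least one regulated enhancer of one
sign only — a regulated link dominates any number of unregulated ones,
matching the "at least one" definition), `None` (only unregulated
links). The ECDF comparison between groups uses the two-sample
Kolmogorov–Smirnov statistic with asymptotic p-values; the ECDF figure
convention does not itself name a test, and KS is the natural
distribution-free choice for a location shift of unspecified shape.
Concordance between enhancer activity and expression is the Pearson
correlation of natural-log fold changes over enhancers reduced to their
strongest-scoring gene (score ties break to the lexicographically
smaller gene id); Spearman and an all-links mode are exposed as flags
because both reductions are defensible.

## GWAS enrichment

The procedure mirrors standard matched-SNP enrichment practice:

1. **Catalog filtering**: keep single-variant records with known
   position at genome-wide significance ($p < 5\times10^{-8}$,
   strict); duplicate (snp, trait) records collapse to the smallest p.
   Haplotype records carry an explicit input flag — how such records
   are marked in any given catalog dump is a property of the dump, not
   of this package.
2. **LD clumping** at $R^2 \ge 0.5$: greedily take the remaining SNP
   with the smallest association p (ties: smaller position, then id)
   and remove everything correlated at or above the threshold. The
   output is order-invariant and is checked against a brute-force
   validity oracle on randomized panels. No distance window is applied;
   correlation is bounded by the block structure of the LD reference,
   which is exactly the information the two thresholds (0.5, 1.0)
   consume.
3. **Control matching**, 1:2 per index SNP: controls must lie within
   ±0.05 *absolute* minor allele frequency and within ±50% *relative*
   windows for gene density, nearest-gene distance, and LD-buddy count
   — the documented semantics of the standard matched-SNP tooling.
   Draws are seeded and without replacement per index; a shortfall is
   flagged, never silently relaxed. Within each disease category,
   duplicate control ids are removed (first occurrence in index
   position order); across categories a control may serve twice.
4. **Tag expansion and block collapse**: each lead (case or control)
   expands to its perfect proxies ($R^2 \ge 1$); the lead scores one
   overlap if *any* tag lies inside an enhancer interval, never more
   than one per lead, however many block members overlap.
5. **Logistic regression** per category and combined:
   $\mathrm{logit}\,P(\text{overlap}) = b_0 + b_1\,\mathrm{GWAS}$,
   fitted by IRLS; $OR = e^{b_1}$ with 95% Wald intervals from the
   observed information — for a saturated binary predictor this equals
   the 2×2 cross-product ratio, which the tests assert to seven
   digits. The combined analysis pools categories and de-duplicates
   leads by id (the treatment of cross-category duplicates is not
   externally specified; de-duplication avoids double-counting a
   signal). A zero margin makes the OR unidentifiable and the result is
   flagged degenerate rather than reported as a number with a fake
   interval; a zero *cell* reports the degenerate cross-product value
   (0 or Inf) with the same flag.

## The synthetic-data generator

`simulate_study()` emulates every input the pipeline consumes, under
one seed that fixes every output bit:

* **Regions**: ~2,000 candidate H3K27ac regions of 0.5–3 kb across four
  chromosomes; 75% also carry H3K4me1 (the dual-mark fraction observed
  in muscle); per-sample peak lists jitter each consensus edge by at
  most 10% of the region width.
* **Counts**: negative binomial with mean `library_size ×
  region_weight × exp(participant + training × planted lnFC)`,
  dispersion 0.1, library sizes 200k–500k (reads summarised onto
  regions), lognormal region weights. Participant effects (SD 0.2) are
  drawn once and shared between the ChIP and RNA simulations — the
  paired-design realism that makes `~participant` worth fitting.
* **Planted truth**: exactly `round(0.10 × n_dual)` regulated regions;
  21% of effects positive (matching the observed predominance of
  decreasing acetylation); magnitudes `|N(1.5, 0.25)|` on the natural
  log scale.
* **Gene coupling**: a gene's planted lnFC is `0.8 ×` the
  score-weighted mean of its linked enhancers' planted lnFC plus
  independent N(0, 0.1) noise; links connect each dual-mark region to
  its 1–3 nearest TSSs.
* **SNP panel**: per GWAS lead, an LD block with 0–2 perfect proxies
  and possibly a loose buddy ($R^2 \in [0.5, 0.95)$); LD-buddy
  covariates equal block size − 1 by construction; 5% of leads share a
  block with a weaker second catalog SNP so clumping has work to do;
  sub-threshold and haplotype rows exercise the catalog filter.
  Placement inside the supplied enhancer set is Bernoulli with odds
  `planted OR × baseline odds`, baseline 1.8% (the observed control
  overlap rate); perfect proxies share their lead's overlap status so
  the block-collapsed flags realize the planted odds. Controls are
  `control_ratio + 1` per lead with covariates perturbed *within* the
  matching windows — matchability is guaranteed by construction, which
  the tests assert.

What the generator does **not** emulate, and hence what green tests do
not certify about real data: read-level artefacts (duplicates, GC,
mappability), peak-caller behaviour, TMM-scale composition bias,
transcript-level quantification uncertainty, realistic human LD decay
(blocks are disjoint with no continuous recombination model), real MAF
spectra, and hg38 geometry. The generator validates the *inference
machinery* under its stated assumptions, not the upstream data
processing.

## Problem sizes and defaults

The shipped defaults — 8 participants, 2,000 regions, 1,000 genes, 19
trait categories, 4,000 GWAS leads (13,000 in the full study-scale
enrichment checks), 1:2 matching — are the design conditions of the
study the pipeline targets, scaled where noted to desk-size panels for
routine runs. The test suite states its sizes explicitly in each test;
stochastic checks fix their seeds and assert bands, not point values.

## Known limitations

* Normalisation is library-size offsets only; strong compositional
  shifts between states would call for TMM-style factors.
* The per-feature dispersion is estimated without empirical-Bayes
  sharing across features; at 8 pairs this costs some power relative to
  moderated pipelines, bought back by the calibrated F reference.
* The logistic enrichment treats leads as independent after clumping
  and block collapse; residual cross-block correlation is assumed
  negligible.
* MDS distances use the top-500 leading log-fold-change convention;
  the informative gene subset is a parameter (`top`), not an inference.
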