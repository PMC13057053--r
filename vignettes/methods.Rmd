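---
title: "Methods: germination indices, heritability, MGIDI selection and single-marker QTL scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germination indices, heritability, MGIDI selection and single-marker QTL scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedqtl)
```

`seedqtl` implements the desk-side analysis of a germination / seedling
drought experiment on a biparental doubled-haploid (DH) population: daily
germination counts and seedling measurements go in; trait tables,
variance components with heritability, a multi-trait selection index, and a
single-marker QTL scan come out. This vignette records the models, the
parameter choices, and the places where a genuinely open design decision was
made.

## The experimental design being analysed

The package assumes the common petri-dish layout: each genotype x treatment
combination is replicated as dishes of `total_seeds` (default 20) seeds
scored every 24 h for `n_days` (default 12) days, in a randomized complete
block design. Treatments are labelled `C` (control), `D` (drought, e.g.
osmotic stress by PEG-6000), `CN` and `DN` (the same two with a seed-priming
pre-treatment such as ZnO nanoparticle soaking). Priming is only a label on
the data here: nothing in the analysis depends on what the priming agent
was.

## Germination and seedling indices

From a dish's daily counts $n_1, \dots, n_k$ (seeds newly germinated on day
$g$, 1-based) with $N = \sum_g n_g$ germinated of $S$ sown:

* $FG\% = 100\,N/S$ and $IG\% = 100\,n_1/S$;
* $MGT = \sum_g n_g\,g / N$ (days), $MGR = 1/MGT$, and the germination pace
  $GP = 100\,N/\sum_g n_g g$, which is *algebraically identical* to
  $100\,MGR$ -- the package computes it that way so the identity holds
  exactly in floating point;
* $U = -\sum_i f_i \log_2 f_i$ (bits), $f_i = n_i/N$ over days with
  $n_i>0$; $Z = \sum_i \binom{n_i}{2} / \binom{N}{2}$, the fraction of
  germinated-seed pairs sharing a day. $U = 0$ and $Z = 1$ both characterise
  single-day germination;
* $CV_t = 100\, s_t / MGT$ with $s_t$ the *sample* ($N-1$ denominator)
  standard deviation of the individual seeds' germination days -- the choice
  of denominator is pinned by a per-seed enumeration oracle in the tests;
* $SVI = (\text{shoot} + \text{root length}) \times FG\%$. Whether the vigor
  index should use total or shoot-only seedling length is a genuine
  ambiguity in the field; total length (the classical convention) is the
  default and `svi_length = "shoot"` switches to shoot-only;
* for each trait $X$ measured under a control/drought pair,
  $DTI = 100\,X_D/X_C$ and the reduction $R = X_C - X_D$. DTI may exceed
  100 (root length often elongates under mild osmotic stress).

MGT is reported in days, not hours: with 24-h scoring intervals the day
index is the only computable time unit. Undefined statistics (no germinated
seeds; $N<2$ for $Z$ or $CV_t$; a zero control value for DTI) propagate as
`NA` with a warning by default; `strict = TRUE` raises an error instead.

`assemble_trait_table()` averages the per-dish indices over replicates
within genotype x treatment and derives the eight stress traits from those
replicate means (not per-replicate-then-averaged), pairing `D` with `C` and
`DN` with `CN`. With all four treatments supplied the table has
14 x 4 + 8 x 2 = 72 columns; each drought environment contributes the 22
traits used for selection.

## Variance components and heritability

`anova_two_way()` fits the balanced random-genotype model
$Y_{ij} = \mu + g_i + r_j + gr_{ij}$ with the genotype x replicate
interaction as the error stratum, by closed-form balanced sums of squares
(the tests cross-check every table against `aov()`). Variance components
follow the ANOVA method, $\hat\sigma^2_{GR} = MS_E$,
$\hat\sigma^2_G = (MS_G - MS_E)/r$, negative estimates clamped to zero.
Only balanced designs are supported; a missing dish must be imputed
upstream or the trait skipped.

Broad-sense heritability comes in two conventions:

* **entry-mean** (default): $H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GR}/r)$,
  equal to $1 - 1/F_G$ for the balanced design. This is the quantity that
  published trait-wise ANOVA tables of this kind tabulate -- their printed
  $h^2$ cells match $1 - 1/F$ for the printed $F$ ratios, which is how the
  package verifies its own arithmetic;
* **plot basis** (`mode = "plot"`): $\sigma^2_G/(\sigma^2_G + \sigma^2_{GR})$,
  the literal one-dish formula. Reports sometimes print this formula while
  tabulating entry-mean values; both are provided so either reading can be
  reproduced.

A zero error SS makes $F$ unbounded; it is reported as a flag
(`f_infinite`), never as a number. `anova_with_treatment()` adds a fixed
treatment factor tested against the random genotype x treatment interaction
($F_T = MS_T/MS_{GT}$), with genotype and interaction tested against the
residual.

## MGIDI selection

Selection uses the multi-trait genotype-ideotype distance index. The
"standardization" is two-stage, which is what makes the all-100 ideotype
well defined:

1. each trait is rescaled to $[0,100]$ with direction awareness
   (`rescale_trait()`): increasing traits map min->0, max->100; decreasing
   traits the reverse, so 100 is always ideal;
2. factor analysis of the rescaled matrix: correlation matrix, eigen
   decomposition, Kaiser retention (eigenvalue >= 1, boundary retained),
   initial loadings $V\sqrt{\Lambda}$, varimax rotation, and regression
   scores $Z R^{-1} \Lambda_{rot}$ where $Z$ is the column-standardized
   rescaled matrix. The ideotype's scores are the same projection of the
   all-100 row standardized with the rescaled-trait means/SDs.

$MGIDI_i = [\sum_j (\gamma_{ij} - \gamma_j)^2]^{1/2}$; lower is closer to
the ideotype. The factor shares
$\omega_{ij} = \sqrt{D^2_{ij}} / \sum_j \sqrt{D^2_{ij}}$ decompose each
genotype's index (rows sum to 1 exactly; a genotype landing on the ideotype
gets the uniform $1/f$ with a warning). Note the Euclidean distance is
invariant to the rotation; varimax only affects the $\omega$ decomposition
and the interpretability of the factors.

The varimax rotation is implemented as normalized pairwise sweeps
(`varimax_rotate()`, angle tolerance 1e-8, at most 1000 sweeps): for two
factors the planar angle is a closed form, so the rotation converges to the
criterion optimum essentially to machine precision. The tests check it
against both an independently coded rotation chain (1e-8) and
`stats::varimax` (looser, since that fixed-point iteration converges less
tightly). A singular trait correlation matrix is inverted with a small
ridge (1e-8) and a warning.

Defaults that matter:

* **selection pressure 0.15** -- ceiling(0.15 x 65) = 10 genotypes from a
  typical DH population of 63-67 lines, the usual "top ten" reporting size;
* **direction map** -- seven traits are marked `decrease` by default: MGT,
  U, CVt (slow/disordered germination) and the four reductions RFW, RSL,
  RRL, RRNo (drought damage). Which traits get reversed desirability is a
  judgment call a study must state; the map is therefore a visible,
  mandatory argument (`trait_directions()`) rather than something inferred;
* **selection gain** is the plain relative-mean form
  $100(\bar x_{sel} - \bar x_{all})/\bar x_{all}$ with desirability judged
  against the trait's direction; no heritability weighting.

## Single-marker QTL analysis

With DH genotypes coded $\pm 1$, the per-marker regression
$y = \mu + a x$ gives the additive effect directly as the slope (half the
difference between homozygote class means; positive means the
first-parent allele increases the trait). Per marker, lines missing either
datum are dropped (pairwise deletion), and

$$LOD = \frac{n}{2}\log_{10}\frac{SS_{tot}}{SS_{res}},\qquad
  PVE = 100\,(1 - SS_{res}/SS_{tot}),$$

the Gaussian maximum-likelihood equivalence, so
$PVE = 100(1 - 10^{-2\,LOD/n})$ holds definitionally for every record.
Monomorphic or under-covered markers (fewer than `min_lines = 10`
informative lines) are skipped and recorded; a zero residual SS caps LOD at
a configurable ceiling (default 50) rather than reporting infinity.

The genome-wide threshold is the $(1-\alpha)$ quantile (type-7
interpolation) of the per-permutation maximum LOD over a seeded set of
phenotype permutations; the seed is a required argument because the
threshold is part of the analysis record. Support intervals use the
standard 1-LOD-drop rule with linear interpolation between markers,
truncated at chromosome ends -- report-style half-unit interval endpoints
in published tables are treated as formatting, not as a reproducible rule.
`call_qtls()` merges significant markers whose support intervals overlap,
reports the peak with its map-neighbour flanking markers, classifies
strength by PVE (>= 20 very strong, 10-20 major, otherwise minor), and
names calls `Q<trait>_<env><chrom>`.

`map_summary()` reproduces the rollup convention of dense wheat DH map
reports: per-chromosome density is markers/cM, but the genome-group and
total "density" rows are the *sum of unrounded per-chromosome densities*.
That convention is unusual (it is not markers/length, which is also
provided as `density_ratio`), but it is the only reading that reproduces
the printed rollups of such tables, so it is the default for the summary
report.

The Kosambi map function $d = \tfrac14\ln\frac{1+2r}{1-2r}$ (inverse
$r = \tfrac12\tanh 2d$) is exposed in cM and is used both by the scan
report and the simulator.

## The synthetic-data generator

Because raw data of this kind are typically unreleased, the simulator is a
first-class module generating every pipeline input with the statistical
structure the analysis assumes. Its defaults *are* the study conditions:
63 DH lines, 3 replicate dishes of 20 seeds, 12 scoring days, four
treatments, and the bundled 21-chromosome / 3,567-SNP / 3,150.71-cM map
template, so `map_summary()` on a default simulation reproduces the
template rollups exactly.

* **Genotypes**: one recombinant gamete per line; the first marker of a
  chromosome is $\pm 1$ with probability 1/2 and each subsequent marker
  flips with the Kosambi $r$ of its interval, intervals independent (no
  interference beyond the Kosambi marginal). No heterozygotes, no
  genotyping error, no segregation distortion.
* **Seedling traits**: $y = \mu + t_k + \sum_q a_q(t)\,x_q + g_i + r_j +
  \varepsilon_{ijk}$ with per-trait polygenic and dish-error variances
  chosen to give entry-mean $H^2 \approx 0.95$, matching the high
  heritabilities such assays report. Planted QTL effects are expressed in
  trait units; `additive_for_pve()` converts a target PVE into an effect
  against the entry-mean background variance. Defaults plant effects with
  PVE spanning roughly 3-22 %, including a drought-specific shoot-length
  QTL near 20 %. Realized per-treatment PVE and $H^2$ are returned as
  `truth` alongside the data, since at $n = 63$ the realized values scatter
  substantially around their targets.
* **Germination**: per seed, a germination day drawn from a rounded
  Gaussian (line mean day + treatment baseline, per-seed SD 1.0) truncated
  to $[1, 12]$; each seed fails with a per-treatment probability. Baseline
  mean days 3.0 / 2.8 / 5.0 / 4.3 and failure probabilities 0.05 / 0.04 /
  0.35 / 0.25 for C / CN / D / DN encode the qualitative pattern such
  experiments show -- drought later and sparser, priming intermediate -- so
  that DTI < 100 and reductions > 0 on average. The rounded-Gaussian model
  is the simplest that produces the unimodal daily-count profiles the
  indices assume; real germination curves can be skewed or multimodal, and
  counts are bounded, so passing tests show the pipeline's arithmetic and
  power behaviour, not distributional fidelity to any particular real
  dataset.

Everything is seeded; identical configurations produce identical outputs.

## Numerical choices and problem sizes

Tolerances: index closed forms agree with per-seed enumeration to 1e-12;
ANOVA SS closure to 1e-9 relative; factor-chain oracle equivalence to 1e-8;
Kosambi round trip to 1e-12. Tie-breaks: selection ties at the cutpoint are
broken by stable input order with a warning. The statistical test suites
run at the study's design size (63 lines, 5 x 100-marker maps, 1000
permutations, 200 scan replicates, 50 selection replicates), which keeps
the full suite around ten seconds while leaving Monte-Carlo noise well
inside the asserted bands.

## Known limitations

* Only balanced designs; no REML or unbalanced mixed models.
* Single-marker analysis only: no interval/composite mapping, no epistasis,
  and no linkage-map construction (the map is an input).
* At $n = 63$, SMA power is limited: a QTL whose true PVE is 20 % has an
  expected peak LOD near $\tfrac{63}{2}\log_{10}(1/0.8) \approx 3.05$, so
  it clears a 3.3 threshold only with upward sampling noise (roughly half
  the time), while clearing the reporting threshold of 2 about two-thirds
  of the time; a 3 %-PVE QTL is rarely found at all. This is the
  quantitative case for lowering the reporting threshold in small DH
  populations, and the acceptance suite measures exactly these rates.
* Per-trait scans are not corrected for multiple testing across traits;
  the permutation threshold controls the genome-wise error within a trait.
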