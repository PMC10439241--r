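---
title: "Models and methods behind the proteodiff pipelines"
author: "proteodiff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the proteodiff pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodiff)
```

# Scope

`proteodiff` implements four differential-analysis arms for labeled
quantitative proteomics of neural stem cell (neurosphere) to
oligodendrocyte-precursor (oligosphere) differentiation, plus a
synthetic-data module that generates inputs with known ground truth for
all of them:

1. **TMT time course** — isobaric 6plex quantification of six time points
   (days 0–15), one plex per biological replicate: within-plex cyclic
   LOESS normalization, per-protein batch regression across plexes,
   paired t-tests of each day against day 0 with Benjamini–Hochberg
   adjustment and a fold-change gate, hierarchical clustering of
   z-scored temporal profiles, and keyword/term over-representation.
2. **Dimethyl phosphoproteomics** — class-I site filtering, multiplicity
   splitting, the both-replicate ±1 log2 regulation rule, Fisher-exact
   keyword enrichment, and position-frequency (sequence-logo style)
   motif analysis.
3. **SILAC BioID interactomes** — light/heavy enrichment ratios against a
   heavy-labeled control, the "two replicate ratios > 1" biotinylation
   rule, cyclic-LOESS (protein) or robust-linear-regression (site)
   normalization, MinProp imputation, empirical-Bayes moderated t-tests
   between bait constructs, and over-representation with Jaccard term
   simplification.
4. **Cleavage mapping** — semi-tryptic peptide ladder detection, exclusion
   of proline-adjacent breaks, retention-time discrimination of
   in-source fragmentation from genuine proteolysis, and matching of the
   surviving breakpoints to an externally predicted protease
   (calpain) site list.

All pipelines start from feature-level tables (protein groups,
phosphosites, peptide evidence); spectral search, PSM-level filtering and
protein inference are upstream and out of scope.

# Statistical core

## Normalization

`cyclic_loess_normalize()` iterates over all sample pairs; for each pair
it regresses the difference M on the average A of the two log2 columns
(first-degree LOESS, symmetric family, default span 0.7, 3 cycles) and
moves each member half of the fitted trend. The TMT arm applies it
within each plex (`normalize_tmt()`): a plex is one labeling and one MS
run, so the trends it can legitimately remove live inside the plex, while
between-plex offsets are left to the batch model. LOESS normalization
assumes most features are unchanged between samples; with strongly
unbalanced regulation it will absorb part of the real signal, which is a
property of the method, not of this implementation.

`rlr_normalize()` regresses each sample on the feature-wise median
reference with a Huber M-estimator (via `MASS::rlm`) and inverts the
fitted line, `x' = (x − b0)/b1`, so a linearly distorted sample is mapped
back onto the reference scale. Exact linear relations short-circuit to
ordinary least squares, where iterative reweighting has a degenerate
(zero) scale.

Both normalizations preserve the missingness pattern; only the explicit
imputation operators (`impute_min()`, `impute_minprop()`) create values.

## Batch correction

`remove_batch_effects()` fits, per feature, a linear model of intensity
on the biological group (time point) and the batch (plex) factor with
sum-to-zero batch contrasts, and subtracts each sample's estimated batch
effect. Sum-to-zero contrasts make the correction level-preserving.
A design in which batch is confounded with group is refused, naming the
factor; features with too few observed values for a full-rank fit pass
through unchanged rather than receiving an unstable correction.

## Paired and moderated tests

`paired_t_test()` is the literal statistic `mean(d)/(sd(d)/sqrt(n))` on
complete pairs with `df = n − 1`. Zero-variance differences with a
nonzero mean get a p-value at the smallest positive double, with a
warning; below two pairs no statistic is produced.

`moderated_t_test()` fits per-feature linear models and shrinks the
residual variances toward a prior by empirical Bayes. The prior is
estimated by moment matching on the log variances: with
`e = log(s²) − digamma(df/2) + log(df/2)`, the excess of `var(e)` over
`mean(trigamma(df/2))` determines the prior degrees of freedom through
the inverse trigamma function, and the prior variance follows from the
mean of `e`. With `trend = TRUE` the prior variance is a LOESS-smoothed
function of the feature's average intensity instead of a constant.
Numerical guards: sample variances are floored at `1e-5` of their median
before taking logs (duplicate imputed values otherwise produce
`log(0)`); when no excess variability remains the prior df is infinite
and the prior is the pooled mean variance; the total df is capped at the
pooled residual df. The implementation is authored from these closed
forms; the test suite verifies it against `limma::eBayes` to `1e-6`
(constant-prior case) and against hand-coded ordinary t-tests in the
zero-shrinkage limit. The intensity trend uses the package's LOESS
primitive, so `trend = TRUE` is intentionally not asserted equal to
limma's spline-based trend.

## Multiplicity, enrichment, clustering

`bh_adjust()` is Benjamini–Hochberg step-up (delegating to
`stats::p.adjust` over the non-missing entries); tests compare it to a
literal step-up oracle. `fisher_enrichment()` tests each annotation term
on the 2×2 membership table (`stats::fisher.test`), with fold enrichment
`(k/set)/(K/background)` and BH across terms; each feature counts once
per term no matter how many of its sites carry it. Two-sided tests are
the default; over-representation analysis (`ora()`) uses the one-sided
upper tail, the convention of enrichment tools.

`hierarchical_cluster()` uses `1 − Spearman ρ` distance and complete
linkage (`stats::hclust`), cut at `k` clusters. Constant profiles have
undefined rank correlation and are split into singleton clusters after
the regular ones, with a warning. `cluster_silhouette()` reports the
mean silhouette width over a k range for users who prefer a data-driven
k; the TMT default remains `k = 7`.

# The synthetic-data module

The generators are first-class, tested code: they define the study
conditions under which the pipelines are validated.

**TMT** (`simulate_tmt()`): defaults of 6 time points (0–15 d) and
5 plexes mirror the experimental design ("five independent biological
replicates"; the elsewhere-quoted n = 7 is left to the `n_plexes`
parameter rather than resolved). Regulated features follow one of seven
temporal archetypes — gradual rise/fall, early rise/fall, mid-course
peak/trough, and a rise-then-fall pattern — scaled so the per-day true
effect lies between 0.75 and 1.0 times `effect_log2`. Two design
constraints shape these curves: every regulated day keeps a near-full
effect (so calling truth is unambiguous at the ±1 log2 gate), and the
seven shapes have distinct, tie-free rank signatures (Spearman distance
cannot separate shapes that share a rank order, and tied values get
their ranks from noise — pure step profiles are degenerate under this
metric, and any two monotone shapes of the same sign are
indistinguishable). Batch offsets are additive per plex on the log2
scale and shared by all channels of the plex — exactly the structure the
per-protein batch regression can remove. Noise is i.i.d. normal on the
log2 scale and missingness is completely at random; real TMT data also
carry intensity-dependent missingness and correlated noise, which these
tests deliberately do not probe.

**Phosphosites** (`simulate_phospho()`): 2 replicates and 3 comparisons
(day 7/0, 14/0, 14/7), localization probabilities with a configurable
sub-0.75 fraction, multiplicities 1–2 per site, and both-replicate
shifts of ±`effect_log2` for the regulated sites (concentrated in the
day 14/0 comparison). Regulated windows embed a proline at +1 with a
basic residue at −3 at `motif_excess` above the uniform background — a
minimal stand-in for proline-directed kinase motifs.

**BioID** (`simulate_bioid()`): four constructs × 3 replicates against a
pooled heavy control whose true abundance is constant, so the
light/heavy log2 ratio is exactly Normal(`effect_log2`, `noise_sd`) for
interactors of the construct and Normal(0, `noise_sd`) otherwise.
Missingness is left-censored through a logistic curve on intensity
(50% missing at the 8th intensity percentile, scale 0.6 log2 units),
the not-at-random pattern that motivates minimum-value imputation.

**Semi-tryptic peptides** (`simulate_semitryptic()`): Trypsin/P digestion
(cleavage after K/R including before proline, ≤2 missed cleavages,
minimum length 7), fully tryptic parents with uniform reference
retention times, in-source fragment ladders jittered within ±0.1 min of
their parent, and true proteolytic products displaced by 10–25 min.
`synthetic_cleavage_protein()` packages a 400-residue fixture whose
breakpoint geometry (true ladders 320–323 and 356–359, in-source ladder
313–316, proline break at 305, tryptic site at R342, sub-length peptide
around Q384) exercises every branch of the mapper, together with a
synthetic predicted-site list at positions 323/342/357/384.

Identical configuration and seed give byte-identical output; the
regulated count is exactly `round(frac_regulated · n_features)`.

# Pipeline-level decisions

* **"Three valid values per comparison"** is read as ≥3 complete
  day/baseline pairs within plexes; no imputation in the TMT arm.
* **BH per comparison** (not pooled across days), matching the
  day-by-day paired testing; a feature is `up` when `q < 0.05` and its
  mean paired difference is ≥ `log2(2)`.
* **Class-I boundary inclusive** (≥0.75): the source descriptions state
  both ">0.75 kept" and "<0.75 removed"; the inclusive reading
  reconciles them and matches field convention.
* **Regulation cutoff per replicate** — no averaging; a site is called
  only when every replicate ratio passes ±1 on the same side.
* **Motif background** defaults to the dataset's own class-I windows; an
  external background can be supplied (a precompiled proteome background
  is out of scope).
* **BioID channel roles**: the heavy control is used only for
  enrichment ratios; construct-versus-construct tests use non-imputed
  light intensities, normalized (cyclic LOESS at protein level, RLR at
  site level), then MinProp-imputed. "MinProp" scales the global minimum
  by an exposed `proportion` parameter (default 1.0, i.e. plain minimum)
  since the method's exact semantics are not published. The differential
  additionally requires ≥2 observed light values per compared construct
  (`min_valid_per_group`), the standard missing-value filter in
  limma-style pipelines: features quantified on one side only would
  otherwise be tested on imputed duplicates with zero residual variance.
* **Term simplification** keeps, of any pair with Jaccard similarity of
  feature sets > 0.7, the term with the smaller adjusted p, processing
  terms in ascending-q order for determinism.
* **Cleavage mapping**: retention times are intensity-weighted means per
  peptide; in-source classification requires all ladder members within
  `rt_tolerance = 1` min of the spanning fully tryptic parent; proline
  exclusion applies to either side of the break; ladders need ≥2
  consecutive breakpoints (singletons are kept as width-1 candidates);
  predictions are matched within ±2 residues, nearest first, ties to the
  higher score. Unmatched predictions are contextualized: on a K/R cut
  position they cannot produce semi-tryptic evidence, and when the
  product to the nearest tryptic cut is shorter than 7 residues they are
  below the detection floor.

# Validation design and problem sizes

Tests validate each primitive against an independent oracle (literal BH
step-up, exhaustive hypergeometric enumeration for all tables with
N ≤ 20, a brute-force O(n³) complete-linkage search, hand-coded ordinary
t statistics, and `limma` as an external cross-check), then measure
truth recovery of the full pipelines on generated data: TMT at 500
features, 20% regulated, |log2 FC| = 1.5, noise 0.3, batch SD 1, 5
plexes over 20 seeds (feature-level sensitivity and FDR); null runs at
0% regulation (called fraction and p-value uniformity); cluster recovery
on an all-archetype, low-noise fixture (adjusted Rand index); phospho
calling at 1000 sites, 10% regulated; BioID at 600 features over 10
seeds; and the cleavage fixture exactly. These sizes keep the whole
suite around two minutes on a single core while leaving the Monte Carlo
error of the recovery rates near one percentage point.

Because a feature's per-day effects are graded, TMT sensitivity is
defined at the feature level (recovered = called with the correct sign
in at least one truly regulated comparison); per-comparison power of a
4-df paired t-test under BH is intrinsically lower, and no threshold in
the package is tuned to mask that.

# Known limitations

* Synthetic noise is homoskedastic and independent across samples;
  passing recovery tests does not certify behavior under correlated or
  intensity-dependent noise.
* The LOESS trend of the moderated test is not exchangeable with
  limma's spline trend at numerical precision (the constant-prior case
  is).
* GO term databases, kinase-motif catalogues and the external cleavage
  predictor are inputs, not components; enrichment quality on real data
  depends entirely on the supplied annotation maps.
* Phosphosite-to-protein normalization and PCA/heatmap figure generation
  are out of scope.
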