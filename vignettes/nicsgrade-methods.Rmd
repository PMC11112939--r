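---
title: "Methods: simulation, copy-number calling and euploidy grading in nicsgrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, copy-number calling and euploidy grading in nicsgrade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nicsgrade` models the analysis chain of a noninvasive chromosome screening
(NICS) grading system: shallow sequencing of embryo spent-culture-medium
cell-free DNA, binned copy-number calling, a mosaicism-aware feature
representation, a random-forest euploidy grader, and the clinical statistics
used to compare embryo-selection strategies. This vignette is the package's
own account of the models, the tunable parameters, the numerical choices,
and what the tests do and do not establish.

## The read-count model

The genome is tiled into 1 Mb bins (`make_genome()`, 24 human-like
chromosomes, 3,102 bins). A bin under an event with mosaic fraction
$m \in (0,1]$ and single-copy change $\Delta \in \{-1,+1\}$ has local copy
number

$$c = b\,(1-m) + (b+\Delta)\,m = b + \Delta m,$$

with baseline $b = 2$ on autosomes ($b$ per sex on X/Y). The sample mixes
the embryo profile with a diploid-XX maternal contamination profile at
fraction $\kappa$ (default 0: the sampling protocol is designed to wash out
maternal DNA; the knob exists to study robustness). Bin means are
proportional to $[(1-\kappa)c_e + \kappa c_x] \cdot g(\text{GC}) \cdot w$,
normalized to an expected library size of `depth` (default 2,000,000 reads,
the typical yield per medium library).

Counts are negative binomial with variance $\mu(1+d)$, i.e. size
$\mu/d$. The dispersion `d = 0.05` keeps variance close to the mean —
shallow whole-genome-amplified libraries are modestly overdispersed — and is
a config knob; the real data's overdispersion is not published, so this
default is *declared*, not inferred. The GC bias default is a unimodal
quadratic peaking at GC = 0.45 (`gc_bias_quadratic()`), the standard shape
of amplification bias; per-bin GC comes from a smooth deterministic
sinusoidal profile rather than a reference FASTA, which preserves the
statistical structure (smooth within-chromosome GC variation) without
binding the package to a genome build.

### Karyotype generator

`simulate_karyotype()` draws an event category — euploid / whole-chromosome
/ arm / segmental — with default probabilities 0.40 / 0.30 / 0.15 / 0.15.
These defaults are a deliberate statement of the simulated world: roughly
60% of blastocysts abnormal at some level, whole-chromosome errors dominant,
consistent with the aneuploidy spectra reported for IVF embryos in the
advanced-maternal-age setting the screening targets. Events are single-copy
gains or losses; a draw is non-mosaic ($m=1$) with probability 0.5,
otherwise $m \sim U(0.2, 0.8)$. Segmental events span at least 10 Mb — the
system's stated resolution — and at most 60 Mb. XX embryos never receive Y
events (no Y material exists to mutate).

**Training label.** An embryo is labelled aneuploid iff it carries any
event with $m \ge 0.5$; low-fraction mosaics count as euploid-compatible.
This mirrors the 50%-mosaicism redefinition built into the features and
keeps labels consistent with the grading threshold philosophy.

## Copy-number calling

`gc_normalize()` corrects counts by smoothed stratified medians over
2%-wide GC strata (deterministic and dependency-light rather than a named
smoother), then scales the autosomal median to 2 copies.
`reference_normalize()` divides by a euploid panel's per-bin median,
attenuating recurrent positional bias; bins whose panel median is near zero
(chrY against an XX panel) are left unscaled.

Segmentation is circular binary segmentation on the copy-number scale (the
original software's internal transform is unpublished; segmenting untransformed
copy number keeps segment means directly interpretable as $2 \pm m$). At
each step the arc $(i,j]$ maximizing

$$T = \frac{|\bar{x}_{\text{arc}} - \bar{x}_{\text{rest}}|}{\sqrt{1/k + 1/(n-k)}}$$

is found (the noise SD is constant under permutation and omitted); the
split is accepted if its permutation p-value over `n_perm = 1000`
permutations is below `alpha = 0.01`, recursing until no split is accepted
or segments reach `min_bins = 3`. Permutations terminate early as soon as
the exceedance count makes rejection certain, which changes nothing about
the accept/reject decision but makes flat chromosomes cheap. Adjacent
segments closer than `undo_sd = 1` noise SDs (noise estimated by
`mad(diff(x))/sqrt(2)`) are re-merged. CBS parameters are conventional
defaults — none are published for the original pipeline — and all are
exposed in the configuration.

Per-segment mosaicism is $\hat m = \min(|\bar c - b|, 1)$. Calls require a
deviation of at least `call_margin = 0.3` copies and a span of at least
10 Mb. The margin sits deliberately *below* the 0.5 feature threshold so
sub-threshold mosaics remain representable in the continuous features
(highest mosaic fraction, largest fragment); it is configurable. Each
call's scope is whole-chromosome if it covers ≥ 90% of the chromosome's
bins, arm if ≥ 90% of exactly one arm, else segmental; the published
resolutions come with no coverage rule, so the 90% rule is this package's
declared convention. Sex is called from chrX/chrY medians with a 0.35-copy
tolerance against the XX and XY expectations; profiles matching neither are
`abnormal`. A mosaicism threshold of 0.6 has been proposed for *clinical
reporting* in NICS; this module estimates continuous fractions and leaves
all thresholding to the feature layer.

## The 11 features

Features 1/3/5 are ordinal CNV calls at 10 Mb / arm / chromosome
resolution: 0 euploid, 1 mosaic-abnormal, 2 full-abnormal, with
`full_threshold = 0.8` separating mosaic from full in the un-redefined
features (the published feature list distinguishes the two but states no
cut; 0.8 is configurable). Features 2/4/6 redefine each resolution by the
50% threshold: events below 0.5 are treated as euploid, at or above as
full — the boundary is *inclusive* at exactly 0.5, a declared convention
the published phrase does not resolve. Feature 7 counts resolutions whose
redefined call is euploid (0–3). The alternative reading — euploid
*chromosomes* per resolution — is noted; the resolution-count reading is
implemented because it makes f7 the natural complement of f2/f4/f6.
Feature 8 counts distinct chromosomes carrying calls, f9 is the highest
mosaic fraction, f10 the span (Mb) of the largest call attaining f9 (ties
resolved toward the largest span), f11 flags an abnormal sex call.

Ordinal {0,1,2} encoding preserves severity ordering for tree-based
models; the original encoding is unpublished.

## Grading

The original model's training data and weights are unavailable; `nicsgrade`
retrains the same *architecture* — a random forest — on labelled synthetic
embryos and treats classifier quality as a recovery/ordering property,
never as a reproduction of the original probabilities. The forest (500
trees, `mtry = 3`, balanced per-class bootstraps, Gini splits) is
implemented in compiled code because no random-forest package is available
in the target environment; probabilities are averaged terminal-node euploid
proportions, used raw (no isotonic or Platt calibration — whether the
original model calibrates is unstated, and raw vote fractions are the
documented choice).

For large labelled cohorts the features are computed from
`callset_from_truth()`: true events converted to calls with Gaussian
measurement error (SD 0.04) on the copy-number shift, matching the
per-chromosome error of the full chain at 2 M reads. This avoids paying
read-level simulation and segmentation for thousands of training embryos;
the fidelity of the full chain itself is established separately by the
segmentation-oracle and mosaicism-recovery tests.

Grades: A iff $p \ge 0.94$, C iff $p \le 0.7$, B otherwise. The published
bins overlap at both edges ("≥ 0.94, 0.7–0.94, ≤ 0.7"); keeping the two
explicitly closed inequalities and making B the open interval is the
declared resolution. Transfer ranking lists A-grades before B-grades,
excludes C, orders by descending probability within grade, and breaks ties
by Gardner morphology priority (AA/AB/BA/BB before AC/BC/CA/CB, the
consensus high-quality set), then input order.

## Clinical outcomes

`reconstruct_patient_table()` expands published per-stratum counts into the
unique patient-level binary table with those marginals, using the outcome
nesting live birth ⊆ ongoing ⊆ clinical ⊆ biochemical; every printed rate
then reproduces exactly under half-up rounding to one decimal. Age and
miscarriage stratifications are reconstructed as separate tables because
the joint distribution across the two stratifiers was never printed.

`chisq_2x2()` defaults to Pearson without continuity correction, with Yates
and Fisher's exact available by flag; which variant produced the published
p-values is unstated (the small-cell strata, e.g. 0/8, are exactly where
the choice matters), so the package computes all and asserts none against
the published values. `fit_logistic()` is a maximum-likelihood logistic fit
(IRLS) with Wald CIs, categorical covariates dummy-coded against declared
references (control group, male-factor indication, primary infertility),
and separation flagged rather than silently dropped.

**The published adjusted odds ratios (2.822, 3.355, 3.089, 2.595) are not
reproducible** from any released data: they condition on seven
patient-level covariates that exist only in the study database.
`compare_groups()` on reconstructed tables therefore reports
`adjusted_available = FALSE` instead of a number. The substitute evidence
that the machinery is correct is parameter recovery: cohorts simulated at a
true group OR of 2.8 with baseline-table-like covariate distributions give
Wald CIs covering the truth at nominal rate (the acceptance suite requires
90–98% over 200 replicates), and the saturated two-group fit equals
$\log(ad/bc)$ to $10^{-8}$.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; bin indices genome-ordered.
* Rates round half-up (`floor(10x + 0.5)/10`), matching printed tables;
  `round()`'s banker's rounding would disagree on exact halves.
* Chromosomes shorter than `2 * min_bins` return a single segment, not an
  error; all-zero count vectors, empty reference panels, zero-margin 2×2
  tables, single-class training labels and out-of-range probabilities are
  rejected with named errors.
* All randomness flows through R's RNG, including inside the compiled CBS
  permutations and forest training, so a single `set.seed()` (or the
  `--seed` flags) makes every path byte-reproducible.

## What the synthetic world does and does not establish

The generator emulates: mosaic aneuploidies at the three resolutions, GC
coverage bias, mild overdispersion, maternal contamination, sex chromosome
constitutions, and cohort covariate distributions with a stated logistic
outcome model. It does not emulate: amplification artifacts with genomic
structure (waviness beyond GC), segmental events below 10 Mb, multi-copy
gains or ploidy-wide abnormalities, inter-embryo correlation within
patients, or the real joint distribution of morphology and karyotype. A
green test therefore establishes that the implementation is faithful to the
stated model and recovers its parameters — not that the grader would attain
any particular clinical accuracy, which only data like the original
study's can establish.

## Known limitations

* The classifier is only as representative as the synthetic label
  distribution; its absolute probabilities should not be transferred to
  real data.
* The mosaic-fraction estimator assumes the single-aberrant-copy scale;
  multi-copy events would alias to fraction 1.
* The 90% coverage rule for scope classing can class a near-complete arm
  deletion with a few noisy bins as segmental; the margin is configurable.
* Reference panels should be sex-matched (or mixed with caution): the chrX
  median of a mixed panel is not a valid diploid baseline, which is why
  chrY-like near-zero bins are left unscaled.
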