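---
title: "Models and methods behind cryptomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cryptomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptomorph)
```

`cryptomorph` reimplements, as a tested pipeline over synthetic data, a
genotype–phenotype analysis of a polymorphic moth whose male hindwing colour
is controlled by one Mendelian locus with two alleles: `W` (white, dominant)
and `y` (yellow, recessive). The interesting scientific twist is that the two
white genotypes (`WW`, `Wy`) differ in the ultraviolet, so they are "cryptic
morphs": indistinguishable to humans but separable to UV-sensitive receivers
such as birds and the moths themselves. The package covers four analyses —
Mendelian segregation and pedigree back-trace, image feature extraction,
discriminant classification, and receptor-noise-limited (RNL) vision
modelling — plus the seeded generator that stands in for the original rearing
and photography data.

This vignette explains the models, the tunable parameters and the numerical
choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The inheritance model

Genotypes are unordered allele pairs over `{W, y}`; males express the locus
through the dominance map `WW, Wy -> white`, `yy -> yellow`. Offspring
genotype distributions are Punnett-square enumerations of parental gametes
(`offspring_genotype_distribution()`), and the male phenotype distribution is
that distribution pushed through dominance: the classic `Wy x Wy` cross
yields 3:1 white:yellow.

**Segregation testing.** `chi_square_gof()` computes the Pearson statistic
over cells with positive expected probability, with `df = cells - 1`, no
continuity correction, and an explicit "impossible observation" error when a
count appears in a zero-probability cell — that situation falsifies the
assumed cross rather than producing a number. `pooled_segregation_test()`
treats every offspring as an independent draw, sums per-family statistics and
degrees of freedom across cross strata. Families with fewer than 10 male or
10 female offspring are flagged and skipped, never silently dropped.

**Cross inference.** `infer_cross_from_offspring()` scores the six cross
types by the binomial likelihood of the yellow-male count under their yellow
probabilities (0, 0, 0, 1/4, 1/2, 1). The three all-white crosses are an
exact likelihood tie whenever no yellow offspring is observed; the tie is
always reported as a set (identifiability class "all-white"), never broken.
A consequence worth knowing when interpreting recovery rates: with 40 male
offspring the maximum-likelihood boundary between yellow probability 1/4 and
1/2 falls at 14.76 yellows, so `Wy x Wy` is misread as `Wy x yy` with
probability `P(Bin(40, 0.25) >= 15) ≈ 0.054` and the converse error has
probability `P(Bin(40, 0.5) <= 14) ≈ 0.040`. These error rates are
properties of the likelihood itself, not of the implementation, and they cap
achievable per-cross recovery near 95–96% at that brood size.

**Pedigree back-trace.** `propagate_pedigree_genotypes()` computes exact
posterior genotype marginals by enumerating joint genotype configurations of
each connected pedigree component: Hardy–Weinberg founder priors, Mendelian
transmission probabilities, dominance likelihoods for observed male
phenotypes, and conditioning on any recorded genotypes. Female phenotypes are
treated as uninformative for this locus (see below). Enumeration prunes
zero-probability branches but remains exponential, so components are capped
at 12 individuals by default — 3^12 ≈ 5·10^5 configurations is comfortably
enumerable in R while 3^20 is not — and larger components raise an explicit
error asking the user to partition. We chose exact enumeration over
approximate peeling so that the brute-force oracle in the test suite can
certify the marginals to 1e-12.

## The synthetic-data generator

The generator defines the study conditions the analyses assume; it is
deliberately simple and every default is stated.

* **Pedigrees** (`simulate_families()`): 452 founder families by default,
  40 offspring each, founder genotypes drawn at Hardy–Weinberg proportions
  with `allele_freq_W = 0.5`, fair coin for sex. The ≥10 male / ≥10 female
  inclusion filter is encoded as an `excluded` flag.
* **Female colour** is a 1–6 yellow–orange–red score drawn from a standard
  normal latent cut at fixed quantile-matched edges so the marginal category
  frequencies are 3% yellow / 68% orange / 29% red regardless of genotype —
  the observed marginals of the system being modelled, which shows no female
  genotype–phenotype coupling. Each colour category splits evenly into its
  two scores. A `female_genotype_shift` parameter (latent-mean offset per W
  allele, default 0) exists because the coupling is an open empirical
  question; the default encodes "no coupling".
* **Specimen images** (`simulate_specimen()`): four co-registered 96×96
  reflectance rasters (uv, sw, mw, lw) with a fixed rectangular ROI layout
  (forewing, hindwing, thorax, abdomen; disjoint by construction), Gaussian
  per-pixel noise (sd 0.02), a per-specimen mean offset per ROI×channel
  (sd 0.03) for between-individual variation, and dark disk markings in the
  forewing. Genotype effects are placed where the real system shows them:
  `yy` hindwings have high long-wave and low short-wave reflectance and
  smaller forewing markings; `WW` differs from `Wy` **only** in UV (thorax
  0.20 vs 0.30, abdomen 0.18 vs 0.28, hindwing 0.30 vs 0.42). The 0.10–0.12
  UV gaps against a 0.03 between-specimen sd make the white genotypes
  cleanly separable with UV access and near-chance without, which is the
  qualitative phenomenon under study. Values are clipped to [0, 1].
* **Reproducibility**: every generator is a pure function of (config, seed);
  cohort members get seeds hashed from (cohort seed, index), so a specimen
  can be regenerated without its cohort.

What the generator does **not** emulate: realistic wing shapes, illumination
and camera spectral response, registration error, or pigment chemistry.
Passing tests therefore certify the pipeline's statistics and numerics, not
performance on real photographs; in particular the classifier accuracies
reported on synthetic cohorts are qualitative analogues of, not estimates
of, accuracies attainable on real images.

## Image features

`calibrate_reflectance()` maps raw responses affinely so the two grey
standards (7% and 93% reflectance) land at 0.07 and 0.93, clipping to
[0, 1]. Synthetic specimens are generated directly in reflectance units, so
calibration is exercised on its own fixtures.

**Granularity analysis.** Band scales form the geometric sequence 2, 2.83,
…, 90.5 px (`start 2, end 100, factor 1.414`; 12 bands). Each band is an
isotropic Fourier band-pass: a raised-cosine response on the log-wavelength
axis, full at the band's scale and falling to zero at the geometric midpoints
to the adjacent scales. A band's scale equals the Fourier wavelength (px) it
passes at full response — a square grating of period 16 px peaks in the band
nearest 16. The response at zero frequency is identically zero, which gives
mean-invariance: adding a constant to the image changes no band energy.
Pixels outside the ROI mask are replaced by the ROI mean before the
transform (a stated approximation that avoids mask-edge energy), the image
is cropped to the mask's bounding box, and a band's energy is the standard
deviation of the filtered pixels inside the mask. Bands wider than the ROI
bounding box carry zero energy and trigger a classed warning.

Summaries follow the field's conventions: dominance (`maxPower`) is the peak
energy, diversity (`propPower`) the peak over the summed energy, marking
size (`maxFreq`) the scale of the peak (ties broken toward the smallest
scale and flagged, so the result is deterministic). "Pattern contrast" is
used by downstream analyses but lacks a standard definition; we implement it
as the root of the summed squared band energies and flag it as a package
convention, toggleable by using the spectrum directly.

**Other features.** ROI channel means and pixel areas; a 20-band equal-width
luminance histogram over [0, 65535] (long-wave reflectance × 65535, the
dynamic-range anchor of 32-bit TIFF), computed on request but excluded from
the default feature set because its role in the original discriminant
analysis is not established; and the four allometric area ratios FW/AB,
FW/TH, FW/HW, TH/AB. The published ROI list contains "forewing to hindwing
(FW/AB)", an evident label typo; we implement FW/HW. Correlation filtering
(`drop_correlated_features()`) is greedy: among the worst remaining pair
above |r| = 0.9 it drops the member with the larger mean absolute
correlation, a deterministic order; zero-variance columns are dropped first
with their own reason.

## Classification

`fit_discriminant()` is classical multi-group LDA with internal
standardization, class means, pooled within-class covariance and whitened
discriminant axes (at most `groups - 1 = 2`). Priors default to uniform
because the cohort's 37/88/42 class sizes would otherwise bias assignment
toward `Wy`; this is configurable. If the pooled covariance is singular the
diagonal is ridged by `1e-6 · trace/d` and the model records it. Evaluation
is leave-one-out (`evaluate_loo()`), chosen because it is deterministic and
needs no split convention; the original analysis reports test-set accuracy
without specifying its split, so only qualitative agreement is meaningful.
Mahalanobis classification makes predictions invariant under invertible
affine maps of the feature space, which the suite verifies, and an
independent implementation (`MASS::lda`) serves as a cross-check oracle in
tests, never as the implementation.

`shadow_feature_selection()` is a Boruta-style screen: each iteration
appends an independently permuted copy of every feature, fits a random
forest (ranger, 500 trees, sqrt-features per split, impurity importance,
seeded), and scores each real feature by whether it beats the best shadow.
Win counts are tested against a fair coin (exact binomial, two-sided 0.01):
significantly above confirms, below rejects, otherwise tentative. Since a
pure-noise feature beats the *maximum* of all shadows only rarely, the
coin-null is conservative for confirmation. One honest caveat: a noise
feature that happens, by sampling accident, to correlate with the labels
carries that association into every iteration while shadows are re-permuted,
so occasional false confirmations are intrinsic to the shadow logic at
moderate n, not an implementation artefact.

## Receptor-noise-limited vision models

Receivers: trichromatic human (sw:mw:lw cone ratios 0.057:0.314:0.629),
tetrachromatic blue tit (uv:sw:mw:lw 1:1.92:2.68:2.7) and trichromatic moth
(uv:sw:mw 1:1:1, the true ratio being unknown), all with Weber fraction 0.05
for the most abundant cone. Channel noise follows
`e_i = ω · sqrt(η_max / η_i)`, anchoring ω to the most abundant cone —
the only rule consistent with specifying a single Weber fraction "for the
most abundant cone type". Quantum catches default to identity selection of
the receiver's channels from the camera channels (uv→uv, …) because no
camera-to-cone mapping matrix is available for the modelled system; a
configurable linear mapping hook accepts one. Catches are floored at 1e-6
(flagged) to keep log ratios finite.

Chromatic contrast uses the high-signal log form `Δf_i = ln(q_A,i/q_B,i)`
and the standard RNL quadratic form, implemented generally for n channels as
`dS² = Δf' Q Δf` with `Q = D⁻¹ − D⁻¹11'D⁻¹ / (1'D⁻¹1)`, `D = diag(e²)`.
This reduces exactly to the published dichromat/trichromat/tetrachromat
closed forms, which the package also ships (`rnl_contrast_closed()`) and the
suite equates to 1e-9 on random inputs. dS is symmetric, zero on identical
stimuli, invariant to uniform scaling of one stimulus and to von Kries
scaling of any channel in both. Achromatic contrast (dL) is intentionally
not implemented: the analysis this package reproduces excludes it. The 1 JND
threshold labels pairs as discriminable; it is a modelling convention, not a
behavioural validation.

## Problem sizes and numerical tolerances

The test suite and acceptance script run everything at sizes a laptop core
handles in minutes: back-trace recovery uses 1000 simulated 40-male broods
per cross type, segregation calibration 2000 family sets of 100, the
pedigree oracle 50 random pedigrees of ≤ 8 individuals (exact agreement to
1e-12), the granularity oracle full-spectrum spatial-domain convolution on
64×64 images (1e-8), RNL identities 1000 random trials (1e-9), and the
classifier analyses ten image cohorts of 167 specimens. The shadow-screen
stability check runs 50 replicates at a reduced per-replicate size (40
iterations, 150 trees) with one full-default replicate (100 iterations, 500
trees) for the confirmation assertions; the binomial decision rule is
size-invariant, and the reduced replicates are actually the more
conservative configuration (the confirmation threshold is a higher win
fraction at smaller n).

## Known limitations

* The generator's fixed rectangular ROI layout removes segmentation and
  registration as sources of error; real pipelines have both.
* Exact enumeration limits back-trace components to ~12 individuals; deep
  linked pedigrees need manual partitioning (no peeling in this version).
* The identity camera-to-cone mapping is a stated approximation; with real
  spectral sensitivities the dS magnitudes would change, though the
  UV-carries-the-difference conclusion is driven by channel access, not by
  the mapping details.
* Mixed-effects significance modelling of dS and human behavioural sorting
  experiments are out of scope; the package emits descriptive pairwise
  tables instead.
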