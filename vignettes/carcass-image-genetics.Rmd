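---
title: "Carcass cross-section image traits and their genetic parameters"
author: "wagyuIAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carcass cross-section image traits and their genetic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wagyuIAT)
```

## The problem

Japanese Black (Wagyu) carcasses are priced per kilogram at auction, and the
price moves with features of the cross-section between the 6th and 7th rib
that human grading only partly captures: the sizes of the five exposed
muscles (*M. longissimus dorsi*, *M. semispinalis capitis*,
*M. semispinalis dorsi*, *M. trapezius dorsi*, *M. latissimus dorsi*), the
amount and texture of marbling inside each muscle, and the intermuscular
(IF) and subcutaneous (SF) fat depots. `wagyuIAT` implements the full
analysis chain for such data: image-analysis trait (IAT) extraction from a
labelled cross-section image, fixed-effects modelling of unit price, and
Bayesian animal-model estimation of heritabilities and genetic
correlations — together with a synthetic-data layer (image phantoms and
pedigreed phenotypes) that makes every stage testable without access to any
private carcass records.

## Carcass phantoms

Real carcass images and the matching commercial segmentations are not
publicly available, so the package generates *phantoms*: label maps with the
full region inventory (five muscles, IF channels, an SF band, other tissue)
plus a rendered grayscale image (lean dark, fat bright, optional Gaussian
noise). Geometry is specified in physical centimetres and rasterized at a
chosen calibration (pixels per cm), and marbling particles — axis-unaligned
ellipses with log-normal areas — are drawn in physical coordinates against
the analytic region shapes. Two consequences matter for testing:

* **Ground truth is defined on the rasterized pixel masks**, not the
  continuous shapes, and is computed by the very trait definitions used for
  extraction (`groundTruthTraits()` shares code with `extractIAT()`, with
  the exact marbling mask standing in for intensity thresholding). Pixel
  quantization therefore cancels in round-trip tests: extracted areas and
  percentages equal ground truth exactly on noiseless phantoms.
* **A fixed seed describes one physical carcass at any resolution**: the
  particle set is sampled before rasterization, so re-rendering at 2x
  calibration changes only the pixel grid. This is what the scale-invariance
  test of the fineness index exercises.

The default marbling spec (3 particles per cm^2, log-normal areas with
median 0.15 cm^2) gives marbling percentages near 40%, typical of highly
marbled Wagyu rib sections; particle sizes are kept large enough that
crack-length perimeter estimates are resolution-stable (the fineness index
moves by under 5% between renders at 20 and 40 px/cm; at coarser
calibrations, sub-ten-pixel particles bias the perimeter estimate). Phantoms are geometric stand-ins: they
reproduce the *measurement structure* of the problem (region areas, particle
area/perimeter statistics, fat depots), not photographic texture, camera
optics, or the anatomical construction of the grading field. Passing tests
therefore validate the measurement and modelling chain, not the behaviour of
any specific camera system on real tissue.

## Image-analysis traits

For each muscle with mask area $A$ (cm^2) and marbling particles with areas
$a_i$ and perimeters $p_i$:

* **area** $A$ = pixel count / (pixels per cm)^2;
* **marbling percentage** $= 100 \sum a_i / A$;
* **new fineness index** $= \sum p_i / \sqrt{A}$ — total marbling
  circumference normalized by muscle size; higher means finer marbling;
* **coarseness index** $= 100 \sum_{a_i \ge c} a_i / A$, the area share of
  large particles (threshold $c$ = 0.3 cm^2 by default, exposed as
  `coarseThreshold`). The literature describes this index only qualitatively,
  so the area-above-threshold definition is adopted here and recorded in
  output metadata;
* **thickness** (reported for *M. trapezius dorsi*, *M. latissimus dorsi*
  and the target field) = the chord of the mask along the *second* inertia
  principal axis through the centroid, in mm.

The target field is an explicit polygon (the anatomical construction of the
bounding lines used in grading practice is not published, so the phantom
emits the polygon rather than deriving it); field traits are the field area
and thickness plus IF/SF areas and their percentages of field area.

Decisions a reader should know about, all configurable:

* **Segmentation** is a global threshold (Otsu's method on within-mask
  pixels by default; a fixed threshold is appropriate on noiseless
  phantoms), 8-connected components, minimum particle size 4 px. The
  commercial software's algorithm is undisclosed; the settings used are
  attached to the output. A mask with no intensity contrast yields zero
  particles rather than an arbitrary Otsu cut.
* **Perimeters** are boundary crack lengths with the isotropic $\pi/4$
  correction (raw crack counts available via `correctedPerimeter = FALSE`).
  The fineness index inherits this choice; it cancels in scale-invariance
  comparisons because both resolutions use the same estimator.
* **Principal-axis tie-break**: for a mask with equal second moments (a
  disk), the horizontal image axis is taken as the first axis, making
  thickness deterministic.
* **Thickness across concavities** sums all in-mask chord segments along the
  axis line (sampled at 0.25 px), which is robust when the line exits and
  re-enters the mask.
* **Units**: areas cm^2, thicknesses mm, percentages 0--100.

## Fixed-effects price models

Unit price (yen/kg) is modelled with categorical fixed effects (grading
date, month of age, sex, farm, meat-quality grade MQ) and one continuous IAT
per fit, optionally with an MQ x IAT interaction. Factors enter as full
indicator blocks with no reference level; the rank-deficient least-squares
system is solved by the minimum-norm (SVD pseudo-inverse) solution, so
estimable quantities are independent of level ordering. Each term's F
statistic is marginal: the full model is compared with an explicit refit
after deleting that term's columns (Type-III-style); aliased terms are
flagged `NA` rather than silently dropped. Per-MQ analyses exclude farm and
MQ (small grades make farm-inclusive fits unstable) and report the
standardized partial regression coefficient $\hat b \,s_x / s_y$ *and* the
coefficient's t statistic: published tables of this analysis carry
magnitudes well beyond the usual $[-1, 1]$ standardized range, so both
quantities are emitted and neither is asserted to be "the" published one.

## Pedigree machinery

`tracePedigree()` keeps phenotyped animals plus ancestors to a configurable
depth (an animal's generation is its shortest ancestral path to a phenotyped
descendant; parents count as generation 1 — a convention, documented rather
than asserted), topologically orders them, and computes inbreeding by the
Meuwissen--Luo recursion. The numerator relationship matrix inverse is built
by Henderson's rules *with* inbreeding: Wagyu pedigrees are inbred, and the
rules reduce gracefully to the classical case at $F = 0$. Unknown parents
are unrelated founders (no genetic groups). The dense tabular A serves as an
in-package oracle: tests require
$\lVert A^{-1}A - I \rVert_\infty < 10^{-8}$ on random pedigrees.

## Animal models by Gibbs sampling

The genetic model is $y = X\beta + Za + e$ with $a \sim N(0, A\sigma_a^2)$
(or $N(0, G_0 \otimes A)$ for two traits) and fixed effects farm, season,
sex and month of age. The sampler (Rcpp) cycles through:

1. every scalar location effect from its normal full conditional, in
   pedigree order, over the joint precision
   $R_0^{-1} \otimes W'W + G_0^{-1} \otimes A^{-1}$ (animal block);
2. $\sigma_a^2$ from a scaled inverse chi-square with quadratic form
   $a'A^{-1}a$ (inverse-Wishart with $S_a = [a_s' A^{-1} a_t]$ for two
   traits);
3. $\sigma_e^2$ (or $R_0$) from the residual quadratic form.

All randomness flows through R's RNG, so a seed fixes the chain exactly.
Derived quantities — $h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)$, genetic,
residual and phenotypic correlations — are computed *per retained sample*
and then summarized; means of ratios, never ratios of means. Summaries
include an initial-positive-sequence effective sample size and a split-chain
mean difference; there is no adaptive stopping (fixed chains match field
practice).

Choices worth stating:

* **Priors.** Flat on fixed effects; inverse chi-square / inverse-Wishart
  with small degrees of freedom ($\nu = 4$) on the (co)variances, scale set
  by an ANOVA-style split of the phenotypic variance remaining after an
  ordinary linear-model sweep of the fixed effects (half genetic, half
  residual by default — `priorSplit`). With thousands of pedigree animals
  the data quadratic dominates these priors.
* **Full-dummy fixed effects.** The location system is singular (as in
  blupf90-family software); every single-site conditional is still proper,
  and variance components and estimable functions are unaffected. The
  confounded contrasts execute a harmless slow random walk.
* **Identifiability edge case.** With unrelated animals ($A = I$) and one
  record each, $\sigma_a^2$ and $\sigma_e^2$ are only *jointly* identified;
  the posterior reproduces their sum and centres $h^2$ near the prior split.
  Tests of that configuration check the sum constraint, not a recovery the
  data cannot support.
* **Near-boundary correlations.** The posterior-mean estimator of a genetic
  correlation shrinks toward zero near $|r_g| = 1$ at moderate sample
  sizes. At the package's desk scale (below) the equilibrium posterior mean
  for a true $r_g = 0.98$ is about 0.93--0.95 — verified against an
  independent dense-matrix Gibbs implementation and against restricted-
  likelihood profiles, and stable over 60,000-cycle chains; this is a
  property of the estimator at this scale, not of the sampler. Recovery
  checks of near-unity correlations should expect a few hundredths of
  attenuation.
* **Degenerate draws.** Numerically singular 2x2 genetic covariance draws
  are jittered on the diagonal and counted (`metadata$jitters`); divergent
  variance samples abort with the cycle number.

## The synthetic genetic data

`simulateGeneticData()` mirrors the shape of the study population at
desk scale, chosen so a full recovery experiment (simulation + 20,000-cycle
chain) runs in about a minute: 1,000 founders plus three generations of
1,000 offspring (~4,000 animals), ~1,500 phenotyped, fixed effects farm (40
levels — collapsed from the field scale of ~166 so small designs stay
estimable), season (4), sex (2), month of age (9), with level-effect SDs
0.30/0.20/0.20/0.10 on the unit phenotypic scale. Matings are
**sire-limited** (25 sires in service per generation): Japanese Black
breeding is dominated by artificial insemination from a small bull battery,
so real pedigrees consist of large paternal half-sib families, and this
structure is also what makes variance components well identified at these
sizes. Breeding values descend as parent average plus Mendelian deviation
with variance $\tfrac12 \sigma_a^2 (1 - (F_s + F_d)/2)$, consistent with the
relationship matrix used in fitting.

For the recovery experiments anchored at published posterior means, the
heritabilities of the grading traits involved in correlation pairs are not
published, so analogues from the same study are used: the marbling
percentage of *M. longissimus dorsi* (0.85) stands in for the marbling
grade, the SF area (0.55) for SF thickness, and the *M. longissimus dorsi*
area (0.67) for rib eye area — in each case the analogue has a published
genetic correlation of 0.92--1.00 with the trait it replaces. Residual
correlations are likewise unpublished and are set on mechanism grounds:
0.6 for price vs marbling grade (price is largely set by the observed
grade), 0.8 for SF area percentage vs SF thickness (two measurements of the
same depot), and -0.2 for IF percentage vs rib eye area (weak compositional
crowding).

## Pipeline

`runPipeline()` drives both arms (phantoms -> traits -> price tables;
genetic simulation -> animal model) from one YAML config, expands a single
seed into per-stage seeds by a fixed rule, checksums every input and output
into `manifest.json`, skips stages whose inputs are unchanged, and logs
stage timings. Identical configs reproduce byte-identical outputs.

## Limitations

* Phantoms do not model photographic texture, lighting, or muscle-boundary
  delineation; extraction starts from a label map.
* The coarseness index uses an adopted (area-above-threshold) definition;
  absolute values are comparable only within a fixed threshold choice.
* The price models are fixed-effects only; no mixed-model price analysis.
* Two-trait models require complete cases, matching carcass data where all
  traits are measured on every animal.
* Published real-data estimates can only be compared in simulation-recovery
  form; nothing here reproduces private carcass records.
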