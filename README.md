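# wagyuIAT

Image-analysis traits of beef carcass cross-sections and their genetic
parameters, for Japanese Black (Wagyu) cattle.

Carcasses are priced per kilogram at auction, and the price tracks features
of the cross-section between the 6th and 7th rib that go beyond the human
grading scores: the areas and thicknesses of the five exposed muscles, the
amount, coarseness and fineness of marbling within each muscle, and the
intermuscular (IF) and subcutaneous (SF) fat depots. This package implements
the complete analysis chain for such data, aimed at animal-breeding
researchers who want to study these traits without access to private
carcass records:

* **Phantoms** (`generatePhantom()`): synthetic cross-section images with
  label maps and *exact* pixel-level ground truth, so every downstream stage
  is testable.
* **Trait extraction** (`extractIAT()`): for each muscle of cross-section
  area `A` (cm²) with marbling particles of areas `a_i` and perimeters
  `p_i`,
  - marbling percentage `= 100 Σ a_i / A`,
  - new fineness index `= Σ p_i / √A` (higher = finer marbling),
  - coarseness index `= 100 Σ_{a_i ≥ c} a_i / A` (area share of particles
    above `c` cm²),
  - thickness = chord along the second inertia principal axis through the
    centroid (mm),
  plus the six target-field traits (field area and thickness, IF/SF areas
  and percentages). 28 traits per carcass in total.
* **Price models** (`anovaFTable()`, `standardizedCoefficients()`):
  fixed-effects models of unit price `UP = date + age + sex + farm + MQ +
  IAT (+ MQ×IAT) + e` with marginal (Type-III-style) F tests, and per-grade
  standardized partial regression coefficients `b·s_x/s_y` with their t
  statistics.
* **Pedigree machinery** (`tracePedigree()`, `aInverse()`): generation
  tracing, Meuwissen–Luo inbreeding, and the sparse inverse of the
  numerator relationship matrix `A` by Henderson's rules with inbreeding.
* **Animal models** (`gibbsSingleTrait()`, `gibbsTwoTrait()`): Bayesian
  `y = Xβ + Za + e`, `a ~ N(0, A σ²_a)` (2×2 `G₀ ⊗ A` for two traits),
  fitted by Gibbs sampling (Rcpp); posterior summaries of heritability
  `h² = σ²_a/(σ²_a + σ²_e)` and genetic/residual/phenotypic correlations,
  computed per retained sample.
* **Synthetic genetics** (`simulateGeneticData()`): sire-limited
  multi-generation pedigrees (AI-style large half-sib families) with
  breeding values transmitted as parent average plus Mendelian deviation,
  user-set true variance components, and realistic fixed-effect structure.
* **Pipeline** (`runPipeline()`): both arms from one YAML config, with
  seeds, checksums and a run manifest.

## Worked example

```r
library(wagyuIAT)

ph  <- generatePhantom(phantomConfig(seed = 7))
ph
#> CarcassPhantom: 420 x 520 px at 10 px/cm
#>   marbling pixels: 8053 | muscle pixels: 20993
#>   ground truth: 28 region-trait rows; seed 7

round(unlist(extractIAT(ph)[1, c("ld_area", "ld_marb_pct", "ld_fineness",
                                 "ld_coarse_pct", "td_thick_mm",
                                 "field_area", "if_pct", "sf_pct")]), 2)
#>       ld_area   ld_marb_pct   ld_fineness ld_coarse_pct   td_thick_mm
#>         62.69         42.00         21.84         38.40         41.00
#>    field_area        if_pct        sf_pct
#>        973.01          8.22          7.19
```

The *M. longissimus dorsi* ellipse covers 62.69 cm² and is 42.0% marbled;
on this phantom the extracted values equal the rasterized ground truth
exactly (`truthTraits(ph)`), which is what the round-trip tests assert.

A small heritability-recovery experiment (800 phenotyped animals in a
1,600-animal sire-limited pedigree, 6,000-cycle chain):

```r
r <- recoveryExperiment(h2 = 0.68, simSeed = 42, gibbsSeed = 43,
                        cfg = gibbsConfig(cycles = 6000, burnin = 2000,
                                          thin = 10),
                        founders = 400, generations = 3,
                        offspringPerGeneration = 400, nPhenotyped = 800)
posteriorSummary(r$chains)
#>   parameter      mean         sd       ess   split_diff
#> 1        va 0.6516840 0.08155685  89.56058 -0.018402351
#> 2        ve 0.2998903 0.04965113 112.51788  0.009475733
#> 3        h2 0.6831884 0.05798561  89.07392 -0.012332440
```

The simulated truth was `h² = 0.68`; the posterior mean is 0.683 with
posterior SD 0.058 — the additive and residual variances are recovered and
the chain diagnostics (effective sample size, split-chain mean difference)
are printed alongside.

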