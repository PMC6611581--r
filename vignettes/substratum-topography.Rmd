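---
title: "Reverse engineering colonization-relevant surface topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering colonization-relevant surface topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisurf)
```

## The problem

Benthic algae colonizing rocks in flowing water respond to the microscale
shape of the substratum: elevated features intercept drifting cells and
filaments, while depressions downstream of them act as low-shear refugia
where biomass accumulates. `perisurf` implements the quantitative pipeline
behind that observation: it characterizes profilometer height maps of
colonized and bare rock surfaces with areal texture parameters, screens
those parameters for association with colonization, synthesizes
pseudo-random substrata that hit targeted values of the parameters that
matter, and analyzes colonization outcomes on the fabricated designs.

The package works entirely on `heightmap` objects: rectangular grids of
heights in micrometres with a lateral step size (5 um steps in the original
scans) and a validity mask for instrument dropouts.

## Preprocessing

Scans are screened by a retention rule: any map whose missing-point
fraction exceeds 10% is rejected outright (`preprocess()` raises an error
rather than silently interpolating a poor scan). Retained maps have
dropouts filled by linear interpolation along rows (columns and the grid
mean as fallbacks) and are leveled by least-squares plane subtraction, so
all downstream parameters see a zero-mean surface. The instrument format
is proprietary in the field, so the package defines a plain-text grid
dialect (3-line header: dimensions, steps, units/sentinel) plus a CSV
variant with a sidecar metadata file.

Leveling by plane removal is a convention choice: the reference workflow this package emulates ran inside vendor
metrology software whose form-removal operator is not documented. Plane subtraction is the most common default for areal
analysis and is the assumption made here; no additional S-filter or
waviness separation is applied.

## The areal parameter set

Twenty-six ISO 25178-2 parameters are computed by `compute_all()`:

* **Height**: `S_a` (mean |z|), `S_q` (RMS), `S_sk`, `S_ku` (standardized
  third/fourth moments), `S_p`, `S_v`, `S_z = S_p + S_v`.
* **Functional**: `S_mr` — the areal material ratio at the mean section
  height, `100 * A(m) / A(N)`, with material counted at `z >= m` so a flat
  surface reads 100% — plus `S_mc` (inverse material ratio height at 10%)
  and `S_xp` (height difference between the 2.5% and 50% material ratios).
* **Spatial**: `S_al`, `S_tr`, `S_td` from the FFT autocorrelation with the
  ISO decay threshold s = 0.2. `S_td` is measured counterclockwise from
  the +x (flow) axis modulo 180 degrees; a surface varying only along x
  (ridges along y) reads 90.
* **Volumetric**: `V_m`, `V_v`, `V_mp`, `V_mc`, `V_vc`, `V_vv` as material
  ratio curve integrals at the ISO default ratios p = 10%, q = 80%.
* **Stratified**: `S_k`, `S_pk`, `S_vk`, `S_mr1`, `S_mr2` from the
  40%-width minimum-slope secant construction on the material ratio curve.
* **Feature**: `S_10z`, `S_5v` (and `S_5p`) from the watershed/Wolf
  pipeline below.

The reference analysis states formulas only for `S_mr` and `S_a`; all
other definitions and default arguments follow ISO 25178-2, the standard the
parameter set comes from. Every parameter is checked in the
test suite against an independently coded brute-force evaluation of the
definitions at 1e-9 relative tolerance.

One scale inconsistency in the reference statistics is left unresolved
on purpose: the screening table reports group `S_mr` statistics
of 0.001-0.004 "%", while the synthesis targets are 30-52%. No single
convention reconciles both. The package computes `S_mr` as defined above;
the screening-table values are treated as opaque group statistics in the
generator configuration and are never re-derived from surfaces.

## Hills, dales and Wolf pruning

`watershed_segment()` partitions a map into catchment basins — dales on
the height function, hills on its negation — by deterministic
lexicographic steepest descent: each cell drains to the neighbour with the
smallest `(height, row, col)` key, so plateaus and ties never introduce
ambiguity. `wolf_prune()` then merges insignificant features: a feature
whose Wolf height (distance from its extreme to the lowest saddle on its
boundary) falls below 10% of `S_z` is merged into the neighbour across
that saddle, smallest Wolf height first, to a fixed point. The 10% default
is the recommended threshold for the method. The map border is treated as
an escape route by default (`border_saddle`), so a featureless tilted
plane correctly ends with zero significant dales; border handling is
configurable because vendor implementations differ.

The phrase "retain data elements below the watershed value" in the method's
original description is ambiguous between keeping and removing sub-threshold
features; standard Wolf pruning removes them, and that reading (supported
by the significant/non-significant framing of the original analysis) is
the default here. Segmentation plus pruning is verified against a naive
full-recompute oracle on toy grids, and the retained count is
property-tested to be non-increasing in the threshold.

Early-colonization analysis uses plain height thresholds rather than
watershed features, mirroring the reference classification: points at or
above 3000 um are hills, at or below 0 um dales (`classify_sites()`), and
`hill_localization()` reports the percentage of observed colonization
sites on hills. The reported "ratio of hills that attract algae to those
that do not" is a different quantity from the 98%-of-sites statement; the
site fraction is the primary output and the per-feature attract ratio is
exposed as a secondary output when a pruned hill segmentation is supplied.

## Pearson-system surface synthesis

Rock height distributions in the source analysis had skewness about -0.3
and kurtosis about 3.0, and those values are retained for engineered
surfaces. The Pearson criterion

$$\kappa = \frac{\beta_1 (\beta_2 + 3)^2}
  {4 (4\beta_2 - 3\beta_1)(2\beta_2 - 3\beta_1 - 6)},
  \qquad \beta_1 = \gamma_1^2,\ \beta_2 = \text{kurtosis},$$

evaluates to -0.256 there, selecting Type I — a bounded, beta-like member
— realized in `sample_pearson()` as a four-parameter beta matched to all
four moments in closed form. Other members are covered for completeness
(normal, symmetric Type II beta, Type III gamma, Type VII scaled t;
Types IV/V/VI by numeric inversion of the Pearson density with a
log-spaced tail grid).

`synthesize_surface()` turns draws into a substratum model in four stages:

1. **Spatial structure.** The i.i.d. draws are low-pass filtered with a
   Gaussian kernel (FFT, periodic) and the marginal is restored exactly by
   rank re-mapping the filtered field onto the sorted draws. The sorted
   heights are therefore identical before and after filtering — all four
   moments survive by construction, which the tests assert exactly. The
   correlation length (default 2.5 mm on a 50 mm tile) sets hill/dale
   widths of roughly 5-10 mm; how mm-scale relief arises from the pseudo-random draws is not part
   of the reference description, so this standard
   non-Gaussian rough-surface construction is the package's own choice.
2. **Amplitude.** The field is scaled to the targeted `S_a` (exact, by
   homogeneity). The pit-depth constant `h` is then applied to the lower
   tail only (below the 1% quantile by default): the reference knob list
   scales "the pseudo-random numbers" to set `S_v`, but a fixed marginal
   cannot hold `S_v/S_a` ratios of 4-9 under pure scaling, so `h` here
   deepens pits while leaving `S_a` and `S_mr` nearly untouched.
3. **Material ratio.** A regular grid of flat-bottomed square depressions
   (pitch 2 mm, depth 0.25 x target `S_v`) is cut; its area fraction is
   solved by scan-plus-refinement, since the response can be non-monotone
   when the depression depth is comparable to the surface spread. Block
   sizes mix the two bracketing integer sizes deterministically so
   coverage is continuous in the fraction.
4. **Re-measurement and iteration.** Achieved `S_a`, `S_v`, `S_mr` are
   recomputed from the surface by the areal-parameter functions — never
   cached from the generator — and stages 2-3 iterate with multiplicative
   corrections (10 fixed-point rounds), falling back to a Nelder-Mead
   refinement of (base amplitude, tail depth, depression fraction) when
   the Sa/Smr pair deadlocks. Convergence is declared only when every
   parameter is within the 5% relative tolerance; otherwise the result
   carries `converged = FALSE` and a warning.

An `S_mr` target above what the undepressed surface already shows is
reported as an explicit infeasibility error, since depressions can only
remove above-mean material. Re-leveling happens after depressions: whether
the original targeting preceded or followed mean re-referencing is
unstated, and the post-depression convention keeps `S_mr` evaluated
against the final mean plane.

Targets are taken from the two fabricated treatment levels (Level 1:
`S_a` 0.7 mm, `S_v` 6.6 mm, `S_mr` 30%; Level 2: 2.1 mm, 8.4 mm, 52%).
These are treated as abstract parameter targets: the reference `S_v`
values exceed the stated tile thickness and relate to flow depth through
geometry that cannot be reconstructed, and the 30%+ fabrication errors of
the fabricated tiles are physical-printing artifacts outside this package's
scope. `validate_surface()` reproduces the targeted/actual/percent-error
bookkeeping of that validation table.

## Colonization statistics

`screen_parameters()` performs the per-parameter two-group ANOVA of the
screening table (for two groups, F is exactly the squared pooled t, which
the tests verify against `stats::aov`). No multiple-testing correction is
applied by default, matching the per-parameter alpha = 0.05 reporting of
the original screen; `p_adjust` enables Bonferroni/FDR variants.
`compare_biomass()` runs the one-way treatment ANOVA with the
supporting checks — Tukey HSD across flow lanes within each level, and an
Anderson-Darling normality test on the residuals, reported but never used
to gate the ANOVA.

## The synthetic-data generators

All inputs the pipeline needs can be generated with seeded, pure
functions, configured by `study_config()` with the reference study statistics:
dale counts 21/21; group moments `S_v` 203.94 +/- 49.14 vs 163.63 +/-
55.86 um, `S_a` 46.63 +/- 12.09 vs 38.24 +/- 10.94 um, `S_mr` 0.001 +/-
0.001 vs 0.004 +/- 0.002; biomass 1.86 +/- 0.40 vs 0.50 +/- 0.16 mg/cm^2
in 3 trials x 4 lanes x 6 alternating tiles; hill-placement bias 0.99 for
early sites. Only means, SDs and residual normality are reported for the
reference data, so draws use zero-truncated normals (biomass, depths and most
parameters cannot be negative) whose parent parameters are solved so the
truncated distribution matches the configured moments; the signed
skewness column uses a plain normal. One configured pair is infeasible
under that family: `S_mr` 0.001 +/- 0.001 implies CV = 1, which a
zero-truncated normal approaches but cannot reach, so the generator caps
the CV at 0.95 with the mean still matched exactly — the difference is
irrelevant to the screen, whose noncentrality at those group means is
about 6 (power ~ 1). The 23 parameters without reported group contrasts
are generated with no group difference, making the screen's specificity
testable; their shared means are plausible round numbers, chosen once.

Rock-like test surfaces (`gen_rock_surface()`) are tilted noise with
embedded cosine-bell pits at registered locations — the registry is the
ground truth for segmentation-recovery tests. The pit geometry is
arbitrary (only depth statistics are reported); depths default to the
colonized-dale moments.

What passing tests on these generators do show: the pipeline recovers
known feature counts and depths, holds its type-I error, reproduces the
reference F statistic from the configured moments, and reproduces the
hill-localization rate under the stated bias. What they cannot show:
anything about real rock mineralogy, real periphyton behaviour, true
instrument noise, or the fabrication error magnitudes of 3D-printed tiles —
those enter only as configuration constants and worked-example
arithmetic.

## Numerical choices and problem sizes

* Material ratio curves sample 1024 section heights; inverses interpolate
  linearly on the empirical quantile function; curve integrals use 2001
  trapezoid nodes. These resolutions keep curve-derived parameters within
  1e-9 of brute-force evaluation on test grids.
* The watershed uses 8-connectivity by default (4 available); the tie
  break is lexicographic; pruning renumbers features by magnitude.
* Synthesis defaults to 128 x 128 grids at 0.4 mm step (a 51 mm tile),
  where the calibration loop converges in a few seconds; moment-fidelity
  checks use 512 x 512, where sample skewness has a standard error of
  about 0.005. Simulation-based checks use 100-2000 replicates, sized so
  Monte-Carlo error sits well inside each stated tolerance.
* Every stochastic function takes an explicit seed, and replicate k of a
  synthesis series uses `seed + k`.

## Limitations

Profile (2-D) parameters, filtration cascades, proprietary instrument
formats, printer slicing and resin behaviour, hydrodynamic modeling of
refugia, and image-based biomass estimation are all out of scope. The
periodic-FFT autocorrelation slightly biases `S_al` on small grids;
spatial-parameter tests therefore use analytic cases (white noise,
sinusoids) rather than the brute-force route used for curve parameters.
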