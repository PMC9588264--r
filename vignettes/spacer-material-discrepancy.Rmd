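---
title: "Material-override discrepancy analysis for iodinated rectal spacers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Material-override discrepancy analysis for iodinated rectal spacers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerdose)
```

## The question

An iodinated hydrogel spacer between prostate and rectum is deliberately
CT-bright (≈ 120 HU) so that it can be localised without MRI. A proton
treatment planning system that derives stopping power from CT intensity
will therefore assign the spacer an SPR of roughly 1.11 on a typical
calibration, although the material is physically almost water
(SPR ≈ 1.02–1.03 from its composition). Every lateral beam that crosses the
spacer is then mis-ranged by the product of the SPR error and the spacer
chord — a few millimetres of water-equivalent depth. `spacerdose` builds a
fully synthetic, end-to-end reproduction of this analysis: which structures
are affected, by how much, and whether the error is visible under standard
gamma-index criteria.

Three spacer scenarios are compared on otherwise identical anatomy:
CT-intensity-based (NM), water override (WM), and true-material override
(TM, the ground truth). Plans are optimized on TM; the *fixed* plan is then
recalculated on the other SPR grids, so every difference is attributable to
the material assignment alone.

## Material physics

`compute_spr()` evaluates the ratio of linear stopping powers
material/water from the Bethe stopping number
$L = \ln(2 m_e c^2 \beta^2 \gamma^2 / I) - \beta^2$, multiplied by the
relative electron density. The mean excitation energy $I$ comes from
Bragg additivity, $\ln I = \sum_i \lambda_i \ln I_i$ over electron
fractions $\lambda_i$, with elemental $I$-values from a bundled
ICRU-49-style table. One deliberate choice: the water reference uses the
*same* additivity rule (giving $I_w \approx 69$ eV) rather than the common
fixed 75 eV, so that the water-on-water ratio is exactly 1 — the
self-consistency matters more here than the absolute $I_w$ convention,
and the spacer value (1.023 at 198.3 MeV) stays inside the product's
nominal 1.03 ± 0.01 either way.

The effective atomic number uses the power-law convention
$(\sum_i \lambda_i Z_i^m)^{1/m}$ with $m = 3.5$. That reproduces the
published 14.47 for the spacer only to about 1.5%; the exponent convention
behind the published figure is not stated, so the package documents its own
convention and makes $m$ a parameter rather than tuning it.

Component molecular formulas are needed to expand the printed recipe:
trilysine is expanded as 3 × lysine − 2 × H₂O (C₁₈H₃₈N₆O₄) and PEG as its
repeat unit C₂H₄O. The default HU→SPR curve — knots (−1000, 0.001),
(−100, 0.93), (0, 1.00), (100, 1.10), (1600, 1.85) — is a representative
soft-tissue/bone calibration, not any institution's curve; the analysis
only depends on the qualitative ordering SPR(120 HU) > SPR(TM) > 1.00,
and any curve can be supplied as a two-column table.

## The synthetic cohort

`generate_phantom()` builds a geometric male pelvis at the prostate level:
elliptical body with fat rim, 42-cc prostate plus seminal vesicles (their
union is the CTV), rectum with gas lumen behind the prostate, bladder,
femoral heads and penile bulb, and the spacer as a crescent shell between
the posterior prostate surface and the anterior rectal wall (10 mm thick,
with a 6-mm lateral bulge giving it a realistic ~4 cm lateral chord,
~10–18 cm³ depending on voxel size and jitter). The neurovascular bundles
are placed where they anatomically run — hugging the posterolateral
capsule at the spacer's lateral tips — which is exactly the corridor a
lateral beam traverses after crossing the spacer; that placement, not any
dose-model detail, is what exposes them to the range error.

Tissue HU means (prostate/muscle 40, bladder content 10, fat −100, rectal
gas −700, cortical bone 700, body background 20) are representative values
with 10 HU Gaussian noise, all configurable. The spacer is generated at
its native 31 HU; `iodinate_spacer()` re-renders it with
Normal(120, 15) draws followed by 3D Gaussian smoothing (σ = 1 voxel)
restricted to the spacer with a one-voxel blend rim — the smoothing kernel
and the 15 HU noise width are package choices (the product's HU texture is
only characterised by its mean), and the in-mask mean is preserved to
within 1 HU for clinically sized spacers.

`generate_cohort()` emulates a 20-patient cohort by jittering sizes
(±10%) and positions (±3 mm) with per-case seeds derived as
`master_seed * 1000 + case`, so the whole analysis is reproducible from
one integer.

What the phantom does *not* emulate: CT artifacts and beam hardening,
heterogeneous marrow/bone texture, inter-patient anatomy beyond the
jitter, and the dose texture of a Monte Carlo calculation. Consequences
for interpretation are discussed below.

## The dose engine

The engine is a deterministic pencil-beam stand-in, not a clinical dose
algorithm. Pristine peaks follow the Bragg–Kleeman rule $R = \alpha E^p$
(α = 0.0022 cm·MeV⁻ᵖ, p = 1.77) with the ideal depth dose
$\propto (R-z)^{1/p-1}$ bin-averaged analytically and convolved with a
range-straggling Gaussian ($\sigma = 0.012\,R^{0.935}$ cm). Because the
smeared peak's maximum sits ~1.5 mm proximal of the nominal range, layer
ranges are offset so peaks land where intended; spread-out Bragg peaks
tile the target interval at 80% of the distal peak's 80%-level width and
solve a non-negative least-squares problem for flatness. The resulting
plateaus are flat to ±1.5% and fall below 0.3% of the plateau within 8 mm
of the distal edge.

Plans use the study geometry: two opposed lateral beams, rays on a 4-mm
lattice over the CTV's beam's-eye view plus a 5-mm margin, per-ray SOBPs
spanning the CTV water-equivalent interval ±5 mm, beams weighted 50/50,
and one global scale set so CTV D95 equals the prescription. The static
5-mm margins stand in for robustness optimization; OAR constraints are
checked post hoc (`constraint_report()`) rather than enforced, because the
comparison only needs a fixed TM-optimized plan. Lateral spreading is a
depth-dependent Gaussian (σ = 3 mm + 0.02·depth). Dose is linear in
fluence, non-negative, and bit-reproducible.

Numerical choices: water-equivalent depth along beam columns uses midpoint
cumulative sums at voxel resolution (the general `wepl_trace()` does
fixed-step trilinear sampling and agrees with a 10×-finer quadrature to
0.5%); depth-dose lookups interpolate tables with 0.5-mm steps; rays snap
to voxel centres.

## Gamma index and dosimetric indices

`gamma_map()` implements the 3D gamma index by exhaustive search over a
subsampled sphere (cap 3 × δr, step 0.1 × δr by default) with trilinear
interpolation of the evaluated dose, normalised globally to the reference
maximum; a local-normalisation flag exists. The C++ search is ordered by
distance with early termination and is verified voxel-for-voxel against an
independent exhaustive R implementation on small grids. Passing ratios use
the strict rule γ < 1 and exclude voxels below 10% of the maximum
*reference* dose (exclusion by evaluated dose would be the other
convention; reference was chosen and documented). A subtlety worth noting:
PR monotonicity across criteria (PR11 ≤ PR22 ≤ PR33) is only guaranteed
numerically when all criteria share the same absolute interpolation step,
so the cohort pipeline fixes a common 0.3-mm step across its three
criteria.

$D_x$ is computed from exact order statistics (hottest-x% convention);
histogram bins (10 cGy) are used only for plotting and the binned EUD
route. EUD uses the printed exponents, a = −10 for targets and a = 8 for
OARs, with zero-dose bins floored at 0.1 cGy for negative exponents
(the power mean is singular at zero; target structures near prescription
dose are unaffected). The power-mean inequality (EUD non-decreasing in a)
is tested. The institutional constraint table ships as editable YAML.

## Statistics

Scenario differences are paired within case, so the permutation test flips
the sign of each case's difference independently (the exchangeable null for
paired data), with the mean difference as statistic and a two-sided
add-one p-value; when $2^n \le 4096$ the flip distribution is enumerated
and the p-value is exact. The statistic and sidedness are package choices —
the study design only specifies "nonparametric permutation test
(n = 1000)". Boxplot summaries follow the 1.5 · IQR whisker convention
with whiskers on actual data points. Raw p-values are reported;
Benjamini–Hochberg annotation is available but off by default, matching
the study's reporting.

## What passing tests do and do not show

At desk scale (60 × 60 × 40 voxels at 4 mm for the cohort, 120 × 120 × 80
at 2 mm for single cases) the synthetic cohort reproduces the *structure*
of the published result: scenario disagreement is invisible at 2%/2 mm and
3%/3 mm, appears at 1%/1 mm, is always at least as bad for the
CT-intensity scenario as for the water override, and concentrates its
dosimetric effect on the neurovascular bundles, which show the largest
EUD shifts among organs at risk. The *magnitudes* (patient-cohort NVB
differences of hundreds of cGy, PR11 down to 0.7) are not reproduced and
are not claimed: they depend on clinical Monte Carlo dose texture, real
heterogeneous anatomy and institutional calibration curves. Smooth
analytic dose fields are exactly the situation in which the 3D gamma
index is most forgiving — displacement errors smaller than the DTA
criterion are absorbed unless they exceed it along the local dose
gradient — so desk-scale passing ratios sit closer to 1 than clinical
ones. The qualitative orderings, not the magnitudes, are the tested
claims.

## Known limitations

No nuclear interactions, halo, or heterogeneity-induced lateral scattering
in the dose engine; beams fixed to ±x; no robust optimization; no DICOM-RT
I/O (NIfTI + JSON sidecars instead); the phantom is geometric, not
anatomical. The acceptance script's problem sizes (1-mm phantom for spacer
HU statistics, one 2-mm case for coverage) were chosen as the smallest
grids at which the respective quantities are well-posed — a ≥10⁴-voxel
spacer at a clinically plausible volume needs 1-mm voxels, and the
coverage objective is stated at 2-mm slices.
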