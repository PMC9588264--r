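# spacerdose

Proton dose consequences of iodinated rectal hydrogel spacers.

Hydrogel spacers pushed between the prostate and rectum protect the rectal
wall during prostate radiotherapy. The iodinated variant of the product is
visible on CT (mean intensity ≈ 120 HU instead of the ≈ 31 HU of the native
gel), but that visibility has a price in proton therapy: a treatment
planning system that converts CT intensity to proton stopping power will
treat the bright spacer as a high-density material and mis-range every beam
that crosses it. `spacerdose` implements the complete analysis of that
material-assignment error for users in radiotherapy physics: synthetic
pelvic CT phantoms with contoured structures, stopping-power physics from
elemental composition, a deterministic pencil-beam dose engine for
two-lateral-beam prostate plans, 3D gamma-index comparison, DVH/EUD
dosimetric indices, and paired permutation statistics over a simulated
patient cohort.

## The model

Three material scenarios are compared for the spacer, everything else held
fixed:

* **NM** (no override) — spacer stopping power follows the HU→SPR
  calibration curve; the iodinated gel (HU 120) maps to SPR ≈ 1.11.
* **WM** (water override) — spacer SPR forced to 1.00.
* **TM** (true material, ground truth) — SPR computed from the
  manufacturer's composition (88% water, 0.7% trilysine, 10.1% PEG, 1.2%
  iodine by weight; ρ = 1.03 g/cm³) with the Bethe stopping number,

  SPR = ρₑ,rel · [ln(2mₑc²β²γ²/Iₘ) − β²] / [ln(2mₑc²β²γ²/I_w) − β²],

  where Iₘ is the Bragg-additivity log-mean excitation energy over electron
  fractions. At 198.3 MeV this gives SPR ≈ 1.02, in agreement with the
  nominal 1.03 of the product.

Plans (70 Gy in 28 fractions, two lateral beams at 90°/270°) are optimized
on the TM grid, then the fixed plan is recalculated on the NM and WM grids.
Disagreement with the TM ground truth is quantified by 3D gamma passing
ratios at 1%/1 mm, 2%/2 mm and 3%/3 mm (γ(r) = min over nearby positions e
of √(|e−r|²/δr² + ΔD²/δD²), excluding voxels below 10% of the maximum
dose), by DVH indices (D02…D98, mean dose) and by the equivalent uniform
dose EUDₐ = (Σ nᵢdᵢᵃ)^{1/a} with a = −10 for targets and a = 8 for organs at
risk. Per-structure scenario differences are tested with a paired sign-flip
permutation test (n = 1000, exact enumeration for small cohorts).

## Worked example

```r
library(spacerdose)

sp <- spacer_material()
sp
#> <material_spec> iodinated_hydrogel, rho = 1.03 g/cm3
#>       H       O       C       N       I
#> 0.10839 0.81932 0.05883 0.00146 0.01200
compute_spr(sp, 198.3)   # 1.0234  — theoretical SPR vs water
effective_z(sp)          # 14.26   — power-law effective atomic number
hu_to_spr(120)           # 1.11    — what an HU-based TPS would assign

rep <- run_cohort_analysis(
  n_cases = 4,
  base_params = phantom_params(shape = c(60L, 60L, 40L),
                               spacing = c(4, 4, 4)),
  master_seed = 1
)
rep
#> <cohort_report> 4 case(s), pairs TM-NM, TM-WM
#>   pair  criteria mean_pr
#> 1 TM-NM 1%/1mm     0.998
#> 2 TM-NM 2%/2mm     1.000
#> 3 TM-NM 3%/3mm     1
#> 4 TM-WM 1%/1mm     1
#> 5 TM-WM 2%/2mm     1
#> 6 TM-WM 3%/3mm     1
```

The mean gamma passing ratio of the CT-intensity-based scenario (TM–NM) is
lowest at the strictest criteria and always at or below the water-override
pair (TM–WM): treating the iodinated spacer by its CT number is worse than
pretending it is water, and the discrepancy only shows up under tight
dose/distance tolerances. `tidy(rep)` returns the permutation-test table —
on synthetic cohorts the neurovascular bundles, which sit behind the spacer
along the lateral beam path, carry the largest EUD shift (tens of cGy at
desk scale); `glance(rep)` gives a one-row cohort summary and
`autoplot(rep)` the per-structure PR boxplots.

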