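# ctdosim

Organ dosimetry and lung-cancer risk estimation for low-pitch helical 4DCT
versus conventional axial 3DCT thoracic scans.

Respiration-correlated (4D) CT oversamples the thorax with a very low-pitch
helical scan (pitch ≈ 0.06) so every couch position is imaged across a full
breathing cycle. At fixed per-rotation mAs the photon fluence per unit scan
length scales as **1/pitch**, so a 4DCT scan deposits roughly an order of
magnitude more dose in organs at risk than a single axial 3DCT scan — a
real concern for radiotherapy planning, where these scans are repeated and
patients may be small or young. `ctdosim` is a desk-scale, fully tested
implementation of the estimation chain a medical physicist would use to
quantify that:

1. **Voxel phantoms** — from Hounsfield-unit volumes via a piecewise HU →
   (density, material) calibration, or from a parametric synthetic thorax
   generator (body ellipse, lungs, heart, esophagus, trachea, spinal cord,
   skin) spanning effective diameters 184.5–465.1 mm;
2. **CT source trajectories** — axial and helical scans discretized into 12
   coplanar gantry fields per rotation at 30° intervals, with helical
   isocenter increments of `pitch × W / 12`;
3. **Monte Carlo kV photon transport** (compiled kernel) — Woodcock delta
   tracking, Klein–Nishina Compton sampling, kerma scoring, per-history
   RNG substreams, history-batch uncertainties;
4. **CTDI calibration** — a 16 cm water CTDI phantom with a central chamber
   volume converts per-history Monte Carlo output to absolute cGy through
   `factor = measured / (simulated × mAs)`;
5. **Size–dose regression** — ordinary least squares of mean organ dose on
   patient effective diameter (`2·sqrt(A/π)` of the body contour),
   `dose = intercept + slope × diameter`;
6. **Risk** — the BEIR VII excess relative risk of lung cancer,

   `ERR(e, a, D) = β_s · D · exp(γ e*) · (a/60)^η`,

   with sex-specific `β` (male 0.32, female 1.40 per Sv, with 95% CIs),
   `γ = −0.30`, `η = −1.4`, and `e* = (e−30)/10` for exposure age `e < 30`
   (0 otherwise).

## Worked example

One 300 mm-effective-diameter synthetic thorax, scanned with the study
protocols (120 kV, 100 mAs per rotation, 16 × 1.5 mm collimation; helical
pitch 0.059 for 4DCT, contiguous axial for 3DCT), calibrated against the
CTDI chamber simulation, 2×10⁵ histories per scan:

```r
library(ctdosim)

th <- make_thorax_phantom(thorax_spec(diameter = 300))
p4 <- scan_protocol(120, 100, c(16, 1.5), "helical", pitch = 0.059,
                    scan_range = th$scan_range)
p3 <- scan_protocol(120, 100, c(16, 1.5), "axial", scan_range = th$scan_range)

ct  <- make_ctdi_phantom()
cal <- scan_protocol(120, 100, c(16, 1.5), "axial", scan_range = c(-12, 12))
dgc <- run_scan(ct$phantom, axial_fields(cal), n_histories = 2e5, seed = 2)
rec <- calibrate(ctdi_reference_measurement(),
                 region_mean(energy_to_dose(dgc, ct$phantom), ct$chamber)$mean,
                 cal)

dose_for <- function(pr, fields, seed) {
  dg <- run_scan(th$phantom, fields, n_histories = 2e5, seed = seed)
  to_absolute(energy_to_dose(dg, th$phantom), rec, pr, override = TRUE)
}
a4 <- dose_for(p4, helical_fields(p4), 3)
a3 <- dose_for(p3, axial_fields(p3), 4)
rbind(organ_mean_dose(a4, th$masks$lungs, "P001", "4DCT"),
      organ_mean_dose(a3, th$masks$lungs, "P001", "3DCT"))
#>   patient_id organ protocol dose_cgy sigma_cgy
#> 1       P001 lungs     4DCT    42.16    0.7621
#> 2       P001 lungs     3DCT     2.42    0.0376

err("female", e = 25, a = 60, D = 42.16 * 0.01)  # 1 cGy = 0.01 Sv
#>     err   lo   hi    sex  e  a     D
#> 1 0.686 0.46 1.03 female 25 60 0.422
```

The lung-dose ratio, 42.16 / 2.42 ≈ 17.4 ± 0.4, is the 1/pitch = 16.9
oversampling factor within Monte Carlo error. The ERR says: for a woman
exposed at age 25 to this 4DCT lung dose, the modelled lung-cancer rate at
age 60 is elevated by 69% (95% CI 46–103%) relative to baseline — the
absolute scale here comes from a packaged *synthetic* chamber value, so
treat cGy magnitudes as illustrative; ratios and trends do not depend on it.

## The analysis workflow

Numbered scripts under `analysis/` (run from the repository root, outputs
in `results/`):

| script | what it does |
|---|---|
| `01_cohort_and_dose_tables.R` | 102-patient synthetic cohort (51/51 sex split, ages 6–93, diameters spanning the study range) and fast organ-dose tables drawn from the published size–dose coefficients |
| `02_monte_carlo_doses.R` | CTDI chamber calibration, then engine-computed absolute organ doses on a 200–400 mm phantom ladder for both protocols |
| `03_size_regression.R` | per-organ/protocol OLS fits of dose vs effective diameter on both dose sources, plus the size–dose figure |
| `04_risk_estimates.R` | per-patient ERR with CIs for both protocols and the 4DCT:3DCT risk-ratio summary |

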