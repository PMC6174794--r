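---
title: "Methods: Monte Carlo organ dosimetry for low-pitch helical 4DCT versus axial 3DCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo organ dosimetry for 4DCT vs 3DCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Respiration-correlated (4D) CT acquires a heavily oversampled helical scan
at very low pitch (here 0.059) so that every couch position is imaged across
a full breathing cycle. At fixed per-rotation mAs, the photon fluence per
unit scan length scales as 1/pitch, so a 4DCT scan deposits roughly an order
of magnitude more dose in thoracic organs at risk than a single axial 3DCT
scan. `ctdosim` implements the full desk-scale estimation chain:

1. voxel phantoms with per-organ masks (from HU volumes, or synthetic),
2. discretized CT source trajectories (axial and helical),
3. Monte Carlo kV photon transport with kerma scoring,
4. absolute-dose calibration against a CTDI-phantom chamber value,
5. linear regression of organ dose on patient effective diameter, and
6. the BEIR VII excess relative risk (ERR) model for lung cancer.

## Transport model and its assumptions

Photons are tracked through the voxel grid by Woodcock (delta) tracking
against the phantom-wide majorant attenuation coefficient. At a real
interaction the channel is chosen from the material's partial cross
sections:

* **photoelectric** — the full photon energy is deposited in the voxel and
  the history ends;
* **incoherent (Compton)** — the scattered-photon energy is drawn from the
  Klein–Nishina distribution with Kahn's rejection method; the transferred
  energy `E − E'` is deposited locally and the photon continues in the
  sampled direction;
* **coherent (Rayleigh)** — the direction is resampled from the
  form-factor-free Thomson law `p(cos θ) ∝ 1 + cos²θ`; no energy is
  deposited. (Omitting atomic form factors over-randomizes what is really
  forward-peaked scatter; at these energies coherent events are a few
  percent of interactions and the effect on organ-mean dose is at the 1–2%
  level. The channel can be disabled by zeroing its column in the
  cross-section object.)

Photons at or below the 10 keV cutoff (PCUT) deposit their remaining energy
locally; photons leaving the grid are tallied as escaped energy, so emitted
= deposited + escaped holds to rounding in every batch and is asserted by
the tests.

**Kerma approximation.** Energy transferred to electrons is deposited at
the interaction site; electrons are not transported. Below 120 keV the CSDA
range of secondary electrons in soft tissue is well under 0.2 mm — far
below the 1–5 mm voxels used here — so electron equilibrium is local and
the approximation is excellent. Electron-transport cutoffs are therefore
configuration metadata, not simulated physics.

**Tracking cross-check.** Besides Woodcock tracking, the kernel implements
plain voxel-by-voxel ray stepping (optical-depth accumulation across voxel
boundaries). The two schemes share the physics sampling but are independent
tracking algorithms; the test suite requires their doses to agree within
combined statistical error on a water/bone slab.

**RNG.** Every history owns a splitmix64 substream derived from
`(seed, history index)`, so results are bit-reproducible for a given seed
and independent of batching.

## Cross sections

No cross-section library is available in the target environment, so the
package builds its own tabulation (10–120 keV, 1 keV grid, log–log
interpolation between anchors):

* **totals** are anchored to the standard published mass attenuation
  coefficients for water, dry air and cortical bone (e.g. water at 60 keV =
  0.2059 cm²/g);
* **incoherent** is the closed-form Klein–Nishina total cross section per
  electron × electron density × a smooth binding correction (0.78 at
  10 keV → 1 at 150 keV, typical of low-Z media);
* **coherent** is an anchored power law (≈ E^−1.9);
* **photoelectric** is the remainder, so the partials sum to the anchored
  total exactly at the anchors.

Soft tissue and lung reuse the water total curve — correct to within about
1% at CT energies — with their own electron densities; lung differs from
soft tissue by mass density (0.26 g/cm³), not composition. The spectrum is
a packaged 120 kVp tungsten-anode table: Kramers continuum hardened by
7 mm Al-equivalent filtration plus K-fluorescence lines, 1 keV bins, mean
energy 59.2 keV.

## Trajectories, normalization and calibration

Both modes are 12 coplanar fields per rotation at 30° intervals. Axial mode
keeps one isocenter z per rotation and steps a full beam width `W` between
rotations; helical mode advances `pitch · W / 12` per field. Per-field
fluence weight is mAs/12, so fluence per unit length is `mAs/W` (axial) and
`mAs/(pitch · W)` (helical): the 1/pitch oversampling factor is exact by
construction.

**Over-ranging is off by default.** A real helical scanner extends the
spiral by about half a beam width past each end of the prescribed range so
edge slices are fully sampled; `helical_fields(..., over_range = TRUE)`
emulates that. It is not the default because it adds end fluence to the
helical arm only, pushing the 4DCT:3DCT dose ratio *above* the 1/pitch
bound that the mode comparison is meant to isolate; with the default, both
modes deliver fluence over exactly the prescribed range and the comparison
is bounded by 1/pitch, which is how the oversampling argument is framed.
(Comparisons between two helical scans are unaffected either way — the
extra fluence cancels.)

`run_scan()` returns energy deposits per history together with the
trajectory's total mAs-equivalent weight. `energy_to_dose(scale = "scan")`
multiplies by `total_weight / mAs`, which is what makes a pitch-0.1 scan
carry ten times the dose of a pitch-1.0 scan at equal histories. Absolute
dose comes from the CTDI chain: simulate the 16 cm water CTDI phantom with
a central chamber volume, form `factor = measured / (simulated × mAs)`, and
multiply (`to_absolute()`). No chamber exists in this artifact: the
packaged "measured" value (1.40 cGy per 100 mAs axial rotation) is a
synthetic fixture of plausible magnitude, so absolute doses have arbitrary
but internally consistent scale; ratios, trends and uncertainties do not
depend on it.

## Risk model

The excess relative risk of lung cancer is

ERR(e, a, D) = β_s · D · exp(γ·e\*) · (a/60)^η,

with equivalent lung dose D in Sv (1 cGy absorbed photon dose = 0.01 Sv,
radiation weighting factor 1), exposure age e, attained age a,
e\* = (e−30)/10 for e < 30 and 0 otherwise, β_male = 0.32 (0.15, 0.70),
β_female = 1.40 (0.94, 2.1), γ = −0.30, η = −1.4. Confidence intervals
substitute the β bounds with the age modifiers fixed. Because the model is
linear in D, each patient's 4DCT:3DCT risk ratio equals their lung-dose
ratio exactly; the cohort summary therefore reports both the mean of
per-patient ratios and the ratio of mean risks, and does not privilege
either as "the" cohort ratio.

## Synthetic data: what it emulates and what it does not

`make_thorax_phantom()` builds an elliptical soft-tissue cylinder (default
AP/LAT 0.75, length 200 mm) containing two ellipsoidal lungs (0.26 g/cm³),
an ellipsoidal heart, a spinal cord inside a bone annulus, an esophagus
tube, a trachea modelled as a soft-tissue cartilage wall around an air
lumen (the wall is the scored organ — analog kerma scoring inside a
low-density lumen is statistically meaningless), and a one-voxel skin
shell. Masks are pairwise disjoint by construction. Organs span the central
80% of the phantom and the default scan range is the organ extent plus a
20 mm margin. The measured effective diameter of the voxelized body is
checked against the request to within 2%.

`make_cohort()` places effective diameters as evenly spaced quantiles over
184.5–465.1 mm (then permutes them with the seed) rather than drawing iid
uniforms, so every generated cohort represents the full size range of the
study population; ages are uniform on 6–93 and sexes split exactly 51/51
at n = 102. `make_dose_table()` draws organ doses from the published
linear size-dose coefficients plus Gaussian noise (σ = 10% of the
organ/protocol cohort mean, floored at zero), giving the regression and
risk stages a millisecond-scale fixture with known truth.

What the generator does **not** emulate: real anatomy (organs are
quadrics), respiratory motion and phase binning (an optional `mip = TRUE`
flag inflates lung density by 1.5× as a crude projection-bias sensitivity
hook), CT texture or noise, and patient extents beyond the scanned thorax.
Passing tests therefore demonstrate correct physics, bookkeeping and
statistics on controlled geometry — not agreement with any specific
patient cohort. Two consequences observed in this artifact's own runs are
worth naming: the skin-shell mean dose *exceeds* the whole-body mean
(peripheral dose is higher than central dose for rotational kV irradiation
of body-size objects), and absolute organ doses sit a few-fold above the
published cohort means because of the synthetic calibration scale and the
shorter phantoms; the inverse size-dose trend and the ≈1/pitch mode ratio
are reproduced.

## Numerical choices

* Voxel convention: values at voxel centres; `origin` is the centre of
  voxel (1,1,1); z is the table axis; all lengths mm, densities g/cm³,
  energies keV.
* Rasterization: even–odd (crossing-number) rule on voxel centres with a
  half-open edge convention — deterministic tie-breaks on vertices/edges.
* HU calibration: piecewise-linear density through the breakpoints,
  clamped beyond the extremes; material = HU bin. Default anchors: air
  (−1000, 0.0012), lung (−850, 0.26), soft tissue (−200, 0.95; 0, 1.000),
  bone (+120, 1.10).
* CTDI phantom grids force an odd in-plane voxel count (a voxel centred on
  the axis) and an even slice count, so the discretized chamber volume
  tracks the nominal cylinder within 5%.
* Negative dose predictions from the linear size model are clamped to zero
  with a warning (extrapolation guard).
* Uncertainty: 10 history batches; region uncertainty is the standard
  error of batch means of the region's mean dose; a zero-dose region
  reports NA, not zero.
* Problem sizes: unit and property tests use 1e4–1.5e5 histories; the
  precision and pitch-ratio checks use the study's 5e5 and 2.5e5 histories
  (seconds on one core with the compiled kernel).

## Known limitations

* No electron transport: skin dose at the very surface (< 0.2 mm) and
  interfaces are kerma, not dose — negligible at these voxel sizes.
* Thomson (form-factor-free) coherent scatter; no bowtie filter or heel
  effect in the default source; a radial fluence weighting hook is the
  natural extension point.
* The spectrum is a filtered-Kramers model, not a measured scanner
  commissioning; mean energy and shape are typical for 120 kVp but not
  scanner-specific.
* Absolute doses inherit the synthetic chamber fixture's scale; supply a
  real measured value to `calibrate()` for metrologically meaningful cGy.
* DICOM import is out of scope in this build; phantoms enter as HU arrays,
  via the NIfTI-based internal format, or from the synthetic generator.
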