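---
title: "Dosimetry of interlaced synchrotron microbeam arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetry of interlaced synchrotron microbeam arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Microbeam radiation therapy (MRT) irradiates tissue with arrays of
quasi-parallel planar X-ray beams a few tens of micrometres wide at
100–400 µm center-to-center (c-t-c) spacing. Normal tissue tolerates
extremely high in-beam ("peak") doses provided the dose midway between
beams (the "valley", produced only by scattered photons and secondary
electrons) stays low; the peak-to-valley dose ratio (PVDR) is the central
dosimetric quantity. *Interlaced* delivery aims radiosurgical damage at a
small target only: several ports each deliver an array, laterally shifted
by a fraction of the spacing, so that the beams tile the gaps *inside*
the target and produce a quasi-solid dose plateau there, while every
other tissue sees only a spatially fractionated array.

This package reproduces that dosimetry chain in water phantoms:

1. **spectrum** — build and calibrate a filtered wiggler-like source
   spectrum;
2. **transport** — Monte Carlo (MC) coupled photon–electron transport of
   one planar microbeam through a cylindrical water phantom (compiled
   core);
3. **compose** — superpose the single-beam profile into arrays; PVDR,
   penumbra and window metrics;
4. **interlace** — multi-port composites, plateau metrics, the
   interlacement enhancement factor (Int.EF);
5. **planner** — entrance-dose back-planning from a prescribed target
   dose;
6. **filmio** — radiochromic-film-like image emulation and profile
   recovery;
7. **synthetic** — analytic kernels with closed-form array sums, used as
   exact oracles, plus the embedded study fixtures.

## Source spectrum

The source is modelled with the universal wiggler emission function
(modified Bessel function `K_{2/3}` integral, evaluated by quadrature on
a photon-energy grid), truncated to the 50–350 keV band and filtered by
the standard stack Be 0.5 mm / C 1.5 mm / Al 1.5 mm / Cu 1.0 mm using the
embedded attenuation tables. The free parameter — the critical energy —
is calibrated by bisection so that the *filtered* spectrum has a median
energy of 107 keV:

```{r spectrum}
library(interbeam)
sp <- source_spectrum()
median_energy(sp)                    # 107 +/- 0.5 keV
attr(sp, "critical_energy_keV")      # ~43.7 keV
```

The median (not the mean) is calibrated because it is insensitive to the
high-energy tail truncation. Monotonicity of the filtered median in the
critical energy makes the bisection well-posed.

## Photon and electron transport

`simulate_single_microbeam()` transports photons sampled from the
spectrum through a water cylinder (rat head: 1.5 cm radius; human head:
8 cm radius). Interaction physics, all on embedded tabulated data with
log–log interpolation:

* **Cross-sections**: total attenuation partitioned into photoelectric,
  incoherent (Compton) and coherent channels; coherent scattering is off
  by default (it is a small, nearly forward correction in this band).
* **Compton scattering**: Klein–Nishina sampling by rejection; the recoil
  electron is emitted coplanar with the scattered photon (azimuth
  `phi + pi`) at the kinematic polar angle.
* **Photoelectric absorption**: the photoelectron direction is sampled
  from the Sauter angular distribution (rejection against a scanned
  envelope). This matters: sub-100 keV photoelectrons emitted
  preferentially sideways seed much of the near-beam valley dose.
* **Electrons** are transported in a condensed-history scheme: stepwise
  continuous-slowing-down (CSDA) energy loss on the embedded stopping
  powers with multiple-scattering deflections whose per-step mean
  deflection matches the first transport moment of the screened
  Rutherford cross-section (Molière screening). The step size is
  controlled so each step loses a small energy fraction. Two cheaper
  modes (`"kernel"`, `"local"`) remain available for sensitivity checks;
  the condensed-history default reproduces both the valley dose and the
  PVDR of the reference study, whereas small-angle (Highland-style)
  scattering underestimates sub-MeV scattering in water by a factor
  ~2.5 and overshoots the valley.

Dose is scored on a 2-D grid: 1 µm transverse bins across the beam
region, geometrically widening outside; 1 mm depth bins; collapsed over
the central 80% of the beam height. Ten independent batches give
per-cell uncertainties, energy bookkeeping (emitted = deposited +
escaped) is exact, and the grid is normalised to the mean dose of the
central 10 µm entrance window, so composite doses scale directly with a
prescribed entrance peak dose.

```{r transport}
g <- simulate_single_microbeam(
  rat_phantom(), microbeam_spec(width_um = 50, height_mm = 2),
  source_spectrum(), transport_config(n_histories = 4e6, seed = 1))
```

An *unscattered diagnostic mode* (`diagnostic_absorb = TRUE`) absorbs
each photon at its first interaction; its depth-dose must match the
spectrum-averaged exponential `narrow_beam_depth_dose()` — one of the
deterministic oracles of the test suite.

## Composition, interlacing and planning

Array composites are exact integer-micron shifted sums of the single-beam
profile (no renormalisation), so superposition is testable bit-for-bit
against brute-force summation. Metric windows: the peak is the mean over
the central 10 µm at the centermost beam; the valley the mean over the
central 20 µm of the centermost gap; the 90–10% penumbra is measured on
the 3 µm-smoothed profile at the outermost edge peak.

The canonical interlaced plan shifts port *p* by `p * spacing / n_ports`
(50 µm steps for 4 ports at 200 µm). `target_report()` reports the
plateau mean, width, heterogeneity and Int.EF
(`plateau / single-array in-beam − 1`). The planner then inverts the
chain: for a prescribed plateau dose `D`, the required single-array
in-beam dose is `D / (1 + Int.EF)`, the valley follows from the PVDR and
the entrance peak dose from the depth attenuation factor. "Table"
rounding mode rounds the in-beam dose to integer Gy before the valley
division, matching the printed planning convention.

```{r planner}
r <- plan_configuration(
  planner_input(target_dose_Gy = 100, int_ef = 0.14, pvdr_depth = 51,
                pvdr_entrance = 71, attenuation_factor = 0.30), "table")
r$inbeam_dose_Gy            # 88 Gy
r$valley_dose_at_depth_Gy   # 1.73 Gy
```

## Synthetic data: fixtures and analytic oracles

The generator defaults *are* the study conditions: 50 µm × 2 mm beams,
200 µm c-t-c, 10-beam arrays, 4 ports with 50 µm interlace steps, 200 Gy
entrance per port in the 1.5 cm rat cylinder; 2×2 mm² to 3×3 cm² fields
at 200/400 µm with 4/8 ports planned at 7.5 cm depth in the 8 cm human
cylinder. `make_rat_fixture()` and `make_table1_fixture()` embed the
published reference numbers (with their source quotes attached as
attributes) for comparison, never for calibration.

The analytic kernel family (top-hat core ⊗ Gaussian + two-sided
exponential tail) has closed-form array sums (geometric series), so the
entire composition/interlacing/planning geometry is tested against exact
values, decoupled from MC noise. `kernel_for_pvdr()` inverts the closed
form to produce a kernel whose composite has an exact target PVDR.

Film emulation (`render_film()`, `profile_from_film()`) box-averages a
dose map onto film pixels, applies a monotone dose–response, adds
Gaussian readout noise, and inverts numerically on the way back; pixels
outside the invertible response range are masked with a warning.

## Numerical choices

* log–log interpolation of attenuation and stopping-power tables
  (strictly monotone between knots in this band);
* bisection for the spectrum calibration (monotone objective);
* rejection sampling for Klein–Nishina and Sauter (envelopes scanned
  numerically and inflated 10%);
* per-element transport cross-sections for water combined at fixed
  number densities; the screened-Rutherford deflection is sampled by
  inverse CDF, with the screening-parameter inversion tabulated once
  (1024-point log–log table) for speed;
* the composite grids stay on the fixed 1 µm lattice end-to-end, so
  array sums are exact integer shifts.

Representative single-core run times: rat phantom 4×10⁶ histories ≈ 20 s;
human phantom 4×10⁶ ≈ 60–90 s; the full test suite a few minutes.

## Limitations

* **Port-shift idealisation.** All ports are modelled as laterally
  shifted copies of one array along a single axis at a common target
  depth, instead of geometrically rotated beams that overlap only inside
  the target. Plateau, valley, PVDR and Int.EF are insensitive to this,
  but *edge* metrics of interlaced fields are pessimistic: the electron
  halos of all `n` ports stack on the same axis, so the outermost-beam
  shoulder sits near 10% of the plateau. For the 1×1 cm² interlaced
  field this inflates the 90–10% penumbra (≈ 94 µm here) and the
  out-of-field dose fraction 10 mm from an 8 mm field center (≈ 2.6%
  instead of ≈ 1.5%), while the *single-array* penumbra (≈ 20–25 µm)
  meets the ≤ 50 µm sharpness expectation. A true cross-fired geometry
  would spread those halos over distinct entry axes.
* Water-only phantoms; no bone/tissue heterogeneity.
* The real storage-ring spectrum is unpublished; the calibrated wiggler
  model matches band and median but not necessarily its exact shape, so
  MC PVDRs are compared with generous tolerances (the reference PVDRs
  come from an independent general-purpose Monte Carlo system).
* No bremsstrahlung or fluorescence transport (sub-percent effects in
  water at these energies); electrons below the cutoff deposit locally.
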