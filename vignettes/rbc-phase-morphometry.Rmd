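---
title: "Red blood cell morphometry from off-axis phase interferograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Red blood cell morphometry from off-axis phase interferograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Quantitative phase imaging records the optical pathlength delay a
transparent cell imposes on transmitted light. In an off-axis
configuration the sample and reference beams interfere at an angle, so the
camera sees carrier fringes whose local bending encodes the phase:

$$I(x, y) = A\,\bigl[1 + m \cos(2\pi(u_0 x + v_0 y) + \varphi(x, y))\bigr]$$

with mean intensity $A$, fringe contrast $m$ and carrier frequency
$(u_0, v_0)$ in cycles/pixel. `rbcphase` implements the standard two-step
reconstruction:

1. **Hilbert (Fourier) demodulation** — `demodulate()` multiplies the
   interferogram by $e^{-2\pi i (u_0 x + v_0 y)}$, which translates the
   first-order spectral lobe to baseband, isolates it with a circular
   low-pass window, and takes the argument of the filtered analytic
   signal. The result is the phase wrapped to $[-\pi, \pi)$.
2. **Unwrapping** — `unwrap_phase()` restores the continuous field.

A cell-free reference frame recorded at the start of a measurement is
demodulated the same way and subtracted (`subtract_background()`), which
removes static dust particles and field aberrations along the optical
path.

Phase converts to physical thickness through
$h = \lambda \varphi / (2\pi\,\Delta n)$, where
$\Delta n = n_{\text{cell}} - n_{\text{medium}}$ and the cell index
follows the linear law $n_{\text{cell}} = n_w + \beta C$ in the
hemoglobin concentration $C$ (MCHC). Per-cell morphology then follows
from the segmented height patches:

* projected area $PA$ = pixel count × pixel area, and the equivalent
  circular diameter $2\sqrt{PA/\pi}$;
* volume $V = \sum h \, dx\, dy$ over the footprint (1 µm³ = 1 fL);
* surface area by Monge parameterisation,
  $SA = \sum \sqrt{1 + h_x^2 + h_y^2}\, dx\, dy + PA$ (the cell lies
  flat on the coverslip, so the base contributes its projected area);
* sphericity $\Psi = \pi^{1/3}(6V)^{2/3} / SA$, equal to 1 for a sphere;
* minimum cylindrical diameter (MCD), the diameter of the narrowest
  capillary the cell can traverse at fixed $SA$ and $V$;
* extended descriptors: perimeter, circularity, eccentricity, thickness
  extrema and mean, integrated density, and variance/skewness/kurtosis of
  the height distribution.

Population statistics aggregate the per-cell volumes into the clinical
indices MCV (mean volume) and RDW (coefficient of variation of volume, in
percent), plus histograms and interquartile summaries per parameter.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `wavelength_nm` | 550 | nm | effective centre wavelength of the white-light illumination |
| `pixel_pitch_um` | 0.16 | µm | sample-plane pixel (6.5 µm camera pitch behind 40× magnification) |
| `n_medium` | 1.337 | — | PBS + 0.1% albumin buffer |
| `n_water`, `beta_dl_per_g` | 1.334, 0.00196 | —, dL/g | linear index law for hemoglobin at visible wavelengths |
| `mchc_g_dl` | 33 | g/dL | per-sample hemoglobin concentration (from a reference analyzer); alternatively `n_cell_override` |
| `carrier_u`, `carrier_v` | 0.32, 0 | cycles/px | fringe frequency, ≈3.1 px/fringe — off-axis systems operate near the 3 px/fringe sampling minimum to save space–bandwidth |
| `filter_radius_frac` | 0.5 | — | Hilbert window radius as a fraction of the carrier magnitude |
| `tau_rad` | 0.3 | rad | global segmentation threshold |
| `connectivity` | 8 | — | cells are blob-like; diagonal bridges belong to one cell |
| `min_volume_fl` | 20 | fL | platelet-exclusion filter for red-cell statistics |

The wavelength and refractive constants are explicit configuration with
documented defaults; a deployment should set them to the instrument's
calibrated values.

## The phantom generator

`sample_population()`, `build_scene()` and `synthesize_interferogram()`
stand in for the microscope. Cells are analytic solids of revolution —
the Evans–Fung biconcave disc
$h(r) = \sqrt{1 - (r/R)^2}\,(C_0 + C_2 (r/R)^2 + C_4 (r/R)^4)$ with the
classic normal-RBC coefficients $(0.81, 7.83, -4.39)$ µm at
$R = 3.91$ µm, spherocyte domes, and thin cylinders for platelets — each
rescaled so its grid-integrated volume matches the drawn target exactly.
Red-cell volumes follow a normal law with mean `mean_volume_fl` and
standard deviation `rdw_percent`/100 × mean, truncated above the 20 fL
platelet boundary; platelets are drawn around 9 fL. Scenes add a smooth
low-order polynomial aberration background (default peak 0.5 rad) and
static Gaussian "dirt" blobs present in both the sample and background
frames. Fringe contrast 0.8 and additive Gaussian camera noise of 1% of
the mean intensity are defaults stated here, not measured values; a
Poisson shot-noise flag exists.

Two modelling points deserve emphasis:

* **Band-limiting.** The analytic profiles have rim kinks (the
  spherocyte's wall is vertical), so their spectra decay slowly; an
  instrument, by contrast, is diffraction-limited. Scenes therefore apply
  a Gaussian point-spread function (`psf_sigma_um = 0.25`) to the cell
  and dirt phase, which keeps the first-order lobe spectrally separated
  from baseband while preserving every cell's integrated volume exactly
  (the kernel is normalised). Ground-truth surface area refers to the
  *physical* cell — it is computed by surface-of-revolution quadrature of
  the analytic profile under the substitution $r = R\sin t$, which
  removes the rim singularity — so measured surface areas carry a small,
  resolution-dependent negative bias relative to truth. Volumes do not:
  end-to-end volume recovery on biconcave populations is accurate to
  about 2%.
* **What passing tests do not show.** The phantom has well-separated
  cells (a dilute smear), perfectly known optics, Gaussian noise and a
  single static background. Real data add focus drift, halo artifacts of
  partially coherent illumination, touching cells, reticulocytes and
  camera nonlinearity — none of which are modelled, so recovery numbers
  here bound only the algorithmic, not the instrumental, error budget.
  Spherocyte and cylinder phantoms keep effectively unlimited bandwidth
  even after the PSF; optics-fidelity guarantees are stated for
  biconcave/platelet scenes, and measured spherocyte rims are smoothed.

## Numerical choices

* **Unwrapper.** Quality-guided flood fill: pixels are integrated outward
  from the locally smoothest pixel in decreasing reliability order
  (reliability = negative sum of squared wrapped differences to the
  4-neighbours). Each output pixel is `wrapped + 2πk` with integer `k`,
  so the congruence contract `wrap(unwrap(ψ)) = ψ` holds for *every*
  input, including residue-laden ones (residues are counted and
  reported). A least-squares unwrapper would not satisfy congruence,
  which is why it is not the default.
* **Hilbert window.** Hard circular window of radius `|carrier|/2` by
  default; a Gaussian taper is available. The hard window keeps the
  passband flat; its ringing on out-of-band content is part of why the
  phantom is band-limited.
* **Background offset.** After subtraction, the global offset is fixed by
  the mode of a coarse (0.05 rad) histogram refined by the median of the
  modal bins — in a dilute smear background pixels dominate, so the mode
  is robust to cell content.
* **Carrier estimation.** Dominant non-DC spectral peak in the
  half-plane, with a 0.08 cycles/px DC exclusion disc and a 3× noise-floor
  gate; a uniform image raises a no-fringe error.
* **MCD root.** The sphero-cylinder with the cell's $SA$ and $V$
  satisfies $\pi D^3 - 3\,SA\,D + 12 V = 0$ (eliminate the cylinder
  length from the area and volume of a cap-ended cylinder). The smallest
  positive real root of the cubic is taken; for a sphere it reduces to
  the diameter exactly. Cells whose discretised sphericity exceeds 1
  have no real deformation and report `NA` with a warning.
* **Perimeter.** Moore-neighbour contour tracing with bias-corrected
  chain weights (0.948 orthogonal, 1.340 diagonal), which converges to
  the true length for smooth shapes as resolution grows — the property
  the circularity descriptor needs. Raw chain weights and crack length
  (which converges to the staircase length, not the true perimeter) are
  available as `method` options.
* **Gradients.** Central differences inside the mask, one-sided at mask
  edges; exact for linear fields.
* **Height moments.** Population (n) normalisation; kurtosis is raw, not
  excess. A constant height distribution reports 0 for variance,
  skewness and kurtosis with a `degenerate_height` flag rather than NaN.
* **Integrated density** sums *phase* (radians × pixels) over the mask;
  summing height instead would duplicate the volume up to a constant.
* **Filters.** Objects below 20 fL (platelets) and objects touching the
  image border (partial cells would corrupt volume statistics) are
  excluded from red-cell statistics. Thickness extrema use the full
  mask, boundary pixels included. No hole filling or morphological
  cleanup is applied; an optional `min_px` speck filter exists and is
  logged in the manifest when it removes anything.
* **Estimators.** RDW uses the sample (n−1) standard deviation;
  quartiles use linear interpolation; histogram bins default to 1 fL
  (volume) and 5 µm² (surface area).
* **Phase TIFFs.** 32-bit float TIFF storage is defined on [0, 1] here,
  so phase maps are written affinely rescaled with a `.range.txt`
  sidecar recording the inverse map; reading is exact to float
  precision.

## Multi-frame runs

A measurement is a sequence of frames sharing one background.
`analyze_run()` accepts several sample paths, analyzes each frame
independently and concatenates the cell records; no deduplication across
overlapping fields is attempted (frames are assumed disjoint, as when
the stage steps by a full field). Each run writes a manifest with the
configuration snapshot, stage decisions, residue/clamp counts and
timings; identical inputs and seed reproduce identical outputs
bit for bit.

## Validation problem sizes

The shipped test suite validates on 512×512-pixel frames with 25 cells
per frame (a dilute smear; macrocytic cells pack no denser under the
non-overlap constraint), 200-cell populations for index recovery, and
the three regimes (67 fL/30%, 90 fL/15%, 125 fL/15%) for MCV/RDW
ordering, with around 75 cells per regime. At these sizes the full suite
runs in well under a minute on one CPU; the per-cell error budget is
volume ≈ 2% (median), surface area ≈ 5–7% (bias discussed above), and
MCV/RDW recover within 5% and 3 percentage points of ground truth.

## Known limitations

* Sequential execution; the real-time/GPU engineering of the original
  instrument is out of scope, as are camera control and stage motion.
* No halo/shade-off correction; the demodulator assumes the off-axis
  geometry separates the lobes cleanly.
* Touching or overlapping cells are not split (no watershed); the
  generator never produces them.
* Reticulocytes are not discriminated from mature cells.
* Per-cell hemoglobin is not estimated; MCHC is a configuration input,
  as when an impedance analyzer provides it.

## A minimal session

```{r example}
library(rbcphase)

sim <- simulate_run("phantom_run", seed = 42, n_cells = 12)
res <- analyze_run(sim$paths$sample, sim$paths$background,
                   out_dir = "phantom_run/out")
res$stats
recover_run(res$cells, sim$paths$truth, pixel_pitch_um = 0.16)
```
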