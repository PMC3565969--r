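# rbcphase

Label-free red blood cell morphometry from off-axis quantitative phase
interferograms, in R.

Clinical impedance counters report little beyond MCV and MCHC, while the
morphological detail that actually distinguishes anemias lives in the
shape of each cell. Quantitative phase imaging (QPI) measures the optical
pathlength delay of unstained cells with nanometre sensitivity, which —
given the refractive index contrast — is a per-pixel thickness map and
therefore a full 3D morphometric measurement. `rbcphase` implements the
computational half of such a blood-testing instrument for people who want
to analyze (or simulate) off-axis interferograms of dilute blood smears:

* **Phase reconstruction** — Fourier/Hilbert demodulation of the
  first-order fringe lobe, quality-guided phase unwrapping, and
  subtraction of a cell-free background frame (dust, field aberrations).
* **Segmentation** — global phase threshold plus a label-equivalence
  connected-component labeller (the iterative scanning/analysis scheme
  used in massively parallel implementations), verified against flood
  fill.
* **Per-cell morphology** — projected area PA, equivalent circular
  diameter, volume `V = ∫ h dA` with the height map
  `h = λφ / (2π Δn)`, Monge surface area
  `SA = Σ √(1 + hx² + hy²) dx dy + PA`, sphericity
  `Ψ = π^(1/3) (6V)^(2/3) / SA`, minimum cylindrical diameter (smallest
  positive root of `π D³ − 3·SA·D + 12·V = 0`), and a dozen extended
  shape/height descriptors. The cell refractive index follows
  `n = n_w + β·C` from the sample's MCHC.
* **Population statistics** — MCV, RDW (= 100 · sd(V)/mean(V)),
  histograms and quartile summaries; platelets are excluded by the 20 fL
  volume filter. The output is a few kilobytes of numbers per sample,
  not images.
* **A phantom generator** — ground-truthed synthetic scenes
  (Evans–Fung biconcave discs, spherocytes, platelets; aberration and
  dirt backgrounds; carrier fringes, camera noise and quantisation) so
  the whole chain is testable end to end.

## Worked example

Simulate a 12-cell phantom acquisition (sample + background
interferograms plus a ground-truth table), analyze it, and compare
against the truth:

```r
library(rbcphase)

sim <- simulate_run("phantom_run", seed = 42, n_cells = 12)
res <- analyze_run(sim$paths$sample, sim$paths$background,
                   out_dir = "phantom_run/out")
res$stats
#> <population_stats> n = 10 cells
#>   MCV  90.4 fL    RDW  22.4 %
#>   mean SA 132.0 um^2   mean sphericity 0.735   mean MCD 2.91 um

recover_run(res$cells, sim$paths$truth, pixel_pitch_um = 0.16)
#> <recovery_report> 10/10 truth cells matched (100.0%), 10 measured
#>   median |rel err|: volume 1.72%, surface area 6.91%

head(res$cells[, c("id", "volume_fl", "surface_area_um2",
                   "sphericity", "mcd_um")], 3)
#>   id volume_fl surface_area_um2 sphericity   mcd_um
#> 1  1  97.06044        139.55173  0.7318865 2.980808
#> 2  2  52.71252         90.89662  0.7479609 2.499593
#> 3  3 106.05142        148.43303  0.7299580 3.060047
```

The 12 simulated objects include platelets (< 20 fL); the analysis keeps
the 10 red cells, recovers each volume to about 2%, and reports the
sample's MCV/RDW. `analyze_run()` writes the per-cell CSV, a compact
key-value summary, phase and label TIFFs, and a manifest recording every
configuration choice, filter decision and timing.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/rbcphase.R simulate --out-dir run1 --seed 42 --n-cells 12
Rscript inst/cli/rbcphase.R analyze  --sample run1/sample.tif \
    --background run1/background.tif --out-dir run1/out
Rscript inst/cli/rbcphase.R recover  --cells run1/out/cells.csv \
    --truth run1/truth.csv
```

See `vignettes/rbc-phase-morphometry.Rmd` for the measurement model, the
phantom's scope, and every numerical design choice (filter window,
unwrapper, perimeter estimator, moment conventions).

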