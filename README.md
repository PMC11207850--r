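# mofdiff

Tools for watching guest molecules diffuse into and out of a **single
porous crystal** with an ordinary optical microscope — and for getting
numbers out of what you see.

Mesoporous metal–organic frameworks (MOFs) such as Tb-mesoMOF are
colourless crystals of ~100 µm that load intensely coloured guests like
vitamin B12 (cobalamin). Batch assays (gravimetry, UV–VIS, HPLC) average
over thousands of heterogeneous crystals; time-lapse microscopy of one
crystal instead shows *where* and *how fast* the guest moves — corners
redden first, then edges, then faces, then the interior, and release
fades to a plateau. This package is for experimentalists and modellers
who want that analysis chain as tested, reusable code:

* **`crystal_sim`** — a 3-D finite-difference diffusion solver for a
  faceted crystal (per-face exposure, face-dependent diffusivity layers,
  surface defects) plus a Beer–Lambert optical renderer that turns
  concentration fields into microscopy-like 8-bit RGB frame stacks, and a
  Brownian-walk generator for ground truth.
* **`histogram_pipeline`** — the image-processing procedure: reference
  subtraction, red-channel extraction, mean-intensity traces, and the
  spot-change measurement ω.
* **`kinetics`** — release-curve fitting (capped saturating-log model,
  half-intensity time t_D) and diffusion-coefficient estimators.
* **`sensing`** — design calculations: loading capacity, pore-window
  accessibility, initial uptake rates, half-saturation ordering.
* **CLI** — `inst/cli/mofdiff` with subcommands `simulate`, `analyze`,
  `fit-release`, `msd`, `design`.

## The core quantities

Mean-square displacement of a freely diffusing molecule:

    x² = qᵢ · D · t        qᵢ = 2, 4, 6  (1-, 2-, 3-D diffusion)

FRAP-style estimate from an imaging experiment:

    D = ω² / (4 · t_D)

where t_D is the time for the release signal to reach 50% of its fitted
plateau and ω is the linear change of the spot that has diffused out,
measured as the hydraulic diameter (4·Area/Perimeter) of the
half-maximum region of the differential red image. Worked example:
ω = 23.16 µm and t_D = 1500 min give D ≈ 1.49 × 10⁻¹⁵ m²/s.

## Worked example

Simulate a release run on a 40 µm crystal, render it to frames, and run
the full analysis chain back to a diffusion coefficient:

```r
library(mofdiff)

geo <- crystal_geometry(extents = 40, voxel_pitch = 1.25)   # 40 um cube, 32^3
par <- diffusion_params(D_face = 1e-15)                     # m^2/s
opt <- optics_model(seed = 11)                              # seeded camera noise

seq <- simulate_sequence(geo, par, opt, mode = "release",
                         sample_times = c(15, 30, 60, 100, 200, 300, 500,
                                          1000, 1600, 2350, 3000))

est <- end_to_end_release_D(seq)
print(est$inputs_echo$fit)
cat(sprintf("omega = %.2f um\n", est$inputs_echo$omega_um))
print(est)
```

which prints:

```
release_fit (capped-log: I(t) = min(A*log(1 + t/tau), P))
  A = 4.46, tau = 5.446 min, plateau = 27.84 counts
  t_D = 118.1 min, rmse = 0.7612 counts
omega = 5.56 um
diffusion_estimate: D = 1.092e-15 m^2/s (method: frap)
```

Reading this: the mean differential red intensity climbs to a plateau of
~27.8 counts; the fitted curve crosses half of that plateau at
t_D ≈ 118 min; between the first frame and the frame nearest t_D the
released band around the crystal rim thickens by ω ≈ 5.6 µm; and
ω²/(4·t_D) returns D ≈ 1.09 × 10⁻¹⁵ m²/s against a simulated ground
truth of 1 × 10⁻¹⁵ m²/s.

The same chain is exposed on the command line:

```sh
inst/cli/mofdiff simulate    --config run.yaml --out frames/
inst/cli/mofdiff analyze     --manifest frames/manifest.csv --out trace.csv
inst/cli/mofdiff fit-release --trace trace.csv --out fit.json
```

## Documentation

The methods vignette (`vignettes/mofdiff-methods.Rmd`) describes the
diffusion model and its boundary conditions, the optical model, the ω
and t_D definitions, every tunable default and why it has the value it
has, and the known limitations of both the simulator and the FRAP-style
estimator.
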