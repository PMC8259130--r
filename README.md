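# BesselFlow

An in-silico imaging flow cytometer and sorter built around a scanning
Bessel–Gaussian beam.

Label-free image-guided cell sorters scan a laser line across a
microfluidic channel and read the transmitted light through a slit with
a single PMT: each fast scan encodes one line of the object's 2D
transmission image into the temporal waveform, and the slow flow
advances the object between scans. A Bessel–Gaussian beam gives the
instrument an extended depth of focus, but its concentric sidelobes mix
neighboring image lines into every sample. BesselFlow simulates this
whole measurement chain on synthetic phantoms and implements the
decoding and sorting analytics that go with it:

- **Beam model** — the J0 profile under a Gaussian envelope collapsed
  to a *delta comb* at the J0 extrema with intensity weights
  `a_l² = J0(u_l)² exp(−2u_l²/(kr w0)²)`; main-lobe intensity FWHM
  pinned to 1.2 µm (`kr ≈ 1.877 rad/µm`).
- **Phantoms** — effective transmission maps `f(y,z)` for polystyrene
  beads (dark rim, bright center), granular cells, and elongated algal
  colonies, plus mixture scenes with sizes, speeds (10–25 cm/s) and
  non-overlapping arrival times.
- **Forward model** — two-channel records: the PMT transmission
  `J(y′) = Σ_l a_l² f(y′ − u_l/kr)` per 5 µs scan (125 samples at
  25 MS/s over a 40 µm FOV), slit integration, per-scan background
  ripple and noise; and a two-slit LED velocimetry channel.
- **Reconstruction** — the 251×251 transfer matrix (unit diagonal,
  symmetric, banded, diagonally dominant), per-scan inversion
  `f = T⁻¹ J` with background-1 closure outside the FOV (machine-
  precision round trip), and speed-corrected 2D image assembly.
- **Features & sorting** — two-slit speed `v`, transit time `T1`,
  per-scan width profile `T2`, positive-peak count `N`; the standard
  speed-corrected axes `L = T1·v`, `W = T2max·v_scan`,
  `(T1·v)(T2·v_scan)`, `N·v`; valley/scatter gating; purity, yield and
  enrichment.

## Worked example

Sort 10 µm beads out of a 1:1 mixture with 7 µm beads (200 + 200
objects, size CV 3%, speeds uniform on 10–25 cm/s, 1% noise), gating on
the size product at the histogram valley:

```r
library(BesselFlow)
res <- runPipeline(demoConfig("beads_7_10"), seed = 1)
res$report
#> SortReport (target 'bead10')
#>   sorted: 200 target + 0 other -> purity 100.0%
#>   yield: 100.0%   enrichment: Inf
head(res$features[, c("speed", "T1", "T2max", "L", "W", "sizeProduct")], 3)
#>      speed       T1 T2max         L    W sizeProduct
#> 1 23.54294 47.12084  1.24 11.093631 9.92   110.04882
#> 2 11.35284 74.21745  0.92  8.425786 7.36    62.01378
#> 3 20.43147 54.91191  1.24 11.219312 9.92   111.29558
```

Each event row is one object: `speed` (cm/s) from the velocimetry
dips, `T1` (µs) the transit time, `T2max` (µs) the widest within-scan
dip, so `L ≈ diameter + 1.5 µm slit` and `W ≈ diameter` (µm), and
`sizeProduct = L·W` (µm²) is the gating axis — ~60 µm² for 7 µm beads
vs ~116 µm² for 10 µm beads, with the gate at the valley between them.
The report counts gated events against ground truth: all 200 bead10
events sorted, zero 7 µm contaminants.

Single-object building blocks:

```r
beam <- BeamParameters()          # kr matched to a 1.2 um FWHM
comb <- combWeights(beam)         # delta comb, 11 sidelobes per side
tm   <- buildTransferMatrix(comb, AcquisitionParams())  # 251 x 251
img  <- makeBead(15)              # a 15 um bead phantom
```

A command-line wrapper for the simulate/reconstruct/sort stages is in
`inst/cli/besselflow.R`; YAML run configurations are documented in
`?defaultConfig` with an example under `inst/extdata/`.

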