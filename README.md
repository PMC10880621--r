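# hyphir

Hyperspectral mid-infrared mapping of fungal decomposition zones around
single hyphae.

A fungal hypha growing on a regenerated-cellulose film oxidizes the film
in a micrometre-scale halo. In a hyperspectral IR image (every pixel a
full absorbance spectrum) that chemistry is readable: cellulose absorbs
most strongly at 1100–950 cm⁻¹ with an ether band at 1160 cm⁻¹,
oxidation adds C=O signal at 1700–1600 cm⁻¹, and the hypha itself shows
the protein amide I/II bands at 1650/1550 cm⁻¹. `hyphir` implements the
full analysis chain for such images:

* **Preprocessing** — atmospheric water-vapor correction (roughness-
  minimizing reference fit), crop to 900–1800 cm⁻¹, rubberband (lower
  convex hull) baseline correction, normalization to the 1370 cm⁻¹
  cellulose band;
* **Unmixing** — SIMPLISMA pure-variable selection (purity
  `sd/(mean + α·max mean)` with determinant-based independence
  weighting) seeding non-negative MCR-ALS, `D ≈ C Sᵀ` with exact NNLS
  half-steps and a provably non-increasing lack of fit
  `100·√(Σ(D−CSᵀ)²/ΣD²)`;
* **Segmentation** — k-means (k = 3) on standardized contributions,
  semantic zone labels (background / decomposition zone / hypha) by
  amide-region ranking, and zone geometry in µm (hyphal width, halo
  extent) from cross-sections perpendicular to the principal axis;
* **Gradient analysis** — radial cuts from the hyphal tip, two-component
  MCR-ALS of the selected spectra, lowess trends of contribution versus
  midline distance, and zone-wise linearity fits;
* **Simulation** — a ground-truth scene generator (hypha, linear
  oxidation ramp, protein, acetate QC components) and instrument models
  for conventional FTIR (wavenumber-dependent Rayleigh PSF
  `0.61·λ/NA`, 2.3 µm pixels, 1024 co-added scans) versus O-PTIR
  (fixed 416 nm probe spot, 0.5 µm pixels, 3 scans), so the whole chain
  is verifiable without experimental data.

Cubes travel as HDF5 (`/wavenumbers_cm1`, `/absorbance`, pixel-size and
modality attributes, provenance group); single spectra as two-column CSV.

## Worked example

```r
library(hyphir)

g <- generate_cube("fig3_optir", seed = 0)   # simulated O-PTIR measurement
g$cube
#> <hyper_cube> optir: 50 x 80 pixels (0.5 um), 551 wavenumbers 800-1900 cm-1, 1 provenance entries

res <- analyze_cube(g$cube, reference = g$reference)
res$unmixing
#> <unmixing_result> k=3, LOF 3.305%, 70 iterations (converged), pure variables: 380, 270, 2
res$cluster_map
#> <cluster_map> background=2552, decomposition=1108, hypha=340, masked=0 (pixel 0.5 um)
res$geometry
#> <zone_geometry> hypha width 4.00 um, halo extent 4.50 um (44 stations)
res$zone_fit$r2_in
#> [1] 0.885
```

The unmixing resolves the cube into cellulose-like, oxidized-cellulose
and protein components (lack of fit ≈ 3 %, dominated by the simulated
noise); the cluster map recovers the hypha as a coherent stripe and an
intermediate decomposition zone around it; the geometry is reported in
micrometres. Note that the cluster-derived halo extent of a linearly
fading halo is systematically below the generating extent — a property
of hard clustering on a gradient, discussed in the methods vignette
(`vignettes/zone-mapping.Rmd`). The in-zone R² shows the decomposition
signature changes linearly with distance inside the zone.

Resolution arithmetic is exposed directly:

```r
rayleigh_resolution(1e4 / 900, 0.4)   # 16.94 um at 900 cm-1, NA 0.4
rayleigh_resolution(532, 0.78)        # 416 nm probe spot
```

A thin command-line wrapper is installed as `exec/hyphir`
(`hyphir generate`, `hyphir analyze`, `hyphir resolution`).

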