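# mitomorph

3-D morphometry and unbiased stereology of cardiac mitochondrial
subpopulations.

## The problem

Cardiac mitochondria form three spatially defined subpopulations:
subsarcolemmal (SSM) directly under the cell membrane, interfibrillar
(IFM) in rows between the myofibrils, and perinuclear (PNM) against the
nuclear envelope. In disease models these populations remodel
differentially — sizes, shapes, tubular projections, overall density
and cristae organisation can all shift — and quantifying that requires
a reproducible measurement layer over 3-D electron-microscopy label
volumes (SBF-SEM, anisotropic voxels of 13.5 × 13.5 × 50 nm) and 2-D
TEM sections.

`mitomorph` is that layer, for researchers analysing segmented EM data
of myocardium (it consumes label volumes; it does not segment raw EM):

* **Per-mitochondrion 3-D morphometry** — exact voxel volume,
  surface area `S` by a smoothed-indicator coarea estimator, `S/V`,
  subtype assignment by mask contact, oval/irregular shape
  classification (ellipsoid-fit overlap + solidity), and detection of
  tubular projections and nanotunnels with lengths measured as
  anisotropy-aware geodesics (µm), tip widths off the distance
  transform.
* **Unbiased stereology** — the two-lattice point-counting estimator
  of the mitochondrial volume fraction

  `V_v = (ΣP_mito · a_green · n·t) / (ΣP_cm · a_red · n·t) × 100`

  with random lattice offsets and uniform-random-systematic slice
  sampling, per-subpopulation shares, and the linear/point test probe
  for cristae surface density `Ŝ_v = 2·ΣI_i / (l/p · ΣP_i)`.
* **Cristae analysis** — Otsu membrane thresholding, sub-pixel line
  profiles, membrane-doublet detection, outer width `W_O`, lumen `W_I`
  and spacing `S` in nm, and the ordinal 1/3/5 cristae quality score.
* **A synthetic phantom generator** — seeded cardiomyocyte label
  volumes (sarcolemma, nucleus, myofibril rows, three subpopulations
  with controllable fraction, mix, shapes, projections, nanotunnels)
  and TEM-like cristae images, all with exhaustive ground truth, so
  every estimator ships validated against known geometry.
* **Reporting** — animal-first hierarchical summaries (mean ± SEM),
  Student t / one-way ANOVA + Tukey / two-way ANOVA + Sidak
  comparisons, and CSV/JSON table output.

## Worked example

Generate a cell-scale phantom at a 25 % mitochondrial volume fraction,
estimate the fraction by two-lattice point counting, and measure
cristae dimensions on a synthetic TEM image:

```r
library(mitomorph)

ph <- simulate_cardiomyocyte(
  volume_params(target_mito_fraction = 0.25, seed = 42),
  voxel_geometry(c(128, 128, 24), c(84, 84, 420)))
print(ph)
#> mito_phantom: 443 objects, true mito fraction 0.250
#> label_volume
#> voxel geometry: 128 x 128 x 24 voxels, 84 x 84 x 420 nm
#>   443 labelled mitochondria; masks: nucleus=TRUE sarcolemma=TRUE cm=TRUE

grid <- grid_spec(red_area_nm2 = 1e6, green_area_nm2 = 0.2e6,
                  slice_interval = 2)
volume_fraction(count_points(ph$volume, grid, seed = 7), grid)
#> volume fraction: 25.67 % (sd 10.72 over 3 regions)
100 * ph$truth$true_fraction
#> [1] 24.99  (exact voxel fraction of the phantom)

img  <- simulate_cristae_image(cristae_params(seed = 5))
pr   <- line_profile(img$image, img$truth$profile_line$p0,
                     img$truth$profile_line$p1, pixel_size_nm = 2)
round(colMeans(measure_dims(detect_doublets(pr)), na.rm = TRUE), 1)
#> W_O_nm W_I_nm   S_nm
#>   36.4   15.6   28.6
```

A single placement of the acquisition-style sparse lattices is noisy (the sd
above is across the three sampling regions); batch analyses pool counts
over many random placements before forming the ratio. The phantom was
generated at 36/16/28 nm cristae dimensions; the line-profile pipeline
recovers them to a fraction of a nanometre.

The methods vignette (`vignettes/mitomorph-methods.Rmd`) documents the
models, the estimator contracts, the numerical choices, and what the
phantom does and does not emulate.

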