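# xylometry

3D morphometry of plant cell walls from nanotomography volumes.

Water moves through xylem vessels under negative pressure, and a conduit's
resistance to collapsing ("imploding") under that tension is classically
summarised by the implosion-resistance parameter

```
(t / b)^2
```

where `t` is the double wall thickness and `b` the maximum lumen diameter of
the vessel. Two-dimensional micrographs give only a handful of `t` and `b`
readings per conduit; high-resolution 3D tomograms (for example
cryo-ptychographic X-ray tomography of petiole tissue at ~50 nm voxels) allow
`t`, `b` and hence `(t/b)^2` to be measured at every height along a cell and
compared between genotypes with different lignin content.

`xylometry` implements that measurement chain for people working with such
volumes:

* **Segmentation** — trainable random-forest pixel classification from
  sparse voxel annotations (3D grey/scale/texture feature bank), grey-level
  and probability thresholding, and morphological refinement with exact
  Euclidean-ball opening/closing, small-component removal and per-slice hole
  filling.
* **3D local thickness** — at every wall (or lumen) voxel, the diameter of
  the largest sphere that fits inside the object (Hildebrand–Rüegsegger),
  with histograms and summary statistics for comparing wall-thickness
  distributions.
* **Per-slice EDT morphometry** — lumen centre (distance-transform maximum),
  centre-to-border radius distribution, lumen diameter `b`; medial axis of
  the wall by topology-preserving thinning and per-medial-pixel wall
  thickness from the distance transform.
* **Implosion profile** — `(t/b)^2` sampled every 50 nm (configurable) along
  the cellular height, with min/max envelopes and per-cell summaries.
* **Reconstruction metrics** — Fourier shell correlation between
  half-dataset reconstructions, the van Heel–Schatz half-bit threshold, the
  resolution at the crossing, and conversion of refractive-index-decrement
  volumes to electron density (e/Å³).
* **Phantoms** — a synthetic generator for vessel-, sclerenchyma- and
  parenchyma-like tubular cells with exactly known wall/lumen geometry,
  optional pits and helical thickenings, Gaussian blur and noise, so every
  stage can be validated against ground truth.

## Worked example

Render a vessel phantom with a 0.5 µm wall and a 2.5 µm lumen radius
(`t = 1 µm`, `b = 5 µm`, so analytically `(t/b)^2 = 0.04`), then measure it:

```r
library(xylometry)

spec <- phantom_spec(c(10, 160, 160),
                     cells = list(cell_spec("vessel",
                                            lumen_radius_um = 2.5,
                                            wall_thickness_um = 0.5)),
                     blur_sigma_nm = 0, noise_sigma = 0)
ph <- render_phantom(spec)
ph$labels
#> <label_volume> 10 x 160 x 160 (z,y,x), voxel 48.87 nm
#>
#> background       wall      lumen
#>     135360      73248      98592

profile <- implosion_profile(ph$labels, interval_nm = 50)
profile
#> <implosion_profile> 10 slices (10 valid), interval 50 nm
#>   (t/b)^2: mean 0.0392, range [0.0392, 0.0392]
```

Every 50 nm slice of this z-invariant tube gives the same record, and the
mean `(t/b)^2` of 0.0392 recovers the analytic 0.04 to about 2% (the
remaining difference is voxel quantisation of the 10.2-voxel wall). On a
grey-level volume the chain is `train_pixel_classifier()` →
`classify_volume()` → `morphological_refine()` → `implosion_profile()`;
`local_thickness_map()` + `thickness_histogram()` give the 3D wall-thickness
distribution, and `fsc_curve()` + `resolution_from_fsc()` estimate the
resolution of a half-dataset pair rendered with `render_halfpair()`.

A command-line front end wrapping these functions is installed at
`inst/cli/xylometry.R` (subcommands `phantom`, `segment`, `thickness`,
`profile`, `fsc`; TIFF stacks with a JSON metadata sidecar).

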