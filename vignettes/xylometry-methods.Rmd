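---
title: "Measuring cell-wall morphometry and implosion resistance in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell-wall morphometry and implosion resistance in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Xylem vessels carry water under negative pressure. Whether a conduit
withstands that tension or buckles is classically summarised by the
implosion-resistance parameter $(t/b)^2$, with $t$ the double wall thickness
and $b$ the maximum lumen diameter: the thicker the wall relative to the
span of the lumen, the more resistant the tube is to transverse buckling.
Estimating $t$ and $b$ from a few 2D micrograph chords is imprecise;
nanotomography (for example cryo-ptychographic X-ray tomography at ~50 nm
voxel size) resolves the full 3D wall, so $t$ and $b$ can be profiled at
every height along a cell and summarised with their whole distributions.

`xylometry` implements this chain — segmentation, 3D local thickness,
per-slice distance-transform morphometry, the $(t/b)^2$ profile, and
reconstruction-quality metrics — together with a phantom generator that
provides exact ground truth for validating every stage.

## Conventions

* Volumes are `(z, y, x)` arrays; the first axis is the cellular height
  along which profiles are computed, and transverse slices are `(y, x)`
  planes.
* Voxels are isotropic with a mandatory physical size in nanometres. Every
  quantitative output (µm, nm) is derived from it; 48.87 nm is only a
  *phantom* default, never assumed for real data.
* Indices are voxel centres; the physical position of 0-based index $i$ is
  $i \cdot \Delta x$.
* Labels are `0 = background, 1 = wall, 2 = lumen`.
* TIFF stacks carry a JSON sidecar (`<file>.json`) with voxel size, units
  and the exact de-scaling needed for floating-point data. HDF5 containers
  are not read; TIFF is the interchange format.

## Segmentation

`train_pixel_classifier()` follows the trainable-segmentation paradigm: a
handful of voxels per class is annotated, a random-forest ensemble is
trained on a per-voxel feature bank, and the remaining volume is classified
automatically (`classify_volume()`). A model trained on one volume can be
applied to another acquired with the same modality — e.g. train on a
wild-type tomogram, segment the mutant one — which keeps the class
definitions consistent between groups.

Features are computed in 3D: the raw grey value, Gaussian-smoothed copies at
$\sigma \in \{1, 2, 4\}$ voxels, gradient magnitude and Laplacian of the
finest smoothed copy, and a Gaussian-windowed local variance
($\sigma = 2$ voxels). The scales are deliberately small multiples of the
voxel so that walls a few hundred nanometres thick survive smoothing.
Defaults: 100 trees, at least 10 annotations per class; training and
prediction are single-threaded and seeded, so results are bit-reproducible
and models survive `saveRDS()` round-trips. Class probabilities sum to one
at every voxel; the label is the argmax with ties broken toward the lowest
class id.

`threshold_labels()` applies an inclusive threshold (`field >= t`,
default 0.5 on probabilities, equivalent to the two-class argmax).
`morphological_refine()` then opens/closes with *exact Euclidean balls*
(derived from the squared distance transform rather than from separable
approximations), removes 26-connected components below a voxel count, and
optionally fills per-slice holes (4-connected background regions not
touching the slice border). Opening-then-closing is idempotent, so repeated
refinement does not drift.

## 3D local thickness

`local_thickness_map()` implements the largest-inscribed-sphere definition:
the thickness at voxel $p$ is the diameter of the largest sphere contained
in the mask that covers $p$. The algorithm computes the exact squared
Euclidean distance transform (Felzenszwalb–Huttenlocher separable
parabolas), discards sphere centres whose sphere is contained in a
26-neighbour's sphere (an exact integer test, which never changes the
result), and propagates the maximal squared radius over each surviving
sphere. On masks up to $32^3$ the result is asserted *identical* to a
brute-force enumeration of all EDT spheres.

Sub-voxel convention: radii are voxel-centre distances to the nearest
background voxel and reported diameters are $2r$ with no half-voxel
correction. Conventions differ between implementations; this one is stated
explicitly because it biases diameters by up to +1 voxel relative to
continuous geometry (a sphere that locally fits an $n$-voxel slab has
diameter $n{+}1$ when $n$ is odd). `thickness_histogram()` bins thickness
(default bin width 0.05 µm from 0) and reports the mean, mode and standard
deviation; histogram modes therefore track a true wall of width $w$ within
$[w - 1, w + 1.3]$ voxels once bin quantisation is included.

## Per-slice morphometry and the implosion profile

For each sampled transverse slice (`measure_slice()`):

* **Lumen centre** — the foreground pixel maximising the distance transform.
  If several pixels tie, the centroid of the argmax set snapped to the
  nearest argmax pixel is used (deterministic and symmetric); remaining ties
  go to the lexicographically smallest index. Slices whose foreground
  touches the image border are rejected, because their distances are
  censored.
* **Radii and diameter** — distances from the centre to every border pixel
  (foreground pixel with a 4-connected background neighbour).
  $b = 2\max(\text{radii})$ by default, reading "maximum diameter"
  literally; `mode = "mean_radius"` is available, and $b_{min} = 2\min$ is
  always recorded. Note that staircase corners put some border pixels up to
  one pixel inside the nominal outline, so the *minimum* radius of a digital
  disk of radius $r$ lies in $[r-1, r]$.
* **Wall thickness** — the wall mask is thinned to its medial axis with the
  Guo–Hall two-subiteration algorithm (topology-preserving, 8-connected
  skeleton); at each medial pixel the thickness is $2 \times$ the distance
  transform value. A mask that thins to nothing falls back to the EDT
  maximum; a single-pixel wall reports one voxel.
* **The $t$ statistic** — per slice, $t = 2 \times$ mean of the single-wall
  thickness multiset, with $t_{min}$ and $t_{max}$ (doubled minimum and
  maximum) always recorded so worst-case analyses can use the envelopes;
  `t_stat = "min"` switches $t$ itself to the worst case. The doubling
  matches the "double intervessel wall thickness" definition; for isolated
  cells this is $2\times$ the single wall, which is stated rather than
  hidden.

`implosion_profile()` samples slices every
`max(1, round(interval_nm / voxel_size_nm))` planes (50 nm by default — one
plane at 48.87 nm voxels), separates cells as 26-connected components of
wall + lumen, and assembles the records. Slices with no measurable lumen
produce explicit missing rows, never zeros. End-cap slices whose lumen area
falls below 25% of the median are recorded but excluded from the summary,
which reports the unweighted mean, minimum and maximum of $(t/b)^2$ over the
remaining slices. Pits (wall perforations) depress $t_{min}$ in the slices
they cross while the default mean statistic dampens them — consistent with
vessels functioning despite wall orifices; the interpretation of specific
$(t/b)^2$ values as collapse pressures is left to the literature and not
computed here.

## Reconstruction metrics

`fsc_curve()` correlates the Fourier transforms of two independent
reconstructions over spherical shells one Fourier voxel wide up to Nyquist:
$\mathrm{FSC}(k) = \Re\sum F_1 \bar F_2 / \sqrt{\sum|F_1|^2 \sum|F_2|^2}$.
An optional cosine taper over the outer 10% of each axis (off by default)
suppresses wrap-around artefacts. `half_bit_threshold()` is the standard
van Heel–Schatz half-bit curve
$T(n) = (0.2071 + 1.9102/\sqrt n)/(1.2071 + 0.9102/\sqrt n)$, clipped at 1.
`resolution_from_fsc()` returns the inverse of the frequency at which the
FSC first falls below the threshold, linearly interpolating
$\mathrm{FSC}-T$ between shells and excluding the DC shell; `NA` if there is
no crossing.

`delta_to_electron_density()` converts a refractive-index-decrement volume
to electron density, $n_e = 2\pi\delta / (r_e \lambda^2)$, with
$\lambda = 12.398419\,\text{keV·Å}/E$ and
$r_e = 2.8179403\times10^{-5}$ Å; the map is linear and exactly invertible.
`phase_to_delta()` provides the per-voxel phase-to-decrement helper
($\delta = \varphi\lambda / 2\pi\Delta x$) for pipelines that store phase.

## The phantom generator

`render_phantom()` produces the three tissue archetypes seen in petiole
tomograms as analytic tubes along z: vessels (large lumen, thin wall,
optional pits and helical thickenings), sclerenchyma fibres (thick wall,
small lumen) and parenchyma (thin wall, filled lumen). Labels come from
exact voxel-centre geometry — they are blur- and noise-free ground truth —
and the grey volume applies class grey levels, a Gaussian blur, and i.i.d.
Gaussian noise from a single integer seed. `render_halfpair()` emulates
half-dataset reconstructions: identical blurred signal, independent noise
with seeds `s` and `s+1`.

Defaults and why:

* voxel 48.87 nm — the reconstruction scale of the motivating experiments;
* blur $\sigma$ = 59.45 nm, i.e. FWHM ≈ 140 nm — matches the poorer of the
  reported reconstruction resolutions, so partial-volume effects are
  exercised at a realistic scale;
* grey levels background 0, lumen 0.45, wall 1 — the milled pillar sits in
  air (lowest density), the lumen is resin-filled (intermediate) and the
  lignified wall is densest; noise levels are quoted as a signal-to-noise
  ratio against the smallest inter-class contrast (0.45), e.g. SNR 4 means
  $\sigma_{noise} = 0.1125$;
* the default tube axis is snapped to the nearest voxel centre so the
  digital lumen radius is exactly representable;
* pit sizes and helical pitch are order-of-magnitude choices (no
  quantitative values exist for them); pits are radial cylindrical
  perforations relabelled as lumen, helical bands thicken the wall inward.

What the phantoms do *not* emulate: reconstruction artefacts (rings, missing
wedge, streaks), spatially correlated noise, intensity gradients, organelle
texture inside parenchyma, non-cylindrical cell shapes, and touching cells
sharing a wall. Passing the phantom suite therefore demonstrates that the
*measurement* chain is correct and stable at realistic scale and noise — not
that segmentation of arbitrary real tomograms will reach the same Dice.

## Validation strategy and problem sizes

The test-suite properties are chosen so each stage is checked against an
independent route: brute-force EDT/inscribed-sphere/border oracles on random
masks (exact equality for local thickness, $10^{-9}$ for distances),
analytic tubes at the reported wall regimes (0.45–1.0 µm walls, 5 µm lumen
radius, 48.87 nm voxels) for voxel-accuracy recovery of $t$, $b$ and
$(t/b)^2$, a grey pipeline at blur FWHM 140 nm and SNR 4 for end-to-end
recovery and the wall-thinning contrast between the 0.8 µm and 0.6 µm
regimes, FSC null bounds ($4/\sqrt{n_k}$) and a constructed band-limited
cutoff, and bit-identical reruns for determinism. Validation volumes range
from $16^3$ oracle masks to $40 \times 284 \times 284$ ramp phantoms —
large enough that quantisation, curvature and noise all act, small enough
that the whole suite runs in minutes on one core.

## Known limitations

* The $2r$ / $2\times$EDT voxel-centre conventions carry a $+0..1$ voxel
  positive bias on thickness-like quantities (parity of the digital width);
  at a 9-voxel wall this propagates to about +5% on $(t/b)^2$. Sub-pixel
  boundary interpolation would remove it but is deliberately out of scope.
* Guo–Hall thinning is not exactly equivariant under 90° rotation; medial
  multisets match under rotation in the mean (≲2%) but not pixel-for-pixel.
* Per-slice measurements assume one cell per connected component; cells
  sharing a wall are not split.
* The FSC module starts from reconstructed volumes; phase retrieval,
  projection alignment and filtered back projection are out of scope.
* Anisotropic voxels are rejected rather than resampled.
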