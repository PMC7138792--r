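# Heavier shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# study-condition grey phantom pair: vessel tubes with wall 0.8 um (wild-type
# regime) and 0.6 um (mutant regime), lumen radius 2 um, 48.87 nm voxels,
# blur FWHM 140 nm, SNR 4 (noise sd = smallest class contrast / 4), plus a
# classifier trained on the 0.8 um phantom and both classifications
segmentation_pair <- function() fixture("segmentation_pair", function() {
  mk <- function(w, seed) phantom_spec(
    c(40, 144, 144),
    cells = list(cell_spec("vessel", lumen_radius_um = 2,
                           wall_thickness_um = w)),
    noise_sigma = 0.45 / 4, seed = seed)
  wt <- render_phantom(mk(0.8, 101))
  mut <- render_phantom(mk(0.6, 202))
  ann <- sample_annotations(wt$labels, 200, seed = 11)
  model <- train_pixel_classifier(wt$volume, ann, seed = 3)
  list(wt = wt, mut = mut, model = model,
       seg_wt = classify_volume(model, wt$volume),
       seg_mut = classify_volume(model, mut$volume))
})

# noiseless analytic label tubes at the printed wall-thickness regimes,
# lumen radius 5 um, 48.87 nm voxels
analytic_tubes <- function() fixture("analytic_tubes", function() {
  lapply(c(0.45, 0.6, 0.8, 1.0), function(w) {
    sp <- phantom_spec(c(8, 256, 256),
                       cells = list(cell_spec("vessel", lumen_radius_um = 5,
                                              wall_thickness_um = w)),
                       blur_sigma_nm = 0, noise_sigma = 0)
    list(wall_um = w, phantom = render_phantom(sp))
  })
})

expect_rel <- function(measured, truth, tol) {
  expect_lt(abs(measured / truth - 1), tol)
}
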