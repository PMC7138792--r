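noiseless_phantom <- function() fixture("noiseless_seg", function() {
  sp <- phantom_spec(c(24, 64, 64),
                     cells = list(cell_spec("vessel", lumen_radius_um = 1,
                                            wall_thickness_um = 0.45)),
                     blur_sigma_nm = 0, noise_sigma = 0)
  render_phantom(sp)
})

test_that("separable classes are learnt perfectly from 20 annotations", {
  ph <- noiseless_phantom()
  ann <- sample_annotations(ph$labels, 20, seed = 2)
  mdl <- train_pixel_classifier(ph$volume, ann, seed = 1)
  seg <- classify_volume(mdl, ph$volume)
  # training annotations are reproduced ...
  lin <- cbind(ann$z, ann$y, ann$x)
  got <- seg$labels$data[lin]
  want <- ph$labels$classes[ann$class]
  expect_equal(unname(got), unname(want))
  # ... and the whole noiseless phantom segments exactly
  expect_equal(dice_coefficient(class_mask(seg$labels, "wall"),
                                class_mask(ph$labels, "wall")), 1.0)
})

test_that("training and prediction are deterministic and reload-stable", {
  ph <- noiseless_phantom()
  ann <- sample_annotations(ph$labels, 20, seed = 2)
  m1 <- train_pixel_classifier(ph$volume, ann, seed = 7)
  m2 <- train_pixel_classifier(ph$volume, ann, seed = 7)
  s1 <- classify_volume(m1, ph$volume)
  s2 <- classify_volume(m2, ph$volume)
  expect_identical(s1$prob, s2$prob)
  expect_identical(s1$labels$data, s2$labels$data)

  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m1, f)
  m3 <- readRDS(f)
  s3 <- classify_volume(m3, ph$volume)
  expect_identical(s1$prob, s3$prob)
})

test_that("noisy study-condition phantom segments with Dice >= 0.95", {
  fx <- segmentation_pair()
  for (cl in c("wall", "lumen")) {
    expect_gte(dice_coefficient(class_mask(fx$seg_wt$labels, cl),
                                class_mask(fx$wt$labels, cl)), 0.95)
  }
  # probabilities are normalised at every voxel
  sums <- apply(fx$seg_wt$prob[1:4, 1:8, 1:8, , drop = FALSE], 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("a model transfers across phantoms with the same grey levels", {
  fx <- segmentation_pair()  # model trained on the 0.8 um wild-type phantom
  expect_gte(dice_coefficient(class_mask(fx$seg_mut$labels, "wall"),
                              class_mask(fx$mut$labels, "wall")), 0.9)
})

test_that("segmentation quality degrades monotonically with noise", {
  dices <- fixture("dice_vs_noise", function() {
    mk <- function(ns) {
      sp <- phantom_spec(c(16, 72, 72),
                         cells = list(cell_spec("vessel",
                                                lumen_radius_um = 1,
                                                wall_thickness_um = 0.45)),
                         noise_sigma = ns, seed = 31)
      render_phantom(sp)
    }
    ph0 <- mk(0)
    ann <- sample_annotations(ph0$labels, 200, seed = 5)
    vapply(c(0, 0.1, 0.2, 0.3) * 0.45, function(ns) {
      ph <- mk(ns)
      mdl <- train_pixel_classifier(ph$volume, ann, seed = 9)
      seg <- classify_volume(mdl, ph$volume)
      dice_coefficient(class_mask(seg$labels, "wall"),
                       class_mask(ph$labels, "wall"))
    }, 0)
  })
  expect_true(all(diff(dices) <= 0.01))
})

test_that("annotation preconditions are enforced", {
  ph <- noiseless_phantom()
  few <- sample_annotations(ph$labels, 5, seed = 1)
  expect_error(train_pixel_classifier(ph$volume, few, seed = 1),
               "at least")
  oob <- annotation_set(z = 1e4, y = 1, x = 1, class = "wall")
  expect_error(train_pixel_classifier(ph$volume, oob, seed = 1), "bounds")
})

test_that("thresholding is inclusive and matches two-class argmax", {
  expect_equal(threshold_labels(c(0.2, 0.5, 0.8), 0.5), c(FALSE, TRUE, TRUE))
  x <- matrix(runif(25), 5, 5)
  expect_true(all(threshold_labels(x, min(x) - 1)))
  expect_error(threshold_labels(c(1, NaN), 0.5), "NaN")
  set.seed(8)
  for (i in 1:20) {
    p <- matrix(runif(64), 8, 8)
    p[sample(64, 4)] <- 0.5  # exercise the tie
    argmax <- p >= 1 - p  # two-class argmax, ties to the first class
    expect_identical(threshold_labels(p, 0.5), argmax)
  }
})

test_that("morphological refinement matches a flood-fill component oracle", {
  set.seed(13)
  for (i in 1:5) {
    m <- rand_mask3d(i, 16)
    m[sample(length(m), 12)] <- TRUE  # speckle
    got <- morphological_refine(m, min_component_vox = 10)
    expect_identical(got, oracle_filter_components(m, 10))
  }
})

test_that("refinement removes speckles, keeps bodies, and is idempotent", {
  m <- array(FALSE, c(12, 24, 24))
  body <- rand_mask3d(3, 12)
  m[, 1:12, 1:12] <- body
  m[6, 20, 20] <- TRUE; m[6, 20, 21] <- TRUE; m[6, 21, 20] <- TRUE
  got <- morphological_refine(m, min_component_vox = 10)
  expect_false(any(got[, 13:24, 13:24]))
  expect_identical(got[, 1:12, 1:12], oracle_filter_components(body, 10))

  expect_identical(morphological_refine(array(FALSE, c(4, 4, 4)),
                                        open_radius_vox = 1),
                   array(FALSE, c(4, 4, 4)))

  once <- morphological_refine(m, open_radius_vox = 1, close_radius_vox = 1)
  twice <- morphological_refine(once, open_radius_vox = 1,
                                close_radius_vox = 1)
  expect_identical(once, twice)
  expect_error(morphological_refine(m, open_radius_vox = 100), "extent")
})

test_that("per-slice hole filling closes enclosed lumina only", {
  sp <- phantom_spec(c(4, 48, 48),
                     cells = list(cell_spec("vessel", lumen_radius_um = 0.8,
                                            wall_thickness_um = 0.3)),
                     blur_sigma_nm = 0, noise_sigma = 0)
  lab <- render_phantom(sp)$labels
  wall <- class_mask(lab, "wall")
  filled <- morphological_refine(wall, fill_holes = TRUE)
  expect_true(all(filled[class_mask(lab, "lumen")]))
  expect_false(any(filled[1, 1:3, 1:3]))
})
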