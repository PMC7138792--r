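test_that("a constant tube yields a flat profile at the analytic value", {
  # t = 1.0 um (w = 0.5), b = 5.0 um (L = 2.5): (t/b)^2 = 0.04
  sp <- phantom_spec(c(10, 160, 160),
                     cells = list(cell_spec("vessel", lumen_radius_um = 2.5,
                                            wall_thickness_um = 0.5)),
                     blur_sigma_nm = 0, noise_sigma = 0)
  lab <- render_phantom(sp)$labels
  pr <- implosion_profile(lab, interval_nm = 50)
  tb <- pr$slices$t_over_b_squared
  # z-invariant geometry: every record identical, internally consistent ...
  expect_equal(max(tb) - min(tb), 0)
  expect_equal(tb, (pr$slices$t_um / pr$slices$b_um)^2, tolerance = 1e-12)
  expect_equal(pr$summary$mean, tb[1])
  # ... and at the analytic value
  expect_rel(pr$summary$mean, 0.04, 0.05)
  expect_true(all(diff(pr$slices$height_um) > 0))
})

test_that("the sampling interval controls the slice step", {
  sp <- phantom_spec(c(12, 64, 64),
                     cells = list(cell_spec("vessel", lumen_radius_um = 1,
                                            wall_thickness_um = 0.4)),
                     blur_sigma_nm = 0, noise_sigma = 0)
  lab <- render_phantom(sp)$labels
  expect_equal(nrow(implosion_profile(lab, interval_nm = 50)$slices), 12L)
  expect_equal(nrow(implosion_profile(lab, interval_nm = 100)$slices), 6L)
  expect_error(implosion_profile(lab, cell_id = 5), "unknown cell")
})

test_that("a wall ramp spanning the wild-type range is recovered", {
  # (t/b)^2 runs linearly 0.002 -> 0.100 over the cell height
  L <- 5
  tb <- function(h) 0.002 + (0.100 - 0.002) * h / ((40 - 1) * 48.87 / 1000)
  wf <- function(h) L * sqrt(tb(h))
  sp <- phantom_spec(c(40, 284, 284),
                     cells = list(cell_spec("vessel", lumen_radius_um = L,
                                            wall_thickness_um = wf)),
                     blur_sigma_nm = 0, noise_sigma = 0)
  lab <- render_phantom(sp)$labels
  pr <- implosion_profile(lab, interval_nm = 50)
  expect_rel(pr$summary$min, 0.002, 0.15)
  expect_rel(pr$summary$max, 0.100, 0.15)
})

test_that("(t/b)^2 is invariant under voxel-size refinement", {
  mk <- function(vx, n) {
    sp <- phantom_spec(c(6, n, n), voxel_size_nm = vx,
                       cells = list(cell_spec("vessel", lumen_radius_um = 2,
                                              wall_thickness_um = 0.6)),
                       blur_sigma_nm = 0, noise_sigma = 0)
    implosion_profile(render_phantom(sp)$labels)$summary$mean
  }
  coarse <- mk(97.74, 120)
  fine <- mk(48.87, 240)
  expect_rel(coarse, fine, 0.06)  # one-voxel quantisation at the coarse scale
})

test_that("thickening the wall strictly increases (t/b)^2 at every height", {
  mk <- function(w) {
    sp <- phantom_spec(c(8, 120, 120),
                       cells = list(cell_spec("vessel", lumen_radius_um = 1.8,
                                              wall_thickness_um = w)),
                       blur_sigma_nm = 0, noise_sigma = 0)
    implosion_profile(render_phantom(sp)$labels)$slices$t_over_b_squared
  }
  expect_true(all(mk(0.7) > mk(0.5)))
})

test_that("pits depress the minimum envelope but not the mean statistic", {
  pits <- data.frame(height_um = 0.7, azimuth_rad = pi / 3, radius_um = 0.15)
  mk <- function(p, t_stat = "mean") {
    sp <- phantom_spec(c(30, 120, 120),
                       cells = list(cell_spec("vessel", lumen_radius_um = 1.8,
                                              wall_thickness_um = 0.5,
                                              pits = p)),
                       blur_sigma_nm = 0, noise_sigma = 0)
    implosion_profile(render_phantom(sp)$labels, t_stat = t_stat)
  }
  plain <- mk(NULL)
  pitted <- mk(pits)
  expect_lt(min(pitted$slices$t_min_um), min(plain$slices$t_min_um))
  expect_rel(pitted$summary$mean, plain$summary$mean, 0.1)
  worst <- mk(pits, t_stat = "min")
  expect_lt(min(worst$slices$t_um, na.rm = TRUE),
            min(pitted$slices$t_um, na.rm = TRUE))
})

test_that("end-cap slices with shrunken lumen are excluded from the summary", {
  sp <- phantom_spec(c(12, 100, 100),
                     cells = list(cell_spec("vessel", lumen_radius_um = 1.5,
                                            wall_thickness_um = 0.5)),
                     blur_sigma_nm = 0, noise_sigma = 0)
  lab <- render_phantom(sp)$labels
  # artificially erode the lumen of the two top slices to a sliver
  for (z in 11:12) {
    sl <- matrix(lab$data[z, , ], 100, 100)
    lum <- which(sl == 2L, arr.ind = TRUE)
    keep <- lum[lum[, 1] <= 51 & lum[, 1] >= 49 &
                  lum[, 2] <= 51 & lum[, 2] >= 49, , drop = FALSE]
    sl[sl == 2L] <- 1L
    sl[keep] <- 2L
    lab$data[z, , ] <- sl
  }
  pr <- implosion_profile(lab)
  expect_equal(sum(pr$valid), 10L)
  expect_equal(nrow(pr$slices), 12L)
  expect_false(anyNA(pr$slices$t_um[1:10]))
})

test_that("profile summaries compare groups with printed-average ratios", {
  mkconst <- function(v) {
    sl <- data.frame(height_um = (0:4) * 0.05, t_um = 1, b_um = 1 / sqrt(v),
                     t_over_b_squared = v, t_min_um = 1, t_max_um = 1,
                     b_min_um = 1, lumen_area_vox = 100)
    structure(list(slices = sl, valid = rep(TRUE, 5),
                   summary = list(mean = v, min = v, max = v, n_valid = 5),
                   interval_nm = 50, voxel_size_nm = 48.87),
              class = "implosion_profile")
  }
  # the printed wild-type and mutant averages: ratio below one half
  tab <- summarize_profiles(list(wt = mkconst(0.04), mut = mkconst(0.019)))
  expect_equal(tab$ratio_to_first[2], 0.475)
  expect_lt(tab$ratio_to_first[2], 0.5)
  one <- summarize_profiles(list(mkconst(0.04)))
  expect_null(one$ratio_to_first)
  expect_error(summarize_profiles(list()), "empty")
})

test_that("noisy replicates recover the analytic mean within 10 percent", {
  reps <- fixture("implosion_replicates", function() {
    lapply(c(41, 42, 43), function(seed) {
      sp <- phantom_spec(c(20, 96, 96),
                         cells = list(cell_spec("vessel",
                                                lumen_radius_um = 1.5,
                                                wall_thickness_um = 0.5)),
                         noise_sigma = 0.45 / 4, seed = seed)
      ph <- render_phantom(sp)
      ann <- sample_annotations(ph$labels, 150, seed = seed + 1)
      mdl <- train_pixel_classifier(ph$volume, ann, seed = seed + 2)
      seg <- classify_volume(mdl, ph$volume)
      wall <- morphological_refine(class_mask(seg$labels, "wall"),
                                   min_component_vox = 50)
      lum <- morphological_refine(class_mask(seg$labels, "lumen"),
                                  min_component_vox = 50)
      lab <- label_volume(array(1L * wall + 2L * lum, dim(wall)), 48.87)
      implosion_profile(lab)
    })
  })
  tab <- summarize_profiles(reps)
  analytic <- (2 * 0.5 / (2 * 1.5))^2
  expect_rel(mean(tab$tbsq_mean), analytic, 0.1)
})
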