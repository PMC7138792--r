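#' Specify a synthetic tubular cell
#'
#' Cells are tubes parallel to the z (height) axis with an analytically known
#' lumen radius and wall thickness at every height, so that rendered volumes
#' carry exact per-slice ground truth. The three kinds mirror the tissue
#' types seen in petiole tomograms: vessels (large lumen, thin wall, optional
#' pits and helical thickenings), sclerenchyma fibres (thick wall, small
#' lumen) and parenchyma (thin wall, filled lumen).
#'
#' @param kind `"vessel"`, `"sclerenchyma"` or `"parenchyma"`.
#' @param center_yx_um tube axis position (y,x) in micrometres; default is
#'   the volume centre.
#' @param lumen_radius_um lumen radius in um: a positive number or a function
#'   of height (um) returning one.
#' @param wall_thickness_um wall thickness in um: number or function of
#'   height.
#' @param pits data frame with columns `height_um`, `azimuth_rad`,
#'   `radius_um`: circular perforations through the wall, modelled as
#'   radially-directed cylinders. Pit size in real vessels is not well
#'   constrained; defaults used in examples are order-of-magnitude choices.
#' @param helicoidal optional `list(pitch_um, band_width_um, amplitude_um)`:
#'   a helical wall thickening protruding into the lumen.
#' @return A `cell_spec` object.
#' @export
cell_spec <- function(kind = c("vessel", "sclerenchyma", "parenchyma"),
                      center_yx_um = NULL,
                      lumen_radius_um = NULL,
                      wall_thickness_um = NULL,
                      pits = NULL,
                      helicoidal = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    vessel       = list(lumen = 2.5, wall = 0.8),
    sclerenchyma = list(lumen = 1.0, wall = 1.0),
    parenchyma   = list(lumen = 3.0, wall = 0.3))
  if (is.null(lumen_radius_um)) lumen_radius_um <- defaults$lumen
  if (is.null(wall_thickness_um)) wall_thickness_um <- defaults$wall
  lum_f <- if (is.function(lumen_radius_um)) lumen_radius_um
           else local({ v <- lumen_radius_um; function(h) rep(v, length(h)) })
  wal_f <- if (is.function(wall_thickness_um)) wall_thickness_um
           else local({ v <- wall_thickness_um; function(h) rep(v, length(h)) })
  if (!is.null(pits))
    stopifnot(all(c("height_um", "azimuth_rad", "radius_um") %in%
                    names(pits)))
  structure(list(kind = kind, center_yx_um = center_yx_um,
                 lumen_radius_um = lum_f, wall_thickness_um = wal_f,
                 pits = pits, helicoidal = helicoidal),
            class = "cell_spec")
}

#' Specify a synthetic tissue phantom
#'
#' Defines the geometry and image-formation model of a synthetic tomogram:
#' analytic cell geometry, class grey levels, Gaussian blur emulating finite
#' reconstruction resolution, and i.i.d. Gaussian noise. The default voxel
#' size (48.87 nm) and blur (FWHM 140 nm, sigma 59.45 nm) match the scale of
#' cryo-nanotomography reconstructions of petiole tissue.
#'
#' @param shape_vox integer triple (nz, ny, nx).
#' @param voxel_size_nm isotropic voxel size, nm.
#' @param cells list of [cell_spec()] objects.
#' @param blur_sigma_nm Gaussian blur sigma in nm (0 = none).
#' @param noise_sigma additive Gaussian noise s.d. in grey units (0 = none).
#' @param grey_levels named vector of mean grey per class. Background (air
#'   outside the milled pillar) is darkest, the resin-filled lumen
#'   intermediate, the lignified wall brightest.
#' @param seed integer seed governing all randomness of the render.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape_vox, voxel_size_nm = 48.87,
                         cells = list(cell_spec("vessel")),
                         blur_sigma_nm = 140 / (2 * sqrt(2 * log(2))),
                         noise_sigma = 0,
                         grey_levels = c(background = 0, wall = 1,
                                         lumen = 0.45),
                         seed = 1L) {
  stopifnot(length(shape_vox) == 3, all(shape_vox >= 1),
            voxel_size_nm > 0, blur_sigma_nm >= 0, noise_sigma >= 0,
            all(c("background", "wall", "lumen") %in% names(grey_levels)))
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  structure(list(shape_vox = as.integer(shape_vox),
                 voxel_size_nm = voxel_size_nm, cells = cells,
                 blur_sigma_nm = blur_sigma_nm, noise_sigma = noise_sigma,
                 grey_levels = grey_levels, seed = as.integer(seed)),
            class = "phantom_spec")
}

# label one slice of one cell; returns integer matrix 0/1/2 painted into `lab`
.paint_cell_slice <- function(lab, cell, h_um, ygrid_um, xgrid_um, cyx) {
  L <- cell$lumen_radius_um(h_um)
  W <- cell$wall_thickness_um(h_um)
  if (L <= 0 || W <= 0) stop("lumen radius and wall thickness must be > 0")
  dy <- outer(ygrid_um - cyx[1], rep(1, length(xgrid_um)))
  dx <- outer(rep(1, length(ygrid_um)), xgrid_um - cyx[2])
  D <- sqrt(dy^2 + dx^2)

  Lmap <- matrix(L, nrow(D), ncol(D))
  if (!is.null(cell$helicoidal)) {
    hp <- cell$helicoidal
    theta <- atan2(dy, dx)
    phase <- (2 * pi * h_um / hp$pitch_um) %% (2 * pi)
    dang <- abs(((theta - phase + pi) %% (2 * pi)) - pi)
    band <- (D * dang) < (hp$band_width_um / 2)
    Lmap[band] <- pmax(L - hp$amplitude_um, 0.1 * L)
  }

  # helicoidal thickening protrudes into the lumen: the outer wall boundary
  # stays at L + W while the lumen shrinks inside the band
  lum <- D <= Lmap
  wall <- !lum & D <= (L + W)

  if (!is.null(cell$pits) && nrow(cell$pits) > 0) {
    theta <- atan2(dy, dx)
    for (p in seq_len(nrow(cell$pits))) {
      pit <- cell$pits[p, ]
      dang <- abs(((theta - pit$azimuth_rad + pi) %% (2 * pi)) - pi)
      inpit <- wall & sqrt((h_um - pit$height_um)^2 + (D * dang)^2) <
        pit$radius_um
      wall[inpit] <- FALSE
      lum[inpit] <- TRUE
    }
  }
  lab[wall] <- 1L
  lab[lum] <- 2L
  lab
}

#' Render a phantom volume with ground truth
#'
#' The label volume is assigned by exact analytic geometry at voxel centres
#' (blur/noise-free ground truth). The grey volume applies the class grey
#' levels, then Gaussian blur, then additive Gaussian noise seeded from
#' `spec$seed`. The returned ground-truth table gives, per slice, the true
#' lumen radius and wall thickness, the double wall thickness `t = 2w`, the
#' lumen diameter `b = 2r` and the implosion-resistance parameter `(t/b)^2`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([volume()]), `labels`
#'   ([label_volume()]) and `truth` (data frame, one row per slice per cell).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_vox
  vx_um <- spec$voxel_size_nm / 1000
  ygrid <- (seq_len(d[2]) - 1) * vx_um
  xgrid <- (seq_len(d[3]) - 1) * vx_um
  heights <- (seq_len(d[1]) - 1) * vx_um

  lab <- array(0L, d)
  truth <- list()
  for (ci in seq_along(spec$cells)) {
    cell <- spec$cells[[ci]]
    cyx <- cell$center_yx_um
    # default axis: volume centre snapped to the nearest voxel centre, so
    # that the analytic lumen radius is exactly representable on the grid
    if (is.null(cyx))
      cyx <- round(c(max(ygrid) / 2, max(xgrid) / 2) / vx_um) * vx_um
    L <- cell$lumen_radius_um(heights)
    W <- cell$wall_thickness_um(heights)
    amp <- if (is.null(cell$helicoidal)) 0 else cell$helicoidal$amplitude_um
    rmax <- max(L + W)
    if (cyx[1] - rmax < 0 || cyx[1] + rmax > max(ygrid) ||
        cyx[2] - rmax < 0 || cyx[2] + rmax > max(xgrid))
      stop("cell geometry exceeds volume bounds")
    for (z in seq_len(d[1])) {
      sl <- .paint_cell_slice(matrix(lab[z, , ], d[2], d[3]), cell,
                              heights[z], ygrid, xgrid, cyx)
      lab[z, , ] <- sl
    }
    truth[[ci]] <- data.frame(
      cell = ci, slice = seq_len(d[1]) - 1L, height_um = heights,
      lumen_radius_um = L, wall_thickness_um = W,
      t_um = 2 * W, b_um = 2 * L,
      t_over_b_squared = (W / L)^2)
  }
  truth <- do.call(rbind, truth)

  grey <- array(spec$grey_levels[["background"]], d)
  grey[lab == 1L] <- spec$grey_levels[["wall"]]
  grey[lab == 2L] <- spec$grey_levels[["lumen"]]
  if (spec$blur_sigma_nm > 0)
    grey <- array(cpp_gauss3d(as.vector(grey), d,
                              spec$blur_sigma_nm / spec$voxel_size_nm), d)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    grey <- grey + array(rnorm(prod(d), 0, spec$noise_sigma), d)
  }
  list(volume = volume(grey, spec$voxel_size_nm, units_tag = "grey"),
       labels = label_volume(lab, spec$voxel_size_nm),
       truth = truth)
}

#' Render a half-dataset pair for resolution estimation
#'
#' Emulates the standard practice of reconstructing two tomograms from
#' interleaved halves of the projections: the two volumes share the identical
#' noiseless (blurred) signal and differ only by independent Gaussian noise
#' realisations drawn with `seeds[1]` and `seeds[2]`.
#'
#' @param spec a [phantom_spec()]; its own `noise_sigma`/`seed` are ignored.
#' @param noise_sigma noise s.d. applied independently to each half.
#' @param seeds two integer seeds, default `c(seed, seed + 1)` from the spec.
#' @return list of two [volume()] objects.
#' @export
render_halfpair <- function(spec, noise_sigma,
                            seeds = c(spec$seed, spec$seed + 1L)) {
  stopifnot(inherits(spec, "phantom_spec"), noise_sigma >= 0,
            length(seeds) == 2)
  spec0 <- spec
  spec0$noise_sigma <- 0
  base <- render_phantom(spec0)$volume
  halves <- lapply(seeds, function(s) {
    x <- base$data
    if (noise_sigma > 0) {
      set.seed(s)
      x <- x + array(rnorm(length(x), 0, noise_sigma), dim(x))
    }
    volume(x, spec$voxel_size_nm, units_tag = "grey")
  })
  names(halves) <- c("half1", "half2")
  halves
}
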