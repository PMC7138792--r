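# 2D squared EDT of a logical matrix (distance to nearest FALSE pixel)
.edt_sq_2d <- function(m) {
  matrix(cpp_edt_sq(as.vector(m), c(dim(m), 1L)), nrow(m), ncol(m))
}

# border pixels: foreground with at least one 4-neighbour background
# (pixels outside the image count as background)
.border_pixels <- function(m) {
  pad <- function(a, dr, dc) {
    n <- nrow(a); p <- ncol(a)
    ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
    ci <- pmin(pmax(seq_len(p) + dc, 1L), p)
    out <- a[ri, ci, drop = FALSE]
    if (dr == 1) out[n, ] <- FALSE
    if (dr == -1) out[1, ] <- FALSE
    if (dc == 1) out[, p] <- FALSE
    if (dc == -1) out[, 1] <- FALSE
    out
  }
  m & !(pad(m, 1, 0) & pad(m, -1, 0) & pad(m, 0, 1) & pad(m, 0, -1))
}

#' Locate the lumen centre of a 2D slice mask
#'
#' The centre is the foreground pixel where the Euclidean distance transform
#' attains its maximum, i.e. the deepest interior point. When several pixels
#' tie, the centroid of the argmax set is snapped to the nearest argmax pixel
#' (deterministic and symmetric under rotation by multiples of 90 degrees).
#'
#' @param slice_mask logical matrix (y,x).
#' @return integer vector `c(y, x)` (1-based indices).
#' @export
lumen_center <- function(slice_mask) {
  stopifnot(is.matrix(slice_mask), is.logical(slice_mask))
  if (!any(slice_mask)) stop("empty mask")
  if (any(slice_mask[1, ]) || any(slice_mask[nrow(slice_mask), ]) ||
      any(slice_mask[, 1]) || any(slice_mask[, ncol(slice_mask)]))
    stop("foreground touches the slice border; distances would be censored")
  ed <- .edt_sq_2d(slice_mask)
  mx <- max(ed)
  arg <- which(ed == mx, arr.ind = TRUE)
  if (nrow(arg) == 1) return(as.integer(arg[1, ]))
  cen <- colMeans(arg)
  d2 <- (arg[, 1] - cen[1])^2 + (arg[, 2] - cen[2])^2
  best <- which(d2 == min(d2))
  # final tie-break: lexicographically smallest (row, col)
  arg <- arg[best, , drop = FALSE]
  arg <- arg[order(arg[, 1], arg[, 2]), , drop = FALSE]
  as.integer(arg[1, ])
}

#' Distances from the lumen centre to every border pixel
#'
#' The radius distribution of the lumen at one height: the Euclidean distance
#' from the centre pixel to each border pixel (foreground pixel with a
#' 4-connected background neighbour), in micrometres.
#'
#' @param slice_mask logical matrix (y,x).
#' @param center integer `c(y, x)` as returned by [lumen_center()].
#' @param voxel_size_nm voxel size in nm.
#' @return numeric vector of radii (um), one per border pixel.
#' @export
lumen_radii <- function(slice_mask, center, voxel_size_nm) {
  stopifnot(is.matrix(slice_mask))
  if (!slice_mask[center[1], center[2]])
    stop("center is not a foreground pixel")
  b <- which(.border_pixels(slice_mask), arr.ind = TRUE)
  sqrt((b[, 1] - center[1])^2 + (b[, 2] - center[2])^2) *
    voxel_size_nm / 1000
}

#' Lumen diameter from the radius distribution
#'
#' Default `"max_radius"` reads the maximum conduit diameter literally as
#' twice the largest centre-to-border distance; `"mean_radius"` gives twice
#' the mean radius as a gentler alternative.
#'
#' @param radii numeric vector from [lumen_radii()] (um).
#' @param mode `"max_radius"` (default) or `"mean_radius"`.
#' @return list with `b_um` (diameter) and `b_min_um` (twice the minimum
#'   radius).
#' @export
lumen_diameter <- function(radii, mode = c("max_radius", "mean_radius")) {
  mode <- match.arg(mode)
  if (length(radii) == 0) stop("empty radii")
  b <- switch(mode, max_radius = 2 * max(radii),
              mean_radius = 2 * mean(radii))
  list(b_um = b, b_min_um = 2 * min(radii))
}

#' Medial-axis wall thickness of a 2D wall mask
#'
#' Extracts the medial axis of the wall by topology-preserving thinning and
#' reads, at every medial pixel, twice the distance-transform value (distance
#' to the nearest background pixel, approximately half the local wall
#' thickness), in micrometres.
#'
#' @param slice_wall_mask logical matrix (y,x).
#' @param voxel_size_nm voxel size in nm.
#' @return numeric vector of wall thickness values (um), one per medial
#'   pixel.
#' @export
wall_medial_thickness <- function(slice_wall_mask, voxel_size_nm) {
  stopifnot(is.matrix(slice_wall_mask))
  if (!any(slice_wall_mask)) stop("empty wall mask")
  vx_um <- voxel_size_nm / 1000
  if (sum(slice_wall_mask) == 1) return(vx_um)
  sk <- matrix(cpp_thin2d(as.vector(slice_wall_mask),
                          nrow(slice_wall_mask), ncol(slice_wall_mask)),
               nrow(slice_wall_mask), ncol(slice_wall_mask))
  ed <- .edt_sq_2d(slice_wall_mask)
  if (!any(sk)) {
    # tiny blob eroded away by thinning: fall back to the EDT maximum pixel
    sk <- ed == max(ed) & slice_wall_mask
  }
  2 * sqrt(ed[sk]) * vx_um
}

#' Measure one transverse slice of a cell
#'
#' Combines the lumen and wall measurements of a single (y,x) slice into the
#' per-height record used by the implosion-resistance profile: lumen centre,
#' radius distribution and diameter `b`, and the medial-axis wall thickness
#' distribution summarised as the double wall thickness `t` (per-slice
#' statistic, default twice the mean single-wall thickness) with min/max
#' envelopes.
#'
#' @param lumen_mask,wall_mask logical matrices (y,x) for one cell.
#' @param voxel_size_nm voxel size, nm.
#' @param height_um height of the slice (um).
#' @param b_mode diameter mode, see [lumen_diameter()].
#' @param t_stat `"mean"` (default) or `"min"`: statistic of the single-wall
#'   thickness multiset doubled into `t`. `"min"` gives the worst-case wall.
#' @return one-row data frame with columns `height_um, t_um, b_um,
#'   t_over_b_squared, t_min_um, t_max_um, b_min_um, lumen_area_vox`. If the
#'   slice has no lumen or no wall the measurement fields are `NA` (an
#'   explicit missing record, never zeros).
#' @export
measure_slice <- function(lumen_mask, wall_mask, voxel_size_nm, height_um,
                          b_mode = "max_radius",
                          t_stat = c("mean", "min")) {
  t_stat <- match.arg(t_stat)
  empty <- data.frame(height_um = height_um, t_um = NA_real_,
                      b_um = NA_real_, t_over_b_squared = NA_real_,
                      t_min_um = NA_real_, t_max_um = NA_real_,
                      b_min_um = NA_real_,
                      lumen_area_vox = sum(lumen_mask))
  if (!any(lumen_mask) || !any(wall_mask)) return(empty)
  ctr <- tryCatch(lumen_center(lumen_mask), error = function(e) NULL)
  if (is.null(ctr)) return(empty)
  radii <- lumen_radii(lumen_mask, ctr, voxel_size_nm)
  bb <- lumen_diameter(radii, mode = b_mode)
  wt <- wall_medial_thickness(wall_mask, voxel_size_nm)
  t_um <- switch(t_stat, mean = 2 * mean(wt), min = 2 * min(wt))
  data.frame(height_um = height_um, t_um = t_um, b_um = bb$b_um,
             t_over_b_squared = (t_um / bb$b_um)^2,
             t_min_um = 2 * min(wt), t_max_um = 2 * max(wt),
             b_min_um = bb$b_min_um, lumen_area_vox = sum(lumen_mask))
}
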