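#' Implosion-resistance profile along the cellular height
#'
#' Samples transverse slices of a segmented cell at a fixed physical interval
#' and assembles the per-height implosion-resistance parameter
#' `(t/b)^2`, where `t` is the double wall thickness and `b` the maximum
#' lumen diameter, both measured per slice by distance-transform morphometry
#' ([measure_slice()]). The conduit's resistance to collapse under negative
#' sap pressure grows with `(t/b)^2`.
#'
#' Cells are identified as 26-connected components of the wall-plus-lumen
#' foreground, numbered by decreasing voxel count; `cell_id` selects one.
#' Slices without a measurable lumen yield explicit missing records. End-cap
#' slices, where the lumen area falls below `endcap_frac` of its median over
#' measured slices, are recorded but excluded from the summary statistics, as
#' is usual for avoiding boundary artefacts. The summary mean is the
#' unweighted mean of `(t/b)^2` over the remaining valid slices.
#'
#' @param labels a [label_volume()] with wall and lumen classes.
#' @param cell_id which cell (component) to profile, 1 = largest.
#' @param interval_nm physical sampling interval along the height; slices are
#'   taken every `max(1, round(interval_nm / voxel_size_nm))` planes.
#' @param b_mode,t_stat statistic choices passed to [measure_slice()];
#'   `t_stat = "min"` switches the per-slice `t` to the worst-case minimum.
#' @param endcap_frac end-cap exclusion threshold on relative lumen area.
#' @return An `implosion_profile`: list with `slices` (per-slice data frame),
#'   `valid` (logical, slices entering the summary), `summary`
#'   (`mean`/`min`/`max` of `(t/b)^2` and `n_valid`), `interval_nm`,
#'   `voxel_size_nm`.
#' @export
implosion_profile <- function(labels, cell_id = 1L, interval_nm = 50,
                              b_mode = "max_radius", t_stat = "mean",
                              endcap_frac = 0.25) {
  stopifnot(inherits(labels, "label_volume"), interval_nm > 0)
  vx <- labels$voxel_size_nm
  d <- dim(labels$data)
  fg <- labels$data != labels$classes[["background"]]
  comp <- array(cpp_label_components(as.vector(fg), d, 26L), d)
  ncomp <- max(comp)
  if (ncomp == 0) stop("no cells in label volume")
  sizes <- tabulate(comp[comp > 0], ncomp)
  ord <- order(sizes, decreasing = TRUE)
  if (cell_id < 1 || cell_id > ncomp) stop("unknown cell id ", cell_id)
  cell <- comp == ord[cell_id]

  wall <- class_mask(labels, "wall") & cell
  lumen <- class_mask(labels, "lumen") & cell
  if (!any(wall) || !any(lumen))
    stop("selected cell lacks wall or lumen voxels")

  step <- max(1L, as.integer(round(interval_nm / vx)))
  zs <- seq(1L, d[1], by = step)
  recs <- lapply(zs, function(z)
    measure_slice(matrix(lumen[z, , ], d[2], d[3]),
                  matrix(wall[z, , ], d[2], d[3]),
                  vx, (z - 1) * vx / 1000,
                  b_mode = b_mode, t_stat = t_stat))
  slices <- do.call(rbind, recs)

  measured <- !is.na(slices$t_over_b_squared)
  if (!any(measured)) stop("no valid slices")
  med_area <- median(slices$lumen_area_vox[measured])
  valid <- measured & slices$lumen_area_vox >= endcap_frac * med_area
  if (!any(valid)) stop("no valid slices")
  tb <- slices$t_over_b_squared[valid]
  structure(list(slices = slices, valid = valid,
                 summary = list(mean = mean(tb), min = min(tb),
                                max = max(tb), n_valid = sum(valid)),
                 interval_nm = interval_nm, voxel_size_nm = vx),
            class = "implosion_profile")
}

#' @export
print.implosion_profile <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<implosion_profile> %d slices (%d valid), interval %g nm\n",
    nrow(x$slices), s$n_valid, x$interval_nm))
  cat(sprintf("  (t/b)^2: mean %.4f, range [%.4f, %.4f]\n",
              s$mean, s$min, s$max))
  invisible(x)
}

#' Compare implosion-resistance profiles across cells or genotypes
#'
#' @param profiles list of [implosion_profile()] objects (optionally named).
#' @return data frame with one row per profile: valid slice count, mean, min
#'   and max of `(t/b)^2`, and (when more than one profile is given) the
#'   ratio of each mean to the first profile's mean.
#' @export
summarize_profiles <- function(profiles) {
  if (inherits(profiles, "implosion_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, TRUE, "implosion_profile")))
  nm <- names(profiles)
  if (is.null(nm)) nm <- paste0("profile", seq_along(profiles))
  tab <- data.frame(
    profile = nm,
    n_valid = vapply(profiles, function(p) p$summary$n_valid, 1),
    tbsq_mean = vapply(profiles, function(p) p$summary$mean, 1),
    tbsq_min = vapply(profiles, function(p) p$summary$min, 1),
    tbsq_max = vapply(profiles, function(p) p$summary$max, 1))
  if (length(profiles) > 1)
    tab$ratio_to_first <- tab$tbsq_mean / tab$tbsq_mean[1]
  tab
}
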