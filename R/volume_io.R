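#' Construct a 3D volume
#'
#' A `volume` is a 3D scalar field with isotropic voxel size. The first array
#' axis (z) is the cellular height axis; transverse slices are (y,x) planes.
#' Physical position of voxel index `i` (0-based) is `i * voxel_size_nm`.
#'
#' @param data numeric 3D array (axis order z,y,x). A matrix is promoted to a
#'   single-slice volume.
#' @param voxel_size_nm positive isotropic voxel size in nanometres.
#' @param units_tag one of `"grey"`, `"phase_rad"`, `"delta"`,
#'   `"electron_density_e_per_A3"`.
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_size_nm,
                   units_tag = c("grey", "phase_rad", "delta",
                                 "electron_density_e_per_A3")) {
  units_tag <- match.arg(units_tag)
  if (is.matrix(data)) dim(data) <- c(1L, dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z,y,x)")
  if (anyNA(data)) stop("volume contains NaN/NA voxels")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a single positive number")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 units_tag = units_tag),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d (z,y,x), voxel %.4g nm, units '%s'\n",
              d[1], d[2], d[3], x$voxel_size_nm, x$units_tag))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a label volume
#'
#' Integer class field over the same grid as a [volume()]. Default classes
#' follow the wall/lumen segmentation convention:
#' 0 = background, 1 = wall, 2 = lumen.
#'
#' @param data integer 3D array of class ids.
#' @param voxel_size_nm positive isotropic voxel size in nanometres.
#' @param classes named integer vector mapping class name to id.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxel_size_nm,
                         classes = c(background = 0L, wall = 1L, lumen = 2L)) {
  if (is.matrix(data)) dim(data) <- c(1L, dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z,y,x)")
  storage.mode(data) <- "integer"
  if (anyNA(data)) stop("label volume contains NA voxels")
  if (!all(unique(as.vector(data)) %in% classes))
    stop("label volume contains values outside the class mapping")
  if (voxel_size_nm <= 0) stop("`voxel_size_nm` must be positive")
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 classes = classes),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), voxel %.4g nm\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  tab <- table(factor(x$data, levels = x$classes,
                      labels = names(x$classes)))
  print(tab)
  invisible(x)
}

#' Extract the binary mask of one class
#'
#' @param labels a [label_volume()].
#' @param class class name (e.g. `"wall"`, `"lumen"`).
#' @return logical 3D array.
#' @export
class_mask <- function(labels, class) {
  stopifnot(inherits(labels, "label_volume"))
  if (!class %in% names(labels$classes))
    stop("unknown class '", class, "'")
  labels$data == labels$classes[[class]]
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume or label volume to a multi-page TIFF
#'
#' Integer-valued data (and all label volumes) are stored bit-exactly as
#' uint8/uint16. Floating-point data are stored as 32-bit samples after affine
#' scaling to \[0,1\]; the scaling is recorded in a JSON sidecar
#' (`<path>.json`) together with `voxel_size_nm` and `units_tag`, so the
#' round-trip is exact to storage precision (2^-32 of the data range).
#'
#' @param vol a [volume()] or [label_volume()].
#' @param path output file path (`.tif`); the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  is_label <- inherits(vol, "label_volume")
  if (!is_label && !inherits(vol, "volume"))
    stop("`vol` must be a volume or label_volume")
  d <- dim(vol$data)
  x <- vol$data
  meta <- list(voxel_size_nm = vol$voxel_size_nm,
               dim = as.integer(d))
  if (is_label) {
    meta$kind <- "label_volume"
    meta$classes <- as.list(vol$classes)
    maxv <- max(x, 1L)
    bits <- if (maxv < 256) 8L else 16L
    denom <- 2^bits - 1
    meta$storage <- list(type = "uint", bits = bits, scale = denom,
                         offset = 0)
    pages <- lapply(seq_len(d[1]), function(z) matrix(x[z, , ] / denom,
                                                      d[2], d[3]))
  } else {
    meta$kind <- "volume"
    meta$units_tag <- vol$units_tag
    if (is.integer(x) || all(x == round(x) & x >= 0 & x <= 65535)) {
      bits <- if (max(x) < 256) 8L else 16L
      denom <- 2^bits - 1
      meta$storage <- list(type = "uint", bits = bits, scale = denom,
                           offset = 0)
      pages <- lapply(seq_len(d[1]), function(z) matrix(x[z, , ] / denom,
                                                        d[2], d[3]))
    } else {
      lo <- min(x); hi <- max(x)
      scale <- if (hi > lo) hi - lo else 1
      meta$storage <- list(type = "scaled_float", bits = 32L,
                           scale = scale, offset = lo)
      pages <- lapply(seq_len(d[1]),
                      function(z) matrix((x[z, , ] - lo) / scale, d[2], d[3]))
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = meta$storage$bits,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF
#'
#' Reads a TIFF stack written by [write_volume()] (using its JSON sidecar for
#' voxel size, units and exact de-scaling), or any plain multi-page TIFF, in
#' which case `voxel_size_nm` must be supplied explicitly: quantitative
#' outputs are derived from it and it is never silently assumed.
#'
#' @param path TIFF file path.
#' @param voxel_size_nm voxel size in nm; overrides/replaces sidecar metadata.
#' @return a [volume()] or, for stacks written from one, a [label_volume()].
#' @export
read_volume <- function(path, voxel_size_nm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- NULL
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  if (!is.null(meta) && !is.null(meta$voxel_size_nm)) {
    if (length(meta$voxel_size_nm) > 1 &&
        length(unique(meta$voxel_size_nm)) > 1)
      stop("anisotropic voxel metadata: pipeline assumes isotropic voxels")
    vs <- meta$voxel_size_nm[1]
  } else vs <- NULL
  if (!is.null(voxel_size_nm)) vs <- voxel_size_nm
  if (is.null(vs))
    stop("voxel size not in metadata; pass `voxel_size_nm` explicitly")

  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]])[1:2])
  x <- array(0, d)
  for (z in seq_len(d[1])) x[z, , ] <- pages[[z]][, , drop = TRUE]
  if (anyNA(x)) stop("volume contains NaN voxels")

  if (!is.null(meta) && !is.null(meta$storage)) {
    st <- meta$storage
    if (identical(st$type, "uint")) {
      x <- round(x * st$scale)
    } else {
      x <- x * st$scale + st$offset
    }
  }
  if (!is.null(meta) && identical(meta$kind, "label_volume")) {
    storage.mode(x) <- "integer"
    return(label_volume(x, vs, classes = unlist(meta$classes)))
  }
  units <- if (!is.null(meta) && !is.null(meta$units_tag)) meta$units_tag
           else "grey"
  if (is.null(meta) || identical(meta$storage$type, "uint"))
    storage.mode(x) <- if (max(x) <= .Machine$integer.max && all(x == round(x)))
      "integer" else "double"
  volume(x, vs, units_tag = units)
}

#' Write an implosion profile to CSV
#'
#' One row per analysed slice, ordered by height; columns `height_um, t_um,
#' b_um, t_over_b_squared, t_min_um, t_max_um, b_min_um`. Slices without a
#' measurable lumen keep their row with empty (missing) measurement fields.
#'
#' @param profile an `implosion_profile` (see [implosion_profile()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "implosion_profile"))
  tab <- profile$slices
  if (nrow(tab) == 0) stop("empty profile")
  cols <- c("height_um", "t_um", "b_um", "t_over_b_squared",
            "t_min_um", "t_max_um", "b_min_um")
  tab <- tab[order(tab$height_um), cols]
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an implosion profile table written by [write_profile_table()]
#'
#' @param path CSV path.
#' @return data frame of per-slice records.
#' @export
read_profile_table <- function(path) {
  read.csv(path, na.strings = c("NA", ""))
}
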