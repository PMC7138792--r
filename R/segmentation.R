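# shift a 3D array by one voxel along an axis, clamping at the edge
.shift1 <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + dir
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx))
}

#' Compute per-voxel classification features
#'
#' The feature bank used for trainable pixel classification, all computed in
#' 3D: raw grey value, Gaussian-smoothed grey at several scales, gradient
#' magnitude and Laplacian of the finest smoothed volume, and local variance
#' (Gaussian-windowed second moment minus squared first moment).
#'
#' @param vol a [volume()].
#' @param sigmas Gaussian scales in voxels.
#' @param var_sigma window scale (voxels) for the local variance.
#' @return numeric matrix, one row per voxel (column-major voxel order), with
#'   named feature columns.
#' @export
pixel_features <- function(vol, sigmas = c(1, 2, 4), var_sigma = 2) {
  stopifnot(inherits(vol, "volume"))
  d <- dim(vol$data)
  x <- vol$data
  feats <- list(grey = as.vector(x))
  smooth <- list()
  for (s in sigmas) {
    g <- array(cpp_gauss3d(as.vector(x), d, s), d)
    smooth[[as.character(s)]] <- g
    feats[[sprintf("gauss_s%g", s)]] <- as.vector(g)
  }
  g1 <- smooth[[1]]
  gz <- (.shift1(g1, 1, 1L) - .shift1(g1, 1, -1L)) / 2
  gy <- (.shift1(g1, 2, 1L) - .shift1(g1, 2, -1L)) / 2
  gx <- (.shift1(g1, 3, 1L) - .shift1(g1, 3, -1L)) / 2
  feats$grad_mag <- as.vector(sqrt(gz^2 + gy^2 + gx^2))
  lap <- .shift1(g1, 1, 1L) + .shift1(g1, 1, -1L) +
         .shift1(g1, 2, 1L) + .shift1(g1, 2, -1L) +
         .shift1(g1, 3, 1L) + .shift1(g1, 3, -1L) - 6 * g1
  feats$laplacian <- as.vector(lap)
  m1 <- array(cpp_gauss3d(as.vector(x), d, var_sigma), d)
  m2 <- array(cpp_gauss3d(as.vector(x^2), d, var_sigma), d)
  feats$local_var <- pmax(as.vector(m2 - m1^2), 0)
  do.call(cbind, feats)
}

#' Build an annotation set
#'
#' Sparse manual (or, on phantoms, simulated) voxel annotations used to train
#' the pixel classifier.
#'
#' @param z,y,x 1-based voxel indices.
#' @param class character class names (`"background"`, `"wall"`, `"lumen"`).
#' @return data frame of class `annotation_set`.
#' @export
annotation_set <- function(z, y, x, class) {
  ann <- data.frame(z = as.integer(z), y = as.integer(y), x = as.integer(x),
                    class = as.character(class))
  structure(ann, class = c("annotation_set", "data.frame"))
}

#' Sample annotations from a ground-truth label volume
#'
#' Draws a fixed number of voxel annotations per class uniformly at random,
#' emulating the sparse manual annotation step on data with known labels.
#'
#' @param labels a [label_volume()].
#' @param n_per_class annotations per class.
#' @param seed integer seed.
#' @param classes class names to annotate (default: all present).
#' @return an [annotation_set()].
#' @export
sample_annotations <- function(labels, n_per_class, seed = 1L,
                               classes = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(classes))
    classes <- names(labels$classes)[labels$classes %in%
                                       unique(as.vector(labels$data))]
  d <- dim(labels$data)
  set.seed(seed)
  out <- lapply(classes, function(cl) {
    idx <- which(labels$data == labels$classes[[cl]])
    if (length(idx) == 0) stop("class '", cl, "' absent from labels")
    pick <- idx[sample.int(length(idx), min(n_per_class, length(idx)))]
    ai <- arrayInd(pick, d)
    annotation_set(ai[, 1], ai[, 2], ai[, 3], cl)
  })
  do.call(rbind, out)
}

.check_annotations <- function(ann, d, min_per_class) {
  if (any(ann$z < 1 | ann$z > d[1] | ann$y < 1 | ann$y > d[2] |
          ann$x < 1 | ann$x > d[3]))
    stop("annotation indices out of bounds")
  cnt <- table(ann$class)
  if (any(cnt < min_per_class))
    stop("each class needs at least ", min_per_class,
         " annotated voxels; got: ",
         paste(names(cnt), cnt, sep = "=", collapse = ", "))
}

#' Train a pixel classifier from sparse annotations
#'
#' Random-forest ensemble on the 3D feature bank of [pixel_features()],
#' mirroring the trainable-segmentation approach of annotating a handful of
#' voxels per class and classifying the remaining volume automatically. The
#' trained model can be applied to other volumes of the same modality (e.g. a
#' model trained on a wild-type tomogram applied to a mutant one).
#'
#' @param vol training [volume()].
#' @param annotations an [annotation_set()].
#' @param config list: `num_trees` (default 100), `sigmas`, `var_sigma`,
#'   `min_per_class` (default 10).
#' @param seed integer seed; training is deterministic given it.
#' @return a `pixel_classifier` object (serializable with `saveRDS()`).
#' @export
train_pixel_classifier <- function(vol, annotations,
                                   config = list(), seed = 1L) {
  stopifnot(inherits(vol, "volume"))
  cfg <- modifyList(list(num_trees = 100L, sigmas = c(1, 2, 4),
                         var_sigma = 2, min_per_class = 10L), config)
  d <- dim(vol$data)
  .check_annotations(annotations, d, cfg$min_per_class)
  feats <- pixel_features(vol, cfg$sigmas, cfg$var_sigma)
  lin <- annotations$z + d[1] * (annotations$y - 1 +
                                   d[2] * (annotations$x - 1))
  train <- as.data.frame(feats[lin, , drop = FALSE])
  class_names <- sort(unique(annotations$class))
  train$.class <- factor(annotations$class, levels = class_names)
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = train,
    num.trees = cfg$num_trees, probability = TRUE,
    seed = seed, num.threads = 1)
  structure(list(forest = forest, config = cfg, classes = class_names,
                 n_features = ncol(feats)),
            class = "pixel_classifier")
}

#' Classify every voxel of a volume
#'
#' Applies a trained [train_pixel_classifier()] model, returning per-class
#' probabilities (summing to 1 at every voxel) and the argmax label volume.
#' Ties are broken toward the lowest class id.
#'
#' @param model a `pixel_classifier`.
#' @param vol a [volume()] of the same modality as the training volume.
#' @return list with `prob` (4D array z,y,x,class, dimnames on class) and
#'   `labels` (a [label_volume()]).
#' @export
classify_volume <- function(model, vol) {
  stopifnot(inherits(model, "pixel_classifier"), inherits(vol, "volume"))
  feats <- pixel_features(vol, model$config$sigmas, model$config$var_sigma)
  if (ncol(feats) != model$n_features)
    stop("feature mismatch between model and volume")
  pred <- predict(model$forest, data = as.data.frame(feats),
                  num.threads = 1)$predictions
  all_classes <- c(background = 0L, wall = 1L, lumen = 2L)
  ids <- all_classes[model$classes]
  if (anyNA(ids))
    ids <- setNames(seq_along(model$classes) - 1L, model$classes)
  ord <- order(ids)
  pred <- pred[, model$classes[ord], drop = FALSE]
  ids <- ids[ord]
  amax <- max.col(pred, ties.method = "first")
  d <- dim(vol$data)
  lab <- array(as.integer(ids[amax]), d)
  prob <- array(pred, c(d, ncol(pred)),
                dimnames = list(NULL, NULL, NULL, names(ids)))
  list(prob = prob,
       labels = label_volume(lab, vol$voxel_size_nm,
                             classes = all_classes))
}

#' Threshold a scalar field into a binary mask
#'
#' @param field numeric array (probability or grey field) or [volume()].
#' @param threshold inclusive threshold: mask is `field >= threshold`.
#' @return logical array.
#' @export
threshold_labels <- function(field, threshold) {
  if (inherits(field, "volume")) field <- field$data
  if (anyNA(field)) stop("field contains NaN")
  field >= threshold
}

#' Morphological refinement of a binary mask
#'
#' Refines segmentation masks with exact Euclidean-ball morphology derived
#' from the distance transform: opening then closing with spherical
#' structuring elements, removal of small 26-connected components, and
#' optional per-slice hole filling.
#'
#' @param mask logical 2D/3D array.
#' @param open_radius_vox,close_radius_vox structuring-ball radii in voxels
#'   (0 = skip).
#' @param min_component_vox drop 26-connected components smaller than this.
#' @param fill_holes fill background holes slice-by-slice (4-connected
#'   background regions not touching the slice border).
#' @return refined logical array of the same shape.
#' @export
morphological_refine <- function(mask, open_radius_vox = 0,
                                 close_radius_vox = 0,
                                 min_component_vox = 0,
                                 fill_holes = FALSE) {
  stopifnot(is.logical(mask))
  d <- dim(mask)
  if (is.null(d)) stop("mask must be an array")
  if (length(d) == 2) d <- c(d, 1L)
  if (max(open_radius_vox, close_radius_vox) >= max(d))
    stop("structuring radius exceeds volume extent")

  erode <- function(m, r) array(cpp_edt_sq(as.vector(m), d) > r^2 &
                                  as.vector(m), dim(mask))
  dilate <- function(m, r) array(cpp_edt_sq(as.vector(!m), d) <= r^2,
                                 dim(mask))
  out <- mask
  if (open_radius_vox > 0)
    out <- dilate(erode(out, open_radius_vox), open_radius_vox)
  if (close_radius_vox > 0)
    out <- erode(dilate(out, close_radius_vox), close_radius_vox)
  if (min_component_vox > 0) {
    lab <- cpp_label_components(as.vector(out), d, 26L)
    if (max(lab) > 0) {
      sizes <- tabulate(lab)
      keep <- which(sizes >= min_component_vox)
      out <- array(lab %in% keep, dim(mask))
    }
  }
  if (fill_holes) {
    if (length(dim(mask)) == 2) {
      out <- .fill_holes_2d(out)
    } else {
      for (z in seq_len(dim(out)[1]))
        out[z, , ] <- .fill_holes_2d(out[z, , ])
    }
  }
  out
}

.fill_holes_2d <- function(m) {
  d2 <- dim(m)
  bg <- cpp_label_components(as.vector(!m), c(d2, 1L), 6L)
  bg <- matrix(bg, d2[1], d2[2])
  border <- unique(c(bg[1, ], bg[d2[1], ], bg[, 1], bg[, d2[2]]))
  border <- border[border > 0]
  m | (bg > 0 & !(bg %in% border))
}

#' Dice similarity coefficient between two masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|A∩B| / (|A|+|B|)`; 1 if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
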