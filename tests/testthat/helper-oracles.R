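# Brute-force reference implementations, independent of the package's
# distance-transform code paths. All operate on logical arrays/matrices.

# squared Euclidean distance (voxel centres) to the nearest background voxel
oracle_edt_sq <- function(mask) {
  d <- dim(mask)
  out <- numeric(length(mask))
  fg <- which(mask)
  bg <- which(!mask)
  if (length(bg) == 0) {
    out[fg] <- Inf
    return(array(out, d))
  }
  bgc <- arrayInd(bg, d)
  chunk <- max(1L, floor(2e6 / length(bg)))
  for (s in seq(1, length(fg), by = chunk)) {
    idx <- fg[s:min(s + chunk - 1, length(fg))]
    fgc <- arrayInd(idx, d)
    d2 <- 0
    for (k in seq_along(d))
      d2 <- d2 + outer(fgc[, k], bgc[, k], `-`)^2
    out[idx] <- apply(d2, 1, min)
  }
  array(out, d)
}

# largest-inscribed-sphere local thickness: enumerate every foreground
# centre's EDT sphere and propagate the maximal squared radius to all voxels
# strictly inside it
oracle_local_thickness_sq <- function(mask) {
  d <- dim(mask)
  r2 <- oracle_edt_sq(mask)
  fg <- which(mask)
  fgc <- arrayInd(fg, d)
  out <- numeric(length(mask))
  for (i in seq_along(fg)) {
    rc2 <- r2[fg[i]]
    d2 <- 0
    for (k in seq_along(d)) d2 <- d2 + (fgc[, k] - fgc[i, k])^2
    cover <- fg[d2 < rc2]
    out[cover] <- pmax(out[cover], rc2)
  }
  array(out, d)
}

# border pixels: foreground with a 4-neighbour background (or image edge)
oracle_border <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && m[i, j]
  out <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j]) next
    if (!at(i - 1, j) || !at(i + 1, j) || !at(i, j - 1) || !at(i, j + 1))
      out[i, j] <- TRUE
  }
  out
}

# EDT-maximum centre with the centroid-snap tie-break
oracle_center <- function(m) {
  ed <- oracle_edt_sq(m)
  arg <- which(ed == max(ed), arr.ind = TRUE)
  if (nrow(arg) == 1) return(as.integer(arg[1, ]))
  cen <- colMeans(arg)
  d2 <- (arg[, 1] - cen[1])^2 + (arg[, 2] - cen[2])^2
  arg <- arg[d2 == min(d2), , drop = FALSE]
  arg <- arg[order(arg[, 1], arg[, 2]), , drop = FALSE]
  as.integer(arg[1, ])
}

# min distance from given pixels to the background, by exhaustive scan
oracle_min_dist_to_bg <- function(m, pix) {
  bg <- which(!m, arr.ind = TRUE)
  vapply(seq_len(nrow(pix)), function(i)
    sqrt(min((bg[, 1] - pix[i, 1])^2 + (bg[, 2] - pix[i, 2])^2)), 0)
}

# connected-component small-object removal by flood fill (26-connectivity)
oracle_filter_components <- function(mask, min_vox) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  a <- array(mask, d)
  seen <- array(FALSE, d)
  out <- array(FALSE, d)
  for (s in which(a & !seen)) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      ci <- arrayInd(cur, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        p <- ci + c(dz, dy, dx)
        if (any(p < 1) || any(p > d)) next
        lin <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (a[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
    if (length(comp) >= min_vox) out[comp] <- TRUE
  }
  array(out, dim(mask))
}

# random single-component 2D blob away from the border
rand_blob2d <- function(seed, n = 48) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  yy <- row(m); xx <- col(m)
  k <- sample(2:5, 1)
  cy0 <- runif(1, n * 0.35, n * 0.65)
  cx0 <- runif(1, n * 0.35, n * 0.65)
  for (i in seq_len(k)) {
    r <- runif(1, 3, 8)
    cy <- min(max(cy0 + runif(1, -6, 6), r + 3), n - r - 3)
    cx <- min(max(cx0 + runif(1, -6, 6), r + 3), n - r - 3)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  # keep the largest 8-connected component
  lab <- matrix(xylometry:::cpp_label_components(as.vector(m),
                                                c(dim(m), 1L), 26L),
                n, n)
  if (max(lab) > 1) m <- lab == which.max(tabulate(lab))
  m
}

# random 3D mask: union of a few balls, may touch the volume border
rand_mask3d <- function(seed, n = 20) {
  set.seed(seed)
  a <- array(FALSE, c(n, n, n))
  idx <- arrayInd(seq_along(a), dim(a))
  for (i in seq_len(sample(1:3, 1))) {
    r <- runif(1, 2, 6)
    c3 <- runif(3, 1, n)
    a <- a | array((idx[, 1] - c3[1])^2 + (idx[, 2] - c3[2])^2 +
                     (idx[, 3] - c3[3])^2 <= r^2, dim(a))
  }
  if (!any(a)) a[n %/% 2, n %/% 2, n %/% 2] <- TRUE
  a
}
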