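.fft_freqs <- function(n) {
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  k / n
}

#' Fourier shell correlation between two volumes
#'
#' Correlation of the Fourier transforms of two independent reconstructions
#' of the same object over spherical shells of spatial frequency:
#' `FSC(k) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)` per shell.
#' Shells are one Fourier voxel wide by default, indexed up to the Nyquist
#' frequency `1 / (2 voxel)`.
#'
#' @param v1,v2 [volume()] objects of identical shape and voxel size.
#' @param shell_width shell width in Fourier voxels (of the largest axis).
#' @param taper apply a cosine (Tukey) taper over the outer 10% of each axis
#'   before transforming, to suppress wrap-around edge artefacts. Default
#'   off.
#' @return An `fsc_curve`: data frame with per-shell `freq_per_nm` (shell
#'   centre), `fsc`, `n` (voxel count) and `threshold` (half-bit), plus
#'   attributes `voxel_size_nm` and `resolution_nm` (see
#'   [resolution_from_fsc()], computed lazily as `NA` here).
#' @export
fsc_curve <- function(v1, v2, shell_width = 1, taper = FALSE) {
  stopifnot(inherits(v1, "volume"), inherits(v2, "volume"))
  if (!identical(dim(v1$data), dim(v2$data)))
    stop("volumes have different shapes")
  if (abs(v1$voxel_size_nm - v2$voxel_size_nm) > 1e-9)
    stop("volumes have different voxel sizes")
  d <- dim(v1$data)
  a <- v1$data
  b <- v2$data
  if (taper) {
    w <- .tukey3d(d, 0.1)
    a <- a * w
    b <- b * w
  }
  F1 <- fft(a)
  F2 <- fft(b)

  nref <- max(d)
  q <- sqrt(outer(outer(.fft_freqs(d[1])^2, .fft_freqs(d[2])^2, `+`),
                  .fft_freqs(d[3])^2, `+`))
  ring <- as.integer(round(q * nref / shell_width))
  keep <- q <= 0.5 + 1e-12
  ridx <- ring[keep] + 1L

  cross <- Re(F1 * Conj(F2))[keep]
  p1 <- (Mod(F1)^2)[keep]
  p2 <- (Mod(F2)^2)[keep]
  num <- tapply(cross, ridx, sum)
  d1 <- tapply(p1, ridx, sum)
  d2 <- tapply(p2, ridx, sum)
  n <- as.integer(table(ridx))
  shells <- as.integer(names(num))
  fsc <- as.numeric(num) / sqrt(as.numeric(d1) * as.numeric(d2))
  fsc[!is.finite(fsc)] <- 0
  freq <- (shells - 1L) * shell_width / nref / v1$voxel_size_nm
  out <- data.frame(freq_per_nm = freq, fsc = fsc, n = n,
                    threshold = half_bit_threshold(n))
  structure(out, class = c("fsc_curve", "data.frame"),
            voxel_size_nm = v1$voxel_size_nm)
}

.tukey3d <- function(d, frac) {
  w1 <- function(n) {
    t <- seq(0, 1, length.out = n)
    w <- rep(1, n)
    lo <- t < frac
    hi <- t > 1 - frac
    w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / frac - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + frac) / frac)))
    w
  }
  outer(outer(w1(d[1]), w1(d[2])), w1(d[3]))
}

#' Half-bit threshold curve
#'
#' The half-bit information threshold of van Heel and Schatz as a function of
#' the number of independent Fourier voxels per shell:
#' `T(n) = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))`,
#' clipped at 1. A resolution claim is supported where the FSC exceeds this
#' curve.
#'
#' @param n_per_shell positive integer voxel counts.
#' @return numeric threshold per shell, in (0, 1].
#' @export
half_bit_threshold <- function(n_per_shell) {
  if (any(n_per_shell <= 0)) stop("shell voxel counts must be positive")
  s <- sqrt(n_per_shell)
  pmin((0.2071 + 1.9102 / s) / (1.2071 + 0.9102 / s), 1)
}

#' Resolution from an FSC curve
#'
#' The resolution is the inverse of the spatial frequency at which the FSC
#' first falls below the half-bit threshold, with linear interpolation of
#' `FSC - threshold` between neighbouring shells. The DC shell is excluded
#' from the search. Returns `NA` when the curve never crosses.
#'
#' @param curve an [fsc_curve()].
#' @return resolution in nm, or `NA_real_`.
#' @export
resolution_from_fsc <- function(curve) {
  stopifnot(inherits(curve, "fsc_curve"))
  cu <- curve[curve$freq_per_nm > 0, ]
  g <- cu$fsc - cu$threshold
  below <- which(g < 0)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(1 / cu$freq_per_nm[1])
  f0 <- cu$freq_per_nm[i - 1]
  f1 <- cu$freq_per_nm[i]
  fc <- f0 + (f1 - f0) * g[i - 1] / (g[i - 1] - g[i])
  1 / fc
}

#' Photon-energy constants for electron-density conversion
#'
#' @param energy_keV photon energy in keV.
#' @return list with `energy_keV`, `lambda_A` (wavelength, from
#'   `12.398419 keV.A / E`) and `r_e_A` (classical electron radius,
#'   `2.8179403e-5` Angstrom).
#' @export
density_conversion <- function(energy_keV) {
  stopifnot(energy_keV > 0)
  list(energy_keV = energy_keV,
       lambda_A = 12.398419 / energy_keV,
       r_e_A = 2.8179403e-5)
}

#' Convert a refractive-index-decrement volume to electron density
#'
#' For hard X-rays far from absorption edges the refractive-index decrement
#' `delta` maps linearly to electron density:
#' `n_e = 2 pi delta / (r_e lambda^2)` (electrons per cubic Angstrom).
#'
#' @param vol a [volume()] with `units_tag = "delta"`.
#' @param conv a [density_conversion()].
#' @return a [volume()] with `units_tag = "electron_density_e_per_A3"`.
#' @export
delta_to_electron_density <- function(vol, conv) {
  stopifnot(inherits(vol, "volume"))
  if (vol$units_tag != "delta")
    stop("expected units_tag 'delta', got '", vol$units_tag, "'")
  ne <- 2 * pi * vol$data / (conv$r_e_A * conv$lambda_A^2)
  volume(ne, vol$voxel_size_nm, units_tag = "electron_density_e_per_A3")
}

#' Inverse of [delta_to_electron_density()]
#'
#' @param vol a [volume()] with `units_tag = "electron_density_e_per_A3"`.
#' @param conv a [density_conversion()].
#' @return a [volume()] with `units_tag = "delta"`.
#' @export
electron_density_to_delta <- function(vol, conv) {
  stopifnot(inherits(vol, "volume"))
  if (vol$units_tag != "electron_density_e_per_A3")
    stop("expected units_tag 'electron_density_e_per_A3', got '",
         vol$units_tag, "'")
  delta <- vol$data * conv$r_e_A * conv$lambda_A^2 / (2 * pi)
  volume(delta, vol$voxel_size_nm, units_tag = "delta")
}

#' Convert reconstructed phase to refractive-index decrement
#'
#' Helper for the sign convention `phi = 2 pi delta dx / lambda` per voxel of
#' thickness `dx`: `delta = phi lambda / (2 pi dx)` with `dx` the voxel size.
#'
#' @param vol a [volume()] with `units_tag = "phase_rad"`.
#' @param conv a [density_conversion()].
#' @return a [volume()] with `units_tag = "delta"`.
#' @export
phase_to_delta <- function(vol, conv) {
  stopifnot(inherits(vol, "volume"))
  if (vol$units_tag != "phase_rad")
    stop("expected units_tag 'phase_rad', got '", vol$units_tag, "'")
  dx_A <- vol$voxel_size_nm * 10
  delta <- vol$data * conv$lambda_A / (2 * pi * dx_A)
  volume(delta, vol$voxel_size_nm, units_tag = "delta")
}
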