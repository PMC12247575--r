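#' @name morphology
#' @title Euclidean morphology in millimetres
#'
#' @description Binary dilation and erosion use a Euclidean ball structuring
#' element expressed in millimetres, so anisotropic grids behave correctly:
#' a voxel offset belongs to the ball when its physical distance is within
#' the requested radius (inclusive). Everything outside the volume is
#' treated as background.
NULL

# centred FFT convolution with zero padding; kernel dims must be odd
fft_convolve3 <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  stopifnot(length(dx) == 3, all(dk %% 2 == 1))
  half <- (dk - 1L) %/% 2L
  dp <- mapply(function(n, k) stats::nextn(n + k - 1L, c(2L, 3L, 5L)), dx, dk)
  px <- array(0, dp)
  px[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  pk <- array(0, dp)
  wrap <- function(m, n) ((seq.int(-m, m) %% n) + 1L)
  pk[wrap(half[1], dp[1]), wrap(half[2], dp[2]), wrap(half[3], dp[3])] <- kernel
  conv <- Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) / prod(dp)
  conv[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])]
}

# Euclidean ball structuring element (0/1 array) for a radius in mm
ball_kernel <- function(radius_mm, voxel_size) {
  m <- pmax(0L, as.integer(floor(radius_mm / voxel_size + 1e-9)))
  off <- lapply(1:3, function(i) seq.int(-m[i], m[i]) * voxel_size[i])
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+")
  array(as.numeric(d2 <= radius_mm^2 + 1e-9), dim = 2L * m + 1L)
}

#' Dilate a binary mask by a Euclidean radius in mm
#'
#' @param mask logical 3-D array.
#' @param radius_mm dilation radius in millimetres (>= 0; 0 is the identity).
#' @param voxel_size mm per axis (length 3).
#' @return Logical array: voxels within `radius_mm` of any mask voxel.
#' @export
dilate_mm <- function(mask, radius_mm, voxel_size) {
  stopifnot(radius_mm >= 0, length(voxel_size) == 3)
  if (radius_mm == 0 || !any(mask)) return(mask)
  k <- ball_kernel(radius_mm, voxel_size)
  if (all(dim(k) == 1L)) return(mask)
  array(fft_convolve3(mask * 1, k) > 0.5, dim = dim(mask))
}

#' Erode a binary mask by a Euclidean radius in mm
#'
#' The volume boundary counts as background, so voxels whose ball extends
#' outside the array are removed. An erosion that empties the mask returns
#' the empty result with a warning so the caller can decide what to do.
#'
#' @inheritParams dilate_mm
#' @return Logical array: voxels whose whole `radius_mm` ball is inside the
#'   mask.
#' @export
erode_mm <- function(mask, radius_mm, voxel_size) {
  stopifnot(radius_mm >= 0, length(voxel_size) == 3)
  if (radius_mm == 0) return(mask)
  if (!any(mask)) return(mask)
  k <- ball_kernel(radius_mm, voxel_size)
  if (all(dim(k) == 1L)) return(mask)
  counts <- fft_convolve3(mask * 1, k)
  out <- array(counts >= sum(k) - 0.5, dim = dim(mask))
  if (any(mask) && !any(out))
    warning("erode_mm: erosion emptied the mask")
  out
}

#' Meningeal shell ROI around a brain mask
#'
#' Reproduces the standard construction of an extra-cerebral meninges ROI:
#' the brain mask is dilated by `thickness_mm` (Euclidean, in mm) and the
#' original mask subtracted, leaving a shell of that thickness circumscribing
#' the brain.
#'
#' @param brain_mask logical 3-D array.
#' @param thickness_mm shell thickness in mm (> 0); the classic choice is 5.
#' @param voxel_size mm per axis.
#' @return Logical array, disjoint from `brain_mask`.
#' @export
make_meninges_shell <- function(brain_mask, thickness_mm = 5, voxel_size) {
  stopifnot(thickness_mm > 0)
  if (!any(brain_mask)) {
    warning("make_meninges_shell: empty brain mask, returning empty shell")
    return(brain_mask)
  }
  dilate_mm(brain_mask, thickness_mm, voxel_size) & !brain_mask
}

#' Gaussian blur at a physical FWHM
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis, expressed in millimetres and truncated at 4 sigma. Zero padding is
#' used at the edges; a FWHM of 0 on every axis is the identity.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm FWHM in mm, scalar or per-axis vector of length 3.
#' @param voxel_size mm per axis.
#' @return Blurred array of the same dimensions.
#' @export
psf_blur <- function(volume, fwhm_mm, voxel_size) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3)
  stopifnot(all(fwhm_mm >= 0), length(voxel_size) == 3)
  if (all(fwhm_mm == 0)) return(volume)
  k <- gaussian_kernel(fwhm_mm, voxel_size)
  fft_convolve3(volume, k)
}

# normalized, truncated (4 sigma) separable Gaussian kernel
gaussian_kernel <- function(fwhm_mm, voxel_size) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  k1 <- lapply(1:3, function(i) {
    if (sigma[i] == 0) return(1)
    m <- max(1L, as.integer(ceiling(4 * sigma[i] / voxel_size[i])))
    g <- exp(-((seq.int(-m, m) * voxel_size[i])^2) / (2 * sigma[i]^2))
    g / sum(g)
  })
  outer(outer(k1[[1]], k1[[2]]), k1[[3]])
}
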