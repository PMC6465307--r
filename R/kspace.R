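# Spectral helpers shared by the forward model and the reconstruction chain.
# All FFTs are periodic on the native grid (no zero padding); spatial
# frequencies are in cycles/mm, scaled per axis by the voxel size.

#' @keywords internal
fft_freq <- function(n, d = 1) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / (n * d)
}

# Inverse FFT, real part, normalized
ifft_re <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# Arrays of k-coordinates (cycles/mm) broadcast to the full grid
kspace_grids <- function(grid_shape, voxel_size_mm) {
  stopifnot(length(grid_shape) == 3, length(voxel_size_mm) == 3)
  kx <- fft_freq(grid_shape[1], voxel_size_mm[1])
  ky <- fft_freq(grid_shape[2], voxel_size_mm[2])
  kz <- fft_freq(grid_shape[3], voxel_size_mm[3])
  list(
    kx = array(rep(kx, times = grid_shape[2] * grid_shape[3]), dim = grid_shape),
    ky = array(rep(rep(ky, each = grid_shape[1]), times = grid_shape[3]), dim = grid_shape),
    kz = array(rep(kz, each = grid_shape[1] * grid_shape[2]), dim = grid_shape)
  )
}

#' Unit dipole kernel in k-space
#'
#' Builds the k-space dipole kernel `D(k) = 1/3 - kz^2 / |k|^2` relating a
#' susceptibility distribution (in ppm) to the induced resonance-frequency
#' offset (in ppm of B0) along the main field. The undefined value at the
#' k-space origin is set to 0, i.e. the spatial mean of the susceptibility is
#' unobservable and all reconstructed values are relative.
#'
#' @param grid_shape integer vector of length 3.
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm.
#' @param b0_axis which grid axis is parallel to B0 (default 3, the slice
#'   axis of an axial acquisition).
#' @return A real array of dimension `grid_shape` with values in
#'   `[-2/3, 1/3]` and `D(0) = 0`.
#' @export
dipole_kernel <- function(grid_shape, voxel_size_mm = c(0.86, 0.86, 1.5),
                          b0_axis = 3) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape <= 0))
    stop("grid_shape must be three positive integers")
  if (!b0_axis %in% 1:3) stop("b0_axis must be 1, 2 or 3")
  kg <- kspace_grids(grid_shape, voxel_size_mm)
  kpar <- switch(b0_axis, kg$kx, kg$ky, kg$kz)
  k2 <- kg$kx^2 + kg$ky^2 + kg$kz^2
  D <- 1 / 3 - kpar^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Forward dipole field of a susceptibility distribution
#'
#' Computes the field perturbation (ppm of B0) induced by a susceptibility
#' volume (ppm) as the k-space product with the dipole kernel. Linear in the
#' input; a uniform susceptibility offset produces zero field (`D(0) = 0`).
#'
#' @param chi 3D array of susceptibility in ppm.
#' @param kernel dipole kernel from [dipole_kernel()] with matching dimension.
#' @return 3D array, field map in ppm of B0.
#' @export
forward_field <- function(chi, kernel) {
  if (any(!is.finite(chi))) stop("chi contains non-finite values")
  if (!identical(dim(chi), dim(kernel))) stop("chi and kernel shapes differ")
  ifft_re(kernel * stats::fft(chi))
}

# k-space Laplacian multiplier: -(2*pi)^2 * |k|^2
laplace_multiplier <- function(grid_shape, voxel_size_mm) {
  kg <- kspace_grids(grid_shape, voxel_size_mm)
  -(2 * pi)^2 * (kg$kx^2 + kg$ky^2 + kg$kz^2)
}

# Structuring / smoothing elements built on wrapped physical distance from
# the grid origin, so they can be applied by circular FFT convolution.
wrapped_distance2 <- function(grid_shape, voxel_size_mm) {
  ax <- function(n, d) {
    i <- 0:(n - 1)
    (pmin(i, n - i) * d)^2
  }
  dx2 <- ax(grid_shape[1], voxel_size_mm[1])
  dy2 <- ax(grid_shape[2], voxel_size_mm[2])
  dz2 <- ax(grid_shape[3], voxel_size_mm[3])
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# Normalized spherical kernel of radius r_mm (sum 1) and its FFT
smv_kernel_fft <- function(grid_shape, voxel_size_mm, radius_mm) {
  d2 <- wrapped_distance2(grid_shape, voxel_size_mm)
  sph <- array(as.numeric(d2 <= radius_mm^2), dim = grid_shape)
  n <- sum(sph)
  if (n == 0) stop("spherical kernel radius smaller than one voxel")
  stats::fft(sph / n)
}
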