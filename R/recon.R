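# Reconstruction of apparent susceptibility from wrapped, high-pass
# filtered phase: mask erosion -> Laplacian unwrapping -> field scaling ->
# V-SHARP background removal -> iLSQR dipole inversion. The whole chain is
# deterministic.

#' Reconstruction parameters
#'
#' @param erosion_radius_mm brain-mask erosion radius in mm (default 3).
#' @param vsharp_max_radius_mm largest spherical-mean-value kernel radius
#'   (default 12 mm); radii descend from it to the smallest voxel size in
#'   steps of one (smallest) voxel.
#' @param vsharp_tsvd_threshold truncation threshold for the V-SHARP
#'   deconvolution (default 0.05).
#' @param ilsqr_tolerance relative-residual stopping tolerance of the LSQR
#'   iterations (default 0.01).
#' @param ilsqr_max_iter iteration cap (default 50).
#' @param acq an [acquisition_params()] used to scale phase to field.
#' @return Object of class `recon_params`.
#' @export
recon_params <- function(erosion_radius_mm = 3.0,
                         vsharp_max_radius_mm = 12.0,
                         vsharp_tsvd_threshold = 0.05,
                         ilsqr_tolerance = 0.01,
                         ilsqr_max_iter = 50L,
                         acq = acquisition_params()) {
  if (vsharp_max_radius_mm <= 0) stop("vsharp_max_radius_mm must be positive")
  if (ilsqr_tolerance <= 0) stop("ilsqr_tolerance must be positive")
  structure(list(erosion_radius_mm = erosion_radius_mm,
                 vsharp_max_radius_mm = vsharp_max_radius_mm,
                 vsharp_tsvd_threshold = vsharp_tsvd_threshold,
                 ilsqr_tolerance = ilsqr_tolerance,
                 ilsqr_max_iter = as.integer(ilsqr_max_iter),
                 acq = acq),
            class = "recon_params")
}

vsharp_radii <- function(max_radius_mm, voxel_size_mm) {
  step <- min(voxel_size_mm)
  r <- seq(max_radius_mm, step, by = -step)
  r[r >= step]
}

#' Erode a binary mask with an ellipsoidal structuring element
#'
#' 3-D erosion respecting anisotropic voxels: a voxel survives only if the
#' ellipsoid of the given physical radius around it lies entirely inside the
#' input mask. Implemented by circular FFT convolution; masks should not
#' touch the grid edges.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param radius_mm erosion radius in mm (0 returns the input).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return Logical array, a subset of the input mask.
#' @export
erode_mask <- function(mask, radius_mm, voxel_size_mm) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (radius_mm <= 0) return(mask)
  d2 <- wrapped_distance2(dim(mask), voxel_size_mm)
  se <- array(as.numeric(d2 <= radius_mm^2), dim = dim(mask))
  cnt <- sum(se)
  conv <- ifft_re(stats::fft(se) * stats::fft(array(as.numeric(mask), dim(mask))))
  out <- mask & (conv >= cnt - 0.5)
  if (!any(out))
    stop(sprintf("erosion with radius %.2f mm leaves an empty mask", radius_mm))
  out
}

#' Laplacian phase unwrapping
#'
#' Solves `lap(phi_u) = cos(phi) * lap(sin(phi)) - sin(phi) * lap(cos(phi))`
#' spectrally, with the zero-frequency component of the inverse Laplacian set
#' to 0. The result is a continuous phase whose in-mask gradients match the
#' true phase up to the removed harmonic/DC content; any global constant is
#' irrelevant after downstream CSF referencing.
#'
#' @param wrapped_phase 3D array in `[-pi, pi)`.
#' @param mask logical 3D array (used for validity checks; the solve itself
#'   is global/spectral).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return Unwrapped phase array (radians).
#' @export
laplacian_unwrap <- function(wrapped_phase, mask, voxel_size_mm) {
  if (!any(mask)) stop("mask is empty")
  dims <- dim(wrapped_phase)
  L <- laplace_multiplier(dims, voxel_size_mm)
  lap <- function(f) ifft_re(L * stats::fft(f))
  s <- sin(wrapped_phase); cph <- cos(wrapped_phase)
  rhs <- cph * lap(s) - s * lap(cph)
  Linv <- 1 / L
  Linv[L == 0] <- 0
  ifft_re(Linv * stats::fft(rhs))
}

#' Convert phase to a field map in ppm
#'
#' Inverse of [field_to_phase()]: `field = phi / (gamma * B0 * TE) * 1e6`.
#'
#' @param unwrapped_phase 3D phase array in radians.
#' @param acq an [acquisition_params()].
#' @return Field map in ppm of B0.
#' @export
phase_to_field <- function(unwrapped_phase, acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (acq$TE_s == 0) stop("TE must be nonzero")
  unwrapped_phase / (acq$gamma_rad_per_s_per_T * acq$B0_tesla * acq$TE_s) * 1e6
}

#' V-SHARP background field removal
#'
#' Variable-kernel spherical-mean-value filtering: for each voxel the
#' largest kernel radius whose sphere fits inside the mask is used to apply
#' the `(delta - rho_r)` filter, which annihilates fields that are harmonic
#' inside the mask (i.e. generated by sources outside it). The filtered
#' field is then deconvolved by the largest-radius kernel with a truncated
#' inverse. The valid output region is the mask eroded by the largest
#' radius.
#'
#' @param field 3D field map (ppm), finite inside `mask`.
#' @param mask logical 3D brain mask.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param max_radius_mm largest kernel radius (default 12).
#' @param tsvd_threshold truncation threshold for the deconvolution
#'   (default 0.05).
#' @return List with `local_field` (ppm, zero outside `valid_mask`) and
#'   `valid_mask`.
#' @export
vsharp <- function(field, mask, voxel_size_mm, max_radius_mm = 12,
                   tsvd_threshold = 0.05) {
  dims <- dim(field)
  mask <- array(as.logical(mask), dim = dims)
  if (any(!is.finite(field[mask]))) stop("field is not finite inside the mask")
  radii <- vsharp_radii(max_radius_mm, voxel_size_mm)
  f0 <- array(0, dims); f0[mask] <- field[mask]
  F0 <- stats::fft(f0)
  comp <- array(0, dims)
  assigned <- array(FALSE, dims)
  S_max <- NULL
  valid <- NULL
  for (r in radii) {
    er <- tryCatch(erode_mask(mask, r, voxel_size_mm), error = function(e) NULL)
    if (is.null(er)) {
      if (r == radii[1])
        stop(sprintf("V-SHARP radius %.1f mm exceeds the mask extent", r))
      next
    }
    Sr <- smv_kernel_fft(dims, voxel_size_mm, r)
    if (r == radii[1]) { S_max <- Sr; valid <- er }
    Hr <- f0 - ifft_re(Sr * F0)
    sel <- er & !assigned
    comp[sel] <- Hr[sel]
    assigned <- assigned | er
  }
  C <- 1 - S_max
  Cinv <- array(0i, dims)
  keep <- Mod(C) > tsvd_threshold
  Cinv[keep] <- 1 / C[keep]
  tmp <- array(0, dims); tmp[assigned] <- comp[assigned]
  local <- ifft_re(Cinv * stats::fft(tmp))
  out <- array(0, dims)
  out[valid] <- local[valid]
  list(local_field = out, valid_mask = valid)
}

# Matrix-free LSQR (Paige & Saunders) on the masked dipole system
lsqr_solve <- function(Aop, Atop, b, tol, max_iter) {
  u <- b
  beta <- sqrt(sum(u^2))
  if (beta == 0) return(list(x = array(0, dim(b)), iters = 0L, converged = TRUE))
  u <- u / beta
  v <- Atop(u)
  alpha <- sqrt(sum(v^2))
  v <- v / alpha
  w <- v
  x <- array(0, dim(b))
  phibar <- beta; rhobar <- alpha
  b0 <- beta
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    u <- Aop(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- Atop(u) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    iters <- it
    if (phibar / b0 < tol) { converged <- TRUE; break }
  }
  list(x = x, iters = iters, converged = converged)
}

#' iLSQR dipole inversion
#'
#' Solves the inverse problem from local field to susceptibility source by
#' iterative least squares on the masked dipole system, followed by one
#' streaking-suppression pass in which the poorly conditioned k-space region
#' near the dipole cone is replaced by the spectrum of a thresholded
#' fast (truncated k-space division) solution.
#'
#' @param local_field 3D local field map in ppm (background removed).
#' @param valid_mask logical mask of reliable voxels.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param tolerance LSQR relative-residual tolerance (default 0.01).
#' @param max_iter LSQR iteration cap (default 50).
#' @param cone_threshold `|D|` below which k-space is treated as the dipole
#'   cone (default 0.1).
#' @param tkd_threshold truncation level of the fast solution (default 0.15).
#' @param b0_axis B0 axis (default 3).
#' @return Object of class `susceptibility_map`: list with `values` (ppm,
#'   zero outside `valid_mask`), `valid_mask`, `converged`, `iterations`,
#'   `provenance`.
#' @export
ilsqr <- function(local_field, valid_mask, voxel_size_mm,
                  tolerance = 0.01, max_iter = 50L,
                  cone_threshold = 0.1, tkd_threshold = 0.15, b0_axis = 3) {
  if (any(!is.finite(local_field))) stop("local_field contains non-finite values")
  dims <- dim(local_field)
  M <- array(as.numeric(valid_mask), dims)
  D <- dipole_kernel(dims, voxel_size_mm, b0_axis)
  f <- M * local_field
  Aop <- function(x) M * ifft_re(D * stats::fft(M * x))
  Atop <- function(y) M * ifft_re(D * stats::fft(M * y))  # D real, symmetric
  sol <- lsqr_solve(Aop, Atop, f, tolerance, max_iter)
  if (!sol$converged)
    warning(sprintf("iLSQR did not reach tolerance %.3g in %d iterations; returning best iterate",
                    tolerance, max_iter))
  chi <- sol$x
  # streaking-correction pass: replace the dipole-cone spectrum with the
  # spectrum of a truncated-k-division solution of the same field
  Dt <- ifelse(abs(D) >= tkd_threshold, D, sign(D) * tkd_threshold)
  Dt_inv <- ifelse(Dt == 0, 0, 1 / Dt)
  chi_fast <- M * ifft_re(Dt_inv * stats::fft(f))
  cone <- abs(D) < cone_threshold
  Xk <- stats::fft(chi)
  Xk[cone] <- stats::fft(chi_fast)[cone]
  chi <- M * ifft_re(Xk)
  structure(list(values = chi, valid_mask = array(as.logical(valid_mask), dims),
                 converged = sol$converged, iterations = sol$iters,
                 provenance = list(tolerance = tolerance, max_iter = max_iter,
                                   cone_threshold = cone_threshold,
                                   tkd_threshold = tkd_threshold,
                                   voxel_size_mm = voxel_size_mm)),
            class = "susceptibility_map")
}

#' @export
print.susceptibility_map <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[x$valid_mask]
  cat("Apparent susceptibility map\n")
  cat(sprintf("  grid: %d x %d x %d; %d valid voxels\n", d[1], d[2], d[3],
              sum(x$valid_mask)))
  cat(sprintf("  chi in valid mask: median %.4f ppm, range [%.4f, %.4f]\n",
              stats::median(v), min(v), max(v)))
  if (!is.null(x$converged))
    cat(sprintf("  inversion: %d LSQR iterations, %s\n", x$iterations,
                ifelse(x$converged, "converged", "NOT converged")))
  invisible(x)
}

#' Full reconstruction chain
#'
#' Runs erosion, Laplacian unwrapping, phase-to-field scaling, V-SHARP and
#' iLSQR on a (synthetic or loaded) acquisition. Deterministic: identical
#' inputs and parameters give identical output.
#'
#' @param acquisition an `swi_acquisition` (from [simulate_acquisition()])
#'   or a list with `phase_hpf` (or `phase`), `magnitude`, a brain mask in
#'   `truth$brain_mask` or `brain_mask`, and `voxel_size_mm`.
#' @param params a [recon_params()].
#' @return A `susceptibility_map` with provenance recording all parameters.
#' @export
qsm_reconstruct <- function(acquisition, params = recon_params()) {
  stopifnot(inherits(params, "recon_params"))
  phase <- if (!is.null(acquisition$phase_hpf)) acquisition$phase_hpf
  else acquisition$phase
  mask <- if (!is.null(acquisition$truth$brain_mask)) acquisition$truth$brain_mask
  else acquisition$brain_mask
  vox <- acquisition$voxel_size_mm
  if (is.null(phase) || is.null(mask) || is.null(vox))
    stop("acquisition must provide phase, a brain mask and voxel_size_mm")
  mask_e <- erode_mask(mask, params$erosion_radius_mm, vox)
  phi_u <- laplacian_unwrap(phase, mask_e, vox)
  field <- phase_to_field(phi_u, params$acq)
  vs <- vsharp(field, mask_e, vox, params$vsharp_max_radius_mm,
               params$vsharp_tsvd_threshold)
  chi <- ilsqr(vs$local_field, vs$valid_mask, vox,
               tolerance = params$ilsqr_tolerance,
               max_iter = params$ilsqr_max_iter)
  chi$provenance <- c(chi$provenance,
                      list(erosion_radius_mm = params$erosion_radius_mm,
                           vsharp_max_radius_mm = params$vsharp_max_radius_mm,
                           vsharp_tsvd_threshold = params$vsharp_tsvd_threshold,
                           input_fingerprint = volume_fingerprint(phase)))
  chi
}

# lightweight content fingerprint (dims + moment sums)
volume_fingerprint <- function(x) {
  sprintf("%s|%.10e|%.10e", paste(dim(x), collapse = "x"),
          sum(x), sum(x^2))
}
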