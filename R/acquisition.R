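# Forward SWI acquisition model: dipole field -> phase at TE -> wrapping,
# complex noise, and the scanner-style homodyne high-pass filter that makes
# clinical SWI phase "high-pass filtered".

#' Acquisition parameters for the SWI forward model
#'
#' @param B0_tesla main field strength in tesla (default 3).
#' @param TE_s echo time in seconds (default 0.020).
#' @param gamma_rad_per_s_per_T proton gyromagnetic ratio (default
#'   2.675153e8 rad/s/T).
#' @param snr signal-to-noise ratio of the complex data, or `NULL` for a
#'   noiseless acquisition.
#' @param hpf_kernel in-plane width (k-space samples) of the Hanning
#'   low-pass window used by the homodyne high-pass filter; `NULL` disables
#'   the filter. Default 64.
#' @param rng_seed integer seed for the noise generator.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(B0_tesla = 3.0, TE_s = 0.020,
                               gamma_rad_per_s_per_T = 2.675153e8,
                               snr = NULL, hpf_kernel = 64L,
                               rng_seed = 1L) {
  if (TE_s <= 0 || B0_tesla <= 0) stop("TE_s and B0_tesla must be positive")
  if (!is.null(snr) && snr <= 0) stop("snr must be positive")
  structure(list(B0_tesla = B0_tesla, TE_s = TE_s,
                 gamma_rad_per_s_per_T = gamma_rad_per_s_per_T,
                 snr = snr, hpf_kernel = if (is.null(hpf_kernel)) NULL
                 else as.integer(hpf_kernel),
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_params")
}

#' Convert a field map (ppm) to phase at the echo time
#'
#' `phi = gamma * B0 * (field * 1e-6) * TE`, in radians; linear in the field
#' and in TE.
#'
#' @param field 3D array, field perturbation in ppm of B0.
#' @param acq an [acquisition_params()] object.
#' @return 3D phase array in radians (unwrapped).
#' @export
field_to_phase <- function(field, acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  acq$gamma_rad_per_s_per_T * acq$B0_tesla * (field * 1e-6) * acq$TE_s
}

#' Wrap phase into [-pi, pi)
#'
#' @param phase array of phase values in radians.
#' @return Array congruent to the input modulo 2*pi, in `[-pi, pi)`.
#' @export
wrap_phase <- function(phase) {
  if (any(!is.finite(phase))) stop("phase contains non-finite values")
  ((phase + pi) %% (2 * pi)) - pi
}

# 1-D Hanning taper of total width w centered on DC (in fftshift-free
# indexing), length n
hanning_window_1d <- function(n, w) {
  if (w > n) stop("hpf_kernel exceeds the in-plane grid size")
  f <- fft_freq(n) * n                     # integer frequencies -n/2..n/2-1
  win <- numeric(n)
  inside <- abs(f) <= w / 2
  win[inside] <- 0.5 * (1 + cos(2 * pi * f[inside] / w))
  win
}

#' Scanner-style homodyne high-pass phase filter
#'
#' Emulates the high-pass filtered phase produced by clinical SWI
#' reconstruction: the complex image `m * exp(i*phi)` is divided, slice by
#' slice, by its low-pass reconstruction from a Hanning-windowed central
#' k-space region of `hpf_kernel x hpf_kernel` samples. Smooth, large-scale
#' phase (background field) is strongly attenuated while fine structure is
#' retained — which is also why the result is an *apparent* rather than a
#' true susceptibility upstream of dipole inversion.
#'
#' @param magnitude 3D nonnegative array.
#' @param wrapped_phase 3D phase array in `[-pi, pi)`.
#' @param hpf_kernel low-pass window width in k-space samples per in-plane
#'   axis.
#' @return High-pass filtered phase in `[-pi, pi)`.
#' @export
apply_scanner_hpf <- function(magnitude, wrapped_phase, hpf_kernel = 64L) {
  if (all(magnitude == 0)) stop("magnitude is zero everywhere")
  dims <- dim(magnitude)
  stopifnot(identical(dims, dim(wrapped_phase)))
  wx <- hanning_window_1d(dims[1], hpf_kernel)
  wy <- hanning_window_1d(dims[2], hpf_kernel)
  win2d <- outer(wx, wy)
  out <- array(0, dim = dims)
  for (z in seq_len(dims[3])) {
    cplx <- magnitude[, , z] * exp(1i * wrapped_phase[, , z])
    lp <- stats::fft(stats::fft(cplx) * win2d, inverse = TRUE) / (dims[1] * dims[2])
    out[, , z] <- Arg(cplx * Conj(lp))
  }
  wrap_phase(out)
}

#' Add complex Gaussian noise to a magnitude/phase pair
#'
#' Independent Gaussian noise on the real and imaginary channels with
#' standard deviation `mean(magnitude[magnitude > 0]) / snr`; appropriate in
#' the high-SNR regime where magnitude noise is approximately Gaussian.
#'
#' @param magnitude,phase 3D arrays (phase in radians).
#' @param snr positive signal-to-noise ratio; `Inf` or `NULL` returns the
#'   input unchanged.
#' @param seed integer RNG seed; the same seed reproduces the same noise.
#' @return List with noisy `magnitude` and `phase` (wrapped to `[-pi, pi)`).
#' @export
add_complex_noise <- function(magnitude, phase, snr, seed = 1L) {
  if (is.null(snr) || !is.finite(snr))
    return(list(magnitude = magnitude, phase = wrap_phase(phase)))
  if (snr <= 0) stop("snr must be positive")
  sigma <- mean(magnitude[magnitude > 0]) / snr
  n <- length(magnitude)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cplx <- magnitude * exp(1i * phase) +
    complex(real = stats::rnorm(n, 0, sigma),
            imaginary = stats::rnorm(n, 0, sigma))
  list(magnitude = array(Mod(cplx), dim = dim(magnitude)),
       phase = array(Arg(cplx), dim = dim(magnitude)))
}

#' Simulate a complete SWI acquisition from a phantom
#'
#' Composes the forward chain: rasterize the phantom, compute the dipole
#' field of internal and background sources plus the linear ramp, scale to
#' phase at TE, add complex noise, wrap, and apply the scanner high-pass
#' filter. The ground truth (susceptibility, atlas, brain mask, internal
#' field) is bundled with the observed channels.
#'
#' @param spec a [phantom_spec()].
#' @param acq an [acquisition_params()].
#' @return Object of class `swi_acquisition`: list with `magnitude`,
#'   `phase_hpf`, `phase_wrapped_raw`, `truth` (chi_true, roi_atlas,
#'   brain_mask, field_true), `voxel_size_mm`, `acq`.
#' @export
simulate_acquisition <- function(spec, acq = acquisition_params()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "acquisition_params"))
  ph <- build_phantom(spec)
  D <- dipole_kernel(spec$grid_shape, spec$voxel_size_mm)
  field_true <- forward_field(ph$chi, D)
  bg <- background_field(spec)
  field_total <- field_true + forward_field(bg$chi_bg, D) + bg$ramp_ppm
  # signal model: unit brain signal over a faint non-brain background
  magnitude <- array(0.05, dim = spec$grid_shape)
  magnitude[ph$brain_mask] <- 1
  phase <- field_to_phase(field_total, acq)
  noisy <- add_complex_noise(magnitude, phase, acq$snr, acq$rng_seed)
  phase_wrapped_raw <- wrap_phase(noisy$phase)
  phase_hpf <- if (is.null(acq$hpf_kernel)) phase_wrapped_raw
  else apply_scanner_hpf(noisy$magnitude, phase_wrapped_raw, acq$hpf_kernel)
  structure(list(magnitude = noisy$magnitude,
                 phase_hpf = phase_hpf,
                 phase_wrapped_raw = phase_wrapped_raw,
                 truth = list(chi_true = ph$chi, roi_atlas = ph$atlas,
                              brain_mask = ph$brain_mask, field_true = field_true),
                 voxel_size_mm = spec$voxel_size_mm,
                 acq = acq),
            class = "swi_acquisition")
}

#' @export
print.swi_acquisition <- function(x, ...) {
  d <- dim(x$magnitude)
  cat("Synthetic SWI acquisition\n")
  cat(sprintf("  grid: %d x %d x %d, voxel %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3]))
  cat(sprintf("  B0 = %.1f T, TE = %.1f ms, HPF kernel = %s, SNR = %s\n",
              x$acq$B0_tesla, 1000 * x$acq$TE_s,
              ifelse(is.null(x$acq$hpf_kernel), "off", x$acq$hpf_kernel),
              ifelse(is.null(x$acq$snr), "Inf", format(x$acq$snr))))
  invisible(x)
}
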