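test_that("dipole kernel has the correct limits, root and bounds", {
  D <- dipole_kernel(c(32, 32, 32), c(1, 1, 1))
  expect_equal(D[1, 1, 1], 0)              # D(0) convention
  expect_equal(D[1, 1, 2], -2 / 3)         # k purely along B0
  expect_equal(D[2, 1, 1], 1 / 3)          # k in-plane
  expect_true(all(D >= -2 / 3 - 1e-12 & D <= 1 / 3 + 1e-12))
  # magic angle: kz^2/|k|^2 = 1/3
  kg <- swiqsm:::kspace_grids(c(32, 32, 32), c(1, 1, 1))
  frac <- kg$kz^2 / (kg$kx^2 + kg$ky^2 + kg$kz^2)
  near <- which(abs(frac - 1 / 3) < 1e-9)
  expect_true(length(near) > 0 && all(abs(D[near]) < 1e-9))
  expect_error(dipole_kernel(c(0, 32, 32), c(1, 1, 1)))
})

test_that("forward field is linear and blind to uniform susceptibility", {
  gs <- c(24, 24, 24)
  D <- dipole_kernel(gs, c(1, 1, 1))
  expect_equal(max(abs(forward_field(array(0.3, gs), D))), 0, tolerance = 1e-12)
  set.seed(3)
  c1 <- array(rnorm(prod(gs)), gs); c2 <- array(rnorm(prod(gs)), gs)
  lhs <- forward_field(2 * c1 - 0.5 * c2, D)
  rhs <- 2 * forward_field(c1, D) - 0.5 * forward_field(c2, D)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  c1[1] <- NaN
  expect_error(forward_field(c1, D), "finite")
})

test_that("sphere field matches the analytic dipole solution", {
  ph <- sphere_phantom(n = 64, radius = 6, chi = 0.2)
  D <- dipole_kernel(ph$grid, ph$vox)
  f <- forward_field(ph$chi, D)
  # far field on the B0 axis at 2a: chi/12
  iz <- ph$grid[3] / 2 + 2 * ph$radius  # voxel center at ctr + 2a
  ix <- ph$grid[1] / 2
  expect_equal(f[ix, ix, iz], 0.2 / 12, tolerance = 0.05)
  # Lorentz-corrected interior: ~0 at the center
  expect_lt(abs(f[ix, ix, ph$grid[3] / 2]), 0.002)
  # full exterior oracle at >= 2 voxels from the surface
  co <- swiqsm:::voxel_coords(ph$grid, ph$vox)
  r <- sqrt(ph$r2)
  cosz <- (co$z - ph$center[3]) / r
  ana <- 0.2 * ph$radius^3 * (3 * cosz^2 - 1) / (3 * r^3)
  outside <- ph$r2 >= (ph$radius + 2)^2 & ph$r2 <= 24^2
  expect_lt(max(abs(f - ana)[outside]), 0.05 * 0.2)
})

test_that("field_to_phase scales correctly and linearly", {
  acq <- acquisition_params()
  f <- array(0.1, c(4, 4, 4))
  expect_equal(field_to_phase(f, acq)[1], 2.675153e8 * 3 * 1e-7 * 0.02)
  expect_equal(field_to_phase(f, acq)[1], 1.605, tolerance = 1e-3)
  expect_equal(field_to_phase(array(0, c(4, 4, 4)), acq),
               array(0, c(4, 4, 4)))
  acq2 <- acquisition_params(TE_s = 0.040)
  expect_equal(field_to_phase(f, acq2), 2 * field_to_phase(f, acq))
})

test_that("wrap_phase maps onto [-pi, pi) and is idempotent", {
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  expect_equal(wrap_phase(0.3), 0.3)
  expect_equal(wrap_phase(-3 * pi), -pi)    # boundary representative
  x <- seq(-20, 20, length.out = 401)
  w <- wrap_phase(x)
  expect_true(all(w >= -pi & w < pi))
  expect_equal(wrap_phase(w), w)
  expect_equal(sin(w), sin(x), tolerance = 1e-12)  # congruence mod 2*pi
  expect_error(wrap_phase(c(1, NA)))
})

test_that("scanner HPF kills smooth phase and keeps fine structure", {
  gs <- c(64, 64, 8)
  m <- array(1, gs)
  ramp <- array(rep(2 * pi * (seq_len(gs[1]) - 1) / gs[1],
                    times = gs[2] * gs[3]), gs)
  hp <- apply_scanner_hpf(m, wrap_phase(ramp), 32)
  expect_lt(sum(hp^2) / sum(wrap_phase(ramp)^2), 0.1)  # >90% energy removed
  pt <- array(0, gs); pt[32, 32, 4] <- 1
  hp2 <- apply_scanner_hpf(m, pt, 32)
  expect_gt(hp2[32, 32, 4], 0.5)                       # within 50% amplitude
  expect_equal(apply_scanner_hpf(m, array(0, gs), 32), array(0, gs),
               tolerance = 1e-12)
  expect_error(apply_scanner_hpf(array(0, gs), pt, 32), "zero")
  expect_error(apply_scanner_hpf(m, pt, 100), "exceeds")
})

test_that("complex noise is seeded, vanishes at infinite SNR, and has the
           predicted phase SD", {
  gs <- c(24, 24, 24)
  m <- array(1, gs); p <- array(0.2, gs)
  expect_identical(add_complex_noise(m, p, Inf)$magnitude, m)
  n1 <- add_complex_noise(m, p, 20, seed = 5)
  n2 <- add_complex_noise(m, p, 20, seed = 5)
  expect_identical(n1, n2)
  n3 <- add_complex_noise(m, p, 50, seed = 9)
  expect_equal(sd(n3$phase), 1 / 50, tolerance = 0.1)  # small-angle regime
})

test_that("simulated acquisition is reproducible and carries background", {
  spec <- coarse_phantom_spec()
  acq <- acquisition_params(snr = 30, hpf_kernel = 24, rng_seed = 11)
  s1 <- simulate_acquisition(spec, acq)
  s2 <- simulate_acquisition(spec, acq)
  expect_identical(s1$phase_hpf, s2$phase_hpf)
  expect_identical(s1$magnitude, s2$magnitude)
  expect_true(all(s1$phase_hpf >= -pi & s1$phase_hpf < pi))
  expect_true(all(s1$phase_wrapped_raw >= -pi & s1$phase_wrapped_raw < pi))
  # background sources induce large-scale phase away from internal sources
  spec0 <- spec
  spec0$background_sources <- list(spheres = list(), linear_ppm_per_mm = c(0, 0, 0))
  s0 <- simulate_acquisition(spec0, acquisition_params(snr = NULL, hpf_kernel = NULL))
  sb <- simulate_acquisition(spec, acquisition_params(snr = NULL, hpf_kernel = NULL))
  far <- s0$truth$brain_mask & s0$truth$chi_true == 0
  expect_gt(rms(sb$phase_wrapped_raw[far]), 3 * rms(s0$phase_wrapped_raw[far]))
})

test_that("noiseless unfiltered raw phase unwraps back to the true field", {
  spec <- default_phantom_spec()  # native resolution: edge ringing is small
  spec$background_sources <- list(spheres = list(), linear_ppm_per_mm = c(0, 0, 0))
  acq <- acquisition_params(snr = NULL, hpf_kernel = NULL)
  sim <- simulate_acquisition(spec, acq)
  u <- laplacian_unwrap(sim$phase_wrapped_raw, sim$truth$brain_mask,
                        spec$voxel_size_mm)
  truth <- field_to_phase(sim$truth$field_true, acq)
  me <- erode_mask(sim$truth$brain_mask, 4, spec$voxel_size_mm)
  d <- u - truth
  d <- d - mean(d[me])
  # spectral ringing at the sharp source edges bounds the agreement
  expect_lt(rms(d[me]) / rms(truth[me] - mean(truth[me])), 0.1)
  expect_gt(cor(u[me], truth[me]), 0.99)
})
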