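# Shared fixtures: small grids keep the component tests fast; the full
# default grid is exercised once in the end-to-end file and in the
# acceptance suite.

rms <- function(x) sqrt(mean(x^2))

# coarse phantom (2 mm isotropic) on which the 12 mm V-SHARP radius and
# 3 mm erosion still leave all nuclei usable
coarse_phantom_spec <- function() {
  default_phantom_spec(grid_shape = c(48L, 48L, 48L),
                       voxel_size_mm = c(2, 2, 2))
}

# single centered sphere phantom on an isotropic grid
sphere_phantom <- function(n = 64, vox = 1, radius = 6, chi = 0.2,
                           brain_frac = 0.42) {
  gs <- rep(n, 3)
  co <- swiqsm:::voxel_coords(gs, rep(vox, 3))
  ctr <- (gs / 2 - 0.5) * vox   # a voxel center, so axis samples align
  r2 <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2
  chi_vol <- array(0, gs)
  chi_vol[r2 <= radius^2] <- chi
  brain <- r2 <= (brain_frac * n * vox)^2
  list(chi = chi_vol, brain = brain, grid = gs, vox = rep(vox, 3),
       center = ctr, radius = radius, sphere = r2 <= radius^2, r2 = r2)
}

# standard small cohort used across the stats tests
scenario_cohort <- function(seed = 7) simulate_cohort(default_separation_scenario(seed))

gender01 <- function(g) as.numeric(factor(g, levels = c("M", "F"))) - 1
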