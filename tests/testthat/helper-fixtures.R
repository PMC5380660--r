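# Small fixtures shared across the suite; everything is built in code.

# All-ECM cube with an optional centred impermeable cube inclusion.
cube_inclusion_micro <- function(n = 16L, inclusion = TRUE, spacing = 1) {
  mask <- array(TRUE, c(n, n, n))
  if (inclusion) {
    lo <- n / 4 + 1L
    hi <- n / 4 + n / 2
    mask[lo:hi, lo:hi, lo:hi] <- FALSE
  }
  microstructure(mask, rep(spacing, 3))
}

# Filled 2-D ellipse as a logical matrix.
ellipse_mask <- function(nr, nc, ctr, semi) {
  outer(seq_len(nr), seq_len(nc), function(i, j)
    ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 <= 1)
}

# Microstructure whose slices each hold the given cell-phase pattern
# (pattern TRUE = cell); ECM is the complement.
slice_micro <- function(pattern, n_slices = 3L, spacing = 1) {
  mask <- array(rep(!pattern, n_slices),
                c(dim(pattern), n_slices))
  microstructure(mask, rep(spacing, 3))
}

# Forward Darcy samples from a known tensor k (m^2): <u> = k g / mu.
forward_samples <- function(k, mu, grads = diag(3) * 1e5) {
  lapply(1:3, function(s) {
    g <- grads[s, ]
    structure(list(mean_velocity = as.vector(k %*% g) / mu,
                   mean_pressure_gradient = g,
                   direction_label = c("r", "z", "theta")[s]),
              class = "homog_sample")
  })
}

# Random symmetric positive-definite tensor on the 1e-18 m^2 scale.
random_spd_tensor <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  (crossprod(A) + diag(3) * 0.5) * 1e-18
}

small_preset_micro <- function(name, seed, n = 24L, spacing = 1.25) {
  generate_microstructure(preset_params(
    name, seed = seed, grid_shape = rep(n, 3L),
    voxel_spacing = rep(spacing, 3L), periodic = TRUE))
}
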