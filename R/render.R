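#' Parameters for confocal acquisition emulation
#'
#' Controls how a binary microstructure is turned into an emulated confocal
#' intensity volume: the tracer fills the ECM, so ECM voxels are bright and
#' cell voxels dark; intensity decays exponentially with imaging depth;
#' an isotropic Gaussian blur approximates the point-spread function; and
#' zero-mean noise is added.
#'
#' @param attenuation_length Micrometres; exponential decay length of
#'   intensity along the depth axis.  `Inf` disables attenuation.
#' @param noise_sd Intensity units; sd of the added noise (>= 0).
#' @param blur_sigma Micrometres; Gaussian blur sd (0 disables).
#' @param ecm_intensity,cell_intensity Mean phase intensities; must satisfy
#'   `ecm_intensity > cell_intensity` (the tracer fills the ECM).
#' @param noise_model `"gaussian"` (additive) or `"poisson"`
#'   (signal-dependent: sd scales with the square root of the local signal,
#'   normalised so `noise_sd` applies at `ecm_intensity`).
#' @param depth_axis Axis (1..3) along which acquisition depth runs.
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `"confocal_params"`.
#' @export
confocal_params <- function(attenuation_length = 50, noise_sd = 5,
                            blur_sigma = 0.5, ecm_intensity = 100,
                            cell_intensity = 20,
                            noise_model = c("gaussian", "poisson"),
                            depth_axis = 3L, seed = 1L) {
  if (!(attenuation_length > 0)) stop("`attenuation_length` must be > 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (blur_sigma < 0) stop("`blur_sigma` must be >= 0")
  if (!(ecm_intensity > cell_intensity))
    stop("`ecm_intensity` must exceed `cell_intensity` (tracer fills ECM)")
  depth_axis <- as.integer(depth_axis)
  if (!depth_axis %in% 1:3) stop("`depth_axis` must be 1, 2 or 3")
  structure(list(attenuation_length = attenuation_length, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, ecm_intensity = ecm_intensity,
                 cell_intensity = cell_intensity,
                 noise_model = match.arg(noise_model),
                 depth_axis = depth_axis, seed = as.integer(seed)),
            class = "confocal_params")
}

#' Render an emulated confocal volume from a binary microstructure
#'
#' Intensity is the phase mean (`ecm_intensity` in ECM, `cell_intensity` in
#' cells) multiplied by `exp(-depth / attenuation_length)`, Gaussian-blurred,
#' plus zero-mean noise; negative values are clipped at zero.  The depth
#' axis is recorded in the returned volume's metadata.
#'
#' @param micro A [microstructure()].
#' @param emu A [confocal_params()].
#' @return An `image_volume`.
#' @export
render_confocal <- function(micro, emu = confocal_params()) {
  stopifnot(inherits(micro, "binary_microstructure"),
            inherits(emu, "confocal_params"))
  n <- dim(micro$mask)
  h <- micro$voxel_spacing
  arr <- ifelse(micro$mask, emu$ecm_intensity, emu$cell_intensity)
  d <- emu$depth_axis
  if (is.finite(emu$attenuation_length)) {
    depth <- (seq_len(n[d]) - 1) * h[d]
    fac <- exp(-depth / emu$attenuation_length)
    arr <- sweep(arr, d, fac, `*`)
  }
  if (emu$blur_sigma > 0)
    arr <- gaussian_blur_3d(arr, emu$blur_sigma / h)
  if (emu$noise_sd > 0) {
    noise <- with_seed(emu$seed, rnorm(length(arr)))
    sdl <- if (emu$noise_model == "poisson")
      emu$noise_sd * sqrt(pmax(arr, 0) / emu$ecm_intensity) else emu$noise_sd
    arr <- arr + sdl * array(noise, n)
    arr[arr < 0] <- 0
  }
  image_volume(arr, h, micro$axes, depth_axis = d)
}

# Separable Gaussian blur; sigma_vox per axis, replicate-edge padding.
gaussian_blur_3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

convolve_axis <- function(arr, k, axis) {
  n <- dim(arr)
  r <- (length(k) - 1L) / 2L
  out <- arr * k[r + 1L]
  base <- seq_len(n[axis])
  for (s in seq_len(r)) {
    up <- pmin(base + s, n[axis])
    dn <- pmax(base - s, 1L)
    out <- out + k[r + 1L + s] * index_axis(arr, up, axis) +
                 k[r + 1L - s] * index_axis(arr, dn, axis)
  }
  out
}

index_axis <- function(arr, idx, axis) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}
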