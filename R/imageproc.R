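#' Correct intensity attenuation with imaging depth
#'
#' Confocal stacks lose intensity with depth.  The default model normalises
#' each slice along the depth axis to the mean intensity of the first slice
#' (no optics assumptions); the `"exponential"` model fits a single decay
#' length to the per-slice means by linear regression on the log scale and
#' divides it out.  After correction the per-slice mean profile is flat.
#'
#' @param vol An `image_volume` with `depth_axis` set.
#' @param model `"per_slice_mean"` or `"exponential"`.
#' @return The corrected `image_volume`.
#' @export
correct_attenuation <- function(vol,
                                model = c("per_slice_mean", "exponential")) {
  stopifnot(inherits(vol, "image_volume"))
  model <- match.arg(model)
  d <- vol$depth_axis
  means <- apply(vol$intensity, d, mean)
  if (any(means <= 0))
    stop("volume has an all-zero (or non-positive) slice along the depth ",
         "axis; attenuation correction is undefined")
  depth <- (seq_along(means) - 1) * vol$voxel_spacing[d]
  fac <- switch(model,
    per_slice_mean = means[1] / means,
    exponential = {
      fit <- stats::lm(log(means) ~ depth)
      rate <- -stats::coef(fit)[["depth"]]
      exp(rate * depth)
    })
  out <- vol
  out$intensity <- sweep(vol$intensity, d, fac, `*`)
  out
}

#' Per-slice mean intensity profile along the depth axis
#'
#' Diagnostic companion to [correct_attenuation()]: returns the per-slice
#' means and the slope of a linear fit against depth, both in intensity
#' units and relative to the mean intensity (per um).
#'
#' @param vol An `image_volume`.
#' @return List with `depth_um`, `slice_means`, `slope` (intensity per um)
#'   and `relative_slope` (fraction of the mean intensity per um).
#' @export
attenuation_profile <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  d <- vol$depth_axis
  means <- apply(vol$intensity, d, mean)
  depth <- (seq_along(means) - 1) * vol$voxel_spacing[d]
  slope <- stats::coef(stats::lm(means ~ depth))[["depth"]]
  list(depth_um = depth, slice_means = means, slope = slope,
       relative_slope = slope / mean(means))
}

#' Rotate an image volume onto the cylindrical wall axes
#'
#' Applies up to three rotations about the grid axes to align the imaging
#' axes with the (r, z, theta) coordinates of the artery.  Angles that are
#' exact multiples of 90 degrees use lattice-exact array permutations; other
#' angles use trilinear interpolation in physical coordinates about the
#' volume centre, with voxels mapped from outside the original grid set to
#' zero.
#'
#' @param vol An `image_volume`.
#' @param angles Numeric length-3, degrees of rotation about grid axes
#'   1, 2, 3 (right-handed).
#' @param order Integer permutation of 1:3 giving the order in which the
#'   axis rotations are applied.
#' @param axes Axis labels assigned to the rotated volume.
#' @return The rotated `image_volume`, relabelled to `axes`.
#' @export
rotate_to_cylindrical <- function(vol, angles = c(0, 0, 0), order = 1:3,
                                  axes = c("r", "z", "theta")) {
  stopifnot(inherits(vol, "image_volume"))
  if (length(angles) != 3L || !all(is.finite(angles)))
    stop("`angles` must be 3 finite rotation angles in degrees")
  if (!identical(sort(as.integer(order)), 1:3))
    stop("`order` must be a permutation of 1:3")
  out <- vol
  if (all(angles %% 90 == 0)) {
    for (ax in order) {
      turns <- (as.integer(round(angles[ax] / 90)) %% 4L + 4L) %% 4L
      for (t in seq_len(turns)) out$intensity <- rot90_axis(out$intensity, ax)
    }
  } else {
    R <- diag(3)
    for (ax in order) R <- rot_mat_axis(ax, angles[ax] * pi / 180) %*% R
    out$intensity <- resample_rotated(vol$intensity, vol$voxel_spacing, R)
  }
  out$axes <- check_axes(axes)
  out
}

# Right-handed quarter turn about `axis`: the remaining two axes (a, b)
# transform as (a, b) -> (-b, a).
rot90_axis <- function(arr, axis) {
  perm <- switch(axis, c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  out <- aperm(arr, perm)
  flip <- switch(axis, 2L, 3L, 1L)   # axis receiving the sign flip
  idx <- rev(seq_len(dim(out)[flip]))
  index_axis(out, idx, flip)
}

rot_mat_axis <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  switch(axis,
         matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

# Trilinear resampling of `arr` under rotation R about the volume centre,
# in physical coordinates (respects anisotropic spacing).
resample_rotated <- function(arr, h, R) {
  n <- dim(arr)
  ctr <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  pos <- cbind((g$i - ctr[1]) * h[1], (g$j - ctr[2]) * h[2],
               (g$k - ctr[3]) * h[3])
  src <- pos %*% R                      # R^-1 = t(R); pos %*% R = t(t(R) %*% t(pos))
  fi <- src[, 1] / h[1] + ctr[1]
  fj <- src[, 2] / h[2] + ctr[2]
  fk <- src[, 3] / h[3] + ctr[3]
  i0 <- floor(fi); j0 <- floor(fj); k0 <- floor(fk)
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  ok <- i0 >= 1 & i0 + 1 <= n[1] & j0 >= 1 & j0 + 1 <= n[2] &
        k0 >= 1 & k0 + 1 <= n[3]
  val <- numeric(nrow(src))
  lin <- function(i, j, k) ((k - 1) * n[2] + (j - 1)) * n[1] + i
  io <- i0[ok]; jo <- j0[ok]; ko <- k0[ok]
  wio <- wi[ok]; wjo <- wj[ok]; wko <- wk[ok]
  acc <- numeric(sum(ok))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) wio else 1 - wio) * (if (dj) wjo else 1 - wjo) *
         (if (dk) wko else 1 - wko)
    acc <- acc + w * arr[lin(io + di, jo + dj, ko + dk)]
  }
  val[ok] <- acc
  array(val, n)
}

#' Threshold an intensity volume into ECM and cell compartments
#'
#' Divides the volume into two compartments: high-intensity voxels are the
#' tracer-filled ECM (`TRUE`), the rest are SMCs and impervious fibres.
#' The default threshold is Otsu's method on the intensity histogram; a
#' fixed manual value may be supplied instead.
#'
#' @param vol An `image_volume`.
#' @param method `"otsu"` or `"fixed"`.
#' @param value Threshold intensity, required for `method = "fixed"`; must
#'   lie within the intensity range.
#' @return A [microstructure()] with `threshold_used` recorded.
#' @export
threshold_volume <- function(vol, method = c("otsu", "fixed"), value = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  method <- match.arg(method)
  rng <- range(vol$intensity)
  if (rng[1] == rng[2])
    stop("constant intensity volume: no threshold is defined")
  thr <- switch(method,
    otsu = {
      scaled <- (vol$intensity - rng[1]) / (rng[2] - rng[1])
      img <- EBImage::Image(as.vector(scaled), dim = c(length(scaled), 1L))
      as.numeric(EBImage::otsu(img, range = c(0, 1), levels = 256L)) *
        (rng[2] - rng[1]) + rng[1]
    },
    fixed = {
      if (is.null(value)) stop('method = "fixed" requires `value`')
      if (value < rng[1] || value > rng[2])
        stop("fixed threshold outside the intensity range")
      value
    })
  microstructure(vol$intensity > thr, vol$voxel_spacing, vol$axes,
                 threshold_used = thr)
}

#' ECM volume fraction and volumetric strain
#'
#' Exact voxel counting: `phi_ECM = V_ECM / V`.  When a baseline fraction is
#' supplied, the volumetric strain of the ECM relative to that baseline,
#' `J = phi_ECM / phi_ECM_baseline`, is also reported.
#'
#' @param micro A [microstructure()].
#' @param baseline_phi Optional baseline ECM fraction for the strain ratio.
#' @return Object of class `"ecm_fraction"`: `phi_ecm`, `v_ecm` and
#'   `v_total` (um^3), `threshold_used` (if recorded on the mask) and
#'   `j_strain` (if `baseline_phi` given).
#' @export
compute_ecm_fraction <- function(micro, baseline_phi = NULL) {
  stopifnot(inherits(micro, "binary_microstructure"))
  n_true <- sum(micro$mask)
  n_tot <- length(micro$mask)
  if (n_tot == 0L) stop("empty mask")
  vox <- prod(micro$voxel_spacing)
  out <- list(phi_ecm = n_true / n_tot, v_ecm = n_true * vox,
              v_total = n_tot * vox, threshold_used = micro$threshold_used,
              j_strain = NULL)
  if (!is.null(baseline_phi)) {
    if (baseline_phi <= 0) stop("`baseline_phi` must be positive")
    out$j_strain <- out$phi_ecm / baseline_phi
  }
  structure(out, class = "ecm_fraction")
}

#' @export
print.ecm_fraction <- function(x, ...) {
  cat("<ecm_fraction> phi_ECM =", signif(x$phi_ecm, 4))
  if (!is.null(x$j_strain)) cat(", J =", signif(x$j_strain, 4))
  cat("\n")
  invisible(x)
}

#' Measure medial thickness as mean radial extent
#'
#' For every (z, theta) column the radial extent of tissue signal is taken
#' as `(max index - min index + 1) * spacing_r`; the thickness is the mean
#' over columns containing tissue.  Fails when half or more of the columns
#' carry no signal.
#'
#' @param x An `image_volume` (tissue = intensity above
#'   `intensity_threshold`), a 3-D logical array (tissue = `TRUE`), or a
#'   [microstructure()] (tissue = ECM voxels; appropriate for slab volumes
#'   whose exterior carries no ECM).
#' @param intensity_threshold Intensity above which a voxel counts as
#'   tissue (for `image_volume` input).
#' @param min_coverage Minimum fraction of columns that must contain tissue.
#' @return Object of class `"medial_geometry"`: `thickness_T` (um), `sd_T`,
#'   `n_columns` and `method`.
#' @export
measure_medial_thickness <- function(x, intensity_threshold = 0,
                                     min_coverage = 0.5) {
  if (inherits(x, "image_volume")) {
    tissue <- x$intensity > intensity_threshold
    h_r <- x$voxel_spacing[1]
  } else if (inherits(x, "binary_microstructure")) {
    tissue <- x$mask
    h_r <- x$voxel_spacing[1]
  } else if (is.array(x) && is.logical(x) && length(dim(x)) == 3L) {
    tissue <- x
    h_r <- 1
  } else stop("`x` must be an image_volume, microstructure or logical array")
  ext <- apply(tissue, c(2, 3), function(v) {
    w <- which(v)
    if (!length(w)) NA_real_ else (max(w) - min(w) + 1)
  })
  miss <- mean(is.na(ext))
  if (miss > 1 - min_coverage)
    stop("no tissue signal in ", round(100 * miss), "% of (z, theta) columns")
  tvals <- ext[!is.na(ext)] * h_r
  structure(list(thickness_T = mean(tvals), sd_T = stats::sd(tvals),
                 n_columns = length(tvals),
                 method = "mean radial extent over (z, theta) columns"),
            class = "medial_geometry")
}

#' @export
print.medial_geometry <- function(x, ...) {
  cat("<medial_geometry> T =", signif(x$thickness_T, 4), "um (sd",
      signif(x$sd_T, 3), "over", x$n_columns, "columns)\n")
  invisible(x)
}
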