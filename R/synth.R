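#' Parameters for synthetic medial microstructure generation
#'
#' Describes a packing of fusiform (spindle-shaped) smooth muscle cells in
#' extracellular matrix on a voxel grid in cylindrical wall coordinates
#' (r, z, theta).  Cell long axes lie in the z-theta plane at `helix_angle`
#' from the circumferential direction, reflecting the helical (rather than
#' circumferential) orientation of medial SMCs.
#'
#' @param grid_shape Integer length-3, voxels per axis (r, z, theta); at
#'   least 8 per axis.
#' @param voxel_spacing Micrometres per voxel per axis.
#' @param target_phi_ecm Target ECM volume fraction, strictly in (0, 1).
#'   Cells are added until the measured fraction lies within +/- 0.02.
#' @param cell_semi_axes Length-3 in um: long semi-axis (in the z-theta
#'   plane), theta-transverse semi-axis, radial semi-axis.
#' @param helix_angle Degrees between the cell long axis and the
#'   circumferential (theta) direction, within the z-theta plane.
#' @param angle_jitter Degrees, per-cell sd of the helix angle.
#' @param radial_flattening Factor <= 1 multiplying the radial semi-axis;
#'   models the radial flattening of contracted SMCs.
#' @param placement_jitter Micrometres, sd of cell centres about a uniform
#'   seeding lattice.
#' @param seed Integer RNG seed; identical parameters and seed reproduce a
#'   bit-identical volume.
#' @param periodic Logical; wrap cells across grid faces (pairs with
#'   periodic flow boundary conditions).  Default clips at faces.
#' @param max_cells Maximum number of cells to place; `0` requests an empty
#'   (all-ECM) volume.
#' @param thickness_um Nominal medial thickness carried by the preset (used
#'   by slab fixtures; does not affect cube packing).
#' @return An object of class `"synth_params"`.
#' @seealso [generate_microstructure()], [apply_contraction()],
#'   [preset_params()]
#' @export
synth_params <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = c(0.5, 0.5, 0.5),
                         target_phi_ecm = 0.60,
                         cell_semi_axes = c(12, 2.5, 2.5),
                         helix_angle = 20,
                         angle_jitter = 5,
                         radial_flattening = 1,
                         placement_jitter = 3,
                         seed = 1L,
                         periodic = FALSE,
                         max_cells = Inf,
                         thickness_um = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must give >= 8 voxels per axis")
  voxel_spacing <- check_spacing(voxel_spacing)
  if (!is.numeric(target_phi_ecm) || target_phi_ecm <= 0 || target_phi_ecm >= 1)
    stop("`target_phi_ecm` must lie strictly in (0, 1)")
  cell_semi_axes <- as.numeric(cell_semi_axes)
  if (length(cell_semi_axes) != 3L || any(cell_semi_axes <= 0))
    stop("`cell_semi_axes` must be 3 positive lengths (um)")
  if (radial_flattening <= 0 || radial_flattening > 1)
    stop("`radial_flattening` must lie in (0, 1]")
  if (placement_jitter < 0) stop("`placement_jitter` must be >= 0")
  if (angle_jitter < 0) stop("`angle_jitter` must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 target_phi_ecm = target_phi_ecm,
                 cell_semi_axes = cell_semi_axes, helix_angle = helix_angle,
                 angle_jitter = angle_jitter,
                 radial_flattening = radial_flattening,
                 placement_jitter = placement_jitter, seed = as.integer(seed),
                 periodic = isTRUE(periodic), max_cells = max_cells,
                 thickness_um = thickness_um),
            class = "synth_params")
}

#' Load a named microstructure preset
#'
#' Presets live in a versioned YAML config shipped with the package
#' (`inst/extdata/presets.yaml`).  `"baseline"` targets the relaxed-wall ECM
#' fraction (0.60) and `"constricted"` the 100 nM noradrenaline state (0.68);
#' cell geometry in the presets is calibration, chosen to reproduce the
#' published volume fractions and aspect-ratio medians, not a measurement.
#'
#' @param name `"baseline"` or `"constricted"`.
#' @param seed RNG seed for the generated volume.
#' @param grid_shape,voxel_spacing,periodic Optional overrides of the preset
#'   grid (e.g. smaller grids for flow fixtures).
#' @return A [synth_params()] object.
#' @export
preset_params <- function(name = c("baseline", "constricted"), seed = 1L,
                          grid_shape = NULL, voxel_spacing = NULL,
                          periodic = FALSE) {
  name <- match.arg(name)
  cfg <- load_presets()
  p <- cfg[[name]]
  synth_params(grid_shape = grid_shape %||% p$grid_shape,
               voxel_spacing = voxel_spacing %||% p$voxel_spacing,
               target_phi_ecm = p$target_phi_ecm,
               cell_semi_axes = p$cell_semi_axes,
               helix_angle = p$helix_angle,
               angle_jitter = p$angle_jitter,
               radial_flattening = p$radial_flattening,
               placement_jitter = p$placement_jitter,
               seed = seed, periodic = periodic,
               thickness_um = p$thickness_um)
}

load_presets <- function() {
  path <- system.file("extdata", "presets.yaml", package = "mediaperm",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Derive contracted-state parameters from a baseline parameter set
#'
#' Smooth muscle contraction shortens cells along their long axis, widens
#' them transversely and flattens them radially, while the wall thickens.
#' The derived ECM volume fraction follows from conservation of cell count:
#' the solid fraction scales by the cell volume factor divided by the wall
#' thickness factor, so `phi' = 1 - (1 - phi) * v_cell_factor /
#' thickness_scale`.
#'
#' @param params Baseline [synth_params()].
#' @param contraction List with `long_axis_scale` (<= 1),
#'   `transverse_scale` (>= 1), `radial_flattening` (<= 1) and
#'   `thickness_scale` (>= 1).  Defaults to the packaged contraction preset
#'   mapping baseline to the constricted state.
#' @param target_phi_ecm Optional explicit target fraction overriding the
#'   derived value.
#' @return A new [synth_params()] whose generated volumes have a higher ECM
#'   fraction and lower median per-slice cell aspect ratio than baseline.
#' @export
apply_contraction <- function(params, contraction = NULL,
                              target_phi_ecm = NULL) {
  stopifnot(inherits(params, "synth_params"))
  if (is.null(contraction)) contraction <- load_presets()$contraction
  las <- contraction$long_axis_scale
  ts  <- contraction$transverse_scale
  rf  <- contraction$radial_flattening
  ths <- contraction$thickness_scale %||% 1
  if (any(c(las, ts, rf, ths) <= 0)) stop("contraction scales must be positive")
  if (las > 1 || ts < 1)
    stop("contraction requires long_axis_scale <= 1 <= transverse_scale")
  vf <- las * ts^2 * rf
  phi <- target_phi_ecm %||% (1 - (1 - params$target_phi_ecm) * vf / ths)
  if (phi <= 0 || phi >= 1)
    stop("contraction drives target ECM fraction out of (0, 1): ",
         signif(phi, 4))
  out <- params
  out$cell_semi_axes <- params$cell_semi_axes * c(las, ts, ts)
  out$radial_flattening <- params$radial_flattening * rf
  out$target_phi_ecm <- phi
  if (!is.null(params$thickness_um)) out$thickness_um <- params$thickness_um * ths
  out
}

#' Generate a synthetic binary medial microstructure
#'
#' Sequentially places fusiform cells (tapered ellipsoids; the transverse
#' radius falls off as `1 - t^2` along the long axis) at jittered-lattice
#' positions with helical orientations, carving them out of an all-ECM
#' volume until the measured ECM fraction lies within +/- 0.02 of
#' `target_phi_ecm`.  Overlap between cells is allowed, so cells touch, as
#' in confocal images of the media.  A placement whose removal overshoots
#' the band is rejected and re-drawn; generation fails with a clear error if
#' the target cannot be reached in a bounded number of attempts.
#'
#' @param params A [synth_params()] object.
#' @return A [microstructure()] with attributes `phi` (achieved fraction),
#'   `n_cells` and `cells` (centres and orientations used).
#' @export
generate_microstructure <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$grid_shape
  h <- params$voxel_spacing
  ext <- n * h
  target <- params$target_phi_ecm
  band <- 0.02
  mask <- array(TRUE, n)
  nvox <- prod(n)
  semi <- params$cell_semi_axes
  semi[3] <- semi[3] * params$radial_flattening
  a <- semi[1]; bt <- semi[2]; br <- semi[3]
  cells <- list()
  if (params$max_cells > 0 && 1 - target > band) {
    with_seed(params$seed, {
      # jittered seeding lattice sized from the expected cell count
      v_cell <- pi * bt * br * a * 16 / 15   # integral of (1-t^2)^2 profile
      n_est <- max(1, ceiling((1 - target) * prod(ext) / v_cell))
      # Cells seed on radial layers (as SMC layers between elastic lamellae),
      # jittered freely in-plane but only slightly across layers; this gives
      # the media its lamellar character and makes radial flow the most
      # obstructed direction.
      n_layers <- max(1L, round(ext[1] / (2.4 * br)))
      lat_zt <- pmax(1L, round(sqrt(n_est / n_layers) *
                               ext[2:3] / sqrt(prod(ext[2:3]))))
      layer_r <- (seq_len(n_layers) - 0.5) * ext[1] / n_layers
      centres <- as.matrix(expand.grid(
        layer_r,
        (seq_len(lat_zt[1]) - 0.5) * ext[2] / lat_zt[1],
        (seq_len(lat_zt[2]) - 0.5) * ext[3] / lat_zt[2]))
      jit <- c(0.15 * br, params$placement_jitter, params$placement_jitter)
      centres <- centres[sample.int(nrow(centres)), , drop = FALSE] +
        matrix(rnorm(3 * nrow(centres), 0, rep(jit, each = nrow(centres))),
               ncol = 3)
      draw_centre <- function(i) {
        if (i <= nrow(centres)) centres[i, ] else
          c(sample(layer_r, 1L) + rnorm(1, 0, jit[1]),
            runif(2) * ext[2:3])
      }
      fails <- 0L; max_fails <- 200L; i_prop <- 0L
      while (mean(mask) > target && length(cells) < params$max_cells) {
        i_prop <- i_prop + 1L
        ctr <- draw_centre(i_prop)
        beta <- (params$helix_angle + rnorm(1, 0, params$angle_jitter)) *
          pi / 180
        dvec <- c(0, sin(beta), cos(beta))   # long axis in z-theta plane
        idx <- carve_cell_idx(n, h, ctr, dvec, a, bt, br, params$periodic)
        idx <- idx[mask[idx]]
        if (!length(idx)) { fails <- fails + 1L } else {
          mask[idx] <- FALSE
          if (mean(mask) < target - band) {     # overshoot: reject, re-draw
            mask[idx] <- TRUE
            fails <- fails + 1L
          } else {
            cells[[length(cells) + 1L]] <- list(centre = ctr, axis = dvec)
            fails <- 0L
          }
        }
        if (fails > max_fails)
          stop("target ECM fraction ", target, " unreachable with cell ",
               "semi-axes (", paste(signif(semi, 3), collapse = ", "),
               ") um after ", max_fails, " rejected placements")
      }
    })
  }
  phi <- mean(mask)
  if (abs(phi - target) > band && !(params$max_cells == 0))
    stop("achieved phi_ECM ", signif(phi, 4), " outside +/-", band,
         " of target ", target,
         " (cell volume too large relative to the band?)")
  out <- microstructure(mask, h)
  attr(out, "phi") <- phi
  attr(out, "n_cells") <- length(cells)
  attr(out, "cells") <- cells
  attr(out, "params") <- params
  out
}

# Linear voxel indices covered by one fusiform cell.
# Local frame: dvec = long axis (unit, in the z-theta plane), e1 = radial
# unit vector, e2 = dvec x e1 (transverse, in the z-theta plane).  A voxel
# centre x is inside when |t| < 1 and (c1^2 + c2^2) <= (1 - t^2)^2 with
# t = <x-ctr, d>/a, c1 = <x-ctr, e1>/br, c2 = <x-ctr, e2>/bt.
carve_cell_idx <- function(n, h, ctr, dvec, a, bt, br, periodic) {
  bmax <- max(bt, br)
  ext <- abs(dvec) * a + bmax
  lo <- floor((ctr - ext) / h + 0.5)
  hi <- ceiling((ctr + ext) / h + 0.5)
  if (!periodic) {
    lo <- pmax(lo, 1); hi <- pmin(hi, n)
    if (any(lo > hi)) return(integer(0))
  }
  ir <- lo[1]:hi[1]; iz <- lo[2]:hi[2]; it <- lo[3]:hi[3]
  xr <- (ir - 0.5) * h[1] - ctr[1]
  xz <- (iz - 0.5) * h[2] - ctr[2]
  xt <- (it - 0.5) * h[3] - ctr[3]
  nb <- c(length(ir), length(iz), length(it))
  X1 <- array(xr, nb)
  X2 <- array(rep(xz, each = nb[1]), nb)
  X3 <- array(rep(xt, each = nb[1] * nb[2]), nb)
  e2 <- c(0, dvec[3], -dvec[2])             # dvec x e_r
  tt <- (X2 * dvec[2] + X3 * dvec[3]) / a
  c1 <- X1 / br
  c2 <- (X2 * e2[2] + X3 * e2[3]) / bt
  inside <- abs(tt) < 1 & (c1^2 + c2^2) <= (1 - tt^2)^2
  if (!any(inside)) return(integer(0))
  w <- which(inside)
  sub <- arrayInd(w, nb)
  i <- ir[sub[, 1]]; j <- iz[sub[, 2]]; k <- it[sub[, 3]]
  if (periodic) {
    i <- (i - 1L) %% n[1] + 1L
    j <- (j - 1L) %% n[2] + 1L
    k <- (k - 1L) %% n[3] + 1L
  }
  unique(((k - 1L) * n[2] + (j - 1L)) * n[1] + i)
}

#' Synthetic medial slab for thickness measurement
#'
#' Tissue occupies radial positions in `[0, thickness_um + ripple]`, where
#' the upper surface may carry a sinusoidal ripple along z with an integer
#' number of cycles (so the mean thickness over the slab equals
#' `thickness_um`).  Intensity is 1 inside tissue and 0 outside.
#'
#' @param thickness_um Mean slab thickness, micrometres.
#' @param voxel_spacing Micrometres per voxel.
#' @param grid_shape Voxels per axis (r, z, theta).
#' @param ripple_amplitude_um Peak surface ripple, micrometres.
#' @param ripple_cycles Integer number of ripple periods along z.
#' @return An `image_volume`.
#' @export
generate_slab_volume <- function(thickness_um, voxel_spacing = c(1, 1, 1),
                                 grid_shape = c(48L, 48L, 16L),
                                 ripple_amplitude_um = 0, ripple_cycles = 2L) {
  voxel_spacing <- check_spacing(voxel_spacing)
  n <- as.integer(grid_shape)
  zpos <- (seq_len(n[2]) - 0.5) * voxel_spacing[2]
  lz <- n[2] * voxel_spacing[2]
  top <- thickness_um +
    ripple_amplitude_um * sin(2 * pi * ripple_cycles * zpos / lz)
  if (max(top) > n[1] * voxel_spacing[1])
    stop("slab thicker than the radial grid extent")
  rpos <- (seq_len(n[1]) - 0.5) * voxel_spacing[1]
  slab2d <- outer(rpos, top, `<=`) * 1.0     # n_r x n_z
  arr <- array(slab2d, c(n[1], n[2], n[3]))
  image_volume(arr, voxel_spacing, depth_axis = 3L)
}
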