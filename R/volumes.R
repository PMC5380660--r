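#' Construct a 3-D scalar image volume
#'
#' Container for confocal-style intensity data on a regular voxel grid.  Axis
#' labels follow the cylindrical coordinates of the artery wall: `r` (radial,
#' transmural), `z` (axial) and `theta` (circumferential).
#'
#' @param intensity 3-D numeric array of finite intensities.
#' @param voxel_spacing Numeric length-3, micrometres per voxel along each
#'   array dimension; all entries must be positive.
#' @param axes Character length-3, a permutation of `c("r","z","theta")`
#'   labelling the array dimensions.
#' @param depth_axis Integer in 1..3, the acquisition (imaging depth) axis
#'   along which intensity attenuation occurs.
#' @return An object of class `"image_volume"`.
#' @seealso [microstructure()], [render_confocal()]
#' @export
image_volume <- function(intensity, voxel_spacing,
                         axes = c("r", "z", "theta"), depth_axis = 3L) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("`intensity` must be a 3-D array")
  if (!all(is.finite(intensity)))
    stop("`intensity` must be finite everywhere")
  voxel_spacing <- check_spacing(voxel_spacing)
  axes <- check_axes(axes)
  depth_axis <- as.integer(depth_axis)
  if (!depth_axis %in% 1:3) stop("`depth_axis` must be 1, 2 or 3")
  structure(list(intensity = intensity, voxel_spacing = voxel_spacing,
                 axes = axes, depth_axis = depth_axis),
            class = "image_volume")
}

#' Construct a binary medial microstructure
#'
#' Two-phase voxel representation of the tunica media: `TRUE` voxels are
#' extracellular matrix (ECM, the pore space accessible to an albumin-scale
#' tracer), `FALSE` voxels are smooth muscle cells and impervious fibres,
#' treated as impermeable in flow simulations.
#'
#' @param mask 3-D logical array, `TRUE` = ECM.
#' @param voxel_spacing Micrometres per voxel along each dimension.
#' @param axes Permutation of `c("r","z","theta")`.
#' @param threshold_used Optional intensity threshold that produced the mask.
#' @return An object of class `"binary_microstructure"`.
#' @export
microstructure <- function(mask, voxel_spacing, axes = c("r", "z", "theta"),
                           threshold_used = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a 3-D logical array")
  if (anyNA(mask)) stop("`mask` must not contain NA")
  voxel_spacing <- check_spacing(voxel_spacing)
  axes <- check_axes(axes)
  structure(list(mask = mask, voxel_spacing = voxel_spacing, axes = axes,
                 threshold_used = threshold_used),
            class = "binary_microstructure")
}

check_spacing <- function(voxel_spacing) {
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (length(voxel_spacing) != 3L || !all(is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be 3 positive values (um per voxel)")
  voxel_spacing
}

check_axes <- function(axes) {
  if (length(axes) != 3L || !setequal(axes, c("r", "z", "theta")))
    stop('`axes` must be a permutation of c("r", "z", "theta")')
  as.character(axes)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$intensity), collapse = " x "),
      " voxels (", paste(x$axes, collapse = ","), "), spacing ",
      paste(signif(x$voxel_spacing, 3), collapse = "/"),
      " um, depth axis ", x$axes[x$depth_axis], "\n", sep = "")
  cat("  intensity range [", signif(min(x$intensity), 4), ", ",
      signif(max(x$intensity), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_microstructure <- function(x, ...) {
  cat("<binary_microstructure> ", paste(dim(x$mask), collapse = " x "),
      " voxels (", paste(x$axes, collapse = ","), "), spacing ",
      paste(signif(x$voxel_spacing, 3), collapse = "/"), " um\n", sep = "")
  cat("  phi_ECM = ", signif(mean(x$mask), 4), sep = "")
  if (!is.null(x$threshold_used))
    cat(", threshold = ", signif(x$threshold_used, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' ECM volume fraction of a mask (quick accessor)
#'
#' Exact voxel-count fraction `phi_ECM = V_ECM / V`.
#' @param micro A `binary_microstructure`.
#' @return Numeric scalar in \[0, 1\].
#' @export
phi_ecm <- function(micro) {
  stopifnot(inherits(micro, "binary_microstructure"))
  mean(micro$mask)
}

## ---- TIFF round trip -------------------------------------------------------
## Multi-page TIFF, one page per slice along the depth axis, with a JSON
## sidecar (<path>.json) recording spacing, axes and the intensity scale.

#' Write an image volume as a multi-page TIFF with JSON sidecar
#'
#' Pages run along the volume's depth axis.  Intensities are stored as 32-bit
#' values normalised to \[0,1\]; the original range is recorded in the sidecar
#' and restored by [read_volume_tiff()].
#'
#' @param vol An `image_volume`.
#' @param path Output TIFF path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  d <- vol$depth_axis
  arr <- aperm(vol$intensity, c(setdiff(1:3, d), d))
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[3]), function(s) (arr[, , s] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(type = "intensity", voxel_spacing = vol$voxel_spacing,
               axes = vol$axes, depth_axis = vol$depth_axis,
               intensity_min = lo, intensity_scale = scale)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image volume written by [write_volume_tiff()]
#' @param path TIFF path with accompanying `.json` sidecar.
#' @return An `image_volume`.
#' @export
read_volume_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages)
  arr <- arr * side$intensity_scale + side$intensity_min
  d <- as.integer(side$depth_axis)
  arr <- aperm(arr, order(c(setdiff(1:3, d), d)))
  image_volume(arr, side$voxel_spacing, side$axes, d)
}

#' Write a binary microstructure as an 8-bit 0/255 TIFF with JSON sidecar
#' @param micro A `binary_microstructure`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(micro, path) {
  stopifnot(inherits(micro, "binary_microstructure"))
  pages <- lapply(seq_len(dim(micro$mask)[3]),
                  function(s) micro$mask[, , s] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  side <- list(type = "mask", voxel_spacing = micro$voxel_spacing,
               axes = micro$axes)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a binary microstructure written by [write_mask_tiff()]
#' @param path TIFF path with accompanying `.json` sidecar.
#' @return A `binary_microstructure`.
#' @export
read_mask_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages) > 0.5
  microstructure(arr, side$voxel_spacing, side$axes)
}
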