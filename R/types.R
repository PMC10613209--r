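#' @useDynLib conereg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cov optim rnorm runif sd approx isoreg median
#' @importFrom utils modifyList
NULL

# Spatial conventions shared by every module:
#  * world coordinates are right-handed, in millimetres, and refer to
#    voxel/pixel CENTERS;
#  * a 3D volume is an array dim c(nx, ny, nz) with x fastest-varying;
#    voxel (i,j,k) has world position origin + spacing * (i-1, j-1, k-1);
#  * a 2D image/mask is a matrix [x, y]; pixel (i,j) sits at
#    spacing * (i - 0.5, j - 0.5) in its own frame.

#' 3D scalar volume with isotropic spacing
#'
#' Container for a microCT-like volume: a rectangular grid of finite
#' intensities (dimensionless detector units), the isotropic voxel spacing in
#' mm, and the world position of the center of voxel (1,1,1).
#'
#' @param intensities numeric 3D array, dim `c(nx, ny, nz)`, x fastest.
#' @param spacing isotropic voxel edge length in mm (> 0).
#' @param origin world position (mm) of the first voxel center, length 3.
#' @return An object of class `volume3d` with fields `intensities`,
#'   `spacing`, `origin`.
#' @export
volume3d <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            all(dim(intensities) >= 1L))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("voxel spacing must be a single positive number (mm)")
  if (!all(is.finite(intensities)))
    stop("volume intensities must all be finite")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("volume3d: %d x %d x %d voxels, %.4g mm isotropic, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' RGB histology section image
#'
#' @param rgb numeric array dim `c(nx, ny, 3)` with values in `[0, 1]`.
#' @param pixel_spacing physical length per pixel in mm (> 0).
#' @return Object of class `histology_image`.
#' @export
histology_image <- function(rgb, pixel_spacing) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L)
  if (dim(rgb)[3] < 3L) stop("needs RGB: histology image must have three channels")
  if (dim(rgb)[3] > 3L) rgb <- rgb[, , 1:3, drop = FALSE]
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L || pixel_spacing <= 0)
    stop("pixel_spacing must be a single positive number (mm)")
  structure(list(rgb = rgb, pixel_spacing = pixel_spacing),
            class = "histology_image")
}

#' @export
print.histology_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("histology_image: %d x %d px RGB, %.4g mm/px (%.3g x %.3g mm)\n",
              d[1], d[2], x$pixel_spacing, d[1] * x$pixel_spacing, d[2] * x$pixel_spacing))
  invisible(x)
}

#' Binary mask (2D or 3D) with physical spacing
#'
#' @param values logical matrix (2D) or array (3D).
#' @param spacing mm per cell.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing) {
  stopifnot(is.logical(values), length(dim(values)) %in% c(2L, 3L), spacing > 0)
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s, %.4g mm/cell, %d foreground cells\n",
              paste(dim(x$values), collapse = " x "), x$spacing, sum(x$values)))
  invisible(x)
}

#' Oriented cutting plane in world coordinates
#'
#' A plane through `point` with unit `normal` and an in-plane orthonormal,
#' right-handed basis `(u, v, normal)`: `u x v = normal`.
#'
#' @param point world point on the plane (mm).
#' @param normal plane normal (will be normalized).
#' @param u optional in-plane direction seeding the basis (projected and
#'   normalized); an arbitrary perpendicular is chosen when omitted.
#' @return Object of class `cut_plane` with fields `point`, `normal`, `u`, `v`.
#' @export
cut_plane <- function(point, normal, u = NULL) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("plane normal must be non-zero")
  normal <- normal / nn
  if (is.null(u)) {
    seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seed - sum(seed * normal) * normal
  } else {
    u <- as.numeric(u)
    u <- u - sum(u * normal) * normal
  }
  un <- sqrt(sum(u^2))
  if (un < 1e-9) stop("in-plane seed direction is parallel to the normal")
  u <- u / un
  v <- cross3(normal, u)  # then u x v = normal (right-handed)
  structure(list(point = point, normal = normal, u = u, v = v),
            class = "cut_plane")
}

#' @export
print.cut_plane <- function(x, ...) {
  cat(sprintf("cut_plane: point (%.3f, %.3f, %.3f) mm, normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Fitted ellipse in image pixel coordinates
#'
#' @param center length-2 center (px, in the `[x, y]` image frame).
#' @param major_len full major-axis length (px).
#' @param minor_len full minor-axis length (px).
#' @param angle major-axis orientation in degrees, reduced to `[0, 180)`.
#' @return Object of class `ellipse_detection`.
#' @export
ellipse_detection <- function(center, major_len, minor_len, angle) {
  stopifnot(length(center) == 2L, minor_len > 0, major_len >= minor_len)
  structure(list(center = as.numeric(center), major_len = major_len,
                 minor_len = minor_len, angle = angle %% 180),
            class = "ellipse_detection")
}

#' @export
print.ellipse_detection <- function(x, ...) {
  cat(sprintf("ellipse: center (%.1f, %.1f) px, axes %.1f x %.1f px, angle %.1f deg\n",
              x$center[1], x$center[2], x$major_len, x$minor_len, x$angle))
  invisible(x)
}

# cross product of two length-3 vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}
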