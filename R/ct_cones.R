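# CT side of the workflow: segment the three cone phantoms out of the
# volume and turn each into a geometric model -- centroid, inertia axis and
# a smoothed, strictly monotone diameter -> height lookup table.

#' Threshold the volume to the phantom intensity band
#'
#' The cone phantoms are far brighter than resin (and usually than the
#' specimen), so a simple intensity band isolates them.
#'
#' @param volume a [volume3d].
#' @param intensity_low,intensity_high inclusive intensity band.
#' @return A 3D [binary_mask]; empty masks are allowed here but rejected by
#'   downstream operations (a warning is raised).
#' @export
segment_phantoms <- function(volume, intensity_low, intensity_high) {
  stopifnot(inherits(volume, "volume3d"))
  if (!(intensity_low < intensity_high))
    stop("intensity_low must be < intensity_high")
  m <- volume$intensities >= intensity_low & volume$intensities <= intensity_high
  if (!any(m)) warning("segmentation band selected no voxels")
  binary_mask(m, volume$spacing)
}

#' Label connected components and rank them by size
#'
#' Groups adjacent foreground voxels into labeled objects and sorts them by
#' voxel count, largest first (ties broken by smaller label id). When the
#' specimen shares the intensity band with the phantoms
#' (`specimen_in_band = TRUE`) the largest object is taken to be the
#' specimen and the next three are the cones; otherwise the three largest
#' are the cones.
#'
#' @param mask a 3D [binary_mask].
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @param specimen_in_band does the specimen fall inside the band?
#' @return A `labeled_objects` list: `label_map` (integer array),
#'   `objects` (list of `list(label, count)` sorted by count descending),
#'   `cone_labels` (labels of the three phantom objects, largest first).
#' @export
label_and_rank <- function(mask, connectivity = c(26, 6),
                           specimen_in_band = FALSE) {
  stopifnot(inherits(mask, "binary_mask"), length(dim(mask$values)) == 3L)
  connectivity <- as.integer(connectivity[1])
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (!any(mask$values)) stop("cannot label an empty mask")
  lab <- .label3d_cpp(as.logical(mask$values), dim(mask$values), connectivity)
  counts <- tabulate(lab[lab > 0L])
  ord <- order(-counts, seq_along(counts))  # count desc, smaller label first
  objects <- lapply(ord, function(i) list(label = i, count = counts[i]))
  need <- if (specimen_in_band) 4L else 3L
  if (length(objects) < need)
    stop(sprintf("need three phantoms: found only %d candidate object(s)",
                 length(objects) - (need - 3L)))
  cone_idx <- if (specimen_in_band) 2:4 else 1:3
  structure(list(label_map = lab, objects = objects,
                 cone_labels = vapply(objects[cone_idx],
                                      function(o) o$label, 0L),
                 spacing = mask$spacing),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("labeled_objects: %d object(s); counts: %s\n",
              length(x$objects),
              paste(vapply(utils::head(x$objects, 6), function(o) o$count, 0),
                    collapse = ", ")))
  invisible(x)
}

# voxel indices (i,j,k rows) of one labeled object
object_voxels <- function(labeled, label) {
  idx <- which(labeled$label_map == label)
  if (!length(idx)) stop("no voxels carry label ", label)
  arrayInd(idx, dim(labeled$label_map))
}

#' Centroid of an object in world coordinates
#'
#' Unweighted mean of the voxel-center world positions (the center of
#' gravity of the binary object).
#'
#' @param voxels integer matrix of voxel indices (rows = `(i,j,k)`).
#' @param spacing voxel spacing in mm.
#' @param origin world position of voxel (1,1,1) center.
#' @return Length-3 world point (mm).
#' @export
cone_centroid <- function(voxels, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.matrix(voxels), nrow(voxels) >= 1L)
  origin + spacing * (colMeans(voxels) - 1)
}

#' Inertia axis of an object
#'
#' Eigenvector of the centralized 3x3 covariance of the voxel positions
#' with the largest eigenvalue -- the elongation direction of the object.
#' The returned sign is arbitrary here; [build_cone_model] orients it so
#' the cone diameter increases with the height coordinate.
#'
#' @param voxels integer matrix of voxel indices.
#' @param spacing voxel spacing in mm.
#' @return Unit length-3 vector.
#' @export
cone_axis <- function(voxels, spacing) {
  stopifnot(is.matrix(voxels), nrow(voxels) >= 2L)
  cv <- stats::cov(voxels * spacing)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[1] < 1e-12) stop("degenerate voxel cloud: no elongation")
  if ((e$values[1] - e$values[2]) <= 1e-6 * e$values[1])
    stop("object is not elongated: top two inertia eigenvalues coincide")
  unit3(e$vectors[, 1])
}

#' Central axial cross-section of a 3D mask
#'
#' Samples the mask on the plane containing `centroid` and spanned by
#' `axis` (rows) and one perpendicular `v` (columns), at the volume's voxel
#' spacing with nearest-neighbor lookup. Rows are constant-height lines
#' along the cone axis, which makes per-row pixel counts local diameters.
#'
#' @param mask a 3D [binary_mask].
#' @param centroid world point on the section plane (mm).
#' @param axis unit vector; the section's row direction.
#' @param origin world position of voxel (1,1,1) center.
#' @param v optional unit vector perpendicular to `axis` (chosen otherwise).
#' @return list: `section` (logical matrix rows = heights), `spacing`,
#'   `heights` (mm, centered at the centroid), `v` (the perpendicular used).
#' @export
central_section <- function(mask, centroid, axis, origin = c(0, 0, 0), v = NULL) {
  stopifnot(inherits(mask, "binary_mask"), length(dim(mask$values)) == 3L)
  axis <- unit3(axis)
  if (is.null(v)) {
    seed <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- unit3(seed - sum(seed * axis) * axis)
  } else {
    v <- unit3(v - sum(v * axis) * axis)
  }
  sp <- mask$spacing
  d <- dim(mask$values)
  # generous sampling range: the grid diagonal covers any in-volume object
  half <- ceiling(sqrt(sum((d * sp)^2)) / 2 / sp)
  hs <- (-half:half) * sp
  ss <- (-half:half) * sp
  # world points centroid + h*axis + s*v, nearest voxel lookup
  px <- outer(hs * axis[1], ss * v[1], "+") + centroid[1]
  py <- outer(hs * axis[2], ss * v[2], "+") + centroid[2]
  pz <- outer(hs * axis[3], ss * v[3], "+") + centroid[3]
  ix <- round((px - origin[1]) / sp) + 1
  iy <- round((py - origin[2]) / sp) + 1
  iz <- round((pz - origin[3]) / sp) + 1
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  sec <- matrix(FALSE, nrow = length(hs), ncol = length(ss))
  sec[ok] <- mask$values[cbind(ix[ok], iy[ok], iz[ok])]
  if (!any(sec)) stop("central section does not intersect the object")
  # trim all-empty rows/columns, keep height bookkeeping
  rows <- which(rowSums(sec) > 0)
  cols <- which(colSums(sec) > 0)
  list(section = sec[rows, cols, drop = FALSE], spacing = sp,
       heights = hs[rows], v = v)
}

#' Raw diameter profile from a central section
#'
#' Counts foreground pixels per row of the central section and scales by
#' the voxel spacing: `diameter[r] = count[r] * spacing`, at height
#' `heights[r]` (mm, centered at the centroid). Zero-count rows are trimmed
#' at both ends.
#'
#' @param section logical matrix (rows = constant-height lines).
#' @param spacing mm per pixel of the section grid.
#' @param heights per-row height coordinates (mm); alternatively
#'   `centroid_row` gives the row index at height 0.
#' @param centroid_row used when `heights` is missing.
#' @return list of class `diameter_profile`: `height`, `diameter` (mm).
#' @export
diameter_profile <- function(section, spacing, heights = NULL, centroid_row = NULL) {
  stopifnot(is.matrix(section))
  counts <- rowSums(section)
  if (is.null(heights)) {
    if (is.null(centroid_row)) stop("give heights or centroid_row")
    heights <- (seq_len(nrow(section)) - centroid_row) * spacing
  }
  nz <- which(counts > 0)
  if (!length(nz)) stop("empty section: no foreground pixels")
  keep <- nz[1]:nz[length(nz)]
  structure(list(height = heights[keep], diameter = counts[keep] * spacing),
            class = "diameter_profile")
}

#' Smooth a diameter profile and enforce strict monotonicity
#'
#' Applies a Savitzky-Golay filter (third-degree polynomial regression by
#' default) to the raw per-row diameters, then projects the result onto the
#' strictly increasing cone by isotonic regression plus a vanishing ramp,
#' so the profile is invertible for the diameter -> height lookup.
#'
#' @param raw a `diameter_profile`.
#' @param window odd filter window length (samples); must exceed `polyorder`
#'   and not exceed the sample count.
#' @param polyorder polynomial degree of the filter.
#' @return A `diameter_profile` with smoothed, strictly increasing
#'   diameters; attribute `degenerate` flags inputs with no increasing
#'   trend (e.g. constant profiles).
#' @export
smooth_profile <- function(raw, window = 11L, polyorder = 3L) {
  stopifnot(inherits(raw, "diameter_profile"))
  n <- length(raw$diameter)
  if (n < 5L) stop("profile too short to smooth (need >= 5 samples)")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > n)
    stop(sprintf("window (%d) exceeds sample count (%d); use a smaller window",
                 window, n))
  sm <- signal::sgolayfilt(raw$diameter, p = polyorder, n = window)
  # increasing-in-height orientation is the module convention; callers flip
  # the axis sign (and the profile) when the trend is decreasing
  iso <- stats::isoreg(raw$height, sm)
  y <- iso$yf
  rng <- diff(range(sm))
  degenerate <- rng <= 1e-12 || all(diff(y) <= 0)
  eps <- 1e-9 * max(rng, max(abs(sm)), 1)
  y <- y + eps * seq_len(n)  # break ties: strictly increasing
  structure(list(height = raw$height, diameter = y),
            class = "diameter_profile", degenerate = degenerate)
}

#' @export
print.diameter_profile <- function(x, ...) {
  cat(sprintf("diameter_profile: %d samples, height [%.3f, %.3f] mm, diameter [%.3f, %.3f] mm\n",
              length(x$height), min(x$height), max(x$height),
              min(x$diameter), max(x$diameter)))
  invisible(x)
}

#' Build the geometric model of one cone phantom
#'
#' Composes centroid, inertia axis, central cross-section and the raw and
#' smoothed diameter profiles for the phantom of the given rank (0-2,
#' largest first). The axis sign is fixed so that the diameter increases
#' with the height coordinate (apex at the most negative height).
#'
#' @param volume the [volume3d] the mask came from (for origin bookkeeping).
#' @param labeled a `labeled_objects` from [label_and_rank].
#' @param cone_rank 0, 1 or 2.
#' @param sg_window,sg_polyorder Savitzky-Golay settings for [smooth_profile].
#' @return Object of class `cone_model`: `label`, `centroid`, `axis`,
#'   `profile` (smoothed), `raw_profile`, `voxel_count`, `spacing`.
#' @export
build_cone_model <- function(volume, labeled, cone_rank,
                             sg_window = 11L, sg_polyorder = 3L) {
  stopifnot(inherits(volume, "volume3d"), inherits(labeled, "labeled_objects"))
  if (!is.numeric(cone_rank) || length(cone_rank) != 1L ||
      !cone_rank %in% 0:2)
    stop("cone_rank must be an index ranging from 0 to 2")
  label <- labeled$cone_labels[cone_rank + 1L]
  vox <- object_voxels(labeled, label)
  sp <- volume$spacing
  centroid <- cone_centroid(vox, sp, volume$origin)
  axis <- cone_axis(vox, sp)
  mask <- binary_mask(labeled$label_map == label, sp)
  sec <- central_section(mask, centroid, axis, volume$origin)
  raw <- diameter_profile(sec$section, sp, heights = sec$heights)
  # orient: diameter must grow with height (base at +h, apex at -h)
  slope <- stats::cor(raw$height, raw$diameter)
  if (is.na(slope)) stop("flat diameter profile: object is not a cone")
  if (slope < 0) {
    axis <- -axis
    raw <- structure(list(height = rev(-raw$height),
                          diameter = rev(raw$diameter)),
                     class = "diameter_profile")
  }
  prof <- smooth_profile(raw, window = sg_window, polyorder = sg_polyorder)
  structure(list(label = label, centroid = centroid, axis = axis,
                 profile = prof, raw_profile = raw,
                 voxel_count = nrow(vox), spacing = sp),
            class = "cone_model")
}

#' @export
print.cone_model <- function(x, ...) {
  cat(sprintf("cone_model: label %d, %d voxels, centroid (%.2f, %.2f, %.2f) mm, axis (%.3f, %.3f, %.3f)\n",
              x$label, x$voxel_count,
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$axis[1], x$axis[2], x$axis[3]))
  print(x$profile)
  invisible(x)
}
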