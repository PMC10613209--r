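# Plane solving: invert each cone's diameter -> height lookup at the
# measured minor-axis length, place one point per cone on its inertia
# axis, span the cutting plane through the three points, and resample the
# in-silico plane from the CT volume.

#' Invert a cone's diameter profile
#'
#' Linear interpolation of the inverse of the strictly monotone smoothed
#' profile: the signed height (centered at the centroid) at which the cone
#' has the given local diameter.
#'
#' @param cone a `cone_model` from [build_cone_model].
#' @param d_mm measured diameter (mm); must lie within the profile range.
#' @return Signed height in mm along the cone axis.
#' @export
height_for_diameter <- function(cone, d_mm) {
  stopifnot(inherits(cone, "cone_model"))
  p <- cone$profile
  dmin <- min(p$diameter); dmax <- max(p$diameter)
  if (d_mm < dmin || d_mm > dmax)
    stop(sprintf(paste0("diameter %.4f mm outside this cone's profile range ",
                        "[%.4f, %.4f] mm; the cutting plane must intersect ",
                        "all three phantoms"), d_mm, dmin, dmax))
  stats::approx(p$diameter, p$height, xout = d_mm, ties = "ordered")$y
}

#' Point on a cone's inertia axis at a given height
#'
#' @param cone a `cone_model`.
#' @param h_mm signed height relative to the centroid.
#' @return World point `centroid + h_mm * axis` (mm).
#' @export
point_on_axis <- function(cone, h_mm) {
  stopifnot(inherits(cone, "cone_model"), is.finite(h_mm))
  cone$centroid + h_mm * cone$axis
}

#' Match detected ellipses to cone models
#'
#' For each of the six permutations, the three candidate axis points are
#' computed (ellipse minor axis -> height lookup -> point on axis) and
#' their pairwise 3D distances compared with the pairwise 2D distances of
#' the ellipse centers (both in mm; pairwise distances are invariant to
#' the section's unknown in-plane pose). The permutation minimizing the
#' summed absolute discrepancy wins. Permutations whose diameters fall
#' outside a cone's profile range are infeasible.
#'
#' @param ellipses list of 3 [ellipse_detection]s.
#' @param cones list of 3 `cone_model`s.
#' @param pixel_spacing histology mm/px.
#' @param force optional integer permutation (ellipse index -> cone rank
#'   1..3) applied verbatim.
#' @param max_ambiguity_ratio best-to-second-best residual ratio above
#'   which a warning is raised (default 0.95: within 5%).
#' @return list: `perm` (ellipse i matches cone `perm[i]`), `residual`
#'   (mm), `heights` (per ellipse, mm), `ambiguous` (logical).
#' @export
assign_correspondence <- function(ellipses, cones, pixel_spacing,
                                  force = NULL, max_ambiguity_ratio = 0.95) {
  stopifnot(length(ellipses) == 3L, length(cones) == 3L)
  d_mm <- vapply(ellipses, minor_axis_mm, 0, pixel_spacing = pixel_spacing)
  centers <- t(vapply(ellipses, function(e) e$center, c(0, 0))) * pixel_spacing
  d2 <- as.vector(stats::dist(centers))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  eval_perm <- function(pm) {
    h <- numeric(3)
    for (i in 1:3) {
      h[i] <- tryCatch(height_for_diameter(cones[[pm[i]]], d_mm[i]),
                       error = function(e) NA_real_)
    }
    if (anyNA(h)) return(list(res = Inf, h = h))
    pts <- t(vapply(1:3, function(i) point_on_axis(cones[[pm[i]]], h[i]),
                    c(0, 0, 0)))
    d3 <- as.vector(stats::dist(pts))
    list(res = sum(abs(d3 - d2)), h = h)
  }
  if (!is.null(force)) {
    stopifnot(setequal(force, 1:3))
    ev <- eval_perm(force)
    return(list(perm = as.integer(force), residual = ev$res,
                heights = ev$h, ambiguous = FALSE))
  }
  evs <- lapply(perms, eval_perm)
  res <- vapply(evs, function(e) e$res, 0)
  if (all(!is.finite(res)))
    stop("no feasible correspondence: every assignment puts a diameter outside its cone's profile")
  best <- which.min(res)
  ranked <- sort(res)
  ambiguous <- length(ranked) > 1 && is.finite(ranked[2]) &&
    ranked[1] >= max_ambiguity_ratio * ranked[2]
  if (ambiguous)
    warning(sprintf(paste0("ambiguous cone correspondence (best residual ",
                           "%.4g vs second %.4g mm); consider forcing a ",
                           "permutation"), ranked[1], ranked[2]))
  list(perm = perms[[best]], residual = res[best],
       heights = evs[[best]]$h, ambiguous = ambiguous)
}

#' Fit the cutting plane through three points
#'
#' @param p0,p1,p2 world points (mm); must not be collinear.
#' @return A [cut_plane]: `point` is the centroid of the three points, the
#'   normal is the normalized cross product `(p1-p0) x (p2-p0)` with its
#'   sign fixed toward the +z hemisphere (+y, then +x, on ties), and `u`
#'   is the in-plane direction of `p1-p0`.
#' @export
fit_plane <- function(p0, p1, p2) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  n <- cross3(p1 - p0, p2 - p0)
  area2 <- sqrt(sum(n^2))
  if (area2 / 2 <= 1e-6)
    stop("the three axis points are (nearly) collinear; cannot span a plane")
  n <- n / area2
  s <- sign(n[3])
  if (s == 0) s <- sign(n[2])
  if (s == 0) s <- sign(n[1])
  if (s < 0) n <- -n
  cut_plane(point = (p0 + p1 + p2) / 3, normal = n, u = p1 - p0)
}

#' Resample an oblique plane from a volume
#'
#' Samples the volume on a square grid centered at `plane$point` with axes
#' `(u, v)`, using trilinear interpolation. Samples outside the volume are
#' 0 and flagged invalid.
#'
#' @param volume a [volume3d].
#' @param plane a [cut_plane].
#' @param out_spacing sample pitch in mm (default: the voxel spacing).
#' @param half_extent_mm half edge length of the sampled square (mm).
#' @return A `plane_image`: `intensities` (matrix `[u, v]`), `validity`
#'   (logical), `spacing`, `frame` (the plane), `offsets` (sample
#'   coordinates along u/v, mm, centered on `plane$point`).
#' @export
resample_plane <- function(volume, plane, out_spacing = NULL, half_extent_mm) {
  stopifnot(inherits(volume, "volume3d"), inherits(plane, "cut_plane"))
  if (is.null(out_spacing)) out_spacing <- volume$spacing
  stopifnot(out_spacing > 0, half_extent_mm > 0)
  k <- floor(half_extent_mm / out_spacing)
  off <- (-k:k) * out_spacing
  n <- length(off)
  # world sample points p = point + a*u + b*v
  px <- plane$point[1] + outer(off * plane$u[1], off * plane$v[1], "+")
  py <- plane$point[2] + outer(off * plane$u[2], off * plane$v[2], "+")
  pz <- plane$point[3] + outer(off * plane$u[3], off * plane$v[3], "+")
  ti <- trilinear(volume, px, py, pz)
  if (!any(ti$valid)) stop("plane does not overlap the volume")
  structure(list(intensities = matrix(ti$value, n, n),
                 validity = matrix(ti$valid, n, n),
                 spacing = out_spacing, frame = plane, offsets = off),
            class = "plane_image")
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("plane_image: %d x %d samples at %.4g mm, %.1f%% inside the volume\n",
              nrow(x$intensities), ncol(x$intensities), x$spacing,
              100 * mean(x$validity)))
  invisible(x)
}

# vectorized trilinear interpolation at world points (same-length arrays)
trilinear <- function(volume, px, py, pz) {
  sp <- volume$spacing; o <- volume$origin
  d <- dim(volume$intensities)
  gx <- (as.vector(px) - o[1]) / sp + 1
  gy <- (as.vector(py) - o[2]) / sp + 1
  gz <- (as.vector(pz) - o[3]) / sp + 1
  valid <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2] & gz >= 1 & gz <= d[3]
  x0 <- pmin(pmax(floor(gx), 1), d[1] - 1); fx <- gx - x0
  y0 <- pmin(pmax(floor(gy), 1), d[2] - 1); fy <- gy - y0
  z0 <- pmin(pmax(floor(gz), 1), d[3] - 1); fz <- gz - z0
  # clamp fractions for points exactly on the far face
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1); fz <- pmin(pmax(fz, 0), 1)
  v <- volume$intensities
  at <- function(ix, iy, iz) v[cbind(ix, iy, iz)]
  val <-
    at(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
    at(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
    at(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
    at(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
    at(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  val[!valid] <- 0
  list(value = val, valid = valid)
}
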