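# Ground-truthed synthetic phantoms: voxelized resin blocks containing
# three cones and a tissue-like object, and stain-like section images
# rendered from a known cutting plane, so the whole pipeline can be
# validated without any real scan.

#' Analytic cone specification
#'
#' @param apex world apex position (mm).
#' @param axis unit vector from apex toward the base.
#' @param height apex-to-base distance (mm, > 0).
#' @param base_diameter base diameter (mm, > 0).
#' @param intensity CT intensity of the cone material.
#' @return Object of class `cone_spec`.
#' @export
cone_spec <- function(apex, axis, height, base_diameter, intensity = 3000) {
  stopifnot(height > 0, base_diameter > 0)
  structure(list(apex = as.numeric(apex), axis = unit3(axis),
                 height = height, base_diameter = base_diameter,
                 intensity = intensity),
            class = "cone_spec")
}

#' Generator-side ground truth for one synthetic case
#'
#' @param cones list of 3 [cone_spec]s.
#' @param tissue list with `center`, `radius`, `intensity` (a sphere
#'   emulating the specimen) or `NULL`.
#' @param true_plane the physical cutting plane, a [cut_plane].
#' @param seed integer seed driving all randomness of this case.
#' @param noise list: `ct_sigma` (CT intensity noise sd), `fray_px`
#'   (boundary fray amplitude at histology resolution), `px_sigma`
#'   (image pixel noise sd on a 0-1 scale).
#' @param view list: in-plane `angle_deg`, `offset_mm` (length 2) and
#'   `flip` describing the section image's arbitrary framing.
#' @return Object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(cones, tissue, true_plane, seed,
                            noise = list(ct_sigma = 0, fray_px = 0, px_sigma = 0),
                            view = list(angle_deg = 0, offset_mm = c(0, 0),
                                        flip = FALSE)) {
  stopifnot(length(cones) == 3L, inherits(true_plane, "cut_plane"))
  for (cn in cones) {
    hit <- tryCatch(exact_cone_plane_ellipse(cn, true_plane),
                    error = function(e) NULL)
    if (is.null(hit))
      stop("true_plane must intersect all three phantoms in bounded ellipses")
  }
  structure(list(cones = cones, tissue = tissue, true_plane = true_plane,
                 seed = as.integer(seed), noise = noise, view = view),
            class = "synthetic_truth")
}

# index range of a cone's world-space bounding box on the voxel grid
cone_bbox <- function(cone, spacing, origin, dims) {
  a <- cone$apex; b <- cone$apex + cone$height * cone$axis
  r <- cone$base_diameter / 2
  lo <- pmin(a, b) - r; hi <- pmax(a, b) + r
  i0 <- pmax(floor((lo - origin) / spacing) + 1, 1)
  i1 <- pmin(ceiling((hi - origin) / spacing) + 1, dims)
  if (any(i0 > i1)) NULL else list(i0 = i0, i1 = i1)
}

#' Voxelize a synthetic resin block
#'
#' Voxel intensity is the resin base where the voxel center lies in no
#' solid, the tissue or cone intensity where it lies inside the analytic
#' solids (exact point-in-cone / point-in-sphere tests; cones override
#' tissue), plus seeded Gaussian noise.
#'
#' @param truth a [synthetic_truth].
#' @param shape grid dimensions, default `c(256, 256, 256)`.
#' @param spacing isotropic voxel spacing (mm), default 0.08.
#' @param resin_intensity background intensity.
#' @return A [volume3d].
#' @export
simulate_block <- function(truth, shape = c(256L, 256L, 256L), spacing = 0.08,
                           resin_intensity = 200) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dims <- as.integer(shape)
  origin <- c(0, 0, 0)
  extent_hi <- origin + (dims - 1) * spacing
  vol <- array(resin_intensity, dim = dims)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  if (!is.null(truth$tissue)) {
    tc <- truth$tissue$center; tr2 <- truth$tissue$radius^2
    bb <- list(i0 = pmax(floor((tc - truth$tissue$radius - origin) / spacing) + 1, 1),
               i1 = pmin(ceiling((tc + truth$tissue$radius - origin) / spacing) + 1, dims))
    ix <- bb$i0[1]:bb$i1[1]; iy <- bb$i0[2]:bb$i1[2]; iz <- bb$i0[3]:bb$i1[3]
    dx2 <- (xs[ix] - tc[1])^2; dy2 <- (ys[iy] - tc[2])^2; dz2 <- (zs[iz] - tc[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= tr2
    sub <- vol[ix, iy, iz]; sub[inside] <- truth$tissue$intensity
    vol[ix, iy, iz] <- sub
  }
  for (cone in truth$cones) {
    a <- cone$apex; w <- cone$axis; H <- cone$height
    tanr <- (cone$base_diameter / 2) / H
    base_ctr <- a + H * w
    disc_half <- (cone$base_diameter / 2) * sqrt(pmax(1 - w^2, 0))
    if (any(a < origin - spacing / 2) || any(a > extent_hi + spacing / 2) ||
        any(base_ctr - disc_half < origin - spacing / 2) ||
        any(base_ctr + disc_half > extent_hi + spacing / 2))
      stop("cone extends outside the voxel grid")
    bb <- cone_bbox(cone, spacing, origin, dims)
    ix <- bb$i0[1]:bb$i1[1]; iy <- bb$i0[2]:bb$i1[2]; iz <- bb$i0[3]:bb$i1[3]
    t_arr <- outer(outer((xs[ix] - a[1]) * w[1], (ys[iy] - a[2]) * w[2], "+"),
                   (zs[iz] - a[3]) * w[3], "+")
    d2 <- outer(outer((xs[ix] - a[1])^2, (ys[iy] - a[2])^2, "+"),
                (zs[iz] - a[3])^2, "+")
    inside <- t_arr >= 0 & t_arr <= H & (d2 - t_arr^2) <= (tanr * t_arr)^2
    sub <- vol[ix, iy, iz]; sub[inside] <- cone$intensity
    vol[ix, iy, iz] <- sub
  }
  if (truth$noise$ct_sigma > 0) {
    set.seed(truth$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, truth$noise$ct_sigma),
                       dim = dims)
  }
  volume3d(vol, spacing, origin)
}

#' Exact ellipse of a cone-plane intersection
#'
#' Restricts the cone's quadric surface to the plane and extracts the
#' resulting conic analytically. Errors when the section is unbounded
#' (parabola/hyperbola: the plane is steeper than the cone's slant).
#'
#' @param cone a [cone_spec].
#' @param plane a [cut_plane].
#' @return An [ellipse_detection] whose `center` is in the plane's (u, v)
#'   coordinates in mm (relative to `plane$point`), `major_len` /
#'   `minor_len` in mm, `angle` relative to the u axis; attribute
#'   `cut_diameter_mm` is the cone's circular diameter at the axial cut
#'   position, and `axis_t_mm` that position's apex distance.
#' @export
exact_cone_plane_ellipse <- function(cone, plane) {
  stopifnot(inherits(cone, "cone_spec"), inherits(plane, "cut_plane"))
  a <- cone$apex; w <- cone$axis
  alpha <- atan2(cone$base_diameter / 2, cone$height)
  c2 <- cos(alpha)^2
  m0 <- plane$point - a
  u <- plane$u; v <- plane$v
  uw <- sum(u * w); vw <- sum(v * w); m0w <- sum(m0 * w)
  A <- uw^2 - c2
  B <- 2 * uw * vw
  C <- vw^2 - c2
  D <- 2 * m0w * uw - 2 * c2 * sum(m0 * u)
  E <- 2 * m0w * vw - 2 * c2 * sum(m0 * v)
  Fc <- m0w^2 - c2 * sum(m0 * m0)
  if (B^2 - 4 * A * C >= 0)
    stop("plane is too steep: cone section is unbounded (not an ellipse)")
  ell <- conic_to_ellipse(c(A, B, C, D, E, Fc))
  if (is.null(ell)) stop("degenerate cone-plane intersection")
  wn <- sum(w * plane$normal)
  if (abs(wn) < 1e-9) stop("plane is parallel to the cone axis")
  t_axis <- sum((plane$point - a) * plane$normal) / wn
  if (t_axis <= 0 || t_axis >= cone$height)
    stop("plane misses the cone's lateral surface between apex and base")
  attr(ell, "cut_diameter_mm") <- cone$base_diameter * t_axis / cone$height
  attr(ell, "axis_t_mm") <- t_axis
  ell
}

# smooth periodic radial perturbation (mm) evaluated at angles theta;
# zero-mean harmonics 2..6, sd ~ amplitude
fray_fun <- function(amplitude_mm, rng_draws) {
  if (amplitude_mm <= 0) return(function(theta) rep(0, length(theta)))
  h <- 2:6
  g <- rng_draws$g; phi <- rng_draws$phi
  amp <- amplitude_mm * sqrt(2) * g / sqrt(sum(g^2))
  function(theta) {
    out <- numeric(length(theta))
    for (k in seq_along(h)) out <- out + amp[k] * cos(h[k] * theta + phi[k])
    out
  }
}

#' Render a stained-section image from the true plane
#'
#' Renders, on the section's own (randomly posed, possibly mirrored) view
#' frame: the tissue cross-section in a stain-like red, the three exact
#' cone ellipses in a dark phantom color on a bright resin background;
#' then applies seeded boundary fray (smooth radial perturbation of the
#' cone contours) and Gaussian pixel noise, quantized to 8 bits.
#'
#' @param truth a [synthetic_truth].
#' @param pixel_spacing mm per pixel (default 0.007).
#' @param half_extent_mm half edge of the rendered square (mm); by default
#'   sized so all three cone cross-sections fit with a 1.5 mm margin.
#' @return list: `image` (a [histology_image]), `mask_cones` and
#'   `mask_all` (fray-free ground-truth [binary_mask]s), `ellipses_px`
#'   (exact, fray-free cone ellipses in image pixel coordinates).
#' @export
simulate_section <- function(truth, pixel_spacing = 0.007, half_extent_mm = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  pl <- truth$true_plane
  vw <- truth$view
  psi <- vw$angle_deg * pi / 180
  u2 <- cos(psi) * pl$u + sin(psi) * pl$v
  v2 <- -sin(psi) * pl$u + cos(psi) * pl$v
  if (isTRUE(vw$flip)) v2 <- -v2
  q <- pl$point + vw$offset_mm[1] * pl$u + vw$offset_mm[2] * pl$v
  view <- cut_plane(q, if (isTRUE(vw$flip)) -pl$normal else pl$normal, u2)
  # cut_plane re-derives v = n x u; for the mirrored normal that equals -v2
  stopifnot(max(abs(view$v - v2)) < 1e-9)
  ells <- lapply(truth$cones, exact_cone_plane_ellipse, plane = view)
  if (is.null(half_extent_mm)) {
    reach <- vapply(ells, function(e) {
      max(abs(e$center)) + e$major_len / 2
    }, 0)
    half_extent_mm <- max(max(reach) + 1.5 +
                            4 * truth$noise$fray_px * pixel_spacing, 8)
  }
  k <- floor(half_extent_mm / pixel_spacing)
  n <- 2L * k + 1L
  px_of_mm <- function(mm) mm / pixel_spacing + k + 0.5  # continuous px coord
  col_bg <- c(0.92, 0.89, 0.86)
  col_tis <- c(0.72, 0.28, 0.32)
  col_cone <- c(0.16, 0.15, 0.18)
  chan <- lapply(col_bg, function(cv) matrix(cv, n, n))
  mask_all <- matrix(FALSE, n, n)
  mask_cones <- matrix(FALSE, n, n)
  xs_mm <- (seq_len(n) - k - 1L) * pixel_spacing
  if (!is.null(truth$tissue)) {
    # sphere cross-section in the view plane is an analytic disk
    dc <- truth$tissue$center - q
    h <- sum(dc * view$normal)
    r2 <- truth$tissue$radius^2 - h^2
    if (r2 > 0) {
      cx <- sum(dc * view$u); cy <- sum(dc * view$v)
      inside <- outer((xs_mm - cx)^2, (xs_mm - cy)^2, "+") <= r2
      for (ch in 1:3) chan[[ch]][inside] <- col_tis[ch]
      mask_all <- mask_all | inside
    }
  }
  set.seed(truth$seed + 1L)
  ellipses_px <- vector("list", 3L)
  for (ci in seq_along(truth$cones)) {
    ell <- ells[[ci]]
    Asemi <- ell$major_len / 2; Bsemi <- ell$minor_len / 2
    phi <- ell$angle * pi / 180
    fr <- fray_fun(truth$noise$fray_px * pixel_spacing,
                   list(g = stats::rnorm(5), phi = stats::runif(5, 0, 2 * pi)))
    margin <- Asemi + truth$noise$fray_px * pixel_spacing * 4 + 2 * pixel_spacing
    ix <- which(xs_mm >= ell$center[1] - margin & xs_mm <= ell$center[1] + margin)
    iy <- which(xs_mm >= ell$center[2] - margin & xs_mm <= ell$center[2] + margin)
    dx <- outer(xs_mm[ix] - ell$center[1], rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), xs_mm[iy] - ell$center[2])
    theta <- atan2(dy, dx)
    rpix <- sqrt(dx^2 + dy^2)
    rb <- Asemi * Bsemi / sqrt((Bsemi * cos(theta - phi))^2 +
                               (Asemi * sin(theta - phi))^2)
    exact_in <- rpix <= rb
    frayed_in <- rpix <= rb + fr(theta)
    for (ch in 1:3) {
      sub <- chan[[ch]][ix, iy]; sub[frayed_in] <- col_cone[ch]
      chan[[ch]][ix, iy] <- sub
    }
    mc <- mask_cones[ix, iy]; mc[exact_in] <- TRUE; mask_cones[ix, iy] <- mc
    ma <- mask_all[ix, iy]; ma[exact_in] <- TRUE; mask_all[ix, iy] <- ma
    ellipses_px[[ci]] <- ellipse_detection(
      center = px_of_mm(ell$center),
      major_len = ell$major_len / pixel_spacing,
      minor_len = ell$minor_len / pixel_spacing,
      angle = ell$angle)
  }
  rgb <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    layer <- chan[[ch]]
    if (truth$noise$px_sigma > 0)
      layer <- layer + matrix(stats::rnorm(n * n, 0, truth$noise$px_sigma), n, n)
    rgb[, , ch] <- pmin(pmax(round(layer * 255) / 255, 0), 1)
  }
  list(image = histology_image(rgb, pixel_spacing),
       mask_cones = binary_mask(mask_cones, pixel_spacing),
       mask_all = binary_mask(mask_all, pixel_spacing),
       ellipses_px = ellipses_px)
}

#' Reproducible suite of synthetic cases
#'
#' Generates `n_cases` ground-truthed cases with randomized cone poses
#' (sizes, small axial tilts, jittered positions), a cutting plane tilted
#' at most 15 degrees from cone-perpendicular that provably intersects
#' all three cones between 30% and 80% of their heights, a tissue sphere,
#' and a randomly posed (rotated/offset/possibly mirrored) section view.
#' `clean` and `noisy` cases differ only in the noise/fray fields.
#'
#' @param n_cases number of cases (>= 1).
#' @param master_seed integer seed; the whole suite is a pure function of it.
#' @param difficulty `"clean"` (no noise, no fray) or `"noisy"`
#'   (CT intensity noise sd 80, fray 2 px, pixel noise sd 0.015).
#' @param spacing voxel spacing the cases are designed for (mm).
#' @param shape grid the cases are designed for.
#' @return list of [synthetic_truth] objects.
#' @export
benchmark_suite <- function(n_cases, master_seed,
                            difficulty = c("clean", "noisy"),
                            spacing = 0.08, shape = c(256L, 256L, 256L)) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_cases >= 1)
  noise <- if (difficulty == "noisy")
    list(ct_sigma = 80, fray_px = 2, px_sigma = 0.015)
  else list(ct_sigma = 0, fray_px = 0, px_sigma = 0)
  set.seed(as.integer(master_seed))
  case_seeds <- sample.int(2^31 - 2, n_cases)
  lapply(seq_len(n_cases), function(i) {
    make_case(case_seeds[i], noise, spacing, shape)
  })
}

# one randomized, guaranteed-solvable case: three cones on a 120-degree
# ring around a central tissue sphere, apexes down, axes leaning only
# inward so every solid stays inside the block
make_case <- function(seed, noise, spacing, shape) {
  set.seed(seed)
  ctr <- (shape - 1) * spacing / 2  # block center (mm)
  ring <- 6.5
  ring_angles <- c(90, 210, 330) * pi / 180
  cones <- vector("list", 3L)
  mid_z <- numeric(3)
  for (i in 1:3) {
    H <- stats::runif(1, 10, 14)
    D <- stats::runif(1, 4, 6)
    xy <- ring * c(cos(ring_angles[i]), sin(ring_angles[i])) +
      stats::runif(2, -0.5, 0.5)
    tilt <- stats::runif(1, 0, 5) * pi / 180
    az <- atan2(-xy[2], -xy[1]) + stats::runif(1, -pi / 3, pi / 3)
    ax <- unit3(c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt)))
    apex_z <- stats::runif(1, 2.6, 3.4)
    apex <- c(ctr[1] + xy[1], ctr[2] + xy[2], apex_z)
    cones[[i]] <- cone_spec(apex, ax, H, D)
    mid_z[i] <- apex_z + 0.55 * H * ax[3]
  }
  ptilt <- stats::runif(1, 2, 15) * pi / 180
  paz <- stats::runif(1, 0, 2 * pi)
  normal <- unit3(c(sin(ptilt) * cos(paz), sin(ptilt) * sin(paz), cos(ptilt)))
  # choose the plane height so every cone is cut at 30-80% of its height
  z_ok <- function(z0) {
    pl <- cut_plane(c(ctr[1], ctr[2], z0), normal)
    frac <- vapply(cones, function(cn) {
      wn <- sum(cn$axis * pl$normal)
      t <- sum((pl$point - cn$apex) * pl$normal) / wn
      t / cn$height
    }, 0)
    all(frac >= 0.30 & frac <= 0.80)
  }
  zs <- seq(min(mid_z) - 4, max(mid_z) + 4, by = 0.05)
  feasible <- zs[vapply(zs, z_ok, TRUE)]
  if (!length(feasible)) stop("internal: no feasible plane height for case")
  z0 <- feasible[ceiling(stats::runif(1) * length(feasible))]
  plane <- cut_plane(c(ctr[1], ctr[2], z0), normal)
  tis_dz <- stats::runif(1, -0.5, 0.5)
  tissue <- list(center = c(ctr[1], ctr[2], z0 + tis_dz),
                 radius = 3.0, intensity = 1200)
  view <- list(angle_deg = stats::runif(1, 0, 360),
               offset_mm = stats::runif(2, -1.5, 1.5),
               flip = stats::runif(1) < 0.5)
  synthetic_truth(cones, tissue, plane, seed = seed,
                  noise = noise, view = view)
}
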