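# Shared fixtures and independent oracles, all built in code.

unit3_h <- function(v) v / sqrt(sum(v^2))

# rasterize a filled ellipse on an n x n grid (pixel centers at i - 0.5)
rasterize_ellipse <- function(cx, cy, semi_a, semi_b, angle_deg, n) {
  th <- angle_deg * pi / 180
  xs <- matrix(rep(seq_len(n) - 0.5, n), n)
  ys <- t(xs)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / semi_a)^2 + (v / semi_b)^2 <= 1
}

# rasterize a solid cone into a logical voxel grid (centers at (i-1)*sp)
rasterize_cone <- function(apex, axis, height, base_diameter, dims, spacing) {
  axis <- axis / sqrt(sum(axis^2))
  xs <- (seq_len(dims[1]) - 1) * spacing
  ys <- (seq_len(dims[2]) - 1) * spacing
  zs <- (seq_len(dims[3]) - 1) * spacing
  t_arr <- outer(outer((xs - apex[1]) * axis[1], (ys - apex[2]) * axis[2], "+"),
                 (zs - apex[3]) * axis[3], "+")
  d2 <- outer(outer((xs - apex[1])^2, (ys - apex[2])^2, "+"),
              (zs - apex[3])^2, "+")
  tanr <- (base_diameter / 2) / height
  t_arr >= 0 & t_arr <= height & (d2 - t_arr^2) <= (tanr * t_arr)^2
}

# exhaustive Otsu: scan all 256 threshold bins, maximize between-class
# variance; returns the dark-class membership of every pixel
exhaustive_otsu_set <- function(gray) {
  lv <- pmin(floor(pmin(pmax(gray, 0), 1) * 256), 255)
  best <- -1; best_t <- 0
  for (t in 0:254) {
    w0 <- mean(lv <= t)
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(lv[lv <= t]); mu1 <- mean(lv[lv > t])
    bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  lv <= best_t
}

# ellipse parameters of a convex planar region from a dense boundary
# polygon: shoelace centroid + second area moments (independent of the
# conic algebra under test)
polygon_ellipse_params <- function(bx, by) {
  n <- length(bx)
  x2 <- c(bx[-1], bx[1]); y2 <- c(by[-1], by[1])
  cr <- bx * y2 - x2 * by
  A <- sum(cr) / 2
  cx <- sum((bx + x2) * cr) / (6 * A)
  cy <- sum((by + y2) * cr) / (6 * A)
  Ixx <- sum((by^2 + by * y2 + y2^2) * cr) / 12 - A * cy^2
  Iyy <- sum((bx^2 + bx * x2 + x2^2) * cr) / 12 - A * cx^2
  Ixy <- sum((bx * y2 + 2 * bx * by + 2 * x2 * y2 + x2 * by) * cr) / 24 -
    A * cx * cy
  # for an ellipse: Iyy/A = a^2 cos^2 + b^2 sin^2 ... eigen decomposition
  M <- matrix(c(Iyy, Ixy, Ixy, Ixx), 2) / A
  e <- eigen(M, symmetric = TRUE)
  semi <- 2 * sqrt(e$values)  # ellipse: I_major/A = a^2/4
  ang <- (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  list(center = c(cx, cy), major = 2 * semi[1], minor = 2 * semi[2],
       angle = ang)
}

# dense numeric boundary of a cone-plane intersection by bisection along
# rays from an interior point (the solid cone is convex)
numeric_cone_plane_boundary <- function(cone, plane, n_rays = 2000) {
  inside <- function(x, y) {
    p <- plane$point + x * plane$u + y * plane$v
    m <- p - cone$apex
    t <- sum(m * cone$axis)
    r2 <- sum(m * m) - t^2
    t >= 0 & t <= cone$height &
      r2 <= ((cone$base_diameter / 2) * t / cone$height)^2
  }
  wn <- sum(cone$axis * plane$normal)
  t0 <- sum((plane$point - cone$apex) * plane$normal) / wn
  p0 <- cone$apex + t0 * cone$axis  # axis point: interior
  x0 <- sum((p0 - plane$point) * plane$u)
  y0 <- sum((p0 - plane$point) * plane$v)
  stopifnot(inside(x0, y0))
  thetas <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  bx <- numeric(n_rays); by <- numeric(n_rays)
  rmax <- cone$base_diameter * 2 + cone$height
  for (i in seq_along(thetas)) {
    dx <- cos(thetas[i]); dy <- sin(thetas[i])
    lo <- 0; hi <- rmax
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (inside(x0 + mid * dx, y0 + mid * dy)) lo <- mid else hi <- mid
    }
    bx[i] <- x0 + lo * dx; by[i] <- y0 + lo * dy
  }
  list(x = bx, y = by)
}

# compact three-cone truth in a small 96^3 grid (fast unit-test fixture;
# not the benchmark geometry)
small_truth <- function(seed = 1, noise = list(ct_sigma = 0, fray_px = 0,
                                               px_sigma = 0)) {
  ctr <- 95 * 0.08 / 2  # 3.8 mm
  mk <- function(ang) {
    xy <- 2.2 * c(cos(ang), sin(ang))
    cone_spec(c(ctr + xy[1], ctr + xy[2], 0.6), c(0, 0, 1),
              height = 4.5, base_diameter = 1.8)
  }
  cones <- lapply(c(90, 210, 330) * pi / 180, mk)
  plane <- cut_plane(c(ctr, ctr, 3.2), c(0.05, -0.03, 1))
  synthetic_truth(cones, tissue = NULL, true_plane = plane, seed = seed,
                  noise = noise)
}

expect_angle_close <- function(a, b, tol) {
  d <- abs(((a - b + 90) %% 180) - 90)
  expect_lt(d, tol)
}
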