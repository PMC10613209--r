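test_that("segment_phantoms keeps exactly the intensity band", {
  v <- volume3d(array(c(0, 100, 1000, 100, 0, 1000, 0, 0), c(2, 2, 2)), 1)
  m <- segment_phantoms(v, 500, 2000)
  expect_identical(m$values, v$intensities == 1000)
  full <- segment_phantoms(v, -1, 1e6)
  expect_true(all(full$values))
  expect_warning(segment_phantoms(v, 5000, 6000), "no voxels")
})

test_that("segmentation band reproduces the generator's cone mask exactly", {
  truth <- small_truth()
  vol <- simulate_block(truth, shape = c(96, 96, 96), spacing = 0.08)
  m <- segment_phantoms(vol, 2500, 4000)
  oracle <- rasterize_cone(truth$cones[[1]]$apex, truth$cones[[1]]$axis,
                           truth$cones[[1]]$height,
                           truth$cones[[1]]$base_diameter, c(96, 96, 96), 0.08)
  for (k in 2:3)
    oracle <- oracle | rasterize_cone(truth$cones[[k]]$apex,
                                      truth$cones[[k]]$axis,
                                      truth$cones[[k]]$height,
                                      truth$cones[[k]]$base_diameter,
                                      c(96, 96, 96), 0.08)
  expect_identical(m$values, oracle)
})

test_that("label_and_rank sorts by size with stable tie-breaks", {
  a <- array(FALSE, c(12, 12, 12))
  a[1:3, 1:3, 1:3] <- TRUE      # 27 voxels
  a[6:7, 6:7, 6:7] <- TRUE      # 8
  a[10:11, 10:11, 10:11] <- TRUE  # 8
  lo <- label_and_rank(binary_mask(a, 1), 26)
  expect_equal(vapply(lo$objects, function(o) o$count, 0), c(27, 8, 8))
  # equal counts: smaller label id first
  labs <- vapply(lo$objects[2:3], function(o) o$label, 0L)
  expect_equal(labs, sort(labs))
  expect_error(label_and_rank(binary_mask(a & FALSE, 1), 26), "empty")
})

test_that("connectivity semantics distinguish diagonal adjacency", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE
  a[2, 2, 2] <- TRUE  # corner neighbor
  a[4, 4, 4] <- TRUE; a[4, 4, 3] <- TRUE; a[4, 3, 4] <- TRUE  # padding objects
  lab_fun <- conereg:::`.label3d_cpp`
  lab26 <- lab_fun(as.logical(a), dim(a), 26L)
  lab6 <- lab_fun(as.logical(a), dim(a), 6L)
  expect_equal(lab26[1, 1, 1], lab26[2, 2, 2])   # one object under 26
  expect_true(lab6[1, 1, 1] != lab6[2, 2, 2])    # two objects under 6
})

test_that("label_and_rank needs three phantom candidates", {
  a <- array(FALSE, c(6, 6, 6)); a[1:2, 1:2, 1:2] <- TRUE; a[5:6, 5:6, 5:6] <- TRUE
  expect_error(label_and_rank(binary_mask(a, 1), 26), "need three phantoms")
  expect_error(label_and_rank(binary_mask(a, 1), 26, specimen_in_band = TRUE),
               "need three phantoms")
})

test_that("cone_centroid matches the analytic solid-cone centroid", {
  # two-voxel example: centers at x = 0 and 2 -> mean (1,0,0)
  expect_equal(cone_centroid(rbind(c(1, 1, 1), c(3, 1, 1)), 1), c(1, 0, 0))
  expect_equal(cone_centroid(rbind(c(4, 5, 6)), 0.5), c(1.5, 2, 2.5))
  # rasterized ideal cone: centroid at 3/4 height from the apex on the axis
  sp <- 0.08
  apex <- c(3.84, 3.84, 0.4)
  m <- rasterize_cone(apex, c(0, 0, 1), 12, 6, c(96, 96, 168), sp)
  vox <- which(m, arr.ind = TRUE)
  cg <- cone_centroid(vox, sp)
  expect_lt(max(abs(cg - (apex + c(0, 0, 9)))), 0.5 * sp)
})

test_that("cone_axis finds the elongation direction, equivariantly", {
  line <- cbind(5, 5, 1:40)
  ax <- cone_axis(line, 1)
  expect_lt(min(sum((ax - c(0, 0, 1))^2), sum((ax + c(0, 0, 1))^2)), 1e-12)
  # rotation equivariance on a noisy elongated cloud
  set.seed(11)
  cloud <- cbind(rnorm(400, sd = 0.5), rnorm(400, sd = 0.7), seq(0, 30, length.out = 400))
  a0 <- cone_axis(cloud, 1)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), sin(th[2]), 0, -sin(th[2]), cos(th[2])), 3)
    R <- Rz %*% Rx
    ar <- cone_axis(cloud %*% t(R), 1)
    expected <- as.vector(R %*% a0)
    ang <- acos(min(1, abs(sum(ar * expected)))) * 180 / pi
    expect_lt(ang, 1)
  }
  expect_error(cone_axis(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(1, 1, 0), c(0.5, 0.5, 0)), 1),
               "not elongated")
})

test_that("a tilted rasterized cone's axis is recovered within 1 degree", {
  sp <- 0.08
  axis_true <- c(sin(pi / 6), 0, cos(pi / 6))  # 30 degrees about y
  m <- rasterize_cone(c(1.6, 5.1, 0.8), axis_true, 8, 3, c(128, 128, 128), sp)
  ax <- cone_axis(which(m, arr.ind = TRUE), sp)
  ang <- acos(min(1, abs(sum(ax * axis_true)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("central_section reduces to the central slice for an aligned cone", {
  sp <- 0.08
  apex <- c(3.84, 3.84, 0.4)
  m <- rasterize_cone(apex, c(0, 0, 1), 6, 3, c(96, 96, 96), sp)
  mask <- binary_mask(m, sp)
  vox <- which(m, arr.ind = TRUE)
  cg <- cone_centroid(vox, sp)
  sec <- central_section(mask, cg, c(0, 0, 1), v = c(1, 0, 0))
  # oracle: the mask's central y slice (y index of the apex center)
  slice <- m[, 49, ]
  counts_sec <- rowSums(sec$section)
  counts_slice <- colSums(slice)[colSums(slice) > 0]
  expect_equal(sort(counts_sec), sort(counts_slice))
})

test_that("central_section row widths of a sphere match circle chords", {
  sp <- 1
  d <- c(61, 61, 61); ctr <- c(31, 31, 31) - 1  # world coords of center voxel
  r <- 20
  xs <- (seq_len(61) - 1)
  dist2 <- outer(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"), (xs - ctr[3])^2, "+")
  m <- dist2 <= r^2
  sec <- central_section(binary_mask(m, sp), ctr, c(0, 0, 1), v = c(1, 0, 0))
  widths <- rowSums(sec$section) * sp
  chords <- 2 * sqrt(pmax(r^2 - sec$heights^2, 0))
  expect_lt(max(abs(widths - chords)), 1 + 1e-9)
})

test_that("central_section is insensitive to the in-plane perpendicular", {
  truth <- small_truth()
  vol <- simulate_block(truth, shape = c(96, 96, 96), spacing = 0.08)
  m <- segment_phantoms(vol, 2500, 4000)
  lab <- label_and_rank(m, 26)
  vox <- which(lab$label_map == lab$cone_labels[1], arr.ind = TRUE)
  cg <- cone_centroid(vox, 0.08)
  one <- binary_mask(lab$label_map == lab$cone_labels[1], 0.08)
  s1 <- central_section(one, cg, c(0, 0, 1), v = c(1, 0, 0))
  s2 <- central_section(one, cg, c(0, 0, 1), v = c(0.6, 0.8, 0))
  c1 <- rowSums(s1$section); c2 <- rowSums(s2$section)
  n <- min(length(c1), length(c2))
  expect_lte(max(abs(c1[1:n] - c2[1:n])), 1)
})

test_that("diameter_profile scales row counts by the spacing", {
  sec <- matrix(FALSE, 5, 4)
  sec[2, 1] <- TRUE; sec[3, 1:2] <- TRUE; sec[4, 1:3] <- TRUE
  p <- diameter_profile(sec, 0.08, centroid_row = 3)
  expect_equal(p$diameter, c(1, 2, 3) * 0.08)
  expect_equal(p$height, c(-1, 0, 1) * 0.08)
  # symmetric heights about the centroid row before trimming
  sec2 <- matrix(TRUE, 5, 2)
  p2 <- diameter_profile(sec2, 1, centroid_row = 3)
  expect_equal(p2$height, c(-2, -1, 0, 1, 2))
})

test_that("an ideal cone's raw profile is a linear ramp within one voxel", {
  sp <- 0.08
  # H chosen so the analytic centroid (3/4 H above the apex) sits exactly
  # on a voxel plane: section rows then align with voxel centers
  apex <- c(3.84, 3.84, 0.4); H <- 6.4; D <- 3.2
  m <- rasterize_cone(apex, c(0, 0, 1), H, D, c(96, 96, 96), sp)
  cg <- apex + c(0, 0, 0.75 * H)  # analytic solid-cone centroid
  sec <- central_section(binary_mask(m, sp), cg, c(0, 0, 1), v = c(1, 0, 0))
  p <- diameter_profile(sec$section, sp, heights = sec$heights)
  h_apex <- p$height + 0.75 * H   # height measured from the apex
  expect_lt(max(abs(p$diameter - D * h_apex / H)), sp + 1e-9)
})

test_that("smooth_profile preserves cubics, damps jitter, stays monotone", {
  h <- seq(-2, 2, by = 0.08)
  ramp <- 1.5 + 0.4 * h
  raw <- structure(list(height = h, diameter = ramp), class = "diameter_profile")
  sm <- smooth_profile(raw, window = 11)
  expect_lt(max(abs(sm$diameter - ramp)), 1e-6)
  expect_false(attr(sm, "degenerate"))
  # jittered ramp: residual RMS reduced by filtering
  set.seed(2)
  jit <- ramp + sample(c(-0.08, 0, 0.08), length(h), TRUE)
  rawj <- structure(list(height = h, diameter = jit), class = "diameter_profile")
  smj <- smooth_profile(rawj, window = 11)
  expect_lt(sqrt(mean((smj$diameter - ramp)^2)),
            sqrt(mean((jit - ramp)^2)))
  expect_true(all(diff(smj$diameter) > 0))
  # constant input: flagged degenerate but still strictly increasing
  rawc <- structure(list(height = h, diameter = rep(2, length(h))),
                    class = "diameter_profile")
  smc <- smooth_profile(rawc, window = 11)
  expect_true(attr(smc, "degenerate"))
  expect_true(all(diff(smc$diameter) > 0))
  expect_lt(max(abs(smc$diameter - 2)), 1e-6 * 2)
  # window validation
  expect_error(smooth_profile(raw, window = 10), "odd")
  expect_error(smooth_profile(raw, window = 3, polyorder = 3), "polyorder")
  short <- structure(list(height = h[1:7], diameter = ramp[1:7]),
                     class = "diameter_profile")
  expect_error(smooth_profile(short, window = 11), "smaller window")
})

test_that("build_cone_model recovers slope D/H and rejects bad ranks", {
  truth <- small_truth()
  vol <- simulate_block(truth, shape = c(96, 96, 96), spacing = 0.08)
  lab <- label_and_rank(segment_phantoms(vol, 2500, 4000), 26)
  models <- lapply(0:2, function(r) build_cone_model(vol, lab, r))
  for (cm in models) {
    fit <- stats::lm(diameter ~ height, data = cm$profile[c("height", "diameter")])
    slope <- coef(fit)[["height"]]
    expect_lt(abs(slope - 1.8 / 4.5) / (1.8 / 4.5), 0.05)
    # axis oriented apex-down: widths grow with +height, apex below centroid
    expect_gt(cm$axis[3], 0)
  }
  # identical cones at different poses: profiles agree within one voxel
  p1 <- models[[1]]$profile; p2 <- models[[2]]$profile
  common <- seq(max(min(p1$height), min(p2$height)),
                min(max(p1$height), max(p2$height)), length.out = 30)
  d1 <- approx(p1$height, p1$diameter, common)$y
  d2 <- approx(p2$height, p2$diameter, common)$y
  expect_lt(max(abs(d1 - d2)), 0.08)
  expect_error(build_cone_model(vol, lab, 3), "0 to 2")
})
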