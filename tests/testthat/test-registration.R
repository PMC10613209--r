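# three-ellipse test pattern rasterized analytically at given centers
tri_pattern <- function(centers, n, axes = rbind(c(20, 14), c(16, 16), c(25, 17)),
                        angles = c(30, 0, 100)) {
  m <- matrix(FALSE, n, n)
  for (i in 1:3)
    m <- m | rasterize_ellipse(centers[i, 1], centers[i, 2],
                               axes[i, 1], axes[i, 2], angles[i], n)
  m
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
}

test_that("rigid transforms invert exactly and compose with points", {
  tr <- rigid_transform2d(23, c(4.5, -7), flip = TRUE, center = c(50, 60))
  pts <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  fwd <- transform_points(tr, pts, c(100, 100))
  back <- conereg:::invert_points(tr, fwd, c(100, 100))
  expect_equal(back, pts, tolerance = 1e-12)
})

test_that("downscale_mask does area-fraction pooling with ties to foreground", {
  full <- binary_mask(matrix(TRUE, 40, 40), 0.01)
  dn <- downscale_mask(full, ct_spacing = 0.04)
  expect_true(all(dn$values))
  expect_equal(dim(dn$values), c(10L, 10L))
  expect_equal(dn$spacing, 0.04)
  # checkerboard at exact 2x downsampling: every cell is half full -> fg
  chk <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0)
  dc <- downscale_mask(binary_mask(chk, 1), ct_spacing = 2)
  expect_true(all(dc$values))
  # rasterized disk: area preserved within 2%
  disk <- rasterize_ellipse(600, 600, 600, 600, 0, 1200)
  dd <- downscale_mask(binary_mask(disk, 0.006), ct_spacing = 0.08)
  a_mm <- sum(dd$values) * 0.08^2
  expect_lt(abs(a_mm - pi * 3.6^2) / (pi * 3.6^2), 0.02)
})

test_that("register_rigid(fixed, fixed) is the identity", {
  fixed <- binary_mask(tri_pattern(rbind(c(80, 80), c(180, 90), c(120, 190)), 260), 1)
  tr <- register_rigid(fixed, fixed)
  expect_false(tr$flip)
  expect_lt(abs(tr$rotation), 0.1)
  expect_lt(max(abs(tr$translation)), 0.1)
})

test_that("known rigid perturbations are recovered within 0.5 px / 0.5 deg", {
  n <- 260
  cf <- rbind(c(80, 80), c(180, 90), c(120, 190))
  fixed <- binary_mask(tri_pattern(cf, n), 1)
  ctr <- c(n, n) / 2
  cases <- list(list(rot = 0, t = c(5, 3), flip = FALSE),
                list(rot = 20, t = c(0, 0), flip = FALSE),
                list(rot = -12, t = c(-8, 6), flip = FALSE),
                list(rot = 9, t = c(10, -10), flip = TRUE))
  for (cs in cases) {
    R <- rot2(cs$rot)
    cm <- t(t(R) %*% (t(cf) - ctr - cs$t) + ctr)  # inverse-map the centers
    angs <- c(30, 0, 100) - cs$rot
    if (cs$flip) {
      cm[, 1] <- n - cm[, 1]
      angs <- 180 - angs
    }
    moving <- binary_mask(tri_pattern(cm, n, angles = angs), 1)
    tr <- register_rigid(fixed, moving)
    expect_equal(tr$flip, cs$flip)
    rec <- transform_points(tr, cm, c(n, n))
    expect_lt(max(sqrt(rowSums((rec - cf)^2))), 0.5)
    if (!cs$flip) {
      expect_lt(abs(((tr$rotation - cs$rot + 180) %% 360) - 180), 0.5)
    }
  }
})

test_that("perturb-and-recover on a thresholded plane image is inverse-consistent", {
  truth <- small_truth(seed = 5)
  vol <- simulate_block(truth, shape = c(96, 96, 96), spacing = 0.08)
  pim <- resample_plane(vol, truth$true_plane, half_extent_mm = 3.6)
  fixed <- binary_mask(pim$intensities >= 2500 & pim$intensities <= 4000 &
                         pim$validity, pim$spacing)
  tr_true <- rigid_transform2d(14, c(6, -4), FALSE, dim(fixed$values) / 2)
  # moving = fixed pulled back through the forward map: each moving pixel
  # takes the fixed value at its forward-transformed position
  d <- dim(fixed$values)
  grid <- cbind(rep(seq_len(d[1]) - 0.5, times = d[2]),
                rep(seq_len(d[2]) - 0.5, each = d[1]))
  src <- transform_points(tr_true, grid, d)
  mv <- matrix(conereg:::bilinear2d(fixed$values * 1, src[, 1], src[, 2]),
               d[1], d[2]) >= 0.5
  moving <- binary_mask(mv, fixed$spacing)
  tr <- register_rigid(fixed, moving)
  # action agreement on the mask's own pixels
  pts <- which(moving$values, arr.ind = TRUE) - 0.5
  rec <- transform_points(tr, pts, dim(moving$values))
  tru <- transform_points(tr_true, pts, dim(moving$values))
  expect_lt(max(sqrt(rowSums((rec - tru)^2))), 0.5)
})

test_that("registration refuses hopeless inputs", {
  empty <- binary_mask(matrix(FALSE, 50, 50), 1)
  blob <- binary_mask(rasterize_ellipse(25, 25, 8, 6, 0, 50), 1)
  expect_error(register_rigid(blob, empty), "non-empty")
})

test_that("frayed_edge_exclusion builds a boundary band of the right area", {
  disk <- binary_mask(rasterize_ellipse(40, 40, 20, 20, 0, 80), 1)
  none <- frayed_edge_exclusion(disk, 0)
  expect_false(any(none$values))
  band <- frayed_edge_exclusion(disk, 2)
  a <- sum(band$values)
  expect_lt(abs(a - 2 * pi * 20 * 2) / (2 * pi * 20 * 2), 0.15)
  # band wider than the object: everything excluded, with a warning
  small <- binary_mask(rasterize_ellipse(25, 25, 3, 3, 0, 50), 1)
  expect_warning(all_ex <- frayed_edge_exclusion(small, 10), "entire object")
  expect_true(all(all_ex$values[small$values]))
})

test_that("classify counts TP/FP/FN outside the excluded set", {
  a <- matrix(FALSE, 10, 10); a[, 1:6] <- TRUE   # rows 0-5 in grid columns
  b <- matrix(FALSE, 10, 10); b[, 4:9] <- TRUE
  pc <- classify(a, b)
  expect_equal(c(pc$tp, pc$fp, pc$fn), c(30, 30, 30))
  same <- classify(a, a)
  expect_equal(c(same$fp, same$fn), c(0, 0))
  disjoint <- classify(a, !a)
  expect_equal(disjoint$tp, 0)
  ex <- matrix(FALSE, 10, 10); ex[, 4] <- TRUE
  pce <- classify(a, b, ex)
  expect_equal(pce$excluded, 10)
  expect_equal(pce$tp, 20)
  expect_error(classify(a, matrix(FALSE, 5, 5)), "grids differ")
})

test_that("IoU and Dice follow their exact formulas and identities", {
  mk <- function(tp, fp, fn)
    structure(list(tp = tp, fp = fp, fn = fn, excluded = 0L),
              class = "pixel_classification")
  expect_equal(unclass(scores(mk(1, 0, 0)))[c("iou", "dsc")],
               list(iou = 1, dsc = 1))
  s <- scores(mk(1, 1, 0))
  expect_equal(s$iou, 0.5); expect_equal(s$dsc, 2 / 3)
  # brute-force count oracle on toy masks: A = 3 px, B = 3 px, overlap 2
  A <- matrix(FALSE, 3, 3); A[1, 1:3] <- TRUE
  B <- matrix(FALSE, 3, 3); B[1, 2:3] <- TRUE; B[2, 1] <- TRUE
  tp <- sum(A & B); fp <- sum(!A & B); fn <- sum(A & !B)
  s2 <- scores(classify(A, B))
  expect_equal(s2$iou, tp / (tp + fp + fn))
  expect_equal(s2$dsc, 2 * tp / (2 * tp + fp + fn))
  # identities: dsc = 2 iou / (1 + iou); fp/fn swap symmetry
  for (counts in list(c(5, 3, 2), c(10, 0, 4), c(7, 7, 7))) {
    si <- scores(mk(counts[1], counts[2], counts[3]))
    expect_equal(si$dsc, 2 * si$iou / (1 + si$iou), tolerance = 1e-15)
    sw <- scores(mk(counts[1], counts[3], counts[2]))
    expect_equal(si$iou, sw$iou)
    expect_equal(si$dsc, sw$dsc)
  }
  expect_error(scores(mk(0, 0, 0)), "undefined")
})

test_that("overlay pixel colors agree with the classification counts", {
  a <- rasterize_ellipse(30, 30, 12, 10, 0, 64)
  b <- rasterize_ellipse(34, 32, 12, 10, 0, 64)
  ex <- frayed_edge_exclusion(binary_mask(a, 1), 2)$values
  ov <- render_overlays(matrix(runif(64^2), 64), matrix(runif(64^2), 64),
                        a, b, ex)
  pc <- classify(a, b, ex)
  isc <- function(r, g, bl) sum(ov$classification[, , 1] == r &
                                  ov$classification[, , 2] == g &
                                  ov$classification[, , 3] == bl)
  expect_equal(isc(0, 0, 0), pc$tp)
  expect_equal(isc(0, 0.75, 0), pc$fp)
  expect_equal(isc(0.85, 0, 0), pc$fn)
  expect_equal(isc(0.6, 0.6, 0.6), pc$excluded)
  # identical masks: no green/red anywhere
  ov2 <- render_overlays(matrix(0, 64, 64), matrix(0, 64, 64), a, a, NULL)
  expect_equal(sum(ov2$classification[, , 2] == 0.75), 0)
  expect_equal(sum(ov2$classification[, , 1] == 0.85), 0)
})
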