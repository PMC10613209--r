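# Rigid 2D registration of the downscaled histology mask onto the
# in-silico CT plane, and TP/FP/FN-based overlap scoring with
# frayed-edge exclusion.

#' Rigid 2D transform (rotation + translation, optional mirror)
#'
#' Maps moving-image pixel coordinates into the fixed frame: an optional
#' horizontal mirror about the moving image's vertical center line is
#' applied first, then rotation by `rotation` degrees about `center`,
#' then translation. Pixel (i,j) has continuous coordinates (i-0.5, j-0.5).
#'
#' @param rotation angle in degrees (counter-clockwise).
#' @param translation length-2 translation in fixed-image pixels.
#' @param flip pre-applied horizontal mirror?
#' @param center rotation center in moving-image pixel coordinates.
#' @return Object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation = 0, translation = c(0, 0),
                              flip = FALSE, center = c(0, 0)) {
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 flip = isTRUE(flip), center = as.numeric(center)),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("rigid_transform2d: rotation %.3f deg, translation (%.2f, %.2f) px, flip %s\n",
              x$rotation, x$translation[1], x$translation[2], x$flip))
  invisible(x)
}

#' Map moving-frame points through a rigid transform
#'
#' @param tr a [rigid_transform2d].
#' @param pts two-column matrix of moving-frame coordinates (px).
#' @param moving_dim dim of the moving image (needed for the mirror line).
#' @return Two-column matrix in the fixed frame.
#' @export
transform_points <- function(tr, pts, moving_dim) {
  pts <- matrix(pts, ncol = 2)
  if (tr$flip) pts[, 1] <- moving_dim[1] - pts[, 1]
  th <- tr$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sw <- sweep(pts, 2, tr$center)
  out <- sw %*% t(R)
  sweep(out, 2, tr$center + tr$translation, "+")
}

# inverse mapping: fixed-frame points -> moving-frame coordinates
invert_points <- function(tr, pts, moving_dim) {
  pts <- matrix(pts, ncol = 2)
  th <- tr$rotation * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)  # R(-th)
  sw <- sweep(pts, 2, tr$center + tr$translation)
  out <- sweep(sw %*% t(R), 2, tr$center, "+")
  if (tr$flip) out[, 1] <- moving_dim[1] - out[, 1]
  out
}

# bilinear sampling of matrix `img` at pixel-center coordinates (x, y);
# outside samples are 0
bilinear2d <- function(img, x, y) {
  d <- dim(img)
  gx <- x + 0.5; gy <- y + 0.5
  valid <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2]
  x0 <- pmin(pmax(floor(gx), 1), d[1] - 1); fx <- pmin(pmax(gx - x0, 0), 1)
  y0 <- pmin(pmax(floor(gy), 1), d[2] - 1); fy <- pmin(pmax(gy - y0, 0), 1)
  val <- img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
  val[!valid] <- 0
  val
}

#' Resample a moving image onto the fixed grid under a rigid transform
#'
#' @param tr a [rigid_transform2d].
#' @param moving numeric matrix (or logical mask) in the moving frame.
#' @param out_dim dim of the fixed grid.
#' @param binarize threshold the warped values at 0.5?
#' @return Matrix on the fixed grid (logical when `binarize`).
#' @export
apply_transform2d <- function(tr, moving, out_dim, binarize = is.logical(moving)) {
  m <- moving * 1
  xs <- seq_len(out_dim[1]) - 0.5
  ys <- seq_len(out_dim[2]) - 0.5
  grid <- cbind(rep(xs, times = out_dim[2]), rep(ys, each = out_dim[1]))
  src <- invert_points(tr, grid, dim(m))
  w <- matrix(bilinear2d(m, src[, 1], src[, 2]), out_dim[1], out_dim[2])
  if (binarize) w >= 0.5 else w
}

#' Downscale a histology mask to CT resolution
#'
#' Area-fraction downsampling: each coarse cell takes the fraction of its
#' fine pixels that are foreground, thresholded at 0.5 (ties resolved to
#' foreground).
#'
#' @param histo_mask a 2D [binary_mask] at histology resolution.
#' @param histo_spacing,ct_spacing mm per pixel before/after.
#' @return A 2D [binary_mask] with spacing `ct_spacing`.
#' @export
downscale_mask <- function(histo_mask, histo_spacing = histo_mask$spacing,
                           ct_spacing) {
  stopifnot(inherits(histo_mask, "binary_mask"), ct_spacing >= histo_spacing)
  m <- histo_mask$values
  d <- dim(m)
  r <- histo_spacing / ct_spacing
  nd <- pmax(ceiling(d * r), 1L)
  bx <- pmin(floor((seq_len(d[1]) - 0.5) * r) + 1L, nd[1])
  by <- pmin(floor((seq_len(d[2]) - 0.5) * r) + 1L, nd[2])
  bin <- outer(bx, (by - 1L) * nd[1], "+")
  tot <- tabulate(bin, nbins = nd[1] * nd[2])
  fg <- tabulate(bin[m], nbins = nd[1] * nd[2])
  frac <- ifelse(tot > 0, fg / tot, 0)
  binary_mask(matrix(frac >= 0.5, nd[1], nd[2]), ct_spacing)
}

# centroid and principal-axis angle (degrees) of a binary mask
mask_moments <- function(m) {
  idx <- which(m, arr.ind = TRUE) - 0.5
  c0 <- colMeans(idx)
  cc <- sweep(idx, 2, c0)
  cv <- crossprod(cc) / nrow(cc)
  e <- eigen(cv, symmetric = TRUE)
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  list(centroid = c0, angle = ang,
       anisotropy = e$values[1] / max(e$values[2], 1e-12))
}

binary_dice <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}

#' Rigid registration of two binary masks
#'
#' Maximizes the Dice overlap over rotation + translation (and optionally
#' a horizontal mirror). Masks are Gaussian-smoothed and a soft-Dice
#' objective is refined by Nelder-Mead from moment-based initializations
#' (centroid alignment plus the principal second-moment angle, both
#' 180-degree alternatives); an explicit initial transform can seed the
#' search instead (e.g. from known landmark correspondences). Both flip
#' states are tried and the better kept. Deterministic given its inputs.
#'
#' @param fixed,moving 2D [binary_mask]s on grids of equal spacing.
#' @param init optional [rigid_transform2d] used as additional seed.
#' @param try_flip search the mirrored state too?
#' @param smoothing_sigma_px Gaussian sigma for the soft objective.
#' @param max_iterations Nelder-Mead iteration budget per start.
#' @return A [rigid_transform2d] with attributes `dice` (final binary
#'   Dice) and `objective` (soft Dice reached).
#' @export
register_rigid <- function(fixed, moving, init = NULL, try_flip = TRUE,
                           smoothing_sigma_px = 2, max_iterations = 300) {
  stopifnot(inherits(fixed, "binary_mask"), inherits(moving, "binary_mask"))
  fm <- fixed$values; mm <- moving$values
  if (!any(fm) || !any(mm)) stop("registration needs non-empty masks")
  fs <- as.matrix(EBImage::gblur(EBImage::Image(fm * 1), smoothing_sigma_px))
  ms <- as.matrix(EBImage::gblur(EBImage::Image(mm * 1), smoothing_sigma_px))
  sum_f <- sum(fs)
  center <- dim(mm) / 2
  dm <- dim(mm)
  # fixed-grid pixel centers, computed once
  gx <- rep(seq_len(dim(fm)[1]) - 0.5, times = dim(fm)[2])
  gy <- rep(seq_len(dim(fm)[2]) - 0.5, each = dim(fm)[1])
  fsv <- as.vector(fs)
  soft_dice <- function(par, flip) {
    th <- par[1] * pi / 180
    cx <- center[1] + par[2]; cy <- center[2] + par[3]
    qx <- cos(th) * (gx - cx) + sin(th) * (gy - cy) + center[1]
    qy <- -sin(th) * (gx - cx) + cos(th) * (gy - cy) + center[2]
    if (flip) qx <- dm[1] - qx
    w <- bilinear2d(ms, qx, qy)
    2 * sum(w * fsv) / (sum_f + sum(w) + 1e-12)
  }
  starts <- list()
  if (is.null(init)) {
    mf <- mask_moments(fm)
    add_start <- function(theta, flip) {
      mmv <- if (flip) mm[rev(seq_len(nrow(mm))), , drop = FALSE] else mm
      cm <- mask_moments(mmv)$centroid
      th <- theta * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      t0 <- mf$centroid - (as.vector(R %*% (cm - center)) + center)
      starts[[length(starts) + 1L]] <<- list(par = c(theta, t0), flip = flip)
    }
    flips <- if (try_flip) c(FALSE, TRUE) else FALSE
    for (fl in flips) {
      mmv <- if (fl) mm[rev(seq_len(nrow(mm))), , drop = FALSE] else mm
      ma <- mask_moments(mmv)$angle
      for (dth in c(0, 180)) add_start(((mf$angle - ma + dth + 180) %% 360) - 180, fl)
    }
  } else {
    # a landmark-derived seed already resolves pose and chirality; search
    # from it (and, defensively, its mirrored twin)
    starts[[1]] <- list(par = c(init$rotation, init$translation),
                        flip = init$flip)
    if (try_flip)
      starts[[2]] <- list(par = c(init$rotation, init$translation),
                          flip = !init$flip)
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s$par, function(p) -soft_dice(p, s$flip),
                        method = "Nelder-Mead",
                        control = list(maxit = max_iterations,
                                       reltol = 1e-8,
                                       parscale = c(2, 1, 1)))
    if (is.null(best) || opt$value < best$value) {
      best <- opt; best$flip <- s$flip
    }
  }
  tr <- rigid_transform2d(best$par[1], best$par[2:3], best$flip, center)
  aligned <- apply_transform2d(tr, mm, dim(fm), binarize = TRUE)
  dice <- binary_dice(fm, aligned)
  if (dice < 0.2)
    stop(sprintf("registration failed: final Dice %.3f below 0.2 (soft objective %.3f)",
                 dice, -best$value))
  structure(tr, dice = dice, objective = -best$value)
}

#' Frayed-edge exclusion band
#'
#' Boundary band of total width `band_px` straddling each cone contour
#' (dilation minus erosion of the mask by half the band each), marking the
#' ragged phantom edges that are deducted from score computation.
#'
#' @param ct_cone_mask a 2D [binary_mask] of the cone cross-sections.
#' @param band_px band width in pixels (0 disables exclusion).
#' @return A 2D [binary_mask] of excluded pixels.
#' @export
frayed_edge_exclusion <- function(ct_cone_mask, band_px = 2L) {
  stopifnot(inherits(ct_cone_mask, "binary_mask"), band_px >= 0)
  m <- ct_cone_mask$values
  if (band_px == 0)
    return(binary_mask(array(FALSE, dim(m)), ct_cone_mask$spacing))
  excl <- dilate_disc(m, ceiling(band_px / 2)) & !erode_disc(m, floor(band_px / 2))
  if (any(m) && !any(m & !excl))
    warning("exclusion band covers entire object(s)")
  binary_mask(excl, ct_cone_mask$spacing)
}

#' Classify pixels into TP / FP / FN outside the excluded band
#'
#' The CT plane mask is the ground truth: TP are object pixels present in
#' both modalities, FN only in CT, FP only in the histology section.
#'
#' @param ct_mask ground-truth 2D [binary_mask] (in-silico CT plane).
#' @param histo_mask_aligned registered histology [binary_mask] (or
#'   logical matrix) on the same grid.
#' @param excluded optional exclusion [binary_mask] (or logical matrix).
#' @return Object of class `pixel_classification`: counts `tp`, `fp`,
#'   `fn`, `excluded`.
#' @export
classify <- function(ct_mask, histo_mask_aligned, excluded = NULL) {
  ct <- if (inherits(ct_mask, "binary_mask")) ct_mask$values else ct_mask
  hs <- if (inherits(histo_mask_aligned, "binary_mask"))
    histo_mask_aligned$values else histo_mask_aligned
  if (!identical(dim(ct), dim(hs)))
    stop("classify: mask grids differ: ", paste(dim(ct), collapse = "x"),
         " vs ", paste(dim(hs), collapse = "x"))
  ex <- if (is.null(excluded)) array(FALSE, dim(ct))
        else if (inherits(excluded, "binary_mask")) excluded$values else excluded
  if (!identical(dim(ex), dim(ct))) stop("classify: exclusion grid differs")
  keep <- !ex
  structure(list(tp = sum(ct & hs & keep),
                 fp = sum(!ct & hs & keep),
                 fn = sum(ct & !hs & keep),
                 excluded = sum(ex)),
            class = "pixel_classification")
}

#' @export
print.pixel_classification <- function(x, ...) {
  cat(sprintf("pixel_classification: TP %d, FP %d, FN %d (excluded %d)\n",
              x$tp, x$fp, x$fn, x$excluded))
  invisible(x)
}

#' Overlap scores from a pixel classification
#'
#' Jaccard / Intersection-over-Union, `IoU = TP / (TP + FP + FN)`, and
#' Dice, `DSC = 2 TP / (2 TP + FP + FN)`. Both derive from the same
#' counts, so `DSC = 2 IoU / (1 + IoU)` exactly.
#'
#' @param pc a `pixel_classification`.
#' @return list of class `similarity_scores`: `iou`, `dsc` in `[0, 1]`.
#' @export
scores <- function(pc) {
  stopifnot(inherits(pc, "pixel_classification"))
  den <- pc$tp + pc$fp + pc$fn
  if (den == 0) stop("scores undefined: TP + FP + FN = 0")
  structure(list(iou = pc$tp / den,
                 dsc = 2 * pc$tp / (2 * pc$tp + pc$fp + pc$fn)),
            class = "similarity_scores")
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat(sprintf("similarity: IoU %.4f, DSC %.4f\n", x$iou, x$dsc))
  invisible(x)
}

#' Render diagnostic overlays
#'
#' (a) A checkerboard of the two (grayscale) intensity images and (b) a
#' color-coded mask overlay: TP black, FP green, FN red, excluded gray,
#' background white.
#'
#' @param fixed_img,moving_img aligned grayscale matrices (intensities).
#' @param ct_mask,histo_mask aligned logical matrices (or [binary_mask]s).
#' @param excluded optional exclusion mask.
#' @param tile_px checkerboard tile edge (px).
#' @return list: `checkerboard`, `classification` -- RGB arrays `[x,y,3]`
#'   in `[0,1]`.
#' @export
render_overlays <- function(fixed_img, moving_img, ct_mask, histo_mask,
                            excluded = NULL, tile_px = 32L) {
  ct <- if (inherits(ct_mask, "binary_mask")) ct_mask$values else ct_mask
  hs <- if (inherits(histo_mask, "binary_mask")) histo_mask$values else histo_mask
  stopifnot(identical(dim(ct), dim(hs)))
  ex <- if (is.null(excluded)) array(FALSE, dim(ct))
        else if (inherits(excluded, "binary_mask")) excluded$values else excluded
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) == 0) return(m * 0)
    (m - r[1]) / diff(r)
  }
  d <- dim(ct)
  ix <- ((seq_len(d[1]) - 1) %/% tile_px) %% 2
  iy <- ((seq_len(d[2]) - 1) %/% tile_px) %% 2
  board <- outer(ix, iy, function(a, b) (a + b) %% 2 == 0)
  chk <- ifelse(board, norm01(fixed_img), norm01(moving_img))
  checkerboard <- array(rep(chk, 3), dim = c(d, 3))
  r <- g <- b <- matrix(1, d[1], d[2])  # background white
  tp <- ct & hs & !ex; fp <- !ct & hs & !ex; fn <- ct & !hs & !ex
  r[tp] <- 0; g[tp] <- 0; b[tp] <- 0
  r[fp] <- 0; g[fp] <- 0.75; b[fp] <- 0
  r[fn] <- 0.85; g[fn] <- 0; b[fn] <- 0
  r[ex] <- 0.6; g[ex] <- 0.6; b[ex] <- 0.6
  list(checkerboard = checkerboard,
       classification = array(c(r, g, b), dim = c(d, 3)))
}
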