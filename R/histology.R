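# Histology side of the workflow: reduce the stained RGB section to a
# clean binary mask and fit ellipses to the three cone cross-sections.
# Grayscale images are matrices [x, y] with values in [0, 1].

#' Morphological cleanup parameters
#'
#' Kernel sizes (in pixels, at histology resolution) for the five-step
#' cleanup chain. A "size" is the diameter of the disk (or edge of the
#' square) structuring element.
#'
#' @param dilate1_disk_px initial dilation closing small holes.
#' @param erode_small_disk_diameter_px erosion removing small objects
#'   (noise, scale bars).
#' @param fill_square_px edge of the square element used during hole
#'   filling.
#' @param erode2_disk_px,dilate2_disk_px final erosion/dilation pass.
#' @return A `morph_params` list.
#' @export
morph_params <- function(dilate1_disk_px = 5L,
                         erode_small_disk_diameter_px = 30L,
                         fill_square_px = 20L,
                         erode2_disk_px = 5L,
                         dilate2_disk_px = 25L) {
  p <- list(dilate1_disk_px = dilate1_disk_px,
            erode_small_disk_diameter_px = erode_small_disk_diameter_px,
            fill_square_px = fill_square_px,
            erode2_disk_px = erode2_disk_px,
            dilate2_disk_px = dilate2_disk_px)
  if (any(vapply(p, function(v) v <= 0 || v != round(v), TRUE)))
    stop("all morphological kernel sizes must be positive integers")
  structure(p, class = "morph_params")
}

# Euclidean-disc morphology via the distance transform: exact disc
# structuring elements of arbitrary (possibly half-integer) radius, O(n).
dilate_disc <- function(m, radius) {
  if (radius <= 0) return(m)
  dist_bg <- EBImage::imageData(EBImage::distmap(1 - m))  # bg px -> nearest fg
  m | (dist_bg <= radius)
}

erode_disc <- function(m, radius) {
  if (radius <= 0) return(m)
  dist_fg <- EBImage::imageData(EBImage::distmap(m * 1))  # fg px -> nearest bg
  m & (dist_fg > radius)
}

disc_radius <- function(size_px) (size_px - 1) / 2

#' Pick the highest-contrast color channel
#'
#' Splits the RGB image into channels and selects the one whose Otsu
#' split yields the largest between-class variance -- the operational
#' reading of "strongest contrast". Ties go to the lowest channel index.
#'
#' @param image a [histology_image].
#' @param channel manual override: 0 (R), 1 (G) or 2 (B); `"auto"` selects.
#' @return list: `gray` (matrix in `[0,1]`), `channel` (0-based index).
#' @export
select_channel <- function(image, channel = "auto") {
  stopifnot(inherits(image, "histology_image"))
  if (!identical(channel, "auto")) {
    ch <- as.integer(channel)
    if (!ch %in% 0:2) stop("channel must be 'auto', 0, 1 or 2")
    return(list(gray = image$rgb[, , ch + 1L], channel = ch))
  }
  scores <- vapply(1:3, function(k) {
    otsu_between_class_variance(image$rgb[, , k])
  }, 0)
  if (all(scores <= 0))
    stop("no contrast: every channel is constant")
  ch <- which.max(scores) - 1L  # which.max takes the first maximum: tie rule
  list(gray = image$rgb[, , ch + 1L], channel = ch)
}

# maximum between-class variance over 256-level thresholds (0 if constant)
otsu_between_class_variance <- function(gray) {
  g <- pmin(pmax(gray, 0), 1)
  h <- tabulate(pmin(floor(g * 256) + 1L, 256L), nbins = 256L)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * (seq_len(256L) - 1L))
  mu_t <- mu[256L]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(0)
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  max(bcv[valid])
}

#' Binarize a grayscale image with Otsu's method
#'
#' @param gray matrix in `[0, 1]`.
#' @param polarity `"auto"` keeps the class with the smaller area fraction
#'   as foreground (objects are assumed sparser than background);
#'   `"dark_fg"` / `"bright_fg"` force the side.
#' @param spacing mm per pixel carried onto the mask.
#' @return A 2D [binary_mask] (spacing 1 px; caller attaches physical
#'   spacing where needed).
#' @export
binarize <- function(gray, polarity = c("auto", "dark_fg", "bright_fg"),
                     spacing = 1) {
  polarity <- match.arg(polarity)
  if (length(unique(as.vector(gray))) < 2L)
    stop("cannot binarize a constant image")
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1), levels = 256)
  dark <- gray <= thr
  fg <- switch(polarity,
    dark_fg = dark,
    bright_fg = !dark,
    auto = if (sum(dark) <= length(dark) / 2) dark else !dark)
  binary_mask(fg, spacing)
}

#' Morphological cleanup of the binarized section
#'
#' Applies, in order: dilation (disk `dilate1`), erosion (disk
#' `erode_small`) removing small objects, hole filling, erosion (disk
#' `erode2`) and dilation (disk `dilate2`). Disk sizes are diameters;
#' operations use exact Euclidean discs via the distance transform. Hole
#' filling is topological (every background region not connected to the
#' border is filled); the `fill_square_px` element size is retained for
#' interface compatibility.
#'
#' @param mask a 2D [binary_mask].
#' @param p a [morph_params].
#' @param ignore optional logical matrix: pixels to blank out before
#'   processing (manual artifact mask).
#' @return A cleaned 2D [binary_mask].
#' @export
cleanup <- function(mask, p = morph_params(), ignore = NULL) {
  stopifnot(inherits(mask, "binary_mask"), length(dim(mask$values)) == 2L)
  m <- mask$values
  if (!any(m)) stop("cleanup received an empty mask")
  if (!is.null(ignore)) {
    stopifnot(identical(dim(ignore), dim(m)))
    m <- m & !ignore
  }
  m <- dilate_disc(m, disc_radius(p$dilate1_disk_px))
  m <- erode_disc(m, disc_radius(p$erode_small_disk_diameter_px))
  m <- fill_holes(m)
  m <- erode_disc(m, disc_radius(p$erode2_disk_px))
  m <- dilate_disc(m, disc_radius(p$dilate2_disk_px))
  if (!any(m)) stop("cleanup removed everything; shrink kernels")
  binary_mask(m, mask$spacing)
}

fill_holes <- function(m) {
  f <- EBImage::fillHull(EBImage::Image(m * 1))
  as.matrix(f) > 0.5
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct conic fit (constrained so the solution is
#' always an ellipse) to a set of 2D points.
#'
#' @param pts two-column matrix of point coordinates (px).
#' @return An [ellipse_detection], or `NULL` when the contour is
#'   degenerate (fewer than 5 points, or no valid elliptic solution).
#' @export
fit_ellipse_direct <- function(pts) {
  if (!is.matrix(pts) || nrow(pts) < 5L) return(NULL)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  x <- pts[, 1] - mx; y <- pts[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T)) return(NULL)
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  ev <- Re(e$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  k <- which(cond > 0)
  if (!length(k)) return(NULL)
  v <- ev[, k[1]]
  a <- c(v, as.vector(T %*% v))  # A B C D E F in centered frame
  conic_to_ellipse(a, shift = c(mx, my))
}

# conic (A,B,C,D,E,F), points shifted by `shift`, -> ellipse parameters
conic_to_ellipse <- function(a, shift = c(0, 0)) {
  A <- a[1]; B <- a[2]; C <- a[3]; D <- a[4]; E <- a[5]; Fc <- a[6]
  den <- 4 * A * C - B^2
  if (den <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  M2 <- matrix(c(A, B / 2, B / 2, C), 2)
  ed <- eigen(M2, symmetric = TRUE)  # values decreasing
  semi <- sqrt(-F0 / ed$values)
  if (any(!is.finite(semi)) || any(semi <= 0)) return(NULL)
  imaj <- which.max(semi)
  major <- 2 * semi[imaj]; minor <- 2 * semi[-imaj]
  vmaj <- ed$vectors[, imaj]
  ang <- (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180
  ellipse_detection(center = c(cx, cy) + shift, major_len = major,
                    minor_len = minor, angle = ang)
}

#' Detect the three cone cross-section ellipses
#'
#' Labels the mask's connected components, traces each external contour,
#' fits an ellipse to it and keeps fits whose minor-axis length falls in
#' the expected range. Exactly three must survive. Fitted axis lengths are
#' corrected by +1 px for the half-pixel-per-side bias of contours traced
#' through pixel centers.
#'
#' @param mask a cleaned 2D [binary_mask].
#' @param minor_range_px `c(min, max)` admissible minor-axis length (px).
#' @return list of exactly 3 [ellipse_detection]s, ordered by center x
#'   then y, plus attribute `labels` (component label per ellipse).
#' @export
detect_cone_ellipses <- function(mask, minor_range_px) {
  stopifnot(inherits(mask, "binary_mask"), length(minor_range_px) == 2L)
  lab <- EBImage::bwlabel(EBImage::Image(mask$values * 1))
  contours <- EBImage::ocontour(lab)
  fits <- list(); labels <- integer()
  all_minor <- numeric()
  for (i in seq_along(contours)) {
    pts <- contours[[i]] + 0.5  # 0-based indices -> pixel-center coordinates
    e <- fit_ellipse_direct(pts)
    if (is.null(e)) next
    e$major_len <- e$major_len + 1
    e$minor_len <- e$minor_len + 1
    all_minor <- c(all_minor, e$minor_len)
    if (e$minor_len >= minor_range_px[1] && e$minor_len <= minor_range_px[2]) {
      fits[[length(fits) + 1L]] <- e
      labels <- c(labels, i)
    }
  }
  if (length(fits) != 3L)
    stop(sprintf(paste0("expected three cone cross-sections, found %d in minor ",
                        "range [%.1f, %.1f] px; candidate minor lengths: %s"),
                 length(fits), minor_range_px[1], minor_range_px[2],
                 paste(sprintf("%.1f", sort(all_minor)), collapse = ", ")))
  ord <- order(vapply(fits, function(e) e$center[1], 0),
               vapply(fits, function(e) e$center[2], 0))
  structure(fits[ord], labels = labels[ord])
}

#' Physical minor-axis length
#'
#' @param e an [ellipse_detection].
#' @param pixel_spacing mm per pixel.
#' @return Minor-axis length in mm -- the proxy for the local cone
#'   diameter at the cut.
#' @export
minor_axis_mm <- function(e, pixel_spacing) {
  stopifnot(inherits(e, "ellipse_detection"), pixel_spacing > 0)
  e$minor_len * pixel_spacing
}

#' Mask of the pixels belonging to the detected cones
#'
#' Returns the union of the connected components whose contours survived
#' ellipse detection; scoring is performed on the phantoms only.
#'
#' @param mask the cleaned mask given to [detect_cone_ellipses].
#' @param ellipses result of [detect_cone_ellipses] (carries labels).
#' @return A 2D [binary_mask] containing only the three cone objects.
#' @export
cone_only_mask <- function(mask, ellipses) {
  lab <- EBImage::bwlabel(EBImage::Image(mask$values * 1))
  keep <- array(as.matrix(lab) %in% attr(ellipses, "labels"),
                dim = dim(mask$values))
  binary_mask(keep, mask$spacing)
}
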