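# End-to-end orchestration: CT cone extraction -> histology processing ->
# plane solving -> in-silico plane extraction -> rigid registration ->
# IoU/Dice scoring, plus batch evaluation over synthetic suites.

#' Default pipeline configuration
#'
#' All tunable parameters of the workflow with their defaults. Values are
#' grouped by stage: `ct.*` (phantom segmentation and cone modelling),
#' `histo.*` (section processing), `plane.*` (plane solving/resampling),
#' `reg.*` (rigid registration) and `score.*` (classification).
#'
#' @param ... named overrides, e.g. `ct.threshold_low = 2000`.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    ct.threshold_low = 2500,
    ct.threshold_high = 4000,
    ct.connectivity = 26L,
    ct.specimen_in_band = FALSE,
    ct.sg_window = 11L,
    ct.sg_polyorder = 3L,
    histo.channel = "auto",
    histo.polarity = "auto",
    histo.morph = morph_params(),
    histo.minor_range_mm = c(0.6, 5.2),
    plane.out_spacing_mm = NULL,   # default: the CT voxel spacing
    plane.half_extent_mm = 11.0,
    plane.max_ambiguity_ratio = 0.95,
    reg.max_iterations = 300L,
    reg.smoothing_sigma_px = 2,
    reg.try_flip = TRUE,
    score.exclusion_band_px = 2L,
    overlay.tile_px = 32L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "run_config")
}

# schema check before any computation
validate_config <- function(cfg) {
  need <- names(default_config())
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  with(cfg, {
    if (!(ct.threshold_low < ct.threshold_high))
      stop("config: ct.threshold_low must be < ct.threshold_high")
    if (!ct.connectivity %in% c(6L, 26L))
      stop("config: ct.connectivity must be 6 or 26")
    if (length(histo.minor_range_mm) != 2L ||
        histo.minor_range_mm[1] >= histo.minor_range_mm[2])
      stop("config: histo.minor_range_mm must be an increasing pair")
    if (plane.half_extent_mm <= 0) stop("config: plane.half_extent_mm must be > 0")
    if (score.exclusion_band_px < 0) stop("config: score.exclusion_band_px must be >= 0")
  })
  invisible(cfg)
}

# closed-form 2D rigid Procrustes fit of moving -> fixed landmark points,
# trying both mirror states; used to seed the mask registration
kabsch2d <- function(moving_pts, fixed_pts, moving_dim) {
  center <- moving_dim / 2
  fit_one <- function(mp, flip) {
    cm <- colMeans(mp); cf <- colMeans(fixed_pts)
    a <- sweep(mp, 2, cm); b <- sweep(fixed_pts, 2, cf)
    num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
    den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
    th <- atan2(num, den)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    res <- b - a %*% t(R)
    rot <- th * 180 / pi
    # express as rotation about `center` plus translation
    t0 <- cf - (as.vector(R %*% (cm - center)) + center)
    list(tr = rigid_transform2d(rot, t0, flip, center),
         rms = sqrt(mean(res^2)))
  }
  mirrored <- moving_pts
  mirrored[, 1] <- moving_dim[1] - mirrored[, 1]
  cand <- list(fit_one(moving_pts, FALSE), fit_one(mirrored, TRUE))
  best <- which.min(vapply(cand, function(x) x$rms, 0))
  structure(cand[[best]]$tr, rms = cand[[best]]$rms)
}

#' Run the full registration workflow on one volume/section pair
#'
#' Executes the four analysis stages in order: (1) segments and models the
#' three cone phantoms from the CT volume; (2) processes the histology
#' section into a clean mask and three fitted ellipses; (3) matches
#' ellipses to cones, inverts the diameter lookups and spans the in-silico
#' cutting plane, which is resampled from the volume; (4) rigidly
#' registers the downscaled histology cone mask to the in-silico plane's
#' cone mask and scores the overlap (IoU, Dice) with frayed-edge
#' exclusion.
#'
#' @param volume a [volume3d].
#' @param histology a [histology_image].
#' @param config a [default_config]-style `run_config`.
#' @return A `run_report` list: `cones`, `ellipses`, `correspondence`,
#'   `plane`, `transform`, `classification`, `scores`, `warnings`, and an
#'   `artifacts` sub-list with the in-memory masks, plane image and
#'   overlays.
#' @export
run_case <- function(volume, histology, config = default_config()) {
  validate_config(config)
  warn <- character()
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  ## stage 1: CT cone extraction
  seg <- catch_warn(segment_phantoms(volume, config$ct.threshold_low,
                                     config$ct.threshold_high))
  labeled <- label_and_rank(seg, config$ct.connectivity,
                            config$ct.specimen_in_band)
  cones <- lapply(0:2, function(r)
    build_cone_model(volume, labeled, r,
                     sg_window = config$ct.sg_window,
                     sg_polyorder = config$ct.sg_polyorder))
  ## stage 2: histology processing
  ps <- histology$pixel_spacing
  sel <- select_channel(histology, config$histo.channel)
  bin <- binarize(sel$gray, config$histo.polarity, spacing = ps)
  clean <- cleanup(bin, config$histo.morph)
  ellipses <- detect_cone_ellipses(clean, config$histo.minor_range_mm / ps)
  ## stage 3: plane solving and in-silico plane extraction
  corr <- catch_warn(assign_correspondence(
    ellipses, cones, ps, max_ambiguity_ratio = config$plane.max_ambiguity_ratio))
  axis_pts <- t(vapply(1:3, function(i)
    point_on_axis(cones[[corr$perm[i]]], corr$heights[i]), c(0, 0, 0)))
  plane <- fit_plane(axis_pts[1, ], axis_pts[2, ], axis_pts[3, ])
  pim <- resample_plane(volume, plane,
                        out_spacing = config$plane.out_spacing_mm,
                        half_extent_mm = config$plane.half_extent_mm)
  ct_mask <- binary_mask(pim$intensities >= config$ct.threshold_low &
                           pim$intensities <= config$ct.threshold_high &
                           pim$validity, pim$spacing)
  if (!any(ct_mask$values))
    stop("in-silico plane contains no phantom pixels; plane estimate is off")
  ## stage 4: registration and scoring (phantoms only)
  histo_cones <- cone_only_mask(clean, ellipses)
  moving <- downscale_mask(histo_cones, ps, pim$spacing)
  k <- (length(pim$offsets) - 1) / 2
  fixed_pts <- cbind(
    (axis_pts %*% plane$u - sum(plane$point * plane$u))[, 1] / pim$spacing + k + 0.5,
    (axis_pts %*% plane$v - sum(plane$point * plane$v))[, 1] / pim$spacing + k + 0.5)
  moving_pts <- t(vapply(ellipses, function(e) e$center, c(0, 0))) * ps / pim$spacing
  init <- kabsch2d(moving_pts, fixed_pts, dim(moving$values))
  tr <- register_rigid(ct_mask, moving, init = init,
                       try_flip = config$reg.try_flip,
                       smoothing_sigma_px = config$reg.smoothing_sigma_px,
                       max_iterations = config$reg.max_iterations)
  aligned <- apply_transform2d(tr, moving$values, dim(ct_mask$values))
  excl <- catch_warn(frayed_edge_exclusion(ct_mask, config$score.exclusion_band_px))
  pc <- classify(ct_mask, aligned, excl)
  sc <- scores(pc)
  overlays <- render_overlays(
    pim$intensities,
    apply_transform2d(tr, downscale_gray(sel$gray, ps, pim$spacing),
                      dim(ct_mask$values), binarize = FALSE),
    ct_mask, aligned, excl, tile_px = config$overlay.tile_px)
  list(
    inputs = list(volume_dim = dim(volume$intensities),
                  voxel_spacing_mm = volume$spacing,
                  section_dim = dim(histology$rgb)[1:2],
                  pixel_spacing_mm = ps,
                  channel = sel$channel),
    cones = lapply(cones, function(cn) list(
      label = cn$label, voxel_count = cn$voxel_count,
      centroid_mm = cn$centroid, axis = cn$axis,
      profile_diameter_range_mm = range(cn$profile$diameter))),
    ellipses = lapply(ellipses, function(e) list(
      center_px = e$center, major_px = e$major_len,
      minor_px = e$minor_len, angle_deg = e$angle,
      minor_mm = e$minor_len * ps)),
    correspondence = list(perm = corr$perm, residual_mm = corr$residual,
                          heights_mm = corr$heights,
                          ambiguous = corr$ambiguous),
    plane = list(point = plane$point, normal = plane$normal,
                 u = plane$u, v = plane$v),
    transform = list(rotation_deg = tr$rotation,
                     translation_px = tr$translation, flip = tr$flip),
    classification = list(tp = pc$tp, fp = pc$fp, fn = pc$fn,
                          excluded = pc$excluded),
    scores = list(iou = sc$iou, dsc = sc$dsc),
    warnings = warn,
    artifacts = list(plane_image = pim, ct_mask = ct_mask,
                     histo_mask = clean, histo_cone_mask = histo_cones,
                     moving = moving, aligned = aligned, excluded = excl,
                     transform = tr, cones = cones, overlays = overlays))
}

# area-average a grayscale image down to a coarser pitch (for overlays)
downscale_gray <- function(gray, spacing_in, spacing_out) {
  d <- dim(gray)
  r <- spacing_in / spacing_out
  nd <- pmax(ceiling(d * r), 1L)
  bx <- pmin(floor((seq_len(d[1]) - 0.5) * r) + 1L, nd[1])
  by <- pmin(floor((seq_len(d[2]) - 0.5) * r) + 1L, nd[2])
  bin <- outer(bx, (by - 1L) * nd[1], "+")
  tot <- tabulate(bin, nbins = nd[1] * nd[2])
  sm <- rowsum(as.vector(gray), as.vector(bin))
  out <- numeric(nd[1] * nd[2])
  out[as.integer(rownames(sm))] <- sm[, 1]
  matrix(out / pmax(tot, 1), nd[1], nd[2])
}

#' Run the workflow from files and write all outputs
#'
#' Thin wrapper over [run_case]: reads the volume and section image,
#' executes the pipeline and writes the JSON/text report, a one-row score
#' CSV and the overlay PNGs into `out_dir`.
#'
#' @param volume_path,volume_format,volume_shape,volume_spacing_mm volume
#'   input (see [read_volume]).
#' @param section_path,pixel_spacing_mm section input (see [read_histology]).
#' @param out_dir output directory (created if needed).
#' @param config a `run_config`.
#' @return The `run_report`, invisibly.
#' @export
run_end_to_end <- function(volume_path, volume_format = "tiff_stack",
                           volume_shape = NULL, volume_spacing_mm,
                           section_path, pixel_spacing_mm,
                           out_dir = ".", config = default_config()) {
  validate_config(config)
  vol <- read_volume(volume_path, volume_format, spacing_mm = volume_spacing_mm,
                     shape = volume_shape)
  sec <- read_histology(section_path, pixel_spacing_mm)
  rep <- run_case(vol, sec, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(rep[setdiff(names(rep), "artifacts")],
               file.path(out_dir, "report.json"))
  utils::write.csv(
    data.frame(iou = rep$scores$iou, dsc = rep$scores$dsc,
               tp = rep$classification$tp, fp = rep$classification$fp,
               fn = rep$classification$fn,
               excluded = rep$classification$excluded),
    file.path(out_dir, "scores.csv"), row.names = FALSE)
  ov <- rep$artifacts$overlays
  png::writePNG(aperm(ov$checkerboard, c(2, 1, 3)),
                file.path(out_dir, "overlay_checkerboard.png"))
  png::writePNG(aperm(ov$classification, c(2, 1, 3)),
                file.path(out_dir, "overlay_classification.png"))
  invisible(rep)
}

#' Evaluate the pipeline on a synthetic benchmark suite
#'
#' Generates `n_cases` ground-truthed cases with [benchmark_suite],
#' simulates the block and section for each, runs [run_case], and
#' collects per-case scores together with plane-recovery errors.
#'
#' @param n_cases number of cases.
#' @param master_seed suite seed.
#' @param difficulty `"clean"` or `"noisy"`.
#' @param config pipeline configuration.
#' @param shape,spacing block geometry passed to [simulate_block].
#' @param pixel_spacing_mm section rendering pitch.
#' @return A data.frame (one row per case): `case`, `seed`, `iou`, `dsc`,
#'   `normal_err_deg` (angle between estimated and true plane normals),
#'   `point_err_mm` (distance of the true plane anchor from the estimated
#'   plane), `ok` and `error` for failed cases; attribute `summary` holds
#'   mean and sample SD of the scores over successful cases.
#' @export
run_benchmark <- function(n_cases, master_seed, difficulty = "noisy",
                          config = default_config(),
                          shape = c(256L, 256L, 256L), spacing = 0.08,
                          pixel_spacing_mm = 0.007) {
  suite <- benchmark_suite(n_cases, master_seed, difficulty,
                           spacing = spacing, shape = shape)
  rows <- lapply(seq_along(suite), function(i) {
    truth <- suite[[i]]
    out <- tryCatch({
      vol <- simulate_block(truth, shape = shape, spacing = spacing)
      sec <- simulate_section(truth, pixel_spacing = pixel_spacing_mm)
      rep <- run_case(vol, sec$image, config)
      est <- cut_plane(rep$plane$point, rep$plane$normal)
      nerr <- angle_deg(est$normal, truth$true_plane$normal)
      nerr <- min(nerr, 180 - nerr)  # normal sign is a convention
      perr <- abs(sum((truth$true_plane$point - est$point) * est$normal))
      data.frame(case = i, seed = truth$seed, iou = rep$scores$iou,
                 dsc = rep$scores$dsc, normal_err_deg = nerr,
                 point_err_mm = perr, ok = TRUE, error = "")
    }, error = function(e) {
      data.frame(case = i, seed = truth$seed, iou = NA_real_,
                 dsc = NA_real_, normal_err_deg = NA_real_,
                 point_err_mm = NA_real_, ok = FALSE,
                 error = conditionMessage(e))
    })
    out
  })
  df <- do.call(rbind, rows)
  ok <- df[df$ok, , drop = FALSE]
  attr(df, "summary") <- list(
    n = nrow(df), n_ok = nrow(ok),
    iou_mean = mean(ok$iou), iou_sd = stats::sd(ok$iou),
    dsc_mean = mean(ok$dsc), dsc_sd = stats::sd(ok$dsc))
  df
}

angle_deg <- function(a, b) {
  ca <- sum(unit3(a) * unit3(b))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' Summarize a batch of per-case scores
#'
#' @param df data.frame with `iou` and `dsc` columns (e.g. from
#'   [run_benchmark]).
#' @return data.frame with per-score mean and sample (n-1) SD.
#' @export
batch_summary <- function(df) {
  ok <- df[!is.na(df$iou), , drop = FALSE]
  if (!nrow(ok)) stop("all cases failed; nothing to summarize")
  data.frame(metric = c("iou", "dsc"),
             mean = c(mean(ok$iou), mean(ok$dsc)),
             sd = c(stats::sd(ok$iou), stats::sd(ok$dsc)),
             n = nrow(ok))
}

#' Write a simulated case to disk
#'
#' Exports one synthetic case as a TIFF volume stack, a PNG section image
#' and a JSON ground-truth file -- the file-based counterpart of
#' [simulate_block] + [simulate_section] for CLI use and fixtures.
#'
#' @param truth a [synthetic_truth].
#' @param out_dir output directory.
#' @param shape,spacing,pixel_spacing_mm generation geometry.
#' @return Paths of the three written files, invisibly.
#' @export
write_simulated_case <- function(truth, out_dir, shape = c(256L, 256L, 256L),
                                 spacing = 0.08, pixel_spacing_mm = 0.007) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vol <- simulate_block(truth, shape = shape, spacing = spacing)
  vol$intensities <- pmin(pmax(round(vol$intensities), 0), 65535)
  sec <- simulate_section(truth, pixel_spacing = pixel_spacing_mm)
  vp <- file.path(out_dir, "block.tiff")
  sp <- file.path(out_dir, "section.png")
  tp <- file.path(out_dir, "truth.json")
  write_volume(vol, vp, "tiff_stack")
  write_histology(sec$image, sp)
  jsonlite::write_json(list(
    seed = truth$seed,
    cones = lapply(truth$cones, function(cn)
      list(apex = cn$apex, axis = cn$axis, height = cn$height,
           base_diameter = cn$base_diameter, intensity = cn$intensity)),
    tissue = truth$tissue,
    plane = list(point = truth$true_plane$point,
                 normal = truth$true_plane$normal),
    noise = truth$noise, view = truth$view,
    voxel_spacing_mm = spacing, pixel_spacing_mm = pixel_spacing_mm),
    tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(volume = vp, section = sp, truth = tp))
}
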