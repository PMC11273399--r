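#' Overhead camera configuration
#'
#' Pinhole model for a downward-looking camera mounted above the weighing
#' channel. `focal_scale` is the pixels-per-cm scale at 1 cm distance, so an
#' object at distance `d` cm is imaged at `focal_scale / d` pixels per cm.
#'
#' @param height_cm Camera height above the ground (cm). Default 145.
#' @param focal_scale Pixel-cm product of the pinhole model. The default 400
#'   images a finishing pig (camera-to-back distance around 73 cm) at roughly
#'   5.5 px/cm, so the longest pigs span about 800 px of the 1080 px frame
#'   height at any rotation.
#' @param image_width,image_height Frame size in pixels. Default 1920 x 1080.
#' @return An object of class `pigwt_camera`.
#' @export
camera_config <- function(height_cm = 145, focal_scale = 400,
                          image_width = 1920, image_height = 1080) {
  if (height_cm <= 0 || focal_scale <= 0) stop("camera parameters must be positive", call. = FALSE)
  if (image_width < 1 || image_height < 1) stop("image dimensions must be positive", call. = FALSE)
  structure(list(height_cm = height_cm, focal_scale = focal_scale,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height)),
            class = "pigwt_camera")
}

#' @export
print.pigwt_camera <- function(x, ...) {
  cat(sprintf("<pigwt_camera> height %.0f cm, focal scale %.0f px*cm, frame %d x %d\n",
              x$height_cm, x$focal_scale, x$image_width, x$image_height))
  invisible(x)
}

# distance from points (x, y) to the body centreline (arc of curvature
# `kappa` and arc length L0, symmetric about the y axis), plus the arc
# parameter s in [-L0/2, L0/2] of the nearest centreline point
dist_to_centreline <- function(x, y, kappa, L0) {
  if (kappa == 0) {
    s <- pmin(pmax(x, -L0 / 2), L0 / 2)
    list(d = sqrt((x - s)^2 + y^2), s = s)
  } else {
    R <- 1 / kappa
    half <- kappa * L0 / 2 # half the subtended angle
    vx <- x
    vy <- y - R
    theta <- atan2(vx, -vy) # angle from the downward direction
    r <- sqrt(vx^2 + vy^2)
    on_arc <- abs(theta) <= half
    d <- numeric(length(x))
    s <- numeric(length(x))
    d[on_arc] <- abs(r[on_arc] - R)
    s[on_arc] <- R * theta[on_arc]
    if (any(!on_arc)) {
      ex <- R * sin(half)
      ey <- R * (1 - cos(half))
      sgn <- sign(theta[!on_arc])
      d[!on_arc] <- sqrt((vx[!on_arc] - sgn * ex)^2 + (y[!on_arc] - ey)^2)
      s[!on_arc] <- sgn * L0 / 2
    }
    list(d = d, s = s)
  }
}

#' Render a synthetic top-view pig mask
#'
#' Rasterizes one pig as a capsule (stadium) of tip-to-tip length `BL` and
#' width `HW` whose centreline is swept along a circular arc of the given
#' curvature, imaged by the pinhole camera at the pig's camera-to-back
#' distance. The capsule convention is: centreline arc length `BL - HW`,
#' cap radius `HW / 2`, so a straight body projects at exactly its body
#' length and the analytic mask area is `BL*HW + (pi/4 - 1)*HW^2` (in cm^2).
#'
#' @param biometry One-row tibble as returned by [sample_biometry()].
#' @param bend_curvature Spine curvature in 1/cm (0 = straight).
#' @param camera A [camera_config()].
#' @param seed Integer seed controlling rotation, placement jitter and
#'   boundary noise.
#' @param boundary_noise Relative amplitude of the smooth radius wobble added
#'   along the body (0 disables it).
#' @param rotation Body axis rotation in radians; `NULL` (default) draws it
#'   uniformly on `[0, 2*pi)`.
#' @param center_jitter Maximum placement offset from the frame centre, as a
#'   fraction of the free margin in each direction.
#' @return An object of class `pigwt_scene`: a list with elements `mask`
#'   (logical matrix, `TRUE` = pig), `biometry`, `bend_curvature`,
#'   `hdep_true` (cm), `pixels_per_cm`, `rotation`.
#' @examples
#' pig <- sample_biometry(1, seed = 7)
#' sc <- render_mask(pig, bend_curvature = 0.003, seed = 7)
#' sc$pixels_per_cm
#' @export
render_mask <- function(biometry, bend_curvature = 0, camera = camera_config(),
                        seed = 1, boundary_noise = 0.015, rotation = NULL,
                        center_jitter = 0.5) {
  stopifnot(nrow(biometry) == 1)
  if (bend_curvature < 0) stop("`bend_curvature` must be >= 0", call. = FALSE)
  bl <- biometry$body_length_cm
  hw <- biometry$hip_width_cm
  if (bl <= hw) stop("body length must exceed hip width", call. = FALSE)
  hdep <- hdep_actual(camera$height_cm, biometry$body_height_cm,
                      biometry$hip_height_cm)
  ppcm <- camera$focal_scale / hdep
  L0 <- bl - hw

  local_seed(seed, {
    phi <- rotation %||% stats::runif(1, 0, 2 * pi)
    # boundary wobble: two low-order harmonics along the arc parameter
    amp <- boundary_noise * stats::runif(2, 0.5, 1)
    pha <- stats::runif(2, 0, 2 * pi)
    jit <- stats::runif(2, -1, 1)

    # centreline sample points (cm, body frame) -> rotated extent
    tt <- seq(-L0 / 2, L0 / 2, length.out = 65)
    if (bend_curvature == 0) {
      cx <- tt; cy <- rep(0, length(tt))
    } else {
      R <- 1 / bend_curvature
      th <- tt / R
      cx <- R * sin(th); cy <- R * (1 - cos(th))
    }
    rad_max <- hw / 2 * (1 + sum(amp))
    rx <- cx * cos(phi) - cy * sin(phi)
    ry <- cx * sin(phi) + cy * cos(phi)
    ext_x <- range(rx) + c(-rad_max, rad_max)
    ext_y <- range(ry) + c(-rad_max, rad_max)
    need_x <- diff(ext_x) * ppcm
    need_y <- diff(ext_y) * ppcm
    if (need_x > camera$image_width)
      stop(sprintf("rendered body length span (%.0f px) exceeds image width (%d px)",
                   need_x, camera$image_width), call. = FALSE)
    if (need_y > camera$image_height)
      stop(sprintf("rendered body height span (%.0f px) exceeds image height (%d px)",
                   need_y, camera$image_height), call. = FALSE)

    # place the shape: bbox centre at frame centre plus jitter within the
    # free margin
    margin_x <- (camera$image_width - need_x) / 2
    margin_y <- (camera$image_height - need_y) / 2
    ctr_px_x <- camera$image_width / 2 + jit[1] * center_jitter * margin_x
    ctr_px_y <- camera$image_height / 2 + jit[2] * center_jitter * margin_y
    # shape bbox centre in body-rotated cm coords
    bb_cx <- mean(ext_x)
    bb_cy <- mean(ext_y)

    mask <- matrix(FALSE, camera$image_height, camera$image_width)
    # pixel window covering the shape
    j0 <- max(1L, floor(ctr_px_x - need_x / 2) - 1L)
    j1 <- min(camera$image_width, ceiling(ctr_px_x + need_x / 2) + 1L)
    i0 <- max(1L, floor(ctr_px_y - need_y / 2) - 1L)
    i1 <- min(camera$image_height, ceiling(ctr_px_y + need_y / 2) + 1L)
    jj <- j0:j1
    ii <- i0:i1
    # pixel centres in rotated-shape cm coordinates
    px <- (jj - 0.5 - ctr_px_x) / ppcm + bb_cx
    py <- (ii - 0.5 - ctr_px_y) / ppcm + bb_cy
    gx <- matrix(px, nrow = length(ii), ncol = length(jj), byrow = TRUE)
    gy <- matrix(py, nrow = length(ii), ncol = length(jj))
    # un-rotate into the body frame
    bx <- gx * cos(phi) + gy * sin(phi)
    by <- -gx * sin(phi) + gy * cos(phi)
    dc <- dist_to_centreline(as.vector(bx), as.vector(by), bend_curvature, L0)
    radius <- hw / 2 * (1 + amp[1] * sin(2 * pi * dc$s / L0 + pha[1]) +
                          amp[2] * sin(4 * pi * dc$s / L0 + pha[2]))
    sub <- matrix(dc$d <= radius, nrow = length(ii))
    mask[ii, jj] <- sub

    structure(
      list(mask = mask, biometry = biometry, bend_curvature = bend_curvature,
           hdep_true = hdep, pixels_per_cm = ppcm, rotation = phi,
           camera = camera),
      class = "pigwt_scene"
    )
  })
}

#' @export
print.pigwt_scene <- function(x, ...) {
  cat(sprintf("<pigwt_scene> %s: %d x %d mask, %d fg px, hdep %.1f cm, %.2f px/cm, curvature %.4f /cm\n",
              x$biometry$pig_id, nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$hdep_true, x$pixels_per_cm, x$bend_curvature))
  invisible(x)
}

#' Plan a multi-frame synthetic acquisition
#'
#' Samples a herd and a per-frame table of poses: each frame of a pig reuses
#' that pig's biometry but redraws bend curvature (half-normal) and pose.
#'
#' @inheritParams sample_biometry
#' @param frames_per_pig Frames recorded per pig. The default herd protocol
#'   (39 pigs x 39 frames = 1521 frames) emulates an acquisition campaign of
#'   about 1.5 thousand images.
#' @param camera A [camera_config()].
#' @param curvature_sd SD of the half-normal spine-curvature distribution
#'   (1/cm).
#' @param boundary_noise Passed to [render_mask()].
#' @return A list of class `pigwt_plan` with `biometry` (one row per pig)
#'   and `frames` (one row per frame: `frame_id`, `pig_id`,
#'   `bend_curvature`, `frame_seed`).
#' @export
simulate_frames <- function(n_pigs = 39, frames_per_pig = 39,
                            params = pig_population(),
                            camera = camera_config(),
                            curvature_sd = 0.004,
                            boundary_noise = 0.015,
                            seed = 1) {
  if (n_pigs < 1 || frames_per_pig < 1) stop("counts must be >= 1", call. = FALSE)
  biometry <- sample_biometry(n_pigs, params, seed = seed)
  n_frames <- as.integer(n_pigs) * as.integer(frames_per_pig)
  frames <- local_seed(seed + 1L, {
    tibble::tibble(
      pig_id = rep(biometry$pig_id, each = frames_per_pig),
      frame = rep(seq_len(frames_per_pig), times = n_pigs),
      bend_curvature = abs(stats::rnorm(n_frames, 0, curvature_sd)),
      frame_seed = sample.int(.Machine$integer.max - 1L, n_frames)
    )
  })
  frames$frame_id <- sprintf("%s_f%03d", frames$pig_id, frames$frame)
  frames <- frames[, c("frame_id", "pig_id", "bend_curvature", "frame_seed")]
  structure(list(biometry = biometry, frames = frames, camera = camera,
                 boundary_noise = boundary_noise, seed = seed),
            class = "pigwt_plan")
}

#' Generate a full synthetic dataset
#'
#' Renders every frame of a [simulate_frames()] plan. Masks can be kept in
#' memory (small runs), streamed to a handler, or written to disk as 8-bit
#' PNGs via [write_scene_dir()].
#'
#' @inheritParams simulate_frames
#' @param handler Optional `function(scene, frame_row)` called per frame; when
#'   supplied, masks are not retained (constant memory).
#' @return A list of class `pigwt_dataset`: `biometry`, `frames` (plan plus
#'   ground-truth columns `hdep_cm`, `pixels_per_cm`), and `scenes` (list of
#'   [render_mask()] scenes, or `NULL` when a handler was used).
#' @examples
#' ds <- generate_dataset(2, 2, seed = 3)
#' length(ds$scenes)
#' @export
generate_dataset <- function(n_pigs = 39, frames_per_pig = 39,
                             params = pig_population(),
                             camera = camera_config(),
                             curvature_sd = 0.004,
                             boundary_noise = 0.015,
                             seed = 1, handler = NULL) {
  plan <- simulate_frames(n_pigs, frames_per_pig, params, camera,
                          curvature_sd, boundary_noise, seed)
  render_plan(plan, handler = handler)
}

#' @rdname generate_dataset
#' @param plan A `pigwt_plan` from [simulate_frames()].
#' @export
render_plan <- function(plan, handler = NULL) {
  stopifnot(inherits(plan, "pigwt_plan"))
  frames <- plan$frames
  keep <- is.null(handler)
  scenes <- if (keep) vector("list", nrow(frames)) else NULL
  hdep <- numeric(nrow(frames))
  ppcm <- numeric(nrow(frames))
  for (k in seq_len(nrow(frames))) {
    bio <- plan$biometry[plan$biometry$pig_id == frames$pig_id[k], ]
    sc <- render_mask(bio, bend_curvature = frames$bend_curvature[k],
                      camera = plan$camera, seed = frames$frame_seed[k],
                      boundary_noise = plan$boundary_noise)
    hdep[k] <- sc$hdep_true
    ppcm[k] <- sc$pixels_per_cm
    if (keep) scenes[[k]] <- sc else handler(sc, frames[k, ])
  }
  frames$hdep_cm <- hdep
  frames$pixels_per_cm <- ppcm
  structure(list(biometry = plan$biometry, frames = frames, scenes = scenes,
                 camera = plan$camera, seed = plan$seed),
            class = "pigwt_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes one 8-bit PNG per frame (0 = background, 255 = pig), a biometry
#' CSV and a ground-truth sidecar CSV keyed by frame filename.
#'
#' @param plan A `pigwt_plan` from [simulate_frames()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the frames tibble with a `file` column.
#' @export
write_scene_dir <- function(plan, out_dir) {
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(plan$frames))
  ds <- render_plan(plan, handler = function(sc, row) {
    f <- file.path(out_dir, "masks", paste0(row$frame_id, ".png"))
    write_mask_png(sc$mask, f)
  })
  frames <- ds$frames
  frames$file <- file.path("masks", paste0(frames$frame_id, ".png"))
  readr::write_csv(ds$biometry, file.path(out_dir, "biometry.csv"))
  readr::write_csv(frames[, c("file", "frame_id", "pig_id", "bend_curvature",
                              "hdep_cm", "pixels_per_cm")],
                   file.path(out_dir, "scenes.csv"))
  invisible(frames)
}
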