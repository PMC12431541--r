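# Ground-truth scene simulator: camera rigs around a gait volume,
# gait-like marker trajectories, calibration-wand sweeps, exact or noisy
# projections, and rendered frames. It provides oracle fixtures for every
# other module; the kinematics are deliberately simple (smooth sinusoids),
# chosen to produce plausible multi-target geometry, not biomechanics.

#' Default measurement volume
#'
#' A 2.0 m (x) x 4.0 m (y) x 2.0 m (z) capture volume, in millimetres,
#' centred on the origin in x/y with z measured up from the floor.
#'
#' @return List with components `x`, `y`, `z`, each `c(min, max)` in mm.
#' @export
default_volume <- function() {
  list(x = c(-1000, 1000), y = c(-2000, 2000), z = c(0, 2000))
}

volume_center <- function(vol) {
  c(mean(vol$x), mean(vol$y), mean(vol$z))
}

volume_corners <- function(vol) {
  as.matrix(expand.grid(x = vol$x, y = vol$y, z = vol$z))
}

#' Build a ring of calibrated cameras around a capture volume
#'
#' Cameras are placed on a circle around the volume centre, at heights
#' drawn from `height_range`, all oriented at the volume centroid. A
#' shared focal length is computed so that every volume corner projects
#' inside every image with a safety margin; construction fails if no
#' such focal length exists.
#'
#' @param n_cameras Number of cameras (>= 2).
#' @param volume Capture volume, as from [default_volume()], mm.
#' @param distance_mm Ring radius from the volume centre (horizontal), mm.
#' @param height_range Camera heights above the floor, `c(min, max)` mm.
#' @param image_size `c(height, width)` in pixels.
#' @param margin Fraction of the half-image kept clear of the volume.
#' @param seed Integer seed for the height/azimuth jitter.
#' @return Named list of [camera_model()] objects.
#' @export
make_rig <- function(n_cameras = 8L, volume = default_volume(),
                     distance_mm = 5500, height_range = c(1200, 2600),
                     image_size = c(1080L, 1920L), margin = 0.07,
                     seed = 1L) {
  stopifnot(n_cameras >= 2L, distance_mm > 0)
  h <- image_size[1]; w <- image_size[2]
  ctr <- volume_center(volume)
  corners <- volume_corners(volume)
  rng <- local_rng(seed)
  az <- 2 * pi * (seq_len(n_cameras) - 1) / n_cameras +
    rng$runif(n_cameras, -0.06, 0.06)
  hz <- rng$runif(n_cameras, height_range[1], height_range[2])
  poses <- lapply(seq_len(n_cameras), function(i) {
    C <- c(ctr[1] + distance_mm * cos(az[i]),
           ctr[2] + distance_mm * sin(az[i]), hz[i])
    fwd <- ctr - C; fwd <- fwd / sqrt(sum(fwd^2))
    right <- c(fwd[2], -fwd[1], 0); right <- right / sqrt(sum(right^2))
    down <- c(fwd[2] * right[3] - fwd[3] * right[2],
              fwd[3] * right[1] - fwd[1] * right[3],
              fwd[1] * right[2] - fwd[2] * right[1])
    list(C = C, R = rbind(right, down, fwd))
  })
  # largest focal length placing all corners inside all images w/ margin
  fmax <- Inf
  for (p in poses) {
    Xc <- sweep(corners, 2, p$C) %*% t(p$R)
    if (any(Xc[, 3] <= 0)) stop("infeasible rig: volume corner behind a camera")
    fmax <- min(fmax,
                (1 - margin) * (w / 2) / max(abs(Xc[, 1] / Xc[, 3])),
                (1 - margin) * (h / 2) / max(abs(Xc[, 2] / Xc[, 3])))
  }
  if (!is.finite(fmax) || fmax <= 0) stop("infeasible rig geometry")
  K <- rbind(c(fmax, 0, (w - 1) / 2), c(0, fmax, (h - 1) / 2), c(0, 0, 1))
  cams <- lapply(seq_len(n_cameras), function(i) {
    p <- poses[[i]]
    P <- K %*% cbind(p$R, -p$R %*% p$C)
    camera_model(sprintf("cam%02d", i), P, w, h)
  })
  names(cams) <- vapply(cams, `[[`, character(1), "id")
  cams
}

#' Simulate gait-like marker trajectories
#'
#' Generates smooth trajectories for markers attached to anatomical
#' landmarks of a walking subject: constant forward progression plus
#' limb-like sinusoidal oscillation, with larger amplitudes for distal
#' (lower) markers. This is plausible multi-target geometry for testing
#' correspondence and reconstruction, not a validated gait model.
#'
#' @param n_markers Number of markers (default 25 landmarks).
#' @param duration_s Trial duration, seconds.
#' @param fps Frame rate, frames per second.
#' @param speed_mm_s Forward walking speed along +y, mm/s.
#' @param stride_hz Oscillation frequency, Hz.
#' @param volume Capture volume the subject walks through.
#' @param seed Integer seed.
#' @return Array `[n_frames, 3, n_markers]` of positions in mm, with
#'   marker names `m01`, `m02`, ... and attribute `fps`.
#' @export
simulate_gait_markers <- function(n_markers = 25L, duration_s = 1.0,
                                  fps = 240, speed_mm_s = 1300,
                                  stride_hz = 0.9,
                                  volume = default_volume(), seed = 1L) {
  stopifnot(duration_s > 0, n_markers >= 1L)
  rng <- local_rng(seed)
  n_frames <- max(2L, round(duration_s * fps))
  t <- (seq_len(n_frames) - 1) / fps
  ctr <- volume_center(volume)
  # body-like base layout: heights from ankle to head, small x/y offsets
  base_z <- seq(100, 1700, length.out = n_markers) +
    rng$runif(n_markers, -40, 40)
  base_x <- ctr[1] + rng$runif(n_markers, -220, 220)
  y0 <- ctr[2] - speed_mm_s * duration_s / 2 + rng$runif(n_markers, -150, 150)
  # distal markers (low z) swing more
  amp <- 30 + 190 * (1 - (base_z - min(base_z)) / diff(range(base_z)))
  phase <- rng$runif(n_markers, 0, 2 * pi)
  traj <- array(0, c(n_frames, 3L, n_markers),
                dimnames = list(NULL, c("x", "y", "z"),
                                sprintf("m%02d", seq_len(n_markers))))
  for (m in seq_len(n_markers)) {
    traj[, 1, m] <- base_x[m] + 0.3 * amp[m] * sin(2 * pi * stride_hz * t + phase[m] + pi / 3)
    traj[, 2, m] <- y0[m] + speed_mm_s * t + amp[m] * sin(2 * pi * stride_hz * t + phase[m])
    traj[, 3, m] <- base_z[m] + 0.5 * amp[m] * abs(sin(2 * pi * stride_hz * t + phase[m]))
  }
  attr(traj, "fps") <- fps
  traj
}

#' Simulate a calibration-wand sweep
#'
#' Two markers a fixed distance apart ride a smooth quasi-periodic path
#' (incommensurate sinusoids per axis) that covers the capture volume,
#' while the wand orientation tumbles slowly. The inter-marker distance
#' is exact in every frame by construction.
#'
#' @param length_mm Known inter-marker distance of the wand, mm.
#' @param n_frames Number of frames.
#' @param volume Capture volume the wand stays inside.
#' @param seed Integer seed for the path phases.
#' @return List with `a`, `b` (`n_frames x 3` matrices, mm) and
#'   `length_mm`.
#' @export
simulate_wand <- function(length_mm = 500, n_frames = 500,
                          volume = default_volume(), seed = 1L) {
  stopifnot(length_mm > 0, n_frames >= 2L)
  rng <- local_rng(seed)
  t <- seq(0, 1, length.out = n_frames)
  half <- length_mm / 2
  ctr <- volume_center(volume)
  # midpoint amplitude: volume shrunk so both endpoints stay inside
  amp <- c(diff(volume$x), diff(volume$y), diff(volume$z)) / 2 - half - 10
  if (any(amp <= 0)) stop("wand longer than the capture volume")
  freq <- c(1.9, 2.7, 3.3)
  ph <- rng$runif(3, 0, 2 * pi)
  mid <- sapply(1:3, function(a)
    ctr[a] + amp[a] * sin(2 * pi * freq[a] * t + ph[a]))
  th <- 2 * pi * 1.3 * t + rng$runif(1, 0, 2 * pi)   # azimuth
  el <- 1.1 * sin(2 * pi * 0.8 * t + rng$runif(1, 0, 2 * pi))  # elevation
  dir <- cbind(cos(el) * cos(th), cos(el) * sin(th), sin(el))
  a <- mid + half * dir
  b <- mid - half * dir
  # endpoints can exceed the box when the wand tilts; clamp the midpoint
  for (ax in 1:3) {
    lim <- list(volume$x, volume$y, volume$z)[[ax]]
    over <- pmax(a[, ax], b[, ax]) - lim[2]
    und <- lim[1] - pmin(a[, ax], b[, ax])
    shift <- pmax(und, 0) - pmax(over, 0)
    a[, ax] <- a[, ax] + shift; b[, ax] <- b[, ax] + shift
  }
  list(a = a, b = b, length_mm = length_mm)
}

#' Assemble a simulated capture session
#'
#' @param n_cameras Number of cameras in the rig.
#' @param n_markers Number of gait markers.
#' @param duration_s Gait trial duration, seconds.
#' @param wand_frames Frames in the wand sweep.
#' @param wand_length_mm Wand inter-marker distance, mm.
#' @param image_size `c(height, width)` px.
#' @param marker_diameter_mm Physical marker diameter, mm.
#' @param seed Integer master seed.
#' @return List of class `mocap_scene`: `cameras`, `trajectories`,
#'   `wand_track`, `volume`, `frame_rate`, `marker_diameter_mm`.
#' @export
make_scene <- function(n_cameras = 8L, n_markers = 25L, duration_s = 1.0,
                       wand_frames = 500L, wand_length_mm = 500,
                       image_size = c(1080L, 1920L),
                       marker_diameter_mm = 24, seed = 1L) {
  volume <- default_volume()
  cams <- make_rig(n_cameras, volume, image_size = image_size, seed = seed)
  traj <- simulate_gait_markers(n_markers, duration_s = duration_s,
                                volume = volume, seed = seed + 1L)
  wand <- simulate_wand(wand_length_mm, wand_frames, volume, seed = seed + 2L)
  structure(list(cameras = cams, trajectories = traj, wand_track = wand,
                 volume = volume, frame_rate = attr(traj, "fps"),
                 marker_diameter_mm = marker_diameter_mm),
            class = "mocap_scene")
}

#' @export
print.mocap_scene <- function(x, ...) {
  cat(sprintf(paste0("<mocap_scene  %d cameras, %d markers x %d frames, ",
                     "wand %d frames (%.0f mm)>\n"),
              length(x$cameras), dim(x$trajectories)[3],
              dim(x$trajectories)[1], nrow(x$wand_track$a),
              x$wand_track$length_mm))
  invisible(x)
}

#' Project scene trajectories into per-camera detection tables
#'
#' Exact projections of every marker into every camera, optionally
#' perturbed by isotropic Gaussian pixel noise and thinned by independent
#' dropout. Behind-camera and out-of-frame projections are excluded.
#' The `marker` column carries the ground-truth correspondence for
#' oracle tests; reconstruction code never reads it.
#'
#' @param scene A [make_scene()] scene (or list with `cameras` and
#'   `trajectories`).
#' @param frames Frame indices to project (default: all).
#' @param noise_sigma_px Isotropic Gaussian noise SD, px.
#' @param dropout_p Probability an observation is dropped.
#' @param seed Integer seed for noise and dropout.
#' @return Data frame: `camera`, `frame`, `u`, `v`, `w`, `h`,
#'   `confidence`, `class`, `marker`.
#' @export
project_scene <- function(scene, frames = NULL, noise_sigma_px = 0,
                          dropout_p = 0, seed = 1L) {
  traj <- scene$trajectories
  if (is.null(frames)) frames <- seq_len(dim(traj)[1])
  rng <- local_rng(seed)
  out <- vector("list", length(scene$cameras))
  marker_ids <- dimnames(traj)[[3]]
  for (ci in seq_along(scene$cameras)) {
    cam <- scene$cameras[[ci]]
    rows <- lapply(frames, function(f) {
      pts <- t(traj[f, , ])
      pr <- project_points(cam, pts)
      ok <- !pr$behind & pr$u >= 0 & pr$u <= cam$image_width - 1 &
        pr$v >= 0 & pr$v <= cam$image_height - 1
      data.frame(camera = cam$id, frame = f, u = pr$u[ok], v = pr$v[ok],
                 marker = marker_ids[ok], stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, rows)
  }
  det <- do.call(rbind, out)
  if (nrow(det) > 0) {
    if (noise_sigma_px > 0) {
      det$u <- det$u + rng$rnorm(nrow(det), 0, noise_sigma_px)
      det$v <- det$v + rng$rnorm(nrow(det), 0, noise_sigma_px)
    }
    if (dropout_p > 0) det <- det[rng$runif(nrow(det)) >= dropout_p, ]
  }
  rownames(det) <- NULL
  data.frame(camera = det$camera, frame = det$frame, u = det$u, v = det$v,
             w = 10, h = 10, confidence = 1, class = 0L,
             marker = det$marker, stringsAsFactors = FALSE)
}

# projected disc radius of a sphere of radius r_mm centred at X, in px
projected_radius_px <- function(camera, X, r_mm) {
  fwd <- camera$P[3, 1:3]
  e <- if (abs(fwd[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- e - sum(e * fwd) * fwd
  perp <- perp / sqrt(sum(perp^2))
  p0 <- project_points(camera, X)
  p1 <- project_points(camera, X + r_mm * perp)
  sqrt((p1$u - p0$u)^2 + (p1$v - p0$v)^2)
}

#' Render one camera frame of a simulated scene
#'
#' Draws every visible marker as a filled disc of its projected size in
#' the spherical-marker HSL colour range, with a soft (coverage
#' anti-aliased) edge, over a uniform background. Intended for
#' end-to-end tests with [naive_color_detector()].
#'
#' @param scene A [make_scene()] scene.
#' @param camera A camera of the scene (or its id).
#' @param frame Frame index.
#' @param background Background grey level (scalar in `[0,1]`) or an
#'   `h x w x 3` array.
#' @param seed Seed for the per-marker colour draw.
#' @return `h x w x 3` numeric array in `[0,1]`.
#' @export
render_frame <- function(scene, camera, frame, background = 0.35, seed = 1L) {
  if (is.character(camera)) camera <- scene$cameras[[camera]]
  h <- camera$image_height; w <- camera$image_width
  img <- if (is.array(background) && length(dim(background)) == 3L) background
         else array(background, c(h, w, 3L))
  traj <- scene$trajectories
  rng <- local_rng(seed)
  n_markers <- dim(traj)[3]
  cols <- t(sapply(seq_len(n_markers), function(i)
    hsl_to_rgb(rng$runif(1, 140, 160), rng$runif(1, 240, 255),
               rng$runif(1, 140, 170))))
  r_mm <- scene$marker_diameter_mm / 2
  for (m in seq_len(n_markers)) {
    X <- traj[frame, , m]
    pr <- project_points(camera, X)
    if (pr$behind) next
    rad <- projected_radius_px(camera, X, r_mm)
    u0 <- floor(pr$u - rad - 2); u1 <- ceiling(pr$u + rad + 2)
    v0 <- floor(pr$v - rad - 2); v1 <- ceiling(pr$v + rad + 2)
    if (u1 < 0 || v1 < 0 || u0 > w - 1 || v0 > h - 1) next
    uu <- max(u0, 0):min(u1, w - 1); vv <- max(v0, 0):min(v1, h - 1)
    du <- matrix(rep(uu - pr$u, each = length(vv)), length(vv), length(uu))
    dv <- matrix(rep(vv - pr$v, times = length(uu)), length(vv), length(uu))
    cov <- pmin(pmax(rad + 0.5 - sqrt(du^2 + dv^2), 0), 1)
    for (ch in 1:3) {
      patch <- img[vv + 1, uu + 1, ch]
      img[vv + 1, uu + 1, ch] <- patch * (1 - cov) + cols[m, ch] * cov
    }
  }
  img
}
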