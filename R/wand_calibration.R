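# Wand calibration: estimate every camera's 11-parameter projection
# matrix from synchronized views of a rigid two-marker wand of known
# length swept through the volume.
#
# Pipeline: (1) eight-point fundamental matrix between the best-connected
# camera pair; (2) metric bootstrap of that pair by a 1-D focal-length
# search that minimizes the spread of reconstructed wand lengths (a rigid
# length standard seen in many poses fixes the metric structure);
# (3) incremental DLT resection of the remaining cameras and linear
# re-triangulation; (4) alternating resection/intersection refinement
# with Huber-reweighted residuals; (5) a length-coupled refinement in
# which per-frame marker pairs are re-estimated under a soft known-length
# penalty; (6) gauge fixing (first camera at the origin, canonical
# orientation) and global rescaling so the mean reconstructed wand
# length equals the known value.

#' Configuration for wand calibration
#'
#' @param max_iter Maximum alternation iterations (resection +
#'   re-triangulation).
#' @param tol Convergence tolerance on the reprojection RMS, px.
#' @param huber_px Huber threshold for reweighting reprojection
#'   residuals, px.
#' @param ba_iter Maximum Levenberg-Marquardt bundle-adjustment
#'   iterations.
#' @param ba_length_weight Weight (px per mm) of the wand length-spread
#'   penalty inside the bundle adjustment; this is what anchors the
#'   metric (non-projective) structure, since reprojection error alone
#'   cannot.
#' @param point_length_weight Weight (relative to a 1 mm ray-distance
#'   residual) of the known-length measurement when the final wand
#'   marker positions are estimated.
#' @param ref_pair Optional `c(id1, id2)` forcing the bootstrap camera
#'   pair; default picks the pair sharing the most observations.
#' @return List of class `wand_config`.
#' @export
wand_config <- function(max_iter = 30L, tol = 1e-10, huber_px = 3,
                        ba_iter = 12L, ba_length_weight = 2,
                        point_length_weight = 4,
                        ref_pair = NULL) {
  structure(list(max_iter = max_iter, tol = tol, huber_px = huber_px,
                 ba_iter = ba_iter, ba_length_weight = ba_length_weight,
                 point_length_weight = point_length_weight,
                 ref_pair = ref_pair),
            class = "wand_config")
}

#' Mean absolute wand-length error
#'
#' Mean (and SD) of the absolute deviation of reconstructed inter-marker
#' distances from the known wand length.
#'
#' @param a,b `n x 3` matrices of reconstructed marker positions, mm.
#' @param length_mm Known inter-marker distance, mm.
#' @return List with `mean`, `sd` (mm) and the per-frame `lengths`.
#' @export
wand_length_error <- function(a, b, length_mm) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3L, length_mm > 0)
  if (nrow(a) == 0L) stop("no reconstructed wand pairs")
  len <- sqrt(rowSums((a - b)^2))
  dev <- abs(len - length_mm)
  list(mean = mean(dev), sd = stats::sd(dev), lengths = len)
}

#' Read / write wand observation tables
#'
#' CSV with columns `frame`, `camera`, `marker` (`"a"` or `"b"`), `u`,
#' `v`.
#'
#' @param path File path.
#' @param observations Data frame to write.
#' @return The observation data frame (read), or `path` invisibly
#'   (write).
#' @export
read_wand_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "camera", "marker", "u", "v")
  if (!all(need %in% names(df)))
    stop("wand observation file must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' @rdname read_wand_observations
#' @export
write_wand_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- internal linear algebra -------------------------------------------

# RQ decomposition of the left 3x3 block: P ~ K [R | -R C], K upper
# triangular with positive diagonal.
decompose_camera <- function(P) {
  M <- P[, 1:3]
  rev3 <- diag(3)[3:1, ]
  qr_ <- qr(t(rev3 %*% M))
  Q <- qr.Q(qr_); Rm <- qr.R(qr_)
  K <- rev3 %*% t(Rm) %*% rev3
  R <- rev3 %*% t(Q)
  s <- sign(diag(K)); s[s == 0] <- 1
  K <- K %*% diag(s); R <- diag(s) %*% R
  if (det(R) < 0) { K <- -K; R <- -R }
  C <- drop(solve(M, -P[, 4]))
  list(K = K / K[3, 3], R = R, C = C)
}

# Normalized eight-point fundamental matrix; x1, x2 are n x 2.
eight_point <- function(x1, x2) {
  n <- nrow(x1)
  stopifnot(n >= 8L)
  norm_t <- function(x) {
    c0 <- colMeans(x)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(x, 2, c0)^2)))
    T <- diag(c(s, s, 1)); T[1:2, 3] <- -s * c0
    list(T = T, xn = cbind(x, 1) %*% t(T))
  }
  n1 <- norm_t(x1); n2 <- norm_t(x2)
  a <- n1$xn; b <- n2$xn
  A <- cbind(b[, 1] * a[, 1], b[, 1] * a[, 2], b[, 1],
             b[, 2] * a[, 1], b[, 2] * a[, 2], b[, 2],
             a[, 1], a[, 2], 1)
  f <- svd(A, nu = 0)$v[, 9]
  F0 <- matrix(f, 3, 3, byrow = TRUE)
  sv <- svd(F0)
  F0 <- sv$u %*% diag(c(sv$d[1:2], 0)) %*% t(sv$v)   # enforce rank 2
  t(n2$T) %*% F0 %*% n1$T
}

# Vectorised midpoint triangulation from two cameras given as
# list(C = centre, Minv = inverse of left 3x3). x1, x2 n x 2 pixels.
tri_two_view <- function(cam1, cam2, x1, x2) {
  dir_of <- function(cam, x) {
    d <- cbind(x, 1) %*% t(cam$Minv)
    if (cam$detM < 0) d <- -d
    d / sqrt(rowSums(d^2))
  }
  D1 <- dir_of(cam1, x1); D2 <- dir_of(cam2, x2)
  w <- cam2$C - cam1$C
  bb <- rowSums(D1 * D2)
  r1 <- drop(D1 %*% w); r2 <- drop(D2 %*% w)
  den <- 1 - bb^2
  den[abs(den) < 1e-12] <- 1e-12
  t1 <- (r1 - bb * r2) / den
  t2 <- (bb * r1 - r2) / den
  P1 <- sweep(D1 * t1, 2, cam1$C, "+")
  P2 <- sweep(D2 * t2, 2, cam2$C, "+")
  (P1 + P2) / 2
}

ray_cam <- function(P) {
  M <- P[, 1:3]
  list(P = P, Minv = solve(M), C = drop(solve(M, -P[, 4])), detM = det(M))
}

# depth of points (n x 3) in camera P (positive = in front), up to the
# positive canonical scaling
cam_depth <- function(P, X) {
  w <- drop(cbind(X, 1) %*% P[3, ])
  s <- sqrt(sum(P[3, 1:3]^2)) * sign(det(P[, 1:3]))
  w / s
}

project_P <- function(P, X) {
  x <- cbind(X, 1) %*% t(P)
  cbind(x[, 1] / x[, 3], x[, 2] / x[, 3])
}

# Weighted DLT resection of one camera from 3D points and pixels.
dlt_resect <- function(X, x, wts = NULL) {
  n <- nrow(X)
  if (n < 6L) stop("camera connectivity insufficient: fewer than 6 resection points")
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * sv[1]) stop("degenerate wand cloud: resection points near-coplanar")
  s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(X, 2, ctr)^2)))
  T3 <- diag(c(s3, s3, s3, 1)); T3[1:3, 4] <- -s3 * ctr
  c2 <- colMeans(x)
  s2 <- sqrt(2) / mean(sqrt(rowSums(sweep(x, 2, c2)^2)))
  T2 <- diag(c(s2, s2, 1)); T2[1:2, 3] <- -s2 * c2
  Xn <- cbind(X, 1) %*% t(T3)
  xn <- cbind(x, 1) %*% t(T2)
  if (is.null(wts)) wts <- rep(1, n)
  sw <- sqrt(wts)
  A <- rbind(
    cbind(Xn, matrix(0, n, 4), -xn[, 1] * Xn) * sw,
    cbind(matrix(0, n, 4), Xn, -xn[, 2] * Xn) * sw)
  p <- svd(A, nu = 0)$v[, 12]
  solve(T2, matrix(p, 3, 4, byrow = TRUE) %*% T3)
}

# Multi-ray midpoint triangulation; cams: list of ray_cam, obs: matrix
# with columns (cam_index, u, v). Returns point or NULL if degenerate.
tri_multi <- function(cams, obs) {
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_len(nrow(obs))) {
    cam <- cams[[obs[i, 1]]]
    d <- drop(cam$Minv %*% c(obs[i, 2:3], 1))
    if (cam$detM < 0) d <- -d
    d <- d / sqrt(sum(d^2))
    Q <- diag(3) - tcrossprod(d)
    A <- A + Q
    b <- b + drop(Q %*% cam$C)
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-9 * ev[1]) return(NULL)
  drop(solve(A, b))
}

# ---- main entry ---------------------------------------------------------

#' Calibrate a multi-camera rig from a two-marker wand sweep
#'
#' Estimates a full projective camera model for every camera from
#' synchronized observations of a rigid wand of known inter-marker
#' distance, then fixes the gauge (first camera centre at the origin,
#' canonical orientation) and the global scale (mean reconstructed wand
#' length equals `wand_length_mm`).
#'
#' @param observations Data frame with columns `frame`, `camera`,
#'   `marker` (`"a"`/`"b"`), `u`, `v`; one row per sighting.
#' @param wand_length_mm Known inter-marker distance of the wand, mm.
#' @param image_size `c(height, width)` of the sensors, px (used for the
#'   nominal principal point of the bootstrap pair and for the returned
#'   camera models).
#' @param config A [wand_config()].
#' @return List of class `wand_calibration` with elements `cameras`
#'   (named list of [camera_model()]), `wand_points` (list `a`, `b`,
#'   `frame`), `length_error_mean`, `length_error_sd`,
#'   `reconstruction_error_mean`, `reprojection_rms`, `rms_trace`.
#' @export
calibrate_from_wand <- function(observations, wand_length_mm,
                                image_size = c(1080L, 1920L),
                                config = wand_config()) {
  obs <- as.data.frame(observations)
  stopifnot(all(c("frame", "camera", "marker", "u", "v") %in% names(obs)),
            wand_length_mm > 0)
  obs$camera <- as.character(obs$camera)
  cam_ids <- sort(unique(obs$camera))
  if (length(cam_ids) < 2L)
    stop("camera connectivity insufficient: need at least 2 cameras")
  obs$pid <- paste0(obs$frame, ":", obs$marker)

  # frames in which >= 2 cameras see both markers
  seen <- table(unique(obs[, c("frame", "camera")])$frame)
  both <- tapply(obs$marker, obs$frame, function(m) all(c("a", "b") %in% m))
  good_frames <- as.numeric(names(seen))[seen >= 2 & both[names(seen)]]
  if (length(good_frames) < 15L)
    stop("camera connectivity insufficient: fewer than 15 usable wand frames")

  # --- reference pair ----------------------------------------------------
  pids_by_cam <- split(obs$pid, obs$camera)
  if (!is.null(config$ref_pair)) {
    pair <- as.character(config$ref_pair)
    if (!all(pair %in% cam_ids)) stop("unknown camera id in ref_pair")
  } else {
    best <- -1L; pair <- NULL
    for (i in seq_along(cam_ids)) for (j in seq_len(i - 1L)) {
      n_sh <- length(intersect(pids_by_cam[[cam_ids[i]]],
                               pids_by_cam[[cam_ids[j]]]))
      if (n_sh > best) { best <- n_sh; pair <- c(cam_ids[j], cam_ids[i]) }
    }
  }
  o1 <- obs[obs$camera == pair[1], ]
  o2 <- obs[obs$camera == pair[2], ]
  shared <- intersect(o1$pid, o2$pid)
  if (length(shared) < 15L)
    stop("camera connectivity insufficient: reference pair shares too few points")
  x1 <- as.matrix(o1[match(shared, o1$pid), c("u", "v")])
  x2 <- as.matrix(o2[match(shared, o2$pid), c("u", "v")])

  Fm <- eight_point(x1, x2)
  h <- image_size[1]; w <- image_size[2]
  pp <- c((w - 1) / 2, (h - 1) / 2)

  # frame/marker bookkeeping on the shared points, for length spread
  sh_frame <- sub(":.*$", "", shared)
  sh_marker <- sub("^.*:", "", shared)
  pairable <- intersect(sh_frame[sh_marker == "a"], sh_frame[sh_marker == "b"])
  ia <- match(paste0(pairable, ":a"), shared)
  ib <- match(paste0(pairable, ":b"), shared)

  boot <- function(f) {
    K <- rbind(c(f, 0, pp[1]), c(0, f, pp[2]), c(0, 0, 1))
    E <- t(K) %*% Fm %*% K
    sv <- svd(E)
    W <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
    cands <- list()
    for (Rm in list(sv$u %*% W %*% t(sv$v), sv$u %*% t(W) %*% t(sv$v))) {
      if (det(Rm) < 0) Rm <- -Rm
      for (tv in list(sv$u[, 3], -sv$u[, 3]))
        cands[[length(cands) + 1L]] <- list(R = Rm, t = tv)
    }
    P1 <- K %*% cbind(diag(3), 0)
    best <- NULL; best_n <- -1L
    for (cd in cands) {
      P2 <- K %*% cbind(cd$R, cd$t)
      X <- tri_two_view(ray_cam(P1), ray_cam(P2), x1, x2)
      n_ok <- sum(cam_depth(P1, X) > 0 & cam_depth(P2, X) > 0)
      if (n_ok > best_n) { best_n <- n_ok; best <- list(P1 = P1, P2 = P2, X = X) }
    }
    best
  }
  score <- function(f) {
    bt <- boot(f)
    len <- sqrt(rowSums((bt$X[ia, , drop = FALSE] - bt$X[ib, , drop = FALSE])^2))
    stats::sd(len) / mean(len)
  }
  # coarse log grid, then golden-section refinement of the focal length
  grid <- max(h, w) * 2^seq(-2, 1.5, length.out = 36)
  sc <- vapply(grid, score, numeric(1))
  k0 <- which.min(sc)
  lo <- grid[max(1L, k0 - 1L)]; hi <- grid[min(length(grid), k0 + 1L)]
  opt <- stats::optimize(score, c(lo, hi), tol = 1e-9 * grid[k0])
  bt <- boot(opt$minimum)

  # --- structure + incremental resection ---------------------------------
  Pmats <- stats::setNames(vector("list", length(cam_ids)), cam_ids)
  Pmats[[pair[1]]] <- bt$P1
  Pmats[[pair[2]]] <- bt$P2
  X <- bt$X
  rownames(X) <- shared
  obs_by_cam <- split(obs, obs$camera)

  remaining <- setdiff(cam_ids, pair)
  while (length(remaining) > 0L) {
    counts <- vapply(remaining, function(cid)
      sum(obs_by_cam[[cid]]$pid %in% rownames(X)), integer(1))
    cid <- remaining[which.max(counts)]
    oc <- obs_by_cam[[cid]]
    idx <- oc$pid %in% rownames(X)
    if (sum(idx) < 6L)
      stop("camera connectivity insufficient: camera ", cid,
           " shares too few points with the calibrated set")
    Pmats[[cid]] <- dlt_resect(X[oc$pid[idx], , drop = FALSE],
                               as.matrix(oc[idx, c("u", "v")]))
    remaining <- setdiff(remaining, cid)
    X <- retriangulate(obs, Pmats)
  }

  # --- alternation: resection / intersection, reprojection-RMS tracked ---
  rms_of <- function(Pmats, X) {
    se <- 0; n <- 0L
    for (cid in names(Pmats)) {
      oc <- obs_by_cam[[cid]]
      idx <- oc$pid %in% rownames(X)
      pr <- project_P(Pmats[[cid]], X[oc$pid[idx], , drop = FALSE])
      se <- se + sum((pr - as.matrix(oc[idx, c("u", "v")]))^2)
      n <- n + sum(idx)
    }
    sqrt(se / (2 * n))
  }
  trace <- rms_of(Pmats, X)
  for (it in seq_len(config$max_iter)) {
    new_P <- Pmats
    for (cid in cam_ids) {
      oc <- obs_by_cam[[cid]]
      idx <- oc$pid %in% rownames(X)
      Xc <- X[oc$pid[idx], , drop = FALSE]
      xc <- as.matrix(oc[idx, c("u", "v")])
      res <- sqrt(rowSums((project_P(Pmats[[cid]], Xc) - xc)^2))
      wts <- pmin(1, config$huber_px / pmax(res, 1e-12))
      new_P[[cid]] <- dlt_resect(Xc, xc, wts)
    }
    new_X <- retriangulate(obs, new_P)
    rms <- rms_of(new_P, new_X)
    if (rms <= trace[length(trace)]) {
      Pmats <- new_P; X <- new_X; trace <- c(trace, rms)
      if (trace[length(trace) - 1L] - rms < config$tol) break
    } else break
  }

  # --- bundle adjustment ---------------------------------------------------
  # skipped when the alternation already converged to numerical zero
  # (noise-free data); the length-spread penalty anchors metric structure
  ba_trace <- NULL
  if (trace[length(trace)] > 1e-7 && config$ba_iter > 0) {
    ba <- ba_refine(obs, Pmats, X, config)
    Pmats <- ba$Pmats; X <- ba$X; ba_trace <- ba$cost_trace
  }
  # metric upgrade: reprojection error is exactly invariant to a scene
  # homography (cameras compensated), so the member of that gauge family
  # that best restores a constant wand length and valid camera
  # intrinsics can be applied for free; it removes the metric drift the
  # soft penalty cannot fully suppress
  # the warp is fitted on plainly re-triangulated lengths: the bundle's
  # own length penalty shrinks per-frame lengths toward their mean and
  # would hide the distortion signal from the fit
  up <- metric_upgrade(retriangulate(obs, Pmats), wand_length_mm, Pmats,
                       pp = pp)
  if (!is.null(up)) {
    Xh <- cbind(X, 1) %*% t(up)
    X <- Xh[, 1:3, drop = FALSE] / Xh[, 4]
    Hi <- solve(up)
    Pmats <- lapply(Pmats, function(P) P %*% Hi)
  }
  lens <- wand_pair_lengths(X)

  # --- gauge fix + global scale ------------------------------------------
  s <- wand_length_mm / mean(lens$len)
  dc <- decompose_camera(Pmats[[cam_ids[1]]])
  Tinv <- rbind(cbind(t(dc$R) / s, dc$C), c(0, 0, 0, 1))
  cams <- lapply(cam_ids, function(cid)
    camera_model(cid, Pmats[[cid]] %*% Tinv, w, h))
  names(cams) <- cam_ids

  # final estimate of the wand marker positions with the fitted cameras;
  # the known inter-marker distance enters as a soft measurement
  Pfin <- lapply(cams, `[[`, "P")
  Xf <- retriangulate(obs, Pfin)
  rcf <- lapply(Pfin, ray_cam)
  Xf <- refine_points_length(obs, rcf, Xf, wand_length_mm,
                             config$point_length_weight)
  lensf <- wand_pair_lengths(Xf)
  le <- wand_length_error(lensf$a, lensf$b, wand_length_mm)
  recon_err <- mean_ray_distances(obs, rcf, Xf)

  structure(list(
    cameras = cams,
    wand_points = list(frame = lensf$frame, a = lensf$a, b = lensf$b),
    length_error_mean = le$mean, length_error_sd = le$sd,
    reconstruction_error_mean = mean(recon_err),
    reprojection_rms = rms_of(Pfin, Xf),
    rms_trace = trace, ba_cost_trace = ba_trace, ref_pair = pair),
    class = "wand_calibration")
}

#' @export
print.wand_calibration <- function(x, ...) {
  cat(sprintf(paste0("<wand_calibration  %d cameras, %d frames\n",
                     "  wand length error %.4f mm (sd %.4f)\n",
                     "  reconstruction error %.4f mm, reprojection RMS %.5f px>\n"),
              length(x$cameras), length(x$wand_points$frame),
              x$length_error_mean, x$length_error_sd,
              x$reconstruction_error_mean, x$reprojection_rms))
  invisible(x)
}

# triangulate every point visible in >= 2 calibrated cameras
retriangulate <- function(obs, Pmats) {
  Pmats <- Filter(Negate(is.null), Pmats)
  rc <- lapply(Pmats, ray_cam)
  have <- obs[obs$camera %in% names(Pmats), ]
  sp <- split(have[, c("camera", "u", "v")], have$pid)
  pts <- matrix(NA_real_, length(sp), 3,
                dimnames = list(names(sp), NULL))
  for (i in seq_along(sp)) {
    g <- sp[[i]]
    if (nrow(g) < 2L) next
    ob <- cbind(match(g$camera, names(rc)), g$u, g$v)
    p <- tri_multi(rc, ob)
    if (!is.null(p)) pts[i, ] <- p
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

wand_pair_lengths <- function(X) {
  pid <- rownames(X)
  fr <- sub(":.*$", "", pid); mk <- sub("^.*:", "", pid)
  frames <- intersect(fr[mk == "a"], fr[mk == "b"])
  a <- X[match(paste0(frames, ":a"), pid), , drop = FALSE]
  b <- X[match(paste0(frames, ":b"), pid), , drop = FALSE]
  list(frame = frames, a = a, b = b, len = sqrt(rowSums((a - b)^2)))
}

# per-observation ray distances to the reconstructed points, by point
mean_ray_distances <- function(obs, rc, X) {
  have <- obs[obs$pid %in% rownames(X) & obs$camera %in% names(rc), ]
  sp <- split(have[, c("camera", "u", "v")], have$pid)
  vapply(names(sp), function(pid) {
    g <- sp[[pid]]
    x <- X[pid, ]
    mean(vapply(seq_len(nrow(g)), function(i) {
      cam <- rc[[g$camera[i]]]
      d <- drop(cam$Minv %*% c(g$u[i], g$v[i], 1))
      if (cam$detM < 0) d <- -d
      d <- d / sqrt(sum(d^2))
      p <- x - cam$C
      sqrt(max(sum(p^2) - sum(p * d)^2, 0))
    }, numeric(1)))
  }, numeric(1))
}

# Levenberg-Marquardt bundle adjustment over all 12 entries of every
# camera matrix and all marker positions. Residuals are Huber-weighted
# reprojection errors (px) plus, for every frame with both markers, a
# length-spread penalty lambda * (|a - b| - target) with target the mean
# reconstructed length at entry: reprojection error alone is invariant
# to a projective warp of the whole scene, and the constancy of the wand
# length is precisely the information that pins down metric structure.
# Point blocks are the per-frame marker pairs (6 dof, or 3 when one
# marker is missing), so the normal equations stay in standard sparse
# bundle form with a small Schur complement over the cameras.
ba_refine <- function(obs, Pmats, X, config) {
  cam_ids <- names(Pmats)
  nc <- length(cam_ids)
  pid <- rownames(X)
  fr <- sub(":.*$", "", pid)
  # blocks: one per frame, holding that frame's available markers
  blk_frames <- unique(fr)
  blk_of <- match(fr, blk_frames)
  members <- split(seq_along(pid), blk_of)     # rows of X per block
  nb <- length(members)
  off_of <- integer(length(pid))               # offset of pid inside block
  for (b in seq_len(nb)) {
    m <- members[[b]]
    m <- m[order(sub("^.*:", "", pid[m]))]     # "a" before "b"
    members[[b]] <- m
    off_of[m] <- 3L * (seq_along(m) - 1L)
  }
  dof <- vapply(members, function(m) 3L * length(m), integer(1))
  pairs <- which(dof == 6L)

  o <- obs[obs$pid %in% pid & obs$camera %in% cam_ids, ]
  o_cam <- match(o$camera, cam_ids)
  o_row <- match(o$pid, pid)
  lam <- config$ba_length_weight
  target <- {
    l <- vapply(pairs, function(b) {
      m <- members[[b]]; sqrt(sum((X[m[1], ] - X[m[2], ])^2))
    }, numeric(1))
    mean(l)
  }

  cost_of <- function(Plist, Xm, wt) {
    se <- 0
    for (c in seq_len(nc)) {
      i <- which(o_cam == c)
      A <- cbind(Xm[o_row[i], , drop = FALSE], 1)
      P <- Plist[[c]]
      w <- drop(A %*% P[3, ])
      ru <- drop(A %*% P[1, ]) / w - o$u[i]
      rv <- drop(A %*% P[2, ]) / w - o$v[i]
      se <- se + sum(wt[i] * (ru^2 + rv^2))
    }
    for (b in pairs) {
      m <- members[[b]]
      se <- se + lam^2 * (sqrt(sum((Xm[m[1], ] - Xm[m[2], ])^2)) - target)^2
    }
    se
  }

  # Huber weights fixed per outer iteration (IRLS)
  huber_wt <- function(Plist, Xm) {
    wt <- numeric(nrow(o))
    for (c in seq_len(nc)) {
      i <- which(o_cam == c)
      A <- cbind(Xm[o_row[i], , drop = FALSE], 1)
      P <- Plist[[c]]
      w <- drop(A %*% P[3, ])
      ru <- drop(A %*% P[1, ]) / w - o$u[i]
      rv <- drop(A %*% P[2, ]) / w - o$v[i]
      r <- sqrt(ru^2 + rv^2)
      wt[i] <- pmin(1, config$huber_px / pmax(r, 1e-12))
    }
    wt
  }

  mu <- 1e-4
  wt <- huber_wt(Pmats, X)
  cost <- cost_of(Pmats, X, wt)
  cost_trace <- cost
  for (iter in seq_len(config$ba_iter)) {
    # --- assemble normal equations ------------------------------------
    U <- array(0, c(12, 12, nc)); gc_ <- matrix(0, 12, nc)
    V <- lapply(dof, function(d) matrix(0, d, d))
    gb <- lapply(dof, function(d) numeric(d))
    W <- lapply(seq_len(nb), function(b) list())
    for (c in seq_len(nc)) {
      i <- which(o_cam == c)
      rows <- o_row[i]
      A <- cbind(X[rows, , drop = FALSE], 1)
      P <- Pmats[[c]]
      aa <- drop(A %*% P[1, ]); bb2 <- drop(A %*% P[2, ])
      w <- drop(A %*% P[3, ])
      ru <- aa / w - o$u[i]; rv <- bb2 / w - o$v[i]
      sw <- sqrt(wt[i])
      for (k in seq_along(i)) {
        Ak <- A[k, ]
        Jp <- rbind(c(Ak / w[k], numeric(4), -aa[k] / w[k]^2 * Ak),
                    c(numeric(4), Ak / w[k], -bb2[k] / w[k]^2 * Ak))
        Jx <- rbind((P[1, 1:3] - (aa[k] / w[k]) * P[3, 1:3]) / w[k],
                    (P[2, 1:3] - (bb2[k] / w[k]) * P[3, 1:3]) / w[k])
        Jp <- sw[k] * Jp; Jx <- sw[k] * Jx
        r2 <- sw[k] * c(ru[k], rv[k])
        b <- blk_of[rows[k]]; of <- off_of[rows[k]]
        U[, , c] <- U[, , c] + crossprod(Jp)
        gc_[, c] <- gc_[, c] + crossprod(Jp, r2)
        sel <- of + 1:3
        V[[b]][sel, sel] <- V[[b]][sel, sel] + crossprod(Jx)
        gb[[b]][sel] <- gb[[b]][sel] + crossprod(Jx, r2)
        key <- as.character(c)
        if (is.null(W[[b]][[key]])) W[[b]][[key]] <- matrix(0, 12, dof[b])
        W[[b]][[key]][, sel] <- W[[b]][[key]][, sel] + crossprod(Jp, Jx)
      }
    }
    for (b in pairs) {
      m <- members[[b]]
      dv <- X[m[1], ] - X[m[2], ]; dl <- sqrt(sum(dv^2))
      u <- dv / dl
      Jl <- lam * c(u, -u)
      rl <- lam * (dl - target)
      V[[b]] <- V[[b]] + tcrossprod(Jl)
      gb[[b]] <- gb[[b]] + Jl * rl
    }
    # --- LM step with adaptive damping --------------------------------
    improved <- FALSE
    for (try in 1:6) {
      S <- matrix(0, 12 * nc, 12 * nc)
      rhs <- -as.numeric(gc_)
      for (c in seq_len(nc)) {
        ii <- (c - 1) * 12 + 1:12
        S[ii, ii] <- U[, , c] + mu * diag(diag(U[, , c]) + 1e-9)
      }
      ok <- TRUE
      Vinv <- vector("list", nb)
      for (b in seq_len(nb)) {
        Vd <- V[[b]] + mu * diag(diag(V[[b]]) + 1e-9, dof[b])
        Vinv[[b]] <- tryCatch(solve(Vd), error = function(e) NULL)
        if (is.null(Vinv[[b]])) { ok <- FALSE; break }
        cams_b <- as.integer(names(W[[b]]))
        Y <- lapply(W[[b]], function(Wc) Wc %*% Vinv[[b]])
        for (ci in seq_along(cams_b)) {
          c1 <- cams_b[ci]; i1 <- (c1 - 1) * 12 + 1:12
          rhs[i1] <- rhs[i1] + drop(Y[[ci]] %*% gb[[b]])
          for (cj in seq_along(cams_b)) {
            c2 <- cams_b[cj]; i2 <- (c2 - 1) * 12 + 1:12
            S[i1, i2] <- S[i1, i2] - Y[[ci]] %*% t(W[[b]][[cj]])
          }
        }
      }
      if (!ok) { mu <- mu * 5; next }
      dc <- tryCatch(solve(S, rhs), error = function(e) NULL)
      if (is.null(dc)) { mu <- mu * 5; next }
      Pnew <- Pmats
      for (c in seq_len(nc))
        Pnew[[c]] <- Pmats[[c]] + matrix(dc[(c - 1) * 12 + 1:12], 3, 4,
                                         byrow = TRUE)
      Xnew <- X
      for (b in seq_len(nb)) {
        dpb <- -drop(Vinv[[b]] %*% (gb[[b]] +
          Reduce(`+`, c(list(numeric(dof[b])),
            lapply(names(W[[b]]), function(key) {
              c1 <- as.integer(key)
              drop(crossprod(W[[b]][[key]], dc[(c1 - 1) * 12 + 1:12]))
            })))))
        for (j in seq_along(members[[b]]))
          Xnew[members[[b]][j], ] <- X[members[[b]][j], ] + dpb[3 * (j - 1) + 1:3]
      }
      cnew <- cost_of(Pnew, Xnew, wt)
      if (cnew < cost) {
        Pmats <- Pnew; X <- Xnew
        improved <- cost - cnew > 1e-12 * cost
        cost <- cnew
        cost_trace <- c(cost_trace, cost)
        mu <- max(mu / 3, 1e-12)
        break
      } else mu <- mu * 5
    }
    if (!improved) break
    wt <- huber_wt(Pmats, X)
    cost <- cost_of(Pmats, X, wt)
  }
  list(Pmats = Pmats, X = X, cost_trace = cost_trace)
}

# Find the 4x4 scene homography H (the full gauge family of reprojection
# error) that (i) makes the reconstructed wand segments match the known
# length and (ii) makes the warped cameras' intrinsics satisfy square
# pixels and zero skew (properties of real sensors, hence near-exact
# constraints, weighted strongly) with the principal point softly tied
# to the image centre. H is parameterized by its first 15 entries
# (H[4,4] = 1); residual Jacobians are numeric (each camera residual is
# a cheap RQ decomposition). Levenberg-damped Gauss-Newton from a pure
# rescaling. Returns NULL with too few segments.
metric_upgrade <- function(X, length_mm, Pmats = NULL, cam_weight = 1000,
                           pp = NULL, pp_weight = 30) {
  lens <- wand_pair_lengths(X)
  if (length(lens$frame) < 15L) return(NULL)
  # work on a centred, unit-scale copy of the scene so all 15 homography
  # parameters are O(1) (numeric Jacobian and damping stay conditioned)
  c0 <- colMeans(rbind(lens$a, lens$b))
  sn <- mean(sqrt(rowSums(sweep(rbind(lens$a, lens$b), 2, c0)^2)))
  Tn <- rbind(cbind(diag(3) / sn, -c0 / sn), c(0, 0, 0, 1))
  Td <- rbind(cbind(diag(3) * sn, c0), c(0, 0, 0, 1))
  An <- cbind(sweep(lens$a, 2, c0) / sn, 1)
  Bn <- cbind(sweep(lens$b, 2, c0) / sn, 1)
  # 12 parameters: the 3x3 linear block and the projective row. The
  # translation column and H[4,4] are fixed (pure gauge: they move
  # neither segment lengths nor camera intrinsics).
  H_of <- function(th) rbind(cbind(matrix(th[1:9], 3, 3, byrow = TRUE), 0),
                             c(th[10:12], 1))
  res_of <- function(th) {
    H <- H_of(th)
    Ah <- An %*% t(H); Bh <- Bn %*% t(H)
    pa <- Ah[, 1:3] / Ah[, 4]; pb <- Bh[, 1:3] / Bh[, 4]
    r <- sn * sqrt(rowSums((pa - pb)^2)) - length_mm
    if (!is.null(Pmats)) {
      Hti <- solve(Td %*% H %*% Tn)
      rc <- unlist(lapply(Pmats, function(P) {
        K <- decompose_camera(P %*% Hti)$K
        r1 <- c(K[1, 2] / K[1, 1], K[1, 1] / K[2, 2] - 1)
        if (!is.null(pp))
          r1 <- c(r1, (pp_weight / cam_weight) *
                    c((K[1, 3] - pp[1]) / K[1, 1],
                      (K[2, 3] - pp[2]) / K[2, 2]))
        r1
      }))
      r <- c(r, cam_weight * rc)
    }
    r
  }
  s0 <- length_mm / mean(sqrt(rowSums((lens$a - lens$b)^2)))
  th <- c(as.numeric(t(diag(3) * s0)), 0, 0, 0)
  r <- res_of(th)
  cost <- sum(r^2)
  mu <- 1e-6
  for (it in 1:40) {
    J <- matrix(0, length(r), 12)
    for (p in 1:12) {
      h <- 1e-6 * (abs(th[p]) + 1e-2)
      th2 <- th; th2[p] <- th2[p] + h
      J[, p] <- (res_of(th2) - r) / h
    }
    JtJ <- crossprod(J)
    ridge <- 1e-9 * max(diag(JtJ)) * diag(12)   # pins gauge rotations
    improved <- FALSE
    for (try in 1:8) {
      step <- tryCatch(
        solve(JtJ + mu * diag(diag(JtJ) + 1e-12) + ridge, crossprod(J, r)),
        error = function(e) NULL)
      if (is.null(step)) { mu <- mu * 10; next }
      th2 <- th - drop(step)
      r2 <- tryCatch(res_of(th2), error = function(e) NULL)
      if (!is.null(r2) && all(is.finite(r2)) && sum(r2^2) < cost) {
        th <- th2; r <- r2
        improved <- cost - sum(r2^2) > 1e-12 * cost
        cost <- sum(r2^2)
        mu <- max(mu / 3, 1e-12)
        break
      } else mu <- mu * 10
    }
    if (!improved) break
  }
  Td %*% H_of(th) %*% Tn
}

# Per-frame joint re-estimation of the two wand markers under a soft
# known-length penalty: minimize sum of squared perpendicular ray
# distances for both markers plus weight^2 * (|a-b| - L)^2 (all mm),
# by Gauss-Newton from the unconstrained triangulation.
refine_points_length <- function(obs, rc, X, target_len, weight) {
  pid <- rownames(X)
  fr <- sub(":.*$", "", pid); mk <- sub("^.*:", "", pid)
  frames <- intersect(fr[mk == "a"], fr[mk == "b"])
  sp <- split(obs[obs$pid %in% pid, c("pid", "camera", "u", "v")],
              obs$pid[obs$pid %in% pid])
  ray_list <- function(p) {
    g <- sp[[p]]
    lapply(seq_len(nrow(g)), function(i) {
      cam <- rc[[g$camera[i]]]
      d <- drop(cam$Minv %*% c(g$u[i], g$v[i], 1))
      if (cam$detM < 0) d <- -d
      d <- d / sqrt(sum(d^2))
      list(Q = diag(3) - tcrossprod(d), C = cam$C)
    })
  }
  Xout <- X
  for (f in frames) {
    pa <- paste0(f, ":a"); pb <- paste0(f, ":b")
    a <- X[pa, ]; b <- X[pb, ]
    ra <- ray_list(pa); rb <- ray_list(pb)
    for (gn in 1:3) {
      # stack residuals r and Jacobian J over (a, b)
      J <- matrix(0, 0, 6); r <- numeric(0)
      for (rr in ra) {
        r <- c(r, drop(rr$Q %*% (a - rr$C)))
        J <- rbind(J, cbind(rr$Q, matrix(0, 3, 3)))
      }
      for (rr in rb) {
        r <- c(r, drop(rr$Q %*% (b - rr$C)))
        J <- rbind(J, cbind(matrix(0, 3, 3), rr$Q))
      }
      dvec <- a - b; dl <- sqrt(sum(dvec^2))
      u <- dvec / dl
      r <- c(r, weight * (dl - target_len))
      J <- rbind(J, weight * c(u, -u))
      step <- tryCatch(solve(crossprod(J) + 1e-9 * diag(6), crossprod(J, r)),
                       error = function(e) NULL)
      if (is.null(step)) break
      a <- a - step[1:3]; b <- b - step[4:6]
    }
    Xout[pa, ] <- a; Xout[pb, ] <- b
  }
  Xout
}
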