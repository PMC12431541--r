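# Multi-view marker correspondence and 3D reconstruction. A candidate
# point is accepted only if it is reconstructed from at least
# `min_cameras` cameras and its distance to every contributing camera
# ray is below the gate (default 5 mm). The search seeds candidates with
# detection pairs from the two widest-baseline cameras, grows them
# greedily one camera at a time (re-triangulating after every addition),
# and resolves conflicts so that no detection contributes to more than
# one point.

#' Reconstruction configuration
#'
#' @param gate_mm Maximum allowed point-to-ray distance for every
#'   contributing camera, mm.
#' @param min_cameras Minimum number of contributing cameras per point
#'   (3 for runs faithful to the published acceptance condition).
#' @return List of class `reconstruction_config`.
#' @export
reconstruction_config <- function(gate_mm = 5, min_cameras = 3L) {
  stopifnot(gate_mm > 0, min_cameras >= 2L)
  structure(list(gate_mm = gate_mm, min_cameras = as.integer(min_cameras)),
            class = "reconstruction_config")
}

# per-camera precomputation: centre, Minv, det sign, plus ray directions
# for each of that camera's detections in the frame
frame_rays <- function(det, cameras) {
  ids <- sort(unique(det$camera))
  unknown <- setdiff(ids, names(cameras))
  if (length(unknown) > 0)
    stop("unknown camera id(s) in detections: ", paste(unknown, collapse = ", "))
  lapply(stats::setNames(ids, ids), function(cid) {
    cam <- cameras[[cid]]
    rows <- which(det$camera == cid)
    x <- cbind(det$u[rows], det$v[rows], 1)
    D <- x %*% t(solve(cam$P[, 1:3]))
    if (det(cam$P[, 1:3]) < 0) D <- -D
    D <- D / sqrt(rowSums(D^2))
    list(id = cid, C = cam$center, D = D, rows = rows)
  })
}

# distances from point p to all rays of one camera entry
dists_to_rays <- function(p, cr) {
  w <- matrix(p - cr$C, nrow(cr$D), 3, byrow = TRUE)
  proj <- rowSums(w * cr$D)
  sqrt(pmax(rowSums(w^2) - proj^2, 0))
}

#' Match detections across cameras and triangulate one frame
#'
#' @param detections Data frame for a single frame: columns `camera`,
#'   `u`, `v` (other columns pass through untouched).
#' @param cameras Named list of [camera_model()] objects covering every
#'   camera id present.
#' @param cfg A [reconstruction_config()].
#' @return List of reconstructed points; each is a list with `position`
#'   (mm), `cameras_used`, `distances` (per-camera ray distance, mm),
#'   `mean_ray_distance`, `detections` (data frame `camera`, `u`, `v`
#'   of the contributing digitized coordinates) and `label` (`NA`,
#'   assigned later).
#' @export
match_and_triangulate <- function(detections, cameras,
                                  cfg = reconstruction_config()) {
  det <- as.data.frame(detections)
  if (nrow(det) == 0L) return(list())
  det$camera <- as.character(det$camera)
  crs <- frame_rays(det, cameras)
  ids <- names(crs)
  if (length(ids) < 2L) return(list())

  # camera pairs ordered by decreasing baseline; seeding starts from the
  # widest pair, later pairs only recover markers the earlier pairs
  # missed (dropout), using detections not yet claimed by a point
  pairs <- list()
  for (i in seq_along(ids)) for (j in seq_len(i - 1L))
    pairs[[length(pairs) + 1L]] <-
      list(i = j, j = i, bl = sqrt(sum((crs[[i]]$C - crs[[j]]$C)^2)))
  pairs <- pairs[order(-vapply(pairs, `[[`, numeric(1), "bl"))]

  used <- character(0)
  out <- list()
  key_of <- function(cams, rows) paste0(cams, "#", rows)
  for (pr in pairs) {
    ca <- crs[[pr$i]]; cb <- crs[[pr$j]]
    free_a <- which(!(key_of(ca$id, ca$rows) %in% used))
    free_b <- which(!(key_of(cb$id, cb$rows) %in% used))
    if (length(free_a) == 0L || length(free_b) == 0L) next
    others <- setdiff(ids, c(ca$id, cb$id))
    cands <- list()
    for (ia in free_a) for (ib in free_b) {
      st <- new_candidate(ca, ia)
      st <- add_ray(st, cb, ib)
      p <- solve_candidate(st)
      if (is.null(p)) next
      dd <- cand_dists(st, p)
      if (any(dd >= cfg$gate_mm)) next
      # grow: per remaining camera, best in-gate detection after
      # re-triangulation against the updated point
      for (cid in others) {
        cr <- crs[[cid]]
        rough <- dists_to_rays(p, cr)
        trial <- which(rough < 2 * cfg$gate_mm &
                         !(key_of(cr$id, cr$rows) %in% used))
        pick_mean <- Inf; pick_st <- NULL; pick_p <- NULL
        for (k in trial) {
          st2 <- add_ray(st, cr, k)
          p2 <- solve_candidate(st2)
          if (is.null(p2)) next
          d2 <- cand_dists(st2, p2)
          if (all(d2 < cfg$gate_mm) && mean(d2) < pick_mean) {
            pick_mean <- mean(d2); pick_st <- st2; pick_p <- p2
          }
        }
        if (!is.null(pick_st)) { st <- pick_st; p <- pick_p }
      }
      dd <- cand_dists(st, p)
      if (length(st$cams) >= cfg$min_cameras && all(dd < cfg$gate_mm))
        cands[[length(cands) + 1L]] <-
          list(st = st, p = p, d = dd, n = length(st$cams), mean_d = mean(dd))
    }
    if (length(cands) == 0L) next
    # conflict resolution: most cameras, then lowest mean ray distance;
    # each detection contributes to at most one point
    ord <- order(-vapply(cands, `[[`, numeric(1), "n"),
                 vapply(cands, `[[`, numeric(1), "mean_d"))
    for (ci in ord) {
      cd <- cands[[ci]]
      keys <- key_of(cd$st$cams, cd$st$det_rows)
      if (any(keys %in% used)) next
      used <- c(used, keys)
      rows <- cd$st$det_rows
      out[[length(out) + 1L]] <- list(
        position = cd$p,
        cameras_used = cd$st$cams,
        distances = stats::setNames(cd$d, cd$st$cams),
        mean_ray_distance = cd$mean_d,
        detections = data.frame(camera = cd$st$cams,
                                u = det$u[rows], v = det$v[rows],
                                stringsAsFactors = FALSE),
        label = NA_character_)
    }
  }
  out
}

new_candidate <- function(cr, k) {
  st <- list(A = matrix(0, 3, 3), b = numeric(3),
             O = matrix(numeric(0), 0, 3), D = matrix(numeric(0), 0, 3),
             cams = character(0), det_rows = integer(0))
  add_ray(st, cr, k)
}

add_ray <- function(st, cr, k) {
  d <- cr$D[k, ]
  Q <- diag(3) - tcrossprod(d)
  st$A <- st$A + Q
  st$b <- st$b + drop(Q %*% cr$C)
  st$O <- rbind(st$O, cr$C)
  st$D <- rbind(st$D, d)
  st$cams <- c(st$cams, cr$id)
  st$det_rows <- c(st$det_rows, cr$rows[k])
  st
}

solve_candidate <- function(st) {
  ev <- eigen(st$A, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-9 * ev[1]) return(NULL)
  drop(solve(st$A, st$b))
}

cand_dists <- function(st, p) {
  w <- sweep(st$O, 2, p, "-")
  proj <- rowSums(w * st$D)
  sqrt(pmax(rowSums(w^2) - proj^2, 0))
}

#' Reconstruct every frame of a detection table
#'
#' Applies [match_and_triangulate()] frame by frame and reports how many
#' points met the reconstruction condition.
#'
#' @param detections Detection table (columns `camera`, `frame`, `u`,
#'   `v`).
#' @param cameras Named list of [camera_model()] objects.
#' @param cfg A [reconstruction_config()].
#' @param expected_per_frame Optional number of physical markers
#'   expected per frame, used for the failure bookkeeping.
#' @return List with `points` (list of per-frame point lists, named by
#'   frame) and `report` (data frame `frame`, `expected`,
#'   `reconstructed`, `failed`, plus totals as attributes).
#' @export
reconstruct_sequence <- function(detections, cameras,
                                 cfg = reconstruction_config(),
                                 expected_per_frame = NA_integer_) {
  det <- as.data.frame(detections)
  if (nrow(det) == 0L) {
    warning("empty detection table")
    rep0 <- data.frame(frame = integer(0), expected = integer(0),
                       reconstructed = integer(0), failed = integer(0))
    return(list(points = list(), report = rep0))
  }
  frames <- sort(unique(det$frame))
  pts <- lapply(frames, function(f)
    match_and_triangulate(det[det$frame == f, , drop = FALSE], cameras, cfg))
  names(pts) <- as.character(frames)
  nrec <- vapply(pts, length, integer(1))
  report <- data.frame(frame = frames,
                       expected = rep(expected_per_frame, length(frames)),
                       reconstructed = nrec,
                       failed = if (is.na(expected_per_frame)) NA_integer_
                                else pmax(expected_per_frame - nrec, 0L))
  attr(report, "total_expected") <-
    if (is.na(expected_per_frame)) NA_integer_
    else expected_per_frame * length(frames)
  attr(report, "total_reconstructed") <- sum(nrec)
  attr(report, "total_failed") <-
    if (is.na(expected_per_frame)) NA_integer_ else sum(report$failed)
  list(points = pts, report = report)
}

#' Track reconstructed points over frames and propagate labels
#'
#' Labels assigned to the first frame's points are carried forward by
#' nearest-neighbour association between consecutive frames. Jumps
#' larger than `max_jump_mm` (per elapsed frame) break the association;
#' unlabelled points receive stable anonymous ids, gaps are recorded,
#' and associations with a second candidate inside the jump radius are
#' flagged ambiguous rather than silently resolved.
#'
#' @param points_by_frame List of per-frame point lists, as produced by
#'   [reconstruct_sequence()].
#' @param initial_labels Character vector of labels for the points of
#'   the first frame (in their list order); must be unique.
#' @param max_jump_mm Maximum allowed displacement between consecutive
#'   frames, mm.
#' @return Data frame with columns `frame`, `label`, `x`, `y`, `z`,
#'   `n_cameras`, `mean_ray_distance`, `ambiguous`; recorded gaps are in
#'   `attr(, "gaps")`.
#' @export
track_and_label <- function(points_by_frame, initial_labels, max_jump_mm = 50) {
  stopifnot(length(points_by_frame) >= 1L)
  if (anyDuplicated(initial_labels))
    stop("duplicate initial labels")
  frames <- names(points_by_frame)
  f1 <- points_by_frame[[1]]
  if (length(initial_labels) != length(f1))
    stop("initial_labels must match the number of frame-1 points")
  anon <- 0L
  state <- list()   # label -> list(pos, frame_idx)
  rows <- list()
  gaps <- list()
  emit <- function(fi, label, pt, ambiguous) {
    rows[[length(rows) + 1L]] <<- data.frame(
      frame = as.integer(frames[fi]), label = label,
      x = pt$position[1], y = pt$position[2], z = pt$position[3],
      n_cameras = length(pt$cameras_used),
      mean_ray_distance = pt$mean_ray_distance,
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  for (i in seq_along(f1)) {
    state[[initial_labels[i]]] <- list(pos = f1[[i]]$position, fi = 1L)
    emit(1L, initial_labels[i], f1[[i]], FALSE)
  }
  for (fi in seq_along(points_by_frame)[-1]) {
    pts <- points_by_frame[[fi]]
    if (length(pts) == 0L) next
    P <- t(vapply(pts, function(p) p$position, numeric(3)))
    labs <- names(state)
    assigned_pt <- rep(FALSE, length(pts))
    ambiguous_pt <- rep(FALSE, length(pts))
    if (length(labs) > 0) {
      Dm <- matrix(Inf, length(labs), length(pts))
      lim <- numeric(length(labs))
      for (li in seq_along(labs)) {
        s <- state[[labs[li]]]
        lim[li] <- max_jump_mm * (fi - s$fi)
        Dm[li, ] <- sqrt(colSums((t(P) - s$pos)^2))
      }
      # greedy nearest-neighbour assignment under the per-label limit
      cand <- which(Dm <= lim, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ordc <- order(Dm[cand])
        used_lab <- rep(FALSE, length(labs))
        for (k in ordc) {
          li <- cand[k, 1]; pi <- cand[k, 2]
          if (used_lab[li] || assigned_pt[pi]) next
          # ambiguity: another free point also inside this label's limit
          other <- which(!assigned_pt & Dm[li, ] <= lim[li])
          amb <- length(other) > 1L
          used_lab[li] <- TRUE; assigned_pt[pi] <- TRUE
          ambiguous_pt[pi] <- amb
          lab <- labs[li]
          if (fi - state[[lab]]$fi > 1L)
            gaps[[length(gaps) + 1L]] <-
              list(label = lab, from = frames[state[[lab]]$fi],
                   to = frames[fi])
          state[[lab]] <- list(pos = P[pi, ], fi = fi)
          emit(fi, lab, pts[[pi]], amb)
        }
      }
    }
    for (pi in which(!assigned_pt)) {
      anon <- anon + 1L
      lab <- sprintf("u%04d", anon)
      state[[lab]] <- list(pos = P[pi, ], fi = fi)
      emit(fi, lab, pts[[pi]], FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "gaps") <- gaps
  out
}

#' Write reconstructed trajectories to CSV or TRC
#'
#' The CSV has one row per frame/label; the TRC export writes the
#' standard tab-separated motion-capture trajectory format (units mm).
#'
#' @param trajectories Data frame from [track_and_label()].
#' @param path Output file.
#' @param fps Frame rate, required for TRC.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories[, c("frame", "label", "x", "y", "z",
                                    "n_cameras", "mean_ray_distance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
export_trc <- function(trajectories, path, fps = 240) {
  labs <- unique(trajectories$label)
  frames <- sort(unique(trajectories$frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t%d\t%d", fps, fps, length(frames),
            length(labs), fps, frames[1], length(frames)),
    paste(c("Frame#", "Time",
            unlist(lapply(labs, function(l) c(l, "", "")))), collapse = "\t"),
    paste(c("", "", unlist(lapply(seq_along(labs), function(i)
      sprintf(c("X%d", "Y%d", "Z%d"), i)))), collapse = "\t")), con)
  for (k in seq_along(frames)) {
    f <- frames[k]
    vals <- unlist(lapply(labs, function(l) {
      r <- trajectories[trajectories$frame == f & trajectories$label == l, ]
      if (nrow(r) == 0) c("", "", "")
      else sprintf("%.5f", c(r$x[1], r$y[1], r$z[1]))
    }))
    writeLines(paste(c(k, sprintf("%.5f", (f - frames[1]) / fps), vals),
                     collapse = "\t"), con)
  }
  invisible(path)
}
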