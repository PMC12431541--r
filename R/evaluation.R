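# Accuracy and robustness evaluation: per-component Bland-Altman
# agreement against a gold standard (fixed bias by one-sample t-test,
# proportional bias by regressing the difference on the pairwise mean),
# resultant-error summary statistics, and a Monte Carlo that perturbs
# digitized coordinates within the reprojection of a small sphere and
# measures the displacement of the re-triangulated point.

#' Bland-Altman agreement analysis per coordinate component
#'
#' For each of x, y, z: difference = proposed - gold; fixed bias is the
#' mean difference, tested against zero with a one-sample t-test;
#' proportional bias is the OLS slope of the difference on the pairwise
#' mean, with a t-test of slope = 0. Limits of agreement are
#' mean +/- 1.96 SD. Parametric tests are appropriate for the large
#' unimodal samples this is designed for.
#'
#' @param proposed,gold `n x 3` matrices of paired 3D positions (mm),
#'   `n >= 3`.
#' @return Object of class `bland_altman`: a data frame with one row per
#'   component and columns `component`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `t_stat`, `p_fixed`, `ci_low`, `ci_high`
#'   (95% CI of the mean difference), `slope`, `slope_se`, `p_slope`,
#'   `slope_ci_low`, `slope_ci_high`, `degenerate`.
#' @export
bland_altman <- function(proposed, gold) {
  proposed <- as.matrix(proposed); gold <- as.matrix(gold)
  stopifnot(ncol(proposed) == 3L, ncol(gold) == 3L)
  n <- nrow(proposed)
  if (n != nrow(gold)) stop("proposed and gold must be paired (equal length)")
  if (n < 3L) stop("Bland-Altman analysis needs at least 3 pairs")
  comp <- c("x", "y", "z")
  rows <- lapply(1:3, function(k) {
    d <- proposed[, k] - gold[, k]
    m <- (proposed[, k] + gold[, k]) / 2
    md <- mean(d); sdd <- stats::sd(d)
    degen <- sdd < .Machine$double.eps^0.5 * max(1, abs(md))
    if (degen) {
      tt <- list(statistic = NA_real_, p.value = NA_real_,
                 conf.int = c(md, md))
    } else {
      tt <- stats::t.test(d)
    }
    if (degen || stats::sd(m) == 0) {
      sl <- c(NA_real_, NA_real_, NA_real_)
      if (degen && stats::sd(m) > 0) sl <- c(0, 0, NA_real_)
    } else {
      fit <- summary(stats::lm(d ~ m))$coefficients
      sl <- c(fit[2, 1], fit[2, 2], fit[2, 4])
    }
    data.frame(component = comp[k], mean_diff = md, sd_diff = sdd,
               loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
               t_stat = unname(tt$statistic), p_fixed = tt$p.value,
               ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
               slope = sl[1], slope_se = sl[2], p_slope = sl[3],
               slope_ci_low = sl[1] - 1.96 * sl[2],
               slope_ci_high = sl[1] + 1.96 * sl[2],
               degenerate = degen, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("bland_altman", "data.frame"))
}

#' Resultant-error summary statistics
#'
#' The resultant error is the Euclidean norm of the 3D error vector.
#' Percentiles use the linear-interpolation convention between order
#' statistics (R quantile type 7).
#'
#' @param error_vectors `n x 3` matrix of error vectors (mm), or a
#'   numeric vector of precomputed norms.
#' @param breaks Histogram bin specification (passed to [hist()]).
#' @return List of class `resultant_error_stats`: `mean`, `p95`, `p99`
#'   (mm), `n`, and `histogram` (counts + breaks).
#' @export
resultant_error_stats <- function(error_vectors, breaks = "Sturges") {
  if (is.matrix(error_vectors) || is.data.frame(error_vectors)) {
    ev <- as.matrix(error_vectors)
    stopifnot(ncol(ev) == 3L)
    r <- sqrt(rowSums(ev^2))
  } else r <- abs(as.numeric(error_vectors))
  if (length(r) == 0L) stop("no error vectors")
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  structure(list(mean = mean(r),
                 p95 = unname(stats::quantile(r, 0.95, type = 7)),
                 p99 = unname(stats::quantile(r, 0.99, type = 7)),
                 n = length(r),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "resultant_error_stats")
}

#' @export
print.resultant_error_stats <- function(x, ...) {
  cat(sprintf("<resultant error  n=%d  mean %.2f mm  p95 %.2f mm  p99 %.2f mm>\n",
              x$n, x$mean, x$p95, x$p99))
  invisible(x)
}

#' Robustness configuration
#'
#' @param noise_sphere_diameter_mm Diameter of the sphere whose
#'   reprojection bounds the pixel noise (default 12 mm, half the
#'   24 mm marker).
#' @param iterations Monte Carlo iterations per camera-count stratum.
#' @param seed Integer seed.
#' @param per_camera `"all"` perturbs every contributing camera each
#'   iteration; `"one"` perturbs a single randomly chosen camera.
#' @return List of class `robustness_config`.
#' @export
robustness_config <- function(noise_sphere_diameter_mm = 12,
                              iterations = 10000L, seed = 1L,
                              per_camera = c("all", "one")) {
  stopifnot(noise_sphere_diameter_mm >= 0, iterations >= 1L)
  structure(list(noise_sphere_diameter_mm = noise_sphere_diameter_mm,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 per_camera = match.arg(per_camera)),
            class = "robustness_config")
}

#' Reprojection-noise robustness Monte Carlo
#'
#' Each iteration picks a reconstructed point uniformly from its
#' camera-count stratum, perturbs the digitized coordinate in each
#' contributing camera by a uniform draw over the disk obtained by
#' reprojecting a sphere of the configured diameter centred at the
#' point, re-triangulates from the noisy coordinates, and records the
#' distance to the unperturbed reconstruction. Means and maxima are
#' aggregated per camera count.
#'
#' @param points List of reconstructed points (from
#'   [match_and_triangulate()]); each must retain its contributing
#'   digitized coordinates in `$detections`.
#' @param cameras Named list of [camera_model()] objects.
#' @param cfg A [robustness_config()].
#' @return Data frame: `n_cameras`, `mean_mm`, `max_mm`, `n_points`,
#'   `iterations`.
#' @export
robustness_mc <- function(points, cameras, cfg = robustness_config()) {
  if (length(points) == 0L) stop("no reconstructed points")
  ok <- vapply(points, function(p) !is.null(p$detections) &&
                 nrow(p$detections) == length(p$cameras_used), logical(1))
  if (!all(ok))
    stop("points lack stored digitized coordinates (run match_and_triangulate)")
  rng <- local_rng(cfg$seed)
  r_mm <- cfg$noise_sphere_diameter_mm / 2
  # precompute per point: camera ray machinery and projected disk radius
  prep <- lapply(points, function(p) {
    cams <- lapply(p$detections$camera, function(cid) {
      cam <- cameras[[cid]]
      if (is.null(cam)) stop("unknown camera id: ", cid)
      cam
    })
    rad <- vapply(cams, function(cam)
      projected_radius_px(cam, p$position, r_mm), numeric(1))
    Minv <- lapply(cams, function(cam) {
      s <- if (det(cam$P[, 1:3]) < 0) -1 else 1
      s * solve(cam$P[, 1:3])
    })
    list(pos = p$position, u = p$detections$u, v = p$detections$v,
         rad = rad, Minv = Minv,
         centers = lapply(cams, `[[`, "center"))
  })
  strata <- split(seq_along(prep),
                  vapply(points, function(p) length(p$cameras_used), integer(1)))
  out <- lapply(names(strata), function(k_str) {
    idx <- strata[[k_str]]
    k <- as.integer(k_str)
    pick <- rng$sample_int(length(idx), cfg$iterations, replace = TRUE)
    theta <- rng$runif(cfg$iterations * k, 0, 2 * pi)
    rr <- sqrt(rng$runif(cfg$iterations * k))
    one_cam <- if (cfg$per_camera == "one")
      rng$sample_int(k, cfg$iterations, replace = TRUE) else NULL
    d <- numeric(cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      pp <- prep[[idx[pick[it]]]]
      A <- matrix(0, 3, 3); b <- numeric(3)
      base <- (it - 1L) * k
      for (ci in seq_len(k)) {
        perturb <- is.null(one_cam) || one_cam[it] == ci
        ru <- pp$u[ci]; rv <- pp$v[ci]
        if (perturb && pp$rad[ci] > 0) {
          rad <- pp$rad[ci] * rr[base + ci]
          ru <- ru + rad * cos(theta[base + ci])
          rv <- rv + rad * sin(theta[base + ci])
        }
        dir <- pp$Minv[[ci]] %*% c(ru, rv, 1)
        dir <- dir / sqrt(sum(dir^2))
        Q <- diag(3) - tcrossprod(drop(dir))
        A <- A + Q
        b <- b + drop(Q %*% pp$centers[[ci]])
      }
      pnew <- drop(solve(A, b))
      d[it] <- sqrt(sum((pnew - pp$pos)^2))
    }
    data.frame(n_cameras = k, mean_mm = mean(d), max_mm = max(d),
               n_points = length(idx), iterations = cfg$iterations)
  })
  out <- do.call(rbind, out)
  out[order(out$n_cameras), ]
}
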