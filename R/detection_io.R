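# Detector-facing plumbing. The detector itself is a contract: any
# function(image, config) returning a detection table can be plugged in
# (a fine-tuned network, or the GPU-free colour detector below). This
# module owns pre-detection upscaling with the coordinate mapping back
# to the original resolution, the square-bounding-box filter, and the
# detection table format.

#' Detection configuration
#'
#' @param confidence_threshold Minimum detection confidence kept.
#' @param iou_threshold IoU suppression threshold, passed through to the
#'   detector.
#' @param upscale_factor Integer upscaling factor applied (bicubic)
#'   before detection; detected coordinates are mapped back by pure
#'   division.
#' @return List of class `detection_config`.
#' @export
detection_config <- function(confidence_threshold = 0.01,
                             iou_threshold = 0.01,
                             upscale_factor = 2) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            iou_threshold >= 0, iou_threshold <= 1, upscale_factor >= 1)
  structure(list(confidence_threshold = confidence_threshold,
                 iou_threshold = iou_threshold,
                 upscale_factor = upscale_factor),
            class = "detection_config")
}

validate_detections <- function(det) {
  need <- c("u", "v", "w", "h", "confidence", "class")
  miss <- setdiff(need, names(det))
  if (length(miss) > 0)
    stop("detector output lacks columns: ", paste(miss, collapse = ", "))
  det
}

#' Run a detector on a bicubically upscaled image
#'
#' The image is upscaled by `cfg$upscale_factor` (bicubic) before being
#' handed to the detector; detected centres and bounding-box sizes are
#' divided by the factor so they are expressed at the original
#' resolution.
#'
#' @param image `h x w x 3` numeric array in `[0,1]`.
#' @param detector Function `(image, cfg)` returning a data frame with
#'   columns `u`, `v`, `w`, `h`, `confidence`, `class`.
#' @param cfg A [detection_config()].
#' @return Detection data frame at original-resolution coordinates,
#'   thresholded at `cfg$confidence_threshold`.
#' @export
detect_with_upscale <- function(image, detector, cfg = detection_config()) {
  stopifnot(is.array(image), length(dim(image)) == 3L, all(dim(image)[1:2] > 0))
  f <- cfg$upscale_factor
  up <- if (f == 1) image else
    resize_image(image, dim(image)[1] * f, dim(image)[2] * f, "bicubic")
  det <- tryCatch(detector(up, cfg),
                  error = function(e) stop("detector failed: ",
                                           conditionMessage(e)))
  det <- validate_detections(det)
  det$u <- det$u / f; det$v <- det$v / f
  det$w <- det$w / f; det$h <- det$h / f
  det[det$confidence >= cfg$confidence_threshold, , drop = FALSE]
}

#' Filter detections whose bounding box deviates from a square
#'
#' Partially occluded markers produce elongated boxes with centres
#' shifted off the true marker centre; discarding boxes whose aspect
#' ratio `min(w, h) / max(w, h)` falls below `1 - tolerance` suppresses
#' them before reconstruction.
#'
#' @param detections Detection data frame with columns `w`, `h`.
#' @param tolerance Allowed relative deviation from a square, in
#'   `[0, 1)`.
#' @return The surviving subset, order preserved.
#' @export
squareness_filter <- function(detections, tolerance = 0.2) {
  stopifnot(tolerance >= 0, tolerance < 1)
  if (nrow(detections) == 0L) return(detections)
  ratio <- pmin(detections$w, detections$h) / pmax(detections$w, detections$h)
  detections[ratio >= 1 - tolerance, , drop = FALSE]
}

#' GPU-free colour-threshold marker detector
#'
#' Thresholds pixels inside the spherical-marker HSL ranges, labels
#' connected components, and reports each component's centroid and tight
#' bounding box with confidence 1. A reference detector for end-to-end
#' tests; it satisfies the detector contract of [detect_with_upscale()].
#'
#' @param image `h x w x 3` RGB array in `[0,1]`.
#' @param cfg Ignored (contract compatibility).
#' @param hsl_ranges List with `H`, `S`, `L`, each `c(min, max)` on the
#'   0-255 scale.
#' @param min_area Minimum component area, px.
#' @return Detection data frame `u`, `v`, `w`, `h`, `confidence`,
#'   `class`.
#' @export
naive_color_detector <- function(image, cfg = NULL,
                                 hsl_ranges = list(H = c(140, 160),
                                                   S = c(240, 255),
                                                   L = c(140, 170)),
                                 min_area = 4L) {
  stopifnot(length(dim(image)) == 3L)
  hsl <- rgb_to_hsl(image)
  mask <- hsl$H >= hsl_ranges$H[1] & hsl$H <= hsl_ranges$H[2] &
    hsl$S >= hsl_ranges$S[1] & hsl$S <= hsl_ranges$S[2] &
    hsl$L >= hsl_ranges$L[1] & hsl$L <= hsl_ranges$L[2]
  empty <- data.frame(u = numeric(0), v = numeric(0), w = numeric(0),
                      h = numeric(0), confidence = numeric(0),
                      class = integer(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask * 1)
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(mask)        # 0-based v
  cols <- (idx - 1) %/% nrow(mask)       # 0-based u
  out <- lapply(split(seq_along(idx), comp), function(k) {
    if (length(k) < min_area) return(NULL)
    u <- cols[k]; v <- rows[k]
    data.frame(u = mean(u), v = mean(v),
               w = diff(range(u)) + 1, h = diff(range(v)) + 1,
               confidence = 1, class = 0L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Read / write detection tables
#'
#' CSV with columns `camera`, `frame`, `u`, `v`, `w`, `h`, `confidence`,
#' `class`. Numeric fields are written with 17 significant digits so a
#' write/read round trip is lossless.
#'
#' @param path File path.
#' @param detections Data frame to write.
#' @return The detection data frame (read) or `path`, invisibly (write).
#' @export
read_detections <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("camera", "frame", "u", "v", "w", "h", "confidence", "class")
  if (!all(need %in% names(raw)))
    stop("detection file must have columns: ", paste(need, collapse = ", "))
  num_cols <- c("frame", "u", "v", "w", "h", "confidence", "class")
  for (cn in num_cols) {
    val <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(val))
    if (length(bad) > 0)
      stop("malformed detection row(s) at line ",
           paste(utils::head(bad + 1L, 5), collapse = ", "),
           ": non-numeric '", cn, "'")
    raw[[cn]] <- val
  }
  raw$frame <- as.integer(raw$frame)
  raw$class <- as.integer(raw$class)
  raw
}

#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  df <- as.data.frame(detections)
  out <- df
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
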