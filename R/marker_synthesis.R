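# Synthesis of annotated training images: virtual spheres (deformed
# discs in the marker colour range), virtual tape patches, their
# composition at the anchor point given by the tape aspect ratio, and
# insertion of 7-12 composed markers into upscaled crops of background
# frames with per-marker boundary blurring and automatic bounding-box
# annotation.

#' Sampling configuration for training-image synthesis
#'
#' All ranges are closed intervals. HSL channels are on a 0-255 scale
#' (hue: 256 steps over the full circle).
#'
#' @param sphere_base_diameter Rasterization diameter of the virtual
#'   sphere before the final resize, px.
#' @param sphere_hsl List `H`, `S`, `L` ranges for the sphere colour.
#' @param sphere_line1,sphere_line2 Sampling ranges (fractions of the
#'   diameter) for the first and second region-boundary lines; used for
#'   both the vertical and the horizontal pair.
#' @param axis_scale Range of the one-axis scaling ("ellipsoid" squash).
#' @param tape_prob Probability that the tape is rendered.
#' @param tape_hsl List `H`, `S`, `L` ranges for the tape colour.
#' @param tape_length,tape_width Tape size ranges, as multiples of the
#'   sphere diameter.
#' @param tape_aspect Tape aspect-ratio (vertical compression) range.
#' @param tape_offset_max Maximum offset of the tape rectangle from its
#'   image centre, as a multiple of the sphere diameter.
#' @param final_diameter Range of the composed sphere diameter, px.
#' @param rotation Range of the random composite rotation, degrees.
#' @param crop_size Background crop size, px (square).
#' @param out_size Training image size, px (square).
#' @param n_markers Range (integers) of markers inserted per image.
#' @param blur_sigma Range of the per-marker Gaussian blur SD, px.
#' @param blur_dilate Marker-mask dilation radius for the blur band, as
#'   a multiple of the blur SD.
#' @param class_id Object class written to annotations.
#' @return List of class `synthesis_config`.
#' @export
synthesis_config <- function(sphere_base_diameter = 48L,
                             sphere_hsl = list(H = c(140, 160),
                                               S = c(240, 255),
                                               L = c(140, 170)),
                             sphere_line1 = c(0.25, 0.42),
                             sphere_line2 = c(0.58, 0.75),
                             axis_scale = c(0.80, 1.00),
                             tape_prob = 0.5,
                             tape_hsl = list(H = c(0, 30),
                                             S = c(0, 20),
                                             L = c(200, 255)),
                             tape_length = c(1.5, 3.0),
                             tape_width = c(0.8, 1.6),
                             tape_aspect = c(0.10, 1.00),
                             tape_offset_max = 0.5,
                             final_diameter = c(8, 24),
                             rotation = c(0, 360),
                             crop_size = 320L,
                             out_size = 640L,
                             n_markers = c(7L, 12L),
                             blur_sigma = c(0.5, 3.0),
                             blur_dilate = 3,
                             class_id = 0L) {
  structure(as.list(environment()), class = "synthesis_config")
}

as_rng <- function(x) if (is.list(x) && is.function(x$runif)) x else local_rng(x)

runif1 <- function(rng, range) rng$runif(1, range[1], range[2])

# ---- virtual sphere -----------------------------------------------------

sample_sphere_spec <- function(rng, config) {
  list(base_diameter = config$sphere_base_diameter,
       l1 = runif1(rng, config$sphere_line1),
       l2 = runif1(rng, config$sphere_line2),
       l3 = runif1(rng, config$sphere_line1),
       l4 = runif1(rng, config$sphere_line2),
       axis_scale = runif1(rng, config$axis_scale),
       axis = if (rng$runif(1) < 0.5) "vertical" else "horizontal",
       hsl = c(H = runif1(rng, config$sphere_hsl$H),
               S = runif1(rng, config$sphere_hsl$S),
               L = runif1(rng, config$sphere_hsl$L)))
}

# nearest-neighbour remap of one axis so the source thirds move to the
# target boundary fractions (l1, l2)
nn_region_map <- function(n, l1, l2) {
  f <- (seq_len(n) - 0.5) / n
  src <- ifelse(f < l1, f / l1 / 3,
         ifelse(f < l2, 1 / 3 + (f - l1) / (l2 - l1) / 3,
                2 / 3 + (f - l2) / (1 - l2) / 3))
  pmin(pmax(floor(src * n), 0), n - 1) + 1L
}

#' Sample a virtual sphere image
#'
#' A disc is divided into nine regions by four boundary lines whose
#' positions are drawn from the configured ranges; the regions are
#' resized (nearest-neighbour) to the sampled boundaries, one axis is
#' scaled by the sampled factor, and the disc is filled with a uniform
#' colour drawn from the marker HSL ranges.
#'
#' @param rng An RNG stream from `local_rng()` or an integer seed.
#' @param config A [synthesis_config()].
#' @param spec Optional pre-sampled specification (for reproducing a
#'   specific sphere).
#' @return List with `image` (`h x w x 3`), `mask` (logical), `spec`.
#' @export
sample_sphere <- function(rng = 1L, config = synthesis_config(), spec = NULL) {
  rng <- as_rng(rng)
  if (is.null(spec)) spec <- sample_sphere_spec(rng, config)
  d <- spec$base_diameter
  stopifnot(d >= 8L)
  r <- d / 2
  cc <- (seq_len(d) - 0.5) - r
  mask <- outer(cc, cc, function(y, x) x^2 + y^2 < r^2)
  mask <- mask[nn_region_map(d, spec$l1, spec$l2),
               nn_region_map(d, spec$l3, spec$l4)]
  if (spec$axis_scale < 1) {
    s <- spec$axis_scale
    if (spec$axis == "vertical") {
      n2 <- max(1L, round(d * s))
      mask <- mask[interp_nn_index(n2, d), , drop = FALSE]
    } else {
      n2 <- max(1L, round(d * s))
      mask <- mask[, interp_nn_index(n2, d), drop = FALSE]
    }
  }
  col <- hsl_to_rgb(spec$hsl["H"], spec$hsl["S"], spec$hsl["L"])
  img <- array(0, c(nrow(mask), ncol(mask), 3L))
  for (ch in 1:3) img[, , ch] <- col[ch] * mask
  list(image = img, mask = mask, spec = spec)
}

interp_nn_index <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pmin(pmax(floor(src + 0.5), 0), n_in - 1) + 1L
}

# ---- virtual tape -------------------------------------------------------

sample_tape_spec <- function(rng, config, sphere_diameter) {
  rendered <- rng$runif(1) < config$tape_prob
  d <- sphere_diameter
  # all geometric quantities are drawn even when the tape is not
  # rendered, so the random-number stream is identical either way
  spec <- list(rendered = rendered,
               length = runif1(rng, config$tape_length) * d,
               width = runif1(rng, config$tape_width) * d,
               aspect_ratio = runif1(rng, config$tape_aspect),
               rotation = runif1(rng, config$rotation),
               center_offset = c(u = rng$runif(1, -1, 1),
                                 v = rng$runif(1, -1, 1)) *
                 config$tape_offset_max * d / sqrt(2),
               hsl = c(H = runif1(rng, config$tape_hsl$H),
                       S = runif1(rng, config$tape_hsl$S),
                       L = runif1(rng, config$tape_hsl$L)))
  spec
}

#' Sample a virtual tape image
#'
#' A rectangle of random length, width, rotation and position, rendered
#' with probability `config$tape_prob`, vertically compressed by the
#' sampled aspect ratio (simulating a tape surface seen off-axis) and
#' filled with a colour from the tape HSL ranges. The tape rectangle is
#' offset from the centre of its own image by the sampled position, so
#' anchoring the image centre at the composition point retains the
#' positional randomness.
#'
#' @inheritParams sample_sphere
#' @param sphere_diameter Diameter of the sphere the tape accompanies,
#'   px (sets the tape size scale).
#' @return `NULL` when the tape is not rendered, else a list with
#'   `image`, `mask`, `spec`.
#' @export
sample_tape <- function(rng = 1L, config = synthesis_config(),
                        sphere_diameter = NULL, spec = NULL) {
  rng <- as_rng(rng)
  if (is.null(sphere_diameter)) sphere_diameter <- config$sphere_base_diameter
  if (is.null(spec)) spec <- sample_tape_spec(rng, config, sphere_diameter)
  if (!spec$rendered) return(NULL)
  h0 <- max(2L, round(spec$width))
  w0 <- max(2L, round(spec$length))
  h1 <- max(1L, round(h0 * spec$aspect_ratio))
  mask <- matrix(TRUE, h1, w0)
  mask <- rotate_nn(list(m = mask * 1), spec$rotation)$m > 0.5
  # embed so the rectangle centre sits at center_offset from the image centre
  off <- round(spec$center_offset)
  pad_u <- abs(off["u"]); pad_v <- abs(off["v"])
  canvas <- matrix(FALSE, nrow(mask) + 2 * pad_v, ncol(mask) + 2 * pad_u)
  canvas[(1:nrow(mask)) + pad_v + off["v"],
         (1:ncol(mask)) + pad_u + off["u"]] <- mask
  col <- hsl_to_rgb(spec$hsl["H"], spec$hsl["S"], spec$hsl["L"])
  img <- array(0, c(nrow(canvas), ncol(canvas), 3L))
  for (ch in 1:3) img[, , ch] <- col[ch] * canvas
  list(image = img, mask = canvas, spec = spec)
}

# ---- composition --------------------------------------------------------

#' Anchor point of the virtual tape relative to the sphere
#'
#' The tape-image centre is anchored at the convex combination of the
#' sphere centroid and the sphere's bottom-edge point, weighted by the
#' tape aspect ratio: a tape seen face-on (`r_aspect` = 1) sits at the
#' sphere centroid, a fully foreshortened tape (`r_aspect` = 0) at the
#' bottom edge.
#'
#' @param v2 Sphere centroid, `c(u, v)` px.
#' @param v3 Sphere bottom-edge point, `c(u, v)` px.
#' @param r_aspect Tape aspect ratio in `[0, 1]`.
#' @return The anchor `v1 = v2 * r_aspect + v3 * (1 - r_aspect)`.
#' @export
tape_anchor <- function(v2, v3, r_aspect) {
  stopifnot(r_aspect >= 0, r_aspect <= 1)
  v2 * r_aspect + v3 * (1 - r_aspect)
}

mask_centroid <- function(mask) {
  idx <- which(mask)
  v <- (idx - 1) %% nrow(mask)
  u <- (idx - 1) %/% nrow(mask)
  c(u = mean(u), v = mean(v))
}

mask_bbox <- function(mask) {
  idx <- which(mask)
  v <- (idx - 1) %% nrow(mask)
  u <- (idx - 1) %/% nrow(mask)
  c(u0 = min(u), v0 = min(v), w = diff(range(u)) + 1, h = diff(range(v)) + 1)
}

#' Compose a virtual marker from a sphere and an optional tape
#'
#' The sphere (and tape) are resized (nearest-neighbour) so the sphere
#' diameter hits a target drawn from `config$final_diameter`, the tape
#' is drawn underneath with its image centre at the anchor from
#' [tape_anchor()], and the whole composite is rotated by a random
#' angle. The bounding box is the tight box of the sphere mask.
#'
#' @param sphere From [sample_sphere()].
#' @param tape From [sample_tape()], or `NULL`.
#' @inheritParams sample_sphere
#' @param final_diameter,rotation Optional overrides of the sampled
#'   values (useful for deterministic tests).
#' @return List with `image`, `mask` (all marker pixels), `sphere_mask`,
#'   `bbox` (`u0`, `v0`, `w`, `h`, 0-based, of the sphere), and `spec`
#'   (contains `v1`, `v2`, `v3`, `r_aspect`, the target and achieved
#'   sphere diameter, and the rotation).
#' @export
compose_marker <- function(sphere, tape = NULL, rng = 1L,
                           config = synthesis_config(),
                           final_diameter = NULL, rotation = NULL) {
  rng <- as_rng(rng)
  if (is.null(final_diameter))
    final_diameter <- round(runif1(rng, config$final_diameter))
  if (is.null(rotation)) rotation <- runif1(rng, config$rotation)
  d_cur <- max(dim(sphere$mask))
  k <- final_diameter / d_cur
  rs <- function(x, nr, nc, logical = FALSE) {
    out <- resize_image(x, nr, nc, "nearest")
    if (logical) out > 0.5 else out
  }
  sm_nr <- max(1L, round(nrow(sphere$mask) * k))
  sm_nc <- max(1L, round(ncol(sphere$mask) * k))
  s_mask <- rs(sphere$mask, sm_nr, sm_nc, logical = TRUE)
  s_img <- rs(sphere$image, sm_nr, sm_nc)
  achieved <- max(dim(s_mask))

  v2 <- mask_centroid(s_mask)
  bb <- mask_bbox(s_mask)
  v3 <- c(u = unname(v2["u"]), v = unname(bb["v0"] + bb["h"] - 1))
  r_aspect <- if (is.null(tape)) NA_real_ else tape$spec$aspect_ratio
  v1 <- if (is.null(tape)) NULL else tape_anchor(v2, v3, r_aspect)

  if (is.null(tape)) {
    img <- s_img; marker_mask <- s_mask; sphere_mask <- s_mask
  } else {
    t_nr <- max(1L, round(nrow(tape$mask) * k))
    t_nc <- max(1L, round(ncol(tape$mask) * k))
    t_mask <- rs(tape$mask, t_nr, t_nc, logical = TRUE)
    t_img <- rs(tape$image, t_nr, t_nc)
    t_u0 <- round(v1["u"] - (t_nc - 1) / 2)
    t_v0 <- round(v1["v"] - (t_nr - 1) / 2)
    u_lo <- min(0, t_u0); v_lo <- min(0, t_v0)
    u_hi <- max(sm_nc, t_u0 + t_nc); v_hi <- max(sm_nr, t_v0 + t_nr)
    cw <- u_hi - u_lo; ch_ <- v_hi - v_lo
    img <- array(0, c(ch_, cw, 3L))
    marker_mask <- matrix(FALSE, ch_, cw)
    sphere_mask <- matrix(FALSE, ch_, cw)
    # tape first (underneath), sphere painted over it
    tv <- (t_v0 - v_lo) + seq_len(t_nr); tu <- (t_u0 - u_lo) + seq_len(t_nc)
    for (c3 in 1:3) {
      plane <- img[, , c3]
      patch <- plane[tv, tu]
      patch[t_mask] <- t_img[, , c3][t_mask]
      plane[tv, tu] <- patch
      img[, , c3] <- plane
    }
    marker_mask[tv, tu] <- t_mask
    sv <- (0 - v_lo) + seq_len(sm_nr); su <- (0 - u_lo) + seq_len(sm_nc)
    for (c3 in 1:3) {
      plane <- img[, , c3]
      patch <- plane[sv, su]
      patch[s_mask] <- s_img[, , c3][s_mask]
      plane[sv, su] <- patch
      img[, , c3] <- plane
    }
    marker_mask[sv, su] <- marker_mask[sv, su] | s_mask
    sphere_mask[sv, su] <- s_mask
    # v1/v2/v3 in composite coordinates
    shift <- c(u = -u_lo, v = -v_lo)
    v1 <- v1 + shift; v2 <- v2 + shift; v3 <- v3 + shift
  }

  rot <- rotate_nn(list(img = img, mm = marker_mask * 1, sm = sphere_mask * 1),
                   rotation)
  marker_mask <- rot$mm > 0.5
  sphere_mask <- rot$sm > 0.5
  img <- rot$img
  bbox <- mask_bbox(sphere_mask)
  list(image = img, mask = marker_mask, sphere_mask = sphere_mask,
       bbox = bbox,
       spec = list(v1 = v1, v2 = v2, v3 = v3, r_aspect = r_aspect,
                   final_diameter = final_diameter,
                   achieved_diameter = achieved,
                   rotation = rotation,
                   sphere = sphere$spec,
                   tape = if (is.null(tape)) NULL else tape$spec))
}

nrow2 <- function(x) dim(x)[1]
ncol2 <- function(x) dim(x)[2]

# ---- training images ----------------------------------------------------

#' Build one annotated training image
#'
#' A random square crop of the background frame is upscaled (bicubic) to
#' the training resolution, 7-12 composed markers are inserted at random
#' non-overlapping positions, and each marker's boundary is smoothed
#' with a Gaussian blur of random SD; background pixels outside the
#' (dilated) marker masks are kept bit-identical to the upscaled crop.
#' Annotations are the tight sphere bounding boxes, normalized to
#' `[0, 1]`.
#'
#' @param background `h x w x 3` array, at least `crop_size` in both
#'   dimensions.
#' @param seed Integer seed; one generator drives the whole image, so
#'   every sample is reproducible from `(background, seed)` alone.
#' @param config A [synthesis_config()].
#' @param frame_id Identifier recorded in the provenance.
#' @return Object of class `training_sample`: `image` (out_size square,
#'   RGB), `annotations` (data frame `class`, `cx`, `cy`, `w`, `h` in
#'   `[0, 1]`), `modified_mask` (logical; `TRUE` where the image differs
#'   from the plain upscaled crop), `markers` (per-marker records with
#'   `bbox`, `sigma`, `offset`, `spec`, `sphere_mask`), `provenance`.
#' @export
make_training_image <- function(background, seed,
                                config = synthesis_config(),
                                frame_id = "frame") {
  stopifnot(length(dim(background)) == 3L)
  H <- dim(background)[1]; W <- dim(background)[2]
  cs <- config$crop_size; os <- config$out_size
  if (H < cs || W < cs)
    stop("background smaller than ", cs, "x", cs)
  rng <- as_rng(seed)
  v0 <- rng$sample_int(H - cs + 1L, 1L) - 1L
  u0 <- rng$sample_int(W - cs + 1L, 1L) - 1L
  crop <- background[v0 + seq_len(cs), u0 + seq_len(cs), , drop = FALSE]
  up <- resize_image(crop, os, os, "bicubic")
  img <- up
  modified <- matrix(FALSE, os, os)
  n <- rng$sample_int(config$n_markers[2] - config$n_markers[1] + 1L, 1L) +
    config$n_markers[1] - 1L
  ann <- vector("list", n)
  markers <- vector("list", n)
  for (i in seq_len(n)) {
    sph <- sample_sphere(rng, config)
    tp <- sample_tape(rng, config, sphere_diameter = max(dim(sph$mask)))
    mk <- compose_marker(sph, tp, rng, config)
    sigma <- runif1(rng, config$blur_sigma)
    dil_r <- ceiling(config$blur_dilate * sigma)
    pad <- dil_r + max(1L, ceiling(3 * sigma))
    mh <- nrow(mk$mask); mw <- ncol(mk$mask)
    if (mh + 2 * pad >= os || mw + 2 * pad >= os)
      stop("marker larger than the training image")
    dfull <- matrix(FALSE, mh + 2 * dil_r, mw + 2 * dil_r)
    dfull[dil_r + seq_len(mh), dil_r + seq_len(mw)] <- mk$mask
    dfull <- dilate_mask(dfull, dil_r)
    placed <- FALSE
    for (try in 1:200) {
      pv <- rng$sample_int(os - mh - 2 * pad + 1L, 1L) - 1L + pad
      pu <- rng$sample_int(os - mw - 2 * pad + 1L, 1L) - 1L + pad
      rv <- pv + seq_len(mh); ru <- pu + seq_len(mw)
      # the blur may modify the mask dilated by the blur band; reject
      # positions whose dilated mask touches previously modified pixels
      rv2 <- (pv - dil_r) + seq_len(mh + 2 * dil_r)
      ru2 <- (pu - dil_r) + seq_len(mw + 2 * dil_r)
      if (any(modified[rv2, ru2] & dfull)) next
      # paint the marker
      for (c3 in 1:3) {
        plane <- img[rv, ru, c3]
        plane[mk$mask] <- mk$image[, , c3][mk$mask]
        img[rv, ru, c3] <- plane
      }
      # blur the patch, restore background outside the dilated mask
      bv <- (pv - pad) + seq_len(mh + 2 * pad)
      bu <- (pu - pad) + seq_len(mw + 2 * pad)
      patch <- img[bv, bu, , drop = FALSE]
      blurred <- gaussian_blur(patch, sigma)
      dpad <- matrix(FALSE, length(bv), length(bu))
      dpad[pad + seq_len(mh), pad + seq_len(mw)] <- mk$mask
      dpad <- dilate_mask(dpad, dil_r)
      for (c3 in 1:3) {
        plane <- patch[, , c3]
        plane[dpad] <- blurred[, , c3][dpad]
        img[bv, bu, c3] <- plane
      }
      modified[bv, bu] <- modified[bv, bu] | dpad
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place marker ", i, " without overlap")
    bb <- mk$bbox
    ann[[i]] <- data.frame(class = config$class_id,
                           cx = (pu + bb["u0"] + bb["w"] / 2) / os,
                           cy = (pv + bb["v0"] + bb["h"] / 2) / os,
                           w = bb["w"] / os, h = bb["h"] / os)
    markers[[i]] <- list(bbox = c(u0 = unname(pu + bb["u0"]),
                                  v0 = unname(pv + bb["v0"]),
                                  w = unname(bb["w"]), h = unname(bb["h"])),
                         offset = c(u = pu, v = pv), sigma = sigma,
                         sphere_mask = mk$sphere_mask, spec = mk$spec)
  }
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL
  structure(list(image = img, annotations = ann, modified_mask = modified,
                 markers = markers,
                 provenance = list(frame_id = frame_id,
                                   crop_origin = c(u = u0, v = v0),
                                   seed = seed)),
            class = "training_sample")
}

#' Write a training dataset to disk
#'
#' Writes `images/*.png` and `labels/*.txt` in the normalized
#' one-object-per-line label format (`class cx cy w h`, floats in
#' `[0, 1]`), a `train.txt` list file, a YAML dump of the sampling
#' configuration, and a JSON manifest recording the seed.
#'
#' @param backgrounds A background array or list of background arrays,
#'   cycled over.
#' @param n_images Number of training images.
#' @param seed Master seed; image `i` uses a seed derived from
#'   `(seed, i)`.
#' @param outdir Output directory (created if needed).
#' @param config A [synthesis_config()].
#' @return Invisibly, the manifest list.
#' @export
build_dataset <- function(backgrounds, n_images, seed, outdir,
                          config = synthesis_config()) {
  if (!is.list(backgrounds)) backgrounds <- list(backgrounds)
  stopifnot(length(backgrounds) >= 1L, n_images >= 1L)
  dir.create(file.path(outdir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "labels"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  img_paths <- character(n_images)
  for (i in seq_len(n_images)) {
    si <- derive_seed(seed, i)
    bg <- backgrounds[[(i - 1L) %% length(backgrounds) + 1L]]
    ts <- make_training_image(bg, si, config,
                              frame_id = sprintf("bg%03d", (i - 1L) %% length(backgrounds) + 1L))
    stem <- sprintf("img%05d", i)
    img_paths[i] <- file.path(outdir, "images", paste0(stem, ".png"))
    png::writePNG(ts$image, img_paths[i])
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f",
                       ts$annotations$class, ts$annotations$cx,
                       ts$annotations$cy, ts$annotations$w,
                       ts$annotations$h),
               file.path(outdir, "labels", paste0(stem, ".txt")))
  }
  writeLines(img_paths, file.path(outdir, "train.txt"))
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  manifest <- list(n_images = n_images, seed = seed,
                   backgrounds = length(backgrounds),
                   config_file = "config.yaml")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a smooth synthetic background frame
#'
#' Low-frequency random texture (bicubically upscaled coarse noise)
#' standing in for a non-marker trial video frame in tests and examples.
#'
#' @param h,w Output size, px.
#' @param seed Integer seed.
#' @param levels Number of octaves of noise.
#' @return `h x w x 3` array in `[0, 1]`.
#' @export
synthetic_background <- function(h = 480L, w = 640L, seed = 1L, levels = 3L) {
  rng <- as_rng(seed)
  img <- array(0, c(h, w, 3L))
  amp <- 0.5
  for (lv in seq_len(levels)) {
    k <- 4L * 2^(lv - 1L)
    coarse <- array(rng$runif(k * k * 3L), c(k, k, 3L))
    img <- img + amp * resize_image(coarse, h, w, "bicubic", clamp = FALSE)
    amp <- amp / 2
  }
  img <- img / (1 - 0.5^levels) * 0.7 + 0.1
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}
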