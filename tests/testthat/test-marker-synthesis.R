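cfg <- synthesis_config()

test_that("identity deformation leaves a plain disc", {
  rng <- rgbmocap:::local_rng(1)
  spec <- rgbmocap:::sample_sphere_spec(rng, cfg)
  spec$l1 <- 1 / 3; spec$l2 <- 2 / 3
  spec$l3 <- 1 / 3; spec$l4 <- 2 / 3
  spec$axis_scale <- 1
  sph <- sample_sphere(rng, cfg, spec = spec)
  d <- cfg$sphere_base_diameter
  expect_equal(dim(sph$mask), c(d, d))
  area <- sum(sph$mask)
  expect_lt(abs(area - pi * (d / 2)^2) / (pi * (d / 2)^2), 0.02)
})

test_that("sampled sphere parameters stay inside the configured ranges", {
  rng <- rgbmocap:::local_rng(2)
  sp <- replicate(10000, rgbmocap:::sample_sphere_spec(rng, cfg),
                  simplify = FALSE)
  hsl <- t(vapply(sp, `[[`, numeric(3), "hsl"))
  expect_true(all(hsl[, "H"] >= 140 & hsl[, "H"] <= 160))
  expect_true(all(hsl[, "S"] >= 240 & hsl[, "S"] <= 255))
  expect_true(all(hsl[, "L"] >= 140 & hsl[, "L"] <= 170))
  ax <- vapply(sp, `[[`, numeric(1), "axis_scale")
  expect_true(all(ax >= 0.8 & ax <= 1))
  expect_true(all(vapply(sp, function(s) s$l1 < s$l2 && s$l3 < s$l4,
                         logical(1))))
})

test_that("sphere masks are single connected components with bounded area", {
  rng <- rgbmocap:::local_rng(3)
  d <- cfg$sphere_base_diameter
  # areas at the two extreme line placements bracket every sample
  extreme <- function(lo, hi) {
    sp <- rgbmocap:::sample_sphere_spec(rng, cfg)
    sp$l1 <- lo; sp$l3 <- lo; sp$l2 <- hi; sp$l4 <- hi; sp$axis_scale <- 1
    sum(sample_sphere(rng, cfg, spec = sp)$mask)
  }
  areas <- c(extreme(0.25, 0.75), extreme(0.42, 0.58),
             extreme(0.25, 0.58), extreme(0.42, 0.75))
  for (i in 1:40) {
    sp <- rgbmocap:::sample_sphere_spec(rng, cfg)
    sp$axis_scale <- 1
    m <- sample_sphere(rng, cfg, spec = sp)$mask
    expect_gte(sum(m), min(areas) - 8)
    expect_lte(sum(m), max(areas) + 8)
    lab <- EBImage::bwlabel(m * 1)
    expect_equal(max(lab), 1)
  }
})

test_that("tape rendering frequency is binomial at one half", {
  rng <- rgbmocap:::local_rng(4)
  n <- 10000
  sp <- replicate(n, rgbmocap:::sample_tape_spec(rng, cfg, 48),
                  simplify = FALSE)
  asp <- vapply(sp, `[[`, numeric(1), "aspect_ratio")
  expect_true(all(asp >= 0.10 & asp <= 1.00))
  hsl <- t(vapply(sp, `[[`, numeric(3), "hsl"))
  expect_true(all(hsl[, "H"] >= 0 & hsl[, "H"] <= 30))
  expect_true(all(hsl[, "S"] >= 0 & hsl[, "S"] <= 20))
  expect_true(all(hsl[, "L"] >= 200 & hsl[, "L"] <= 255))
  rendered <- vapply(sp, `[[`, logical(1), "rendered")
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(rendered), ci[1])
  expect_lte(sum(rendered), ci[2])
})

test_that("tape aspect ratio one keeps the nominal height", {
  rng <- rgbmocap:::local_rng(5)
  sp <- rgbmocap:::sample_tape_spec(rng, cfg, 48)
  sp$rendered <- TRUE; sp$aspect_ratio <- 1; sp$rotation <- 0
  sp$center_offset <- c(u = 0, v = 0)
  tp <- sample_tape(rng, cfg, 48, spec = sp)
  expect_equal(nrow(tp$mask), max(2L, round(sp$width)))
  sp$aspect_ratio <- 0.5
  tp2 <- sample_tape(rng, cfg, 48, spec = sp)
  expect_equal(nrow(tp2$mask), max(1L, round(max(2L, round(sp$width)) * 0.5)))
})

test_that("tape anchor interpolates between centroid and bottom edge", {
  v2 <- c(10, 10); v3 <- c(10, 20)
  expect_identical(tape_anchor(v2, v3, 1), v2)
  expect_identical(tape_anchor(v2, v3, 0), v3)
  expect_identical(tape_anchor(v2, v3, 0.5), c(10, 15))
})

test_that("composed markers satisfy the anchor identity and diameter range", {
  rng <- rgbmocap:::local_rng(6)
  for (i in 1:150) {
    sph <- sample_sphere(rng, cfg)
    tp <- sample_tape(rng, cfg, sphere_diameter = max(dim(sph$mask)))
    mk <- compose_marker(sph, tp, rng, cfg)
    expect_gte(mk$spec$achieved_diameter, 8)
    expect_lte(mk$spec$achieved_diameter, 24)
    if (!is.null(tp)) {
      v1 <- tape_anchor(mk$spec$v2, mk$spec$v3, mk$spec$r_aspect)
      expect_equal(unname(mk$spec$v1), unname(v1), tolerance = 1e-12)
    }
  }
})

test_that("annotation bboxes tightly bound the sphere and a disc covers most of it", {
  rng <- rgbmocap:::local_rng(7)
  cov <- numeric(200)
  for (i in 1:200) {
    sph <- sample_sphere(rng, cfg)
    tp <- sample_tape(rng, cfg, sphere_diameter = max(dim(sph$mask)))
    mk <- compose_marker(sph, tp, rng, cfg)
    bb <- mk$bbox; sm <- mk$sphere_mask
    idx <- which(sm)
    v <- (idx - 1) %% nrow(sm); u <- (idx - 1) %/% nrow(sm)
    expect_identical(unname(bb),
                     c(min(u), min(v), diff(range(u)) + 1, diff(range(v)) + 1))
    cx <- bb["u0"] + (bb["w"] - 1) / 2; cy <- bb["v0"] + (bb["h"] - 1) / 2
    r <- max(bb["w"], bb["h"]) / 2
    cov[i] <- mean((u - cx)^2 + (v - cy)^2 <= r^2)
    expect_gte(cov[i], 0.8)
  }
  expect_gte(mean(cov), 0.95)
})

test_that("training images honor the composition contract", {
  bg <- synthetic_background(480, 640, seed = 3)
  for (seed in c(11, 12, 13)) {
    ts <- make_training_image(bg, seed, cfg)
    expect_identical(dim(ts$image), c(640L, 640L, 3L))
    n <- nrow(ts$annotations)
    expect_gte(n, 7); expect_lte(n, 12)
    expect_true(all(ts$annotations$cx >= 0 & ts$annotations$cx <= 1))
    expect_true(all(ts$annotations$w > 0 & ts$annotations$w <= 1))
    # background retained bit-exactly outside modified regions
    co <- ts$provenance$crop_origin
    crop <- bg[co["v"] + 1:320, co["u"] + 1:320, , drop = FALSE]
    up <- rgbmocap:::resize_image(crop, 640, 640, "bicubic")
    out <- !ts$modified_mask
    for (ch in 1:3)
      expect_identical(ts$image[, , ch][out], up[, , ch][out])
  }
})

test_that("training image generation is deterministic in the seed", {
  bg <- synthetic_background(480, 640, seed = 4)
  a <- make_training_image(bg, 99, cfg)
  b <- make_training_image(bg, 99, cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  c_ <- make_training_image(bg, 100, cfg)
  expect_false(identical(a$image, c_$image))
})

test_that("small backgrounds are rejected", {
  bg <- synthetic_background(200, 200, seed = 1)
  expect_error(make_training_image(bg, 1, cfg), "smaller than")
})

test_that("build_dataset writes a complete, parseable dataset", {
  bg <- synthetic_background(400, 400, seed = 5)
  outdir <- file.path(tempdir(), "ds-test")
  unlink(outdir, recursive = TRUE)
  build_dataset(bg, n_images = 6, seed = 21, outdir = outdir, config = cfg)
  imgs <- list.files(file.path(outdir, "images"), full.names = TRUE)
  labs <- list.files(file.path(outdir, "labels"), full.names = TRUE)
  expect_length(imgs, 6)
  expect_length(labs, 6)
  for (lf in labs) {
    for (line in readLines(lf)) {
      fields <- as.numeric(strsplit(line, " ")[[1]])
      expect_length(fields, 5)
      expect_equal(fields[1], cfg$class_id)
      expect_true(all(fields[2:5] >= 0 & fields[2:5] <= 1))
    }
  }
  expect_true(file.exists(file.path(outdir, "train.txt")))
  expect_true(file.exists(file.path(outdir, "config.yaml")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  # different per-image seeds: no two images identical
  sizes <- lapply(imgs, function(f) unname(tools::md5sum(f)))
  expect_equal(length(unique(unlist(sizes))), 6)
})
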