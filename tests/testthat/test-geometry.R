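test_that("canonical camera projects and back-projects as expected", {
  cm <- camera_model("c", cbind(diag(3), 0), 1920L, 1080L)
  p <- project_points(cm, c(0, 0, 1000))
  expect_equal(c(p$u, p$v), c(0, 0))
  expect_false(p$behind)

  # homogeneous invariance: scaling P changes nothing
  cm7 <- camera_model("c7", 7 * cbind(diag(3), 0), 1920L, 1080L)
  p7 <- project_points(cm7, c(123.4, -55.2, 812))
  p1 <- project_points(cm, c(123.4, -55.2, 812))
  expect_equal(c(p7$u, p7$v), c(p1$u, p1$v))

  r <- pixel_to_ray(cm, 0, 0)
  expect_equal(r$origin, c(0, 0, 0))
  expect_equal(r$direction, c(0, 0, 1))

  # camera centre is the ray origin for any pixel
  r2 <- pixel_to_ray(cm, 300, -40)
  expect_equal(r2$origin, cm$center)

  # behind-camera flag
  expect_true(project_points(cm, c(0, 0, -100))$behind)
})

test_that("invalid cameras are rejected", {
  P <- cbind(diag(3), 0)
  P[3, ] <- P[1, ]  # singular left block
  expect_error(camera_model("bad", P, 10, 10), "singular")
})

test_that("project/pixel_to_ray roundtrip holds for random cameras", {
  rng <- rgbmocap:::local_rng(4)
  for (i in 1:25) {
    cm <- random_camera(rng, id = i)
    X <- rng$rnorm(3, 0, 500)
    pr <- project_points(cm, X)
    if (pr$behind) next
    ray <- pixel_to_ray(cm, pr$u, pr$v)
    expect_lt(as.numeric(point_ray_distance(X, ray)), 1e-9)
    # points along the ray reproduce the pixel
    for (t in c(0.5, 1, 3) * pr$depth) {
      pt <- ray$origin + t * ray$direction
      pr2 <- project_points(cm, pt)
      expect_equal(c(pr2$u, pr2$v), c(pr$u, pr$v), tolerance = 1e-9)
    }
  }
})

test_that("point_ray_distance matches the cross-product closed form", {
  rng <- rgbmocap:::local_rng(5)
  ray <- structure(list(origin = c(1, 2, 3),
                        direction = c(0, 0, 1)), class = "ray")
  expect_equal(as.numeric(point_ray_distance(c(1, 2, 50), ray)), 0)
  expect_equal(as.numeric(point_ray_distance(c(2, 2, 10), ray)), 1)
  for (i in 1:50) {
    o <- rng$rnorm(3); d <- rng$rnorm(3); d <- d / sqrt(sum(d^2))
    p <- rng$rnorm(3, 0, 10)
    r <- structure(list(origin = o, direction = d), class = "ray")
    t <- sum((p - o) * d)
    if (t < 0) {
      expect_equal(as.numeric(point_ray_distance(p, r)),
                   sqrt(sum((p - o)^2)))
      expect_true(attr(point_ray_distance(p, r), "behind"))
    } else {
      cr <- c((p - o)[2] * d[3] - (p - o)[3] * d[2],
              (p - o)[3] * d[1] - (p - o)[1] * d[3],
              (p - o)[1] * d[2] - (p - o)[2] * d[1])
      expect_equal(as.numeric(point_ray_distance(p, r)), sqrt(sum(cr^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("triangulation recovers noiseless points exactly", {
  cams <- ring_cameras(3)
  X <- c(200, -300, 1200)
  obs <- lapply(cams, function(cm) {
    p <- project_points(cm, X)
    list(camera = cm, u = p$u, v = p$v)
  })
  tr <- triangulate(obs)
  expect_lt(sqrt(sum((tr$point - X)^2)), 1e-6)
  expect_true(all(tr$distances < 1e-6))
})

test_that("two skew rays triangulate to the midpoint of the common perpendicular", {
  # rays along x at z=0 and along y at z=10: closest points (0,0,0), (0,0,10)
  A <- matrix(0, 3, 3); b <- numeric(3)
  rays <- list(list(o = c(-5, 0, 0), d = c(1, 0, 0)),
               list(o = c(0, -5, 10), d = c(0, 1, 0)))
  for (r in rays) {
    Q <- diag(3) - tcrossprod(r$d)
    A <- A + Q; b <- b + drop(Q %*% r$o)
  }
  expect_equal(drop(solve(A, b)), c(0, 0, 5), tolerance = 1e-12)
})

test_that("triangulation requires two non-degenerate observations", {
  cams <- ring_cameras(2)
  p <- project_points(cams[[1]], c(0, 0, 1000))
  expect_error(triangulate(list(list(camera = cams[[1]], u = p$u, v = p$v))),
               "at least 2")
  # same camera twice: parallel identical rays
  expect_error(
    triangulate(list(list(camera = cams[[1]], u = p$u, v = p$v),
                     list(camera = cams[[1]], u = p$u, v = p$v))),
    "degenerate")
})

test_that("triangulate matches a dense numerical minimizer of the ray objective", {
  rng <- rgbmocap:::local_rng(6)
  for (i in 1:20) {
    n <- 2 + (i %% 7)
    cams <- ring_cameras(n, seed = 100 + i)
    X <- c(rng$runif(1, -800, 800), rng$runif(1, -800, 800),
           rng$runif(1, 200, 1800))
    obs <- lapply(cams, function(cm) {
      p <- project_points(cm, X)
      list(camera = cm, u = p$u + rng$rnorm(1, 0, 2),
           v = p$v + rng$rnorm(1, 0, 2))
    })
    tr <- triangulate(obs)
    rays <- lapply(obs, function(ob) pixel_to_ray(ob$camera, ob$u, ob$v))
    opt <- dense_ray_minimizer(rays, X)
    expect_lt(sqrt(sum((tr$point - opt)^2)), 1e-6)
  }
})

test_that("geometry is invariant under rigid motion of cameras and points", {
  rng <- rgbmocap:::local_rng(8)
  cams <- ring_cameras(4, seed = 12)
  X <- c(100, 50, 900)
  obs <- lapply(cams, function(cm) {
    p <- project_points(cm, X)
    list(camera = cm, u = p$u + 1, v = p$v - 0.5)
  })
  tr <- triangulate(obs)
  # random rigid transform
  ax <- rng$rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- 1.1
  Kx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  t_ <- c(500, -200, 300)
  Tinv <- rbind(cbind(t(R), -t(R) %*% t_), c(0, 0, 0, 1))
  cams2 <- lapply(cams, function(cm)
    camera_model(cm$id, cm$P %*% Tinv, cm$image_width, cm$image_height))
  obs2 <- lapply(seq_along(cams2), function(i)
    list(camera = cams2[[i]], u = obs[[i]]$u, v = obs[[i]]$v))
  tr2 <- triangulate(obs2)
  expect_equal(unname(tr2$distances), unname(tr$distances), tolerance = 1e-9)
  expect_equal(drop(R %*% tr$point + t_), tr2$point, tolerance = 1e-6)
})

test_that("DLT calibration recovers a camera from noiseless correspondences", {
  rng <- rgbmocap:::local_rng(9)
  cm <- random_camera(rng, "t")
  X <- cbind(rng$runif(20, -500, 500), rng$runif(20, -500, 500),
             rng$runif(20, 500, 1500))
  # keep points in front
  X <- X[!project_points(cm, X)$behind, , drop = FALSE]
  px <- project_points(cm, X)
  est <- dlt_calibrate(X, px, id = "est")
  # recovered up to scale: compare reprojection
  px2 <- project_points(est, X)
  expect_equal(px2$u, px$u, tolerance = 1e-6)
  expect_equal(px2$v, px$v, tolerance = 1e-6)
})

test_that("DLT calibration degrades gracefully with noise and rejects bad input", {
  rng <- rgbmocap:::local_rng(10)
  cm <- random_camera(rng, "t")
  X <- cbind(rng$runif(60, -500, 500), rng$runif(60, -500, 500),
             rng$runif(60, 500, 1500))
  X <- X[!project_points(cm, X)$behind, , drop = FALSE]
  px <- project_points(cm, X)
  pxn <- data.frame(u = px$u + rng$rnorm(nrow(X), 0, 0.5),
                    v = px$v + rng$rnorm(nrow(X), 0, 0.5))
  est <- dlt_calibrate(X, pxn, id = "n")
  rep_ <- project_points(est, X)
  rms <- sqrt(mean((rep_$u - pxn$u)^2 + (rep_$v - pxn$v)^2))
  expect_lt(rms, 1.5 * 0.5)

  expect_error(dlt_calibrate(X[1:5, ], pxn[1:5, ]), "at least 6")
  Xp <- X; Xp[, 3] <- 1000  # coplanar
  expect_error(dlt_calibrate(Xp, pxn), "coplanar")
})

test_that("camera JSON files round-trip bit-exactly", {
  cams <- ring_cameras(3, seed = 77)
  names(cams) <- vapply(cams, `[[`, character(1), "id")
  path <- tempfile(fileext = ".json")
  write_cameras(cams, path)
  back <- read_cameras(path)
  expect_identical(names(back), names(cams))
  for (id in names(cams)) {
    expect_identical(back[[id]]$P, cams[[id]]$P)
    expect_identical(back[[id]]$image_width, cams[[id]]$image_width)
  }
})
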