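# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- get0(key, envir = .fixture_cache)
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixture_cache)
  val
}

# small scene: 8 cameras, 25 markers, short trial
small_scene <- function() {
  cached("small_scene", make_scene(duration_s = 0.1, wand_frames = 60, seed = 2))
}

# wand observation table from a scene's ground truth, optional pixel noise
wand_observations <- function(scene, noise_sigma_px = 0, seed = 7) {
  wt <- scene$wand_track
  n <- nrow(wt$a)
  rng <- rgbmocap:::local_rng(seed)
  do.call(rbind, lapply(names(scene$cameras), function(cid) {
    cam <- scene$cameras[[cid]]
    pa <- project_points(cam, wt$a)
    pb <- project_points(cam, wt$b)
    df <- rbind(
      data.frame(frame = seq_len(n), camera = cid, marker = "a",
                 u = pa$u, v = pa$v, stringsAsFactors = FALSE),
      data.frame(frame = seq_len(n), camera = cid, marker = "b",
                 u = pb$u, v = pb$v, stringsAsFactors = FALSE))
    if (noise_sigma_px > 0) {
      df$u <- df$u + rng$rnorm(nrow(df), 0, noise_sigma_px)
      df$v <- df$v + rng$rnorm(nrow(df), 0, noise_sigma_px)
    }
    df
  }))
}

# Dense numerical minimizer of the sum of squared point-to-ray
# distances: BFGS from the starting point, then Newton polish with a
# finite-difference Hessian. Independent oracle for triangulate().
dense_ray_minimizer <- function(rays, init) {
  objective <- function(p) sum(vapply(rays, function(r) {
    w <- p - r$origin
    sum(w^2) - sum(w * r$direction)^2
  }, numeric(1)))
  gradient <- function(p) Reduce(`+`, lapply(rays, function(r) {
    w <- p - r$origin
    2 * (w - sum(w * r$direction) * r$direction)
  }))
  p <- optim(init, objective, gradient, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 1000))$par
  for (it in 1:5) {
    g <- gradient(p)
    H <- matrix(0, 3, 3)
    h <- 1e-4
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- h
      H[, k] <- (gradient(p + e) - gradient(p - e)) / (2 * h)
    }
    step <- solve(H, g)
    p <- p - step
    if (sqrt(sum(step^2)) < 1e-10) break
  }
  p
}

# random valid camera: K R [I | -C] with sane intrinsics
random_camera <- function(rng, id = "r") {
  f <- rng$runif(1, 600, 2000)
  K <- rbind(c(f, 0, rng$runif(1, 800, 1100)),
             c(0, f, rng$runif(1, 450, 620)),
             c(0, 0, 1))
  ax <- rng$rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- rng$runif(1, 0, 2 * pi)
  Kx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  C <- rng$rnorm(3, 0, 3000)
  camera_model(id, K %*% cbind(R, -R %*% C), 1920L, 1080L)
}

# cameras surrounding the origin that all see points near the origin
ring_cameras <- function(n, radius = 4000, seed = 3) {
  rng <- rgbmocap:::local_rng(seed)
  lapply(seq_len(n), function(i) {
    az <- 2 * pi * (i - 1) / n + rng$runif(1, -0.1, 0.1)
    C <- c(radius * cos(az), radius * sin(az), rng$runif(1, 500, 2500))
    fwd <- -C / sqrt(sum(C^2))
    right <- c(fwd[2], -fwd[1], 0); right <- right / sqrt(sum(right^2))
    down <- c(fwd[2] * right[3] - fwd[3] * right[2],
              fwd[3] * right[1] - fwd[1] * right[3],
              fwd[1] * right[2] - fwd[2] * right[1])
    R <- rbind(right, down, fwd)
    f <- rng$runif(1, 900, 1400)
    K <- rbind(c(f, 0, 959.5), c(0, f, 539.5), c(0, 0, 1))
    camera_model(sprintf("r%02d", i), K %*% cbind(R, -R %*% C), 1920L, 1080L)
  })
}
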