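# Projective camera geometry: the DLT-style 3x4 camera model, projection,
# back-projection to rays, multi-ray triangulation and the ray-distance
# error metric used to gate reconstructions.

#' Construct a projective camera model
#'
#' A camera is represented by a single 3x4 projection matrix `P` mapping
#' homogeneous lab coordinates (millimetres) to homogeneous pixel
#' coordinates, the 11-parameter form used by the Direct Linear
#' Transformation (DLT) method.  No lens distortion is modelled.
#'
#' On construction `P` is brought to a canonical scaling: the left 3x3
#' block has positive determinant and its third row has unit norm, so the
#' homogeneous scale `w` of a projected point equals its depth along the
#' optical axis in millimetres.  Projection is invariant to this rescaling.
#'
#' @param id Camera identifier (coerced to character).
#' @param P 3x4 numeric projection matrix, or a length-12 vector in
#'   row-major order.
#' @param image_width,image_height Sensor size in pixels.
#' @param canonicalize If `FALSE`, `P` is stored as given (used when
#'   reading back a camera file so the round trip is bit-exact).
#' @return An object of class `camera_model` with fields `id`, `P`,
#'   `center` (3-vector, mm), `image_width`, `image_height`.
#' @export
camera_model <- function(id, P, image_width, image_height, canonicalize = TRUE) {
  if (is.vector(P)) {
    stopifnot(length(P) == 12L)
    P <- matrix(as.numeric(P), nrow = 3L, byrow = TRUE)
  }
  P <- unname(as.matrix(P))
  stopifnot(nrow(P) == 3L, ncol(P) == 4L, all(is.finite(P)))
  M <- P[, 1:3]
  dM <- det(M)
  if (abs(dM) < 1e-14 * max(abs(M))^3)
    stop("invalid camera: left 3x3 block of P is singular")
  if (canonicalize) {
    s <- sqrt(sum(P[3, 1:3]^2))
    P <- P / s
    if (det(P[, 1:3]) < 0) P <- -P
  }
  center <- drop(solve(P[, 1:3], -P[, 4]))
  structure(
    list(id = as.character(id), P = P, center = center,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height)),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model '%s'  %dx%d px  center (%.1f, %.1f, %.1f) mm>\n",
              x$id, x$image_width, x$image_height,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Project 3D points to pixel coordinates
#'
#' Pixels are 0-based with origin at the top-left corner, `u` rightward
#' and `v` downward.  Points with projective depth `<= 0` (behind the
#' camera) are flagged, not dropped.
#'
#' @param camera A [camera_model()].
#' @param points Numeric n x 3 matrix (or length-3 vector) of lab
#'   coordinates in mm.
#' @return Data frame with columns `u`, `v`, `depth` (mm along the optical
#'   axis) and logical `behind`.
#' @export
project_points <- function(camera, points) {
  if (is.vector(points)) points <- matrix(points, nrow = 1L)
  stopifnot(ncol(points) == 3L)
  X <- cbind(points, 1)
  x <- X %*% t(camera$P)
  w <- x[, 3]
  data.frame(u = x[, 1] / w, v = x[, 2] / w, depth = w, behind = w <= 0)
}

#' Back-project a pixel to its camera ray
#'
#' Returns the half-line of 3D points that project to the given pixel
#' with positive depth: origin at the camera centre (the null space of
#' `P`), unit direction pointing in front of the camera.
#'
#' @param camera A [camera_model()].
#' @param u,v Pixel coordinates (`v` may be omitted if `u` is a
#'   length-2 vector).
#' @return List of class `ray` with fields `origin` and `direction`
#'   (unit 3-vector).
#' @export
pixel_to_ray <- function(camera, u, v = NULL) {
  if (is.null(v)) { v <- u[2]; u <- u[1] }
  M <- camera$P[, 1:3]
  d <- drop(solve(M, c(u, v, 1)))
  # canonical P has det(M) > 0 and unit third row, so this direction has
  # positive depth; for a non-canonical P fix the sign explicitly
  if (det(M) < 0) d <- -d
  d <- d / sqrt(sum(d^2))
  structure(list(origin = camera$center, direction = d), class = "ray")
}

#' Shortest distance from a point to a camera ray
#'
#' The perpendicular distance from the point to the ray's supporting
#' line.  When the foot of the perpendicular falls behind the ray origin
#' (half-line semantics), the distance to the origin is returned and the
#' `behind` attribute is set.
#'
#' @param point Length-3 numeric, mm.
#' @param ray A ray from [pixel_to_ray()].
#' @return Distance in mm with logical attribute `behind`.
#' @export
point_ray_distance <- function(point, ray) {
  p <- point - ray$origin
  t <- sum(p * ray$direction)
  if (t < 0) {
    structure(sqrt(sum(p^2)), behind = TRUE)
  } else {
    cr <- c(p[2] * ray$direction[3] - p[3] * ray$direction[2],
            p[3] * ray$direction[1] - p[1] * ray$direction[3],
            p[1] * ray$direction[2] - p[2] * ray$direction[1])
    structure(sqrt(sum(cr^2)), behind = FALSE)
  }
}

#' Triangulate a 3D point from multi-camera pixel observations
#'
#' Finds the point minimizing the sum of squared perpendicular distances
#' to the observation rays (the midpoint method, a closed-form linear
#' solve).  The mean of the per-camera ray distances is the
#' reconstruction error reported throughout the package.
#'
#' @param observations List of `list(camera = <camera_model>, u =, v =)`
#'   entries, at least two, from distinct camera centres.
#' @return List with `point` (3-vector mm), `distances` (per-camera ray
#'   distance, mm, named by camera id) and `mean_ray_distance`.
#' @export
triangulate <- function(observations) {
  n <- length(observations)
  if (n < 2L) stop("triangulation requires at least 2 observations")
  A <- matrix(0, 3, 3); b <- numeric(3)
  rays <- vector("list", n)
  for (i in seq_len(n)) {
    ob <- observations[[i]]
    r <- pixel_to_ray(ob$camera, ob$u, ob$v)
    rays[[i]] <- r
    Q <- diag(3) - tcrossprod(r$direction)
    A <- A + Q
    b <- b + drop(Q %*% r$origin)
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-9 * ev[1])
    stop("degenerate ray set: rays are (near-)parallel or cameras coincide")
  point <- drop(solve(A, b))
  distances <- vapply(rays, function(r) as.numeric(point_ray_distance(point, r)),
                      numeric(1))
  names(distances) <- vapply(observations, function(ob) ob$camera$id, character(1))
  list(point = point, distances = distances,
       mean_ray_distance = mean(distances))
}

#' Optimal similarity alignment of two point sets
#'
#' Finds the similarity transform (rotation, translation, optionally
#' scale) minimizing the RMS distance between corresponding rows of `X`
#' and `Y` (Umeyama's closed form), and returns the transformed `X`.
#' Used to compare reconstructions defined up to their gauge.
#'
#' @param X,Y `n x 3` matrices of corresponding points.
#' @param scale If `TRUE`, a global scale is also estimated.
#' @return List with `X_aligned`, `R`, `t`, `s` and `rmsd`.
#' @export
align_similarity <- function(X, Y, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3L, ncol(Y) == 3L)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  D <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) D[3, 3] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (scale) sum(diag(D) * sv$d) / mean(rowSums(Xc^2)) else 1
  t_ <- my - s * drop(R %*% mx)
  Xa <- s * X %*% t(R) + matrix(t_, nrow(X), 3, byrow = TRUE)
  list(X_aligned = Xa, R = R, t = t_, s = s,
       rmsd = sqrt(mean(rowSums((Xa - Y)^2))))
}

#' Calibrate a camera from known 3D-pixel correspondences (DLT)
#'
#' Linear least-squares estimate of the 11-parameter projection matrix
#' from at least six non-coplanar point correspondences, with Hartley
#' normalization for numerical conditioning.
#'
#' @param points3d n x 3 matrix of lab coordinates, mm.
#' @param pixels n x 2 matrix (or data frame with columns `u`, `v`).
#' @param id Identifier for the returned camera.
#' @param image_width,image_height Sensor size of the returned camera.
#' @return A [camera_model()].
#' @export
dlt_calibrate <- function(points3d, pixels, id = "dlt",
                          image_width = 1920L, image_height = 1080L) {
  points3d <- as.matrix(points3d)
  if (is.data.frame(pixels)) pixels <- cbind(pixels$u, pixels$v)
  pixels <- as.matrix(pixels)
  n <- nrow(points3d)
  if (n < 6L || nrow(pixels) != n)
    stop("DLT calibration requires at least 6 point/pixel pairs")
  ctr <- colMeans(points3d)
  sv <- svd(sweep(points3d, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * sv[1])
    stop("degenerate calibration points: (near-)coplanar")
  # similarity normalization of both point sets
  s3 <- sqrt(3) / mean(sqrt(rowSums(sweep(points3d, 2, ctr)^2)))
  T3 <- diag(c(s3, s3, s3, 1)); T3[1:3, 4] <- -s3 * ctr
  c2 <- colMeans(pixels)
  s2 <- sqrt(2) / mean(sqrt(rowSums(sweep(pixels, 2, c2)^2)))
  T2 <- diag(c(s2, s2, 1)); T2[1:2, 3] <- -s2 * c2
  Xn <- cbind(points3d, 1) %*% t(T3)
  xn <- cbind(pixels, 1) %*% t(T2)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    X <- Xn[i, ]
    A[2 * i - 1, ] <- c(X, rep(0, 4), -xn[i, 1] * X)
    A[2 * i, ]     <- c(rep(0, 4), X, -xn[i, 2] * X)
  }
  p <- svd(A, nu = 0)$v[, 12]
  Pn <- matrix(p, 3, 4, byrow = TRUE)
  P <- solve(T2, Pn %*% T3)
  camera_model(id, P, image_width, image_height)
}
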