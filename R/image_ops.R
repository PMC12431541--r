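# Internal raster utilities. Images are numeric arrays in [0,1], indexed
# [row, col] or [row, col, channel]; pixel (u, v) is 0-based with u along
# columns and v along rows, so image[v + 1, u + 1, ].

# Catmull-Rom bicubic kernel (a = -0.5), the common "bicubic" convention.
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  w[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  w
}

# Sparse n_out x n_in interpolation matrix along one axis, half-pixel
# centre convention, edges clamped (weights accumulate on border
# samples). Matrices are cached: the same few geometries recur
# thousands of times during dataset synthesis.
.interp_cache <- new.env(parent = emptyenv())

interp_matrix <- function(n_out, n_in, method = c("bicubic", "nearest")) {
  method <- match.arg(method)
  key <- paste(n_out, n_in, method)
  hit <- get0(key, envir = .interp_cache)
  if (!is.null(hit)) return(hit)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based source coords
  if (method == "nearest") {
    j <- pmin(pmax(floor(src + 0.5), 0), n_in - 1)
    A <- Matrix::sparseMatrix(i = seq_len(n_out), j = j + 1, x = 1,
                              dims = c(n_out, n_in))
  } else {
    base <- floor(src)
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    for (k in -1:2) {
      j <- base + k
      w <- cubic_kernel(src - j)
      j <- pmin(pmax(j, 0), n_in - 1)
      rows <- c(rows, seq_len(n_out)); cols <- c(cols, j + 1)
      vals <- c(vals, w)
    }
    keep <- vals != 0
    A <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = vals[keep],
                              dims = c(n_out, n_in))
  }
  assign(key, A, envir = .interp_cache)
  A
}

apply_separable <- function(img, Ar, Ac) {
  f <- function(m) as.matrix(Ar %*% (m %*% Matrix::t(Ac)))
  if (length(dim(img)) == 3L) {
    out <- array(0, c(nrow(Ar), nrow(Ac), dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
    out
  } else f(img)
}

# Resize an image (matrix or h x w x c array) to out_h x out_w.
# Nearest-neighbour resizing is plain index subsetting (fast path).
resize_image <- function(img, out_h, out_w, method = c("bicubic", "nearest"),
                         clamp = TRUE) {
  method <- match.arg(method)
  d <- dim(img)
  if (method == "nearest") {
    ir <- nn_index(out_h, d[1]); ic <- nn_index(out_w, d[2])
    return(if (length(d) == 3L) img[ir, ic, , drop = FALSE] else img[ir, ic])
  }
  Ar <- interp_matrix(out_h, d[1], method)
  Ac <- interp_matrix(out_w, d[2], method)
  out <- apply_separable(img, Ar, Ac)
  if (clamp) { out[out < 0] <- 0; out[out > 1] <- 1 }
  out
}

# 1-based nearest-neighbour source indices for one axis
nn_index <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pmin(pmax(floor(src + 0.5), 0), n_in - 1) + 1L
}

# Nearest-neighbour rotation about the image centre; the output canvas is
# enlarged to contain the rotated footprint. `layers` is a named list of
# matrices/arrays sharing the same h x w; all are rotated consistently so
# colour planes and masks stay registered. Outside pixels get `fill`.
rotate_nn <- function(layers, angle_deg, fill = 0) {
  h <- nrow(layers[[1]]); w <- ncol(layers[[1]])
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  out_w <- ceiling(abs(w * ct) + abs(h * st))
  out_h <- ceiling(abs(w * st) + abs(h * ct))
  # inverse map: output pixel centre -> input pixel centre
  oc_u <- (out_w - 1) / 2; oc_v <- (out_h - 1) / 2
  ic_u <- (w - 1) / 2; ic_v <- (h - 1) / 2
  ou <- matrix(rep(0:(out_w - 1), each = out_h), out_h, out_w) - oc_u
  ov <- matrix(rep(0:(out_h - 1), times = out_w), out_h, out_w) - oc_v
  su <- round(ct * ou + st * ov + ic_u)
  sv <- round(-st * ou + ct * ov + ic_v)
  ok <- su >= 0 & su < w & sv >= 0 & sv < h
  idx <- sv + 1 + su * h  # column-major linear index into h x w matrix
  idx[!ok] <- 1L
  samp <- function(m) {
    r <- matrix(m[idx], out_h, out_w)
    r[!ok] <- fill
    r
  }
  lapply(layers, function(lyr) {
    if (length(dim(lyr)) == 3L) {
      out <- array(fill, c(out_h, out_w, dim(lyr)[3]))
      for (ch in seq_len(dim(lyr)[3])) out[, , ch] <- samp(lyr[, , ch])
      out
    } else samp(lyr)
  })
}

# HSL with every channel on a 0-255 scale (hue: 256 steps over the full
# circle) -> RGB in [0,1].
hsl_to_rgb <- function(h, s, l) {
  hd <- (h / 256) * 360
  sv <- s / 255; lv <- l / 255
  c <- (1 - abs(2 * lv - 1)) * sv
  x <- c * (1 - abs((hd / 60) %% 2 - 1))
  m <- lv - c / 2
  sector <- floor(hd / 60) %% 6
  r <- c(c, x, 0, 0, x, c)[sector + 1]
  g <- c(x, c, c, x, 0, 0)[sector + 1]
  b <- c(0, 0, x, c, c, x)[sector + 1]
  c(r + m, g + m, b + m)
}

# Vectorised RGB [0,1] -> HSL on the same 0-255 scales; input array
# h x w x 3, output list of matrices H, S, L.
rgb_to_hsl <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- matrix(0, nrow(r), ncol(r))
  nz <- which(d > 0)
  s[nz] <- d[nz] / (1 - abs(2 * l[nz] - 1))
  h <- matrix(0, nrow(r), ncol(r))
  im <- nz[mx[nz] == r[nz]]
  h[im] <- ((g[im] - b[im]) / d[im]) %% 6
  im <- nz[mx[nz] == g[nz] & mx[nz] != r[nz]]
  h[im] <- (b[im] - r[im]) / d[im] + 2
  im <- nz[mx[nz] == b[nz] & mx[nz] != r[nz] & mx[nz] != g[nz]]
  h[im] <- (r[im] - g[im]) / d[im] + 4
  list(H = h * 60 / 360 * 256, S = s * 255, L = l * 255)
}

# Separable Gaussian blur with edge replication, radius 3*sigma.
# Dense banded convolution matrices: the patches are small.
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  blur_axis <- function(n) {
    A <- matrix(0, n, n)
    i <- seq_len(n)
    for (k in -r:r) {
      j <- pmin(pmax(i + k, 1L), n)
      A[cbind(i, j)] <- A[cbind(i, j)] + g[k + r + 1]
    }
    A
  }
  Ar <- blur_axis(dim(img)[1]); Ac <- blur_axis(dim(img)[2])
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- Ar %*% img[, , ch] %*% t(Ac)
    out
  } else Ar %*% img %*% t(Ac)
}

.brush_cache <- new.env(parent = emptyenv())

# Binary dilation of a logical matrix by a disc of the given radius (px).
dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  key <- as.character(ceiling(radius))
  k <- get0(key, envir = .brush_cache)
  if (is.null(k)) {
    k <- EBImage::makeBrush(2L * ceiling(radius) + 1L, shape = "disc")
    assign(key, k, envir = .brush_cache)
  }
  EBImage::dilate(mask * 1, k) > 0
}
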