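# Shared fixtures: all synthetic, built in code at test time.

# Gaussian blob image on [0,1], 0-based centre coordinates (x = column).
blob_image <- function(side = 256, cx = 100, cy = 80, sigma = 6, amp = 0.9) {
  xs <- 0:(side - 1)
  outer(xs, xs, function(y, x) amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
}

# Independent separable Gaussian blur (R implementation, reflected borders);
# the oracle path for DoG checks, deliberately not the package's C++ blur.
gauss_blur_r <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k <- k / sum(k)
  reflect <- function(i, n) {
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  n <- nrow(img)
  pad_idx <- reflect(seq(1 - r, n + r), n)
  horiz <- apply(img[, pad_idx, drop = FALSE], 1, function(row)
    as.numeric(stats::filter(row, k, sides = 2))[(r + 1):(r + n)])
  horiz <- t(horiz)
  vert <- apply(horiz[pad_idx, , drop = FALSE], 2, function(col)
    as.numeric(stats::filter(col, k, sides = 2))[(r + 1):(r + n)])
  vert
}

# Rotate an image about its centre by `deg` degrees (bilinear, zero fill).
rotate_image <- function(img, deg) {
  th <- deg * pi / 180
  n <- nrow(img)
  c0 <- (n - 1) / 2
  out <- matrix(0, n, n)
  for (y in 1:n) {
    yr <- y - 1 - c0
    for (x in 1:n) {
      xr <- x - 1 - c0
      xs <- cos(th) * xr + sin(th) * yr + c0
      ys <- -sin(th) * xr + cos(th) * yr + c0
      x0 <- floor(xs); y0 <- floor(ys)
      if (x0 >= 0 && x0 < n - 1 && y0 >= 0 && y0 < n - 1) {
        fx <- xs - x0; fy <- ys - y0
        out[y, x] <- img[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
          img[y0 + 1, x0 + 2] * fx * (1 - fy) +
          img[y0 + 2, x0 + 1] * (1 - fx) * fy +
          img[y0 + 2, x0 + 2] * fx * fy
      }
    }
  }
  out
}

# Wrap a plain descriptor matrix as a descriptor_set (for vocabulary tests).
fake_dset <- function(desc, method = "sift", id = "fake") {
  desc <- as.matrix(desc)
  n <- nrow(desc)
  structure(list(image_id = id, method = method,
                 keypoints = data.frame(x = numeric(n), y = numeric(n),
                                        scale = rep(1, n),
                                        orientation = rep(0, n),
                                        response = rep(1, n)),
                 descriptors = desc),
            class = "descriptor_set")
}

hamming <- function(a, b) sum(orb_unpack(a) != orb_unpack(b))

# Small feature table straight from matrices.
make_table <- function(rows, labels, image_id = NULL) {
  gasfeeg:::new_feature_table(rows, labels, image_id = image_id)
}
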