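# Shared fixtures and independent brute-force oracles.

make_cube <- function(mats, names = NULL, bit_depth = 8L) {
  if (is.null(names)) names <- paste0("ch", seq_along(mats))
  assemble_cube(mapply(function(m, nm) channel_image(m, bit_depth, nm),
                       mats, names, SIMPLIFY = FALSE))
}

random_u8 <- function(h, w) matrix(sample(0:255, h * w, replace = TRUE), h, w)

random_cube <- function(k = 4, h = 8, w = 8, bit_depth = 8L) {
  make_cube(replicate(k, random_u8(h, w), simplify = FALSE),
            bit_depth = bit_depth)
}

# median filter oracle: per-pixel explicit window gather and sort
median_oracle <- function(x, size) {
  h <- nrow(x); w <- ncol(x)
  lo <- -ceiling((size - 1) / 2); hi <- floor((size - 1) / 2)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- c()
      for (dy in lo:hi) for (dx in lo:hi) {
        vals <- c(vals, x[min(max(i + dy, 1), h), min(max(j + dx, 1), w)])
      }
      s <- sort(vals)
      out[i, j] <- s[length(s) %/% 2 + 1]  # upper middle order statistic
    }
  }
  out
}

# plain global histogram equalization of an 8-bit image (256 bins)
global_equalize_oracle <- function(x) {
  n <- length(x)
  hist <- tabulate(as.vector(x) + 1L, nbins = 256L)
  lut <- pmin(pmax(round(cumsum(hist) * 255 / n), 0), 255)
  matrix(lut[x + 1L], nrow(x), ncol(x))
}

# dense PCA oracle: full pixel-space covariance eigendecomposition
dense_pca_oracle <- function(mats, n_components = 3) {
  X <- t(sapply(mats, function(m) as.vector(t(m))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc)               # p x p scatter matrix
  eg <- eigen(C, symmetric = TRUE)
  evr <- pmax(eg$values, 0) / sum(pmax(eg$values, 0))
  list(axes = eg$vectors[, seq_len(n_components), drop = FALSE],
       evr = evr[seq_len(n_components)])
}

expect_no_error <- function(expr) testthat::expect_error(expr, NA)
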