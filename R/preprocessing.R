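#' CLAHE parameters
#'
#' Parameters of the contrast-limited adaptive histogram equalization
#' operator, in the normalized convention of the widely used computer-vision
#' implementation: the per-tile clip value is
#' `clip_limit * tile_pixels / n_bins` (truncated to an integer, minimum 1),
#' so `clip_limit` is relative to the bin count and tile size rather than an
#' absolute count.
#'
#' @param clip_limit Positive real; the workflow default is 12.0.
#' @param tile_grid Integer pair `(rows, cols)` of the tile grid; default
#'   `c(10, 10)`.
#' @param n_bins Number of histogram bins (default 256).
#' @param border_policy Padding rule used when the image dimensions are not
#'   divisible by the tile grid; only `"replicate_pad"` (edge replication,
#'   cropped after mapping) is implemented.
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(clip_limit = 12.0, tile_grid = c(10L, 10L),
                         n_bins = 256L, border_policy = "replicate_pad") {
  tile_grid <- as.integer(tile_grid)
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0) {
    stop("`clip_limit` must be a positive number", call. = FALSE)
  }
  if (length(tile_grid) != 2L || any(tile_grid < 1L)) {
    stop("`tile_grid` must be two integers >= 1", call. = FALSE)
  }
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  border_policy <- match.arg(border_policy, "replicate_pad")
  structure(list(clip_limit = clip_limit, tile_grid = tile_grid,
                 n_bins = as.integer(n_bins), border_policy = border_policy),
            class = "clahe_params")
}

as_pixel_matrix <- function(image) {
  if (is_channel_image(image)) image$pixels else {
    stopifnot(is.matrix(image), is.numeric(image))
    image
  }
}

#' Row-wise standardization of a channel
#'
#' Standardizes each image row (the pixels along the x-axis) to zero mean
#' and unit population standard deviation (ddof 0). Rows with zero variance
#' map to all zeros rather than NaN, so constant stripes cannot poison the
#' downstream PCA.
#'
#' @param image A [channel_image()] or a numeric matrix.
#' @return A real-valued matrix of the same geometry.
#' @export
std_scale_rows <- function(image) {
  x <- as_pixel_matrix(image)
  mu <- rowMeans(x)
  centered <- x - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  out <- centered / sd_pop
  out[sd_pop == 0, ] <- 0
  out
}

# Quantize a channel to the 8-bit domain CLAHE operates on.
# 8-bit integer data passes through; 16-bit/float is min-max rescaled.
quantize_to_u8 <- function(image) {
  x <- as_pixel_matrix(image)
  depth <- if (is_channel_image(image)) image$bit_depth else 8L
  if (identical(depth, 8L)) return(round(x))
  rng <- range(x)
  if (rng[2] == rng[1]) return(matrix(0, nrow(x), ncol(x)))
  round((x - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit on bin counts and
#' bilinear interpolation of the tile mappings, the standard recipe for
#' local contrast enhancement without block artifacts. The implementation
#' follows the common computer-vision convention exactly: per-tile
#' histograms of `n_bins` bins; clip value `clip_limit * tile_pixels /
#' n_bins` truncated (minimum 1); clipped excess redistributed uniformly,
#' the integer remainder spread over bins with stride
#' `max(n_bins %/% remainder, 1)`; tile mappings are the cumulative
#' histograms scaled onto \[0, 255\] with round-half-even; each pixel is
#' mapped by bilinear interpolation among the four nearest tile-center
#' mappings, degrading to linear/nearest at borders. Images whose
#' dimensions are not divisible by the tile grid are padded by edge
#' replication and cropped afterwards. 16-bit and float channels are
#' min-max rescaled to the 8-bit domain first.
#'
#' @param image A [channel_image()] or numeric matrix.
#' @param params A [clahe_params()] object.
#' @return An integer-valued matrix in \[0, 255\] with the input geometry.
#' @export
clahe <- function(image, params = clahe_params()) {
  stopifnot(inherits(params, "clahe_params"))
  x <- quantize_to_u8(image)
  h <- nrow(x); w <- ncol(x)
  ty <- params$tile_grid[1L]; tx <- params$tile_grid[2L]
  if (ty > h || tx > w) {
    stop(sprintf("tile grid (%d, %d) exceeds image size (%d, %d)",
                 ty, tx, h, w), call. = FALSE)
  }
  n_bins <- params$n_bins

  # pad by edge replication so dimensions divide the grid
  tile_h <- ceiling(h / ty); tile_w <- ceiling(w / tx)
  ph <- tile_h * ty; pw <- tile_w * tx
  xp <- x[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)), drop = FALSE]

  # bin index per pixel, 1-based
  bin <- pmin(floor(xp * n_bins / 256), n_bins - 1) + 1L

  tile_pixels <- tile_h * tile_w
  # clip value in counts; capped at the tile population (no bin can exceed it)
  clip <- max(1, trunc(min(params$clip_limit * tile_pixels / n_bins, tile_pixels)))

  # per-tile LUTs: array [ty, tx, n_bins]
  luts <- array(0, c(ty, tx, n_bins))
  for (i in seq_len(ty)) {
    rows <- ((i - 1L) * tile_h + 1L):(i * tile_h)
    for (j in seq_len(tx)) {
      cols <- ((j - 1L) * tile_w + 1L):(j * tile_w)
      hist <- tabulate(bin[rows, cols], nbins = n_bins)
      over <- hist > clip
      excess <- sum(hist[over] - clip)
      hist[over] <- clip
      if (excess > 0) {
        batch <- excess %/% n_bins
        hist <- hist + batch
        residual <- excess - batch * n_bins
        if (residual > 0) {
          step <- max(n_bins %/% residual, 1L)
          idx <- seq(1L, by = step, length.out = residual)
          hist[idx] <- hist[idx] + 1L
        }
      }
      luts[i, j, ] <- pmin(pmax(round(cumsum(hist) * 255 / tile_pixels), 0), 255)
    }
  }

  # bilinear interpolation among the 4 nearest tile-center mappings
  cy <- (seq_len(ph) - 1) / tile_h - 0.5
  y1 <- floor(cy); ya <- cy - y1
  y1c <- pmin(pmax(y1, 0), ty - 1); y2c <- pmin(y1 + 1, ty - 1)
  cxv <- (seq_len(pw) - 1) / tile_w - 0.5
  x1 <- floor(cxv); xa <- cxv - x1
  x1c <- pmin(pmax(x1, 0), tx - 1); x2c <- pmin(x1 + 1, tx - 1)

  Y1 <- matrix(y1c + 1, ph, pw); Y2 <- matrix(y2c + 1, ph, pw)
  X1 <- matrix(x1c + 1, ph, pw, byrow = TRUE); X2 <- matrix(x2c + 1, ph, pw, byrow = TRUE)
  WY <- matrix(ya, ph, pw); WX <- matrix(xa, ph, pw, byrow = TRUE)
  B <- as.vector(bin)

  v11 <- luts[cbind(as.vector(Y1), as.vector(X1), B)]
  v12 <- luts[cbind(as.vector(Y1), as.vector(X2), B)]
  v21 <- luts[cbind(as.vector(Y2), as.vector(X1), B)]
  v22 <- luts[cbind(as.vector(Y2), as.vector(X2), B)]
  wx <- as.vector(WX); wy <- as.vector(WY)
  res <- (v11 * (1 - wx) + v12 * wx) * (1 - wy) + (v21 * (1 - wx) + v22 * wx) * wy
  out <- matrix(pmin(pmax(round(res), 0), 255), ph, pw)
  out[seq_len(h), seq_len(w), drop = FALSE]
}

#' Median filter with replicate borders
#'
#' Rank filter taking, at each pixel, the median of the `size` x `size`
#' window spanning offsets `-ceiling((size-1)/2) ... floor((size-1)/2)` in
#' each axis, i.e. `[-2, -1, 0, +1]` for the workflow default 4 (the
#' origin-0 rank-filter layout, which makes even sizes well defined). Out-of-bounds samples replicate the
#' nearest edge. For even window populations the upper of the two middle
#' order statistics is taken (0-based sorted index `floor(n/2)`), so every
#' output value is a member of its window.
#'
#' @param grid Numeric matrix (or [channel_image()]).
#' @param size Window side length, a positive integer.
#' @return A matrix of the same geometry.
#' @export
median_filter <- function(grid, size) {
  x <- as_pixel_matrix(grid)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L) {
    stop("`size` must be a positive integer", call. = FALSE)
  }
  if (size == 1L) return(x)
  h <- nrow(x); w <- ncol(x)
  offs <- (-ceiling((size - 1) / 2)):(floor((size - 1) / 2))
  n <- size * size
  # columns of M are the window samples for every pixel (replicated edges)
  M <- matrix(0, h * w, n)
  k <- 0L
  for (dy in offs) {
    ry <- pmin(pmax(seq_len(h) + dy, 1L), h)
    for (dx in offs) {
      k <- k + 1L
      cx <- pmin(pmax(seq_len(w) + dx, 1L), w)
      M[, k] <- x[ry, cx]
    }
  }
  # row-wise order statistic via a single radix sort
  o <- order(rep(seq_len(h * w), times = n), M)
  sorted <- matrix(M[o], nrow = h * w, byrow = TRUE)
  matrix(sorted[, n %/% 2 + 1L], h, w)
}

#' Preprocess a spectral cube along one branch
#'
#' Applies the chosen branch operator — row-wise standardization (`"std"`)
#' or CLAHE (`"clahe"`) — to every channel independently, then the median
#' filter (default size 4) to every channel; the filter always runs after
#' the branch operator. The two branches are the parallel preprocessing
#' paths of the workflow, each feeding its own PCA.
#'
#' @param cube A [assemble_cube()] spectral cube.
#' @param branch `"std"` or `"clahe"`.
#' @param clahe_params A [clahe_params()] (used by the clahe branch).
#' @param median_size Median filter window size (default 4).
#' @return An object of class `preprocessed_cube`: list of real-valued
#'   channel matrices in source order, plus `branch` and `params_echo`.
#' @export
preprocess <- function(cube, branch = c("std", "clahe"),
                       clahe_params = eigenimage::clahe_params(),
                       median_size = 4L) {
  stopifnot(inherits(cube, "spectral_cube"))
  branch <- match.arg(branch)
  op <- switch(branch,
    std = function(im) std_scale_rows(im),
    clahe = function(im) clahe(im, clahe_params)
  )
  channels <- lapply(cube$channels, function(im) median_filter(op(im), median_size))
  names(channels) <- cube$channel_names
  structure(
    list(channels = channels, branch = branch,
         channel_names = cube$channel_names,
         height = cube$height, width = cube$width,
         params_echo = list(
           branch = branch,
           clip_limit = clahe_params$clip_limit,
           tile_grid = clahe_params$tile_grid,
           n_bins = clahe_params$n_bins,
           median_size = as.integer(median_size))),
    class = "preprocessed_cube"
  )
}

#' @export
print.preprocessed_cube <- function(x, ...) {
  cat(sprintf("<preprocessed_cube> branch '%s', %d channels, %d x %d\n",
              x$branch, length(x$channels), x$height, x$width))
  invisible(x)
}
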