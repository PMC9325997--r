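#' Flatten an image row-major
#'
#' Concatenates image pixels row by row, so element `k` (0-based) of the
#' result is `grid[k %/% width, k %% width]` (0-based indices). A full
#' 1392 x 1040 CCD frame flattens to a vector of length 1,447,680 — the
#' dimensionality of the pixel space the PCA operates in.
#'
#' @param grid Numeric matrix.
#' @return Numeric vector of length `nrow(grid) * ncol(grid)`.
#' @export
flatten_row_major <- function(grid) {
  stopifnot(is.matrix(grid), nrow(grid) >= 1L, ncol(grid) >= 1L)
  as.vector(t(grid))
}

#' Reshape a row-major vector back to image geometry
#'
#' Inverse of [flatten_row_major()].
#'
#' @param v Numeric vector of length `height * width`.
#' @param height,width Target geometry.
#' @return A `height` x `width` matrix.
#' @export
reshape_row_major <- function(v, height, width) {
  stopifnot(length(v) == height * width)
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

#' Spectral PCA: channels as observations, pixels as features
#'
#' Decomposes a preprocessed cube by principal component analysis in the
#' orientation where each flattened channel is one observation and each
#' pixel one feature — so the principal axes live in pixel space and
#' reshape into *eigen-images* carrying tissue-discriminating contrast.
#' The channel matrix is centered by subtracting the per-pixel mean across
#' channels; the top right-singular directions are obtained exactly from
#' the eigendecomposition of the small channels-by-channels Gram matrix
#' (no iterative or randomized solver), which makes results bit-stable.
#' Each component's sign is fixed so that its largest-magnitude channel
#' loading is positive (ties broken by lowest channel index).
#'
#' Centering k observations leaves rank at most k - 1, so with 4 channels
#' the 3 retained components capture all variance and their explained
#' variance ratios sum to 1.
#'
#' @param pre A [preprocess()] result (or a `spectral_cube`, whose raw
#'   channel intensities are then decomposed directly).
#' @param n_components Number of components to retain (default 3); must not
#'   exceed the channel count.
#' @return An object of class `eigen_image_set`: `components` (list of
#'   `n_components` eigen-image matrices, unit norm in pixel space),
#'   `loadings` (`n_components` x channels matrix of the centered channels'
#'   coordinates on each axis), `explained_variance_ratio`, `branch`,
#'   `channel_names`.
#' @export
spectral_pca <- function(pre, n_components = 3L) {
  if (inherits(pre, "spectral_cube")) {
    channels <- lapply(pre$channels, function(im) im$pixels)
    branch <- "raw"
    channel_names <- pre$channel_names
  } else if (inherits(pre, "preprocessed_cube")) {
    channels <- pre$channels
    branch <- pre$branch
    channel_names <- pre$channel_names
  } else if (is.list(pre) && all(vapply(pre, is.matrix, logical(1)))) {
    channels <- pre
    branch <- "raw"
    channel_names <- names(pre) %||% paste0("ch", seq_along(pre))
  } else {
    stop("`pre` must be a preprocessed_cube, spectral_cube or list of matrices",
         call. = FALSE)
  }
  k <- length(channels)
  n_components <- as.integer(n_components)
  if (k < 2L) stop("need at least 2 channels", call. = FALSE)
  if (n_components < 1L || n_components > k) {
    stop(sprintf("n_components (%d) must be between 1 and the channel count (%d)",
                 n_components, k), call. = FALSE)
  }
  h <- nrow(channels[[1L]]); w <- ncol(channels[[1L]])

  X <- t(vapply(channels, flatten_row_major, numeric(h * w)))  # k x p
  Xc <- sweep(X, 2L, colMeans(X))

  G <- tcrossprod(Xc)                      # k x k Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  total <- sum(lambda)
  if (total <= .Machine$double.eps * k * h * w * max(1, max(abs(X)))^2) {
    stop("degenerate input: the cube has zero total variance across channels",
         call. = FALSE)
  }

  comps <- vector("list", n_components)
  loadings <- matrix(0, n_components, k,
                     dimnames = list(paste0("PC", seq_len(n_components)),
                                     channel_names))
  evr <- numeric(n_components)
  for (i in seq_len(n_components)) {
    li <- lambda[i]
    evr[i] <- li / total
    if (li > total * 1e-14) {
      u <- eg$vectors[, i]
      v <- drop(crossprod(Xc, u)) / sqrt(li)   # unit-norm pixel-space axis
      load <- u * sqrt(li)                     # channel scores on the axis
      # deterministic sign: largest |loading| positive, ties -> lowest index
      j <- which(abs(load) == max(abs(load)))[1L]
      if (load[j] < 0) { v <- -v; load <- -load }
      comps[[i]] <- reshape_row_major(v, h, w)
      loadings[i, ] <- load
    } else {
      # component beyond the numerical rank: no direction is defined
      comps[[i]] <- matrix(0, h, w)
      evr[i] <- 0
    }
  }

  structure(
    list(components = comps, loadings = loadings,
         explained_variance_ratio = evr, branch = branch,
         channel_names = channel_names, height = h, width = w),
    class = "eigen_image_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eigen_image_set <- function(x, ...) {
  cat(sprintf("<eigen_image_set> branch '%s', %d components, %d x %d\n",
              x$branch, length(x$components), x$height, x$width))
  cat("explained variance ratio:",
      paste(sprintf("%.4f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Min-max normalize a component onto the 8-bit range
#'
#' Affine map of a real-valued eigen-image onto \[0, 255\], rounded
#' half-to-even. A constant component (no contrast to stretch) maps to all
#' zeros.
#'
#' @param component Numeric matrix.
#' @return Integer-valued matrix in \[0, 255\].
#' @export
normalize_to_255 <- function(component) {
  stopifnot(is.matrix(component))
  rng <- range(component)
  if (rng[2] == rng[1]) return(matrix(0, nrow(component), ncol(component)))
  round((component - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Merge three eigen-images into an RGB false-color composite
#'
#' Principal components 1, 2 and 3 become the red, green and blue planes
#' respectively, each min-max normalized to \[0, 255\].
#'
#' @param eigen An [spectral_pca()] result with exactly 3 components.
#' @return An object of class `rgb_composite` with `planes` (list of red,
#'   green, blue integer matrices) and `branch`.
#' @export
compose_rgb <- function(eigen) {
  stopifnot(inherits(eigen, "eigen_image_set"))
  if (length(eigen$components) != 3L) {
    stop(sprintf("an RGB composite needs exactly 3 components (got %d)",
                 length(eigen$components)), call. = FALSE)
  }
  planes <- lapply(eigen$components, normalize_to_255)
  names(planes) <- c("red", "green", "blue")
  structure(list(planes = planes, branch = eigen$branch,
                 height = eigen$height, width = eigen$width),
            class = "rgb_composite")
}

#' @export
print.rgb_composite <- function(x, ...) {
  cat(sprintf("<rgb_composite> branch '%s', %d x %d\n",
              x$branch, x$height, x$width))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full workflow. The defaults are
#' the workflow's reference settings: CLAHE clip limit 12.0 on a 10 x 10
#' tile grid, median filter size 4, 3 retained components, both branches.
#'
#' @param branch `"std"`, `"clahe"` or `"both"` (default).
#' @param clip_limit,tile_grid,n_bins CLAHE settings, see [clahe_params()].
#' @param median_size Median filter window (default 4).
#' @param n_components Components retained by the PCA (default 3).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(branch = c("both", "std", "clahe"),
                            clip_limit = 12.0, tile_grid = c(10L, 10L),
                            n_bins = 256L, median_size = 4L,
                            n_components = 3L) {
  branch <- match.arg(branch)
  structure(list(branch = branch,
                 clahe = clahe_params(clip_limit, tile_grid, n_bins),
                 median_size = as.integer(median_size),
                 n_components = as.integer(n_components)),
            class = "pipeline_config")
}

#' Run the full contrast-enhancement pipeline
#'
#' Runs the requested preprocessing branch(es) — each branch feeds its own
#' PCA, as the two parallel rows of the workflow — and returns, per branch,
#' the eigen-image set and the RGB false-color composite.
#'
#' @param cube A [assemble_cube()] spectral cube (typically 4 channels:
#'   blue, green, red, NIR emission).
#' @param config A [pipeline_config()].
#' @return A named list with one entry per branch run (`std`, `clahe`),
#'   each a list with elements `eigen` ([spectral_pca()] result) and
#'   `composite` ([compose_rgb()] result).
#' @export
run_pipeline <- function(cube, config = pipeline_config()) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(config, "pipeline_config"))
  branches <- if (config$branch == "both") c("std", "clahe") else config$branch
  out <- lapply(branches, function(br) {
    pre <- preprocess(cube, branch = br, clahe_params = config$clahe,
                      median_size = config$median_size)
    eig <- spectral_pca(pre, n_components = config$n_components)
    res <- list(eigen = eig)
    if (config$n_components == 3L) res$composite <- compose_rgb(eig)
    res
  })
  names(out) <- branches
  out
}
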