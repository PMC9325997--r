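#' Specification of a synthetic tissue phantom
#'
#' Describes a labeled multichannel phantom that emulates the statistical
#' structure of a wide-field fluorescence acquisition of periodontal
#' tissue: spatially structured tissue regions, per-tissue 4-channel
#' spectral signatures, dye crosstalk (spectral overlap between emission
#' passbands, modeled by a row-stochastic mixing matrix), a low
#' autofluorescence background well below the labeling signal, shot and
#' read noise, and an optional multiplicative illumination tilt.
#'
#' The defaults are the reference phantom: five regions (root, bone,
#' ligament, gingiva, background) in a nested-annulus layout mimicking a
#' tooth cross-section, 4 emission channels (blue, green, red, NIR), 0.15
#' off-diagonal crosstalk leakage, autofluorescence at 5% of full scale,
#' Gaussian read noise at 2% of full scale, Poisson shot noise on, 16-bit
#' quantization, at the CCD frame size 1392 x 1040 (pass smaller
#' `height`/`width` for fast experiments).
#'
#' @param height,width Image geometry in pixels.
#' @param signatures Tissues x channels matrix of mean emission fractions
#'   in \[0, 1\]; row names are tissue names, column names channel names.
#' @param crosstalk Channels x channels row-stochastic mixing matrix;
#'   entry (c, j) is the fraction of tissue signature in channel j leaking
#'   into recorded channel c. Rows must sum to 1.
#' @param autofluorescence_level Background emission added to every channel,
#'   as a fraction of full scale.
#' @param gaussian_sd Additive Gaussian noise SD as a fraction of full scale.
#' @param poisson Logical; resample each pixel's digital number from a
#'   Poisson law with the noise-free value as mean (shot noise).
#' @param illumination_gradient Maximum relative multiplicative tilt of the
#'   illumination across the field (0 = flat).
#' @param geometry Region layout: `"nested_annuli"` (concentric
#'   rectangular rings, innermost tissue first), `"bands"` (horizontal
#'   stripes) or `"voronoi"` (nearest random seed per tissue).
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; the phantom is a pure function of spec + seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 1040L, width = 1392L,
                         signatures = default_signatures(),
                         crosstalk = default_crosstalk(nrow = ncol(signatures),
                                                       leakage = 0.15),
                         autofluorescence_level = 0.05,
                         gaussian_sd = 0.02,
                         poisson = TRUE,
                         illumination_gradient = 0,
                         geometry = c("nested_annuli", "bands", "voronoi"),
                         bit_depth = 16L,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(height >= 1, width >= 1, is.matrix(signatures),
            autofluorescence_level >= 0, gaussian_sd >= 0,
            illumination_gradient >= 0)
  if (min(signatures) < 0 || max(signatures) > 1) {
    stop("signatures must lie in [0, 1] (fractions of full scale)", call. = FALSE)
  }
  if (autofluorescence_level > 1) {
    stop("autofluorescence_level must lie in [0, 1]", call. = FALSE)
  }
  k <- ncol(signatures)
  if (!is.matrix(crosstalk) || nrow(crosstalk) != k || ncol(crosstalk) != k) {
    stop(sprintf("crosstalk must be a %d x %d matrix", k, k), call. = FALSE)
  }
  rs <- rowSums(crosstalk)
  bad <- which(abs(rs - 1) > 1e-9 | apply(crosstalk, 1, min) < 0)
  if (length(bad)) {
    stop(sprintf("crosstalk rows must be stochastic (nonnegative, sum 1); row(s) %s sum to %s",
                 paste(bad, collapse = ", "),
                 paste(signif(rs[bad], 6), collapse = ", ")), call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 signatures = signatures, crosstalk = crosstalk,
                 autofluorescence_level = autofluorescence_level,
                 gaussian_sd = gaussian_sd, poisson = isTRUE(poisson),
                 illumination_gradient = illumination_gradient,
                 geometry = geometry, bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-tissue spectral signatures
#'
#' Mean emission fractions of the five reference tissues in the four
#' emission channels. Mineralized tissue (root, bone) dominates the blue
#' channel (strong UV-excited emission), soft connective tissue the green,
#' gingival soft tissue the red, and nuclear labeling the NIR; background
#' carries almost nothing. Values are fractions of full scale.
#'
#' @return A 5 x 4 matrix with tissue row names and channel column names.
#' @export
default_signatures <- function() {
  m <- rbind(
    root       = c(blue = 0.90, green = 0.35, red = 0.15, nir = 0.05),
    bone       = c(blue = 0.70, green = 0.30, red = 0.22, nir = 0.10),
    ligament   = c(blue = 0.20, green = 0.70, red = 0.35, nir = 0.20),
    gingiva    = c(blue = 0.15, green = 0.35, red = 0.70, nir = 0.50),
    background = c(blue = 0.02, green = 0.02, red = 0.02, nir = 0.02)
  )
  m
}

#' Row-stochastic crosstalk matrix with uniform off-diagonal leakage
#'
#' @param nrow Number of channels.
#' @param leakage Total off-diagonal leakage per recorded channel (split
#'   evenly over the other channels); the diagonal keeps `1 - leakage`.
#' @return An `nrow` x `nrow` row-stochastic matrix.
#' @export
default_crosstalk <- function(nrow = 4L, leakage = 0.15) {
  stopifnot(leakage >= 0, leakage < 1)
  off <- leakage / (nrow - 1L)
  m <- matrix(off, nrow, nrow)
  diag(m) <- 1 - leakage
  m
}

# Partition the frame into one integer label per pixel, 1..n_tissues,
# in the order of the signature rows.
phantom_labels <- function(spec) {
  h <- spec$height; w <- spec$width
  n <- nrow(spec$signatures)
  if (spec$geometry == "bands") {
    lab <- matrix(rep(pmin(ceiling(seq_len(h) / h * n), n), w), h, w)
  } else if (spec$geometry == "nested_annuli") {
    # Chebyshev-like radius normalized to [0, 1] at the frame edge;
    # innermost tissue listed first, outermost (background) last
    dy <- abs(seq_len(h) - (h + 1) / 2) / (h / 2)
    dx <- abs(seq_len(w) - (w + 1) / 2) / (w / 2)
    r <- pmax(matrix(dy, h, w), matrix(dx, h, w, byrow = TRUE))
    cuts <- seq(0, 1, length.out = n + 1L)[-1L]
    ring_to_label <- seq_len(n)
    if (n == 5L) {
      # anatomical nesting: root, then a thin ligament ring, bone, gingiva,
      # background — mapped back onto the signature row order
      cuts <- c(0.30, 0.42, 0.62, 0.82, 1.0)
      ring_to_label <- match(c("root", "ligament", "bone", "gingiva", "background"),
                             rownames(spec$signatures))
      if (anyNA(ring_to_label)) ring_to_label <- seq_len(n)
    }
    ring <- matrix(findInterval(r, cuts, left.open = TRUE) + 1L, h, w)
    ring[ring > n] <- n
    lab <- matrix(ring_to_label[ring], h, w)
  } else { # voronoi
    seeds_y <- stats::runif(n, 1, h)
    seeds_x <- stats::runif(n, 1, w)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    d <- vapply(seq_len(n),
                function(i) (yy - seeds_y[i])^2 + (xx - seeds_x[i])^2,
                matrix(0, h, w))
    lab <- apply(d, c(1, 2), which.min)
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Generate a synthetic labeled phantom acquisition
#'
#' Draws one multichannel acquisition from the generative model of
#' [phantom_spec()]: per pixel with tissue t, the mean digital number in
#' channel c is `full_scale * (crosstalk %*% signature_t + autofluorescence)`,
#' modulated by the illumination tilt, then Poisson-resampled (if enabled),
#' perturbed by Gaussian read noise, clipped to \[0, full scale\] and
#' quantized. Fully determined by `spec` (including its seed): the same
#' spec yields the same cube.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `cube` (a [assemble_cube()] spectral cube) and
#'   `labels` (integer matrix of tissue indices, with tissue names in
#'   `attr(labels, "tissues")`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    k <- ncol(spec$signatures)
    full <- 2^spec$bit_depth - 1

    labels <- phantom_labels(spec)

    # tissue x channel mean fractions after crosstalk + autofluorescence
    mixed <- spec$signatures %*% t(spec$crosstalk) + spec$autofluorescence_level
    mixed <- pmin(pmax(mixed, 0), 1)

    # left-to-right multiplicative illumination tilt around 1
    illum <- if (spec$illumination_gradient > 0) {
      g <- spec$illumination_gradient
      matrix(1 + g * ((seq_len(w) - 1) / max(w - 1, 1) - 0.5), h, w, byrow = TRUE)
    } else NULL

    chans <- vector("list", k)
    for (c in seq_len(k)) {
      mean_dn <- matrix(mixed[labels, c], h, w) * full
      if (!is.null(illum)) mean_dn <- mean_dn * illum
      val <- if (spec$poisson) {
        matrix(stats::rpois(h * w, lambda = as.vector(mean_dn)), h, w)
      } else mean_dn
      if (spec$gaussian_sd > 0) {
        val <- val + matrix(stats::rnorm(h * w, sd = spec$gaussian_sd * full), h, w)
      }
      pix <- round(pmin(pmax(val, 0), full))
      nm <- colnames(spec$signatures)[c] %||% paste0("ch", c)
      chans[[c]] <- channel_image(pix, bit_depth = spec$bit_depth, channel_name = nm)
    }

    attr(labels, "tissues") <- rownames(spec$signatures)
    list(cube = assemble_cube(chans), labels = labels)
  })
}
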