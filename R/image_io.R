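#' Single-channel image container
#'
#' A `channel_image` wraps one 2-D grid of pixel intensities together with its
#' sample format and a channel name. Row index is y (top to bottom), column
#' index is x (left to right), so a matrix row is one image row along the
#' x-axis. Pixel-size metadata, when present in a file, is carried along but
#' never used by any computation.
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#' @param bit_depth Either `8`, `16` (unsigned integer samples) or `"float"`.
#'   Integer depths enforce the range `[0, 2^bit_depth - 1]`; float data
#'   bypasses range checks.
#' @param channel_name Channel label, conventionally one of `"blue"`,
#'   `"green"`, `"red"`, `"nir"` (named by emission light), but any string is
#'   accepted.
#'
#' @return An object of class `channel_image` with fields `pixels`,
#'   `height`, `width`, `bit_depth`, `channel_name`.
#' @export
channel_image <- function(pixels, bit_depth = 8L, channel_name = "channel") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  }
  if (!identical(bit_depth, "float")) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 16L)) {
      stop("`bit_depth` must be 8, 16 or \"float\"", call. = FALSE)
    }
    full <- 2^bit_depth - 1
    if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > full) {
      stop(sprintf("intensities must lie in [0, %d] for bit depth %d",
                   full, bit_depth), call. = FALSE)
    }
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         bit_depth = bit_depth, channel_name = as.character(channel_name)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s'> %d x %d, bit depth %s\n",
              x$channel_name, x$height, x$width, as.character(x$bit_depth)))
  invisible(x)
}

is_channel_image <- function(x) inherits(x, "channel_image")

#' Read one grayscale channel from a TIFF or PNG file
#'
#' Accepts single-plane grayscale TIFF (8/16-bit unsigned or 32-bit float)
#' and PNG (8/16-bit grayscale). Multi-plane TIFFs and RGB/RGBA images are
#' rejected with an error naming the offending property: the pipeline
#' consumes one emission channel per file.
#'
#' @param path Path to the image file.
#' @param channel_name Name to attach to the channel (defaults to the file
#'   base name).
#' @return A [channel_image()] whose `bit_depth` matches the file's sample
#'   format.
#' @export
read_channel <- function(path, channel_name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  if (is.null(channel_name)) {
    channel_name <- tools::file_path_sans_ext(basename(path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(planes) != 1L) {
      stop(sprintf("'%s' holds %d planes; expected a single-plane grayscale image",
                   path, length(planes)), call. = FALSE)
    }
    img <- planes[[1L]]
    if (length(dim(img)) == 3L) {
      stop(sprintf("'%s' has %d samples per pixel; expected grayscale (1)",
                   path, dim(img)[3L]), call. = FALSE)
    }
    bps <- attr(img, "bits.per.sample")
    if (is.null(bps)) bps <- 8L
    if (bps == 32L) {
      pix <- unclass_matrix(img)
      depth <- "float"
    } else if (bps %in% c(8L, 16L)) {
      # readTIFF scales integer samples to [0,1]; undo exactly
      pix <- round(unclass_matrix(img) * (2^bps - 1))
      depth <- as.integer(bps)
    } else {
      stop(sprintf("'%s': unsupported bits per sample (%d)", path, bps),
           call. = FALSE)
    }
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3L) {
      stop(sprintf("'%s' has %d channels; expected grayscale (1)",
                   path, dim(img)[3L]), call. = FALSE)
    }
    info <- attr(img, "info")
    bps <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    if (!bps %in% c(8L, 16L)) {
      stop(sprintf("'%s': unsupported PNG bit depth (%d)", path, bps),
           call. = FALSE)
    }
    pix <- round(unclass_matrix(img) * (2^bps - 1))
    depth <- as.integer(bps)
  } else {
    stop(sprintf("unsupported image extension '.%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  }
  channel_image(pix, bit_depth = depth, channel_name = channel_name)
}

unclass_matrix <- function(img) {
  attributes(img) <- list(dim = dim(img))
  img
}

#' Write one grayscale channel to a TIFF or PNG file
#'
#' Inverse of [read_channel()]: 8/16-bit integer data round-trips losslessly.
#' Float data is written as 32-bit float TIFF and must lie in \[0, 1\] (the
#' storage range of float TIFF samples here); PNG output supports 8-bit only.
#'
#' @param image A [channel_image()].
#' @param path Destination path; format chosen by extension (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_channel <- function(image, path) {
  stopifnot(is_channel_image(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (identical(image$bit_depth, "float")) {
      if (min(image$pixels) < 0 || max(image$pixels) > 1) {
        stop("float TIFF output requires intensities in [0, 1]; rescale first",
             call. = FALSE)
      }
      tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L,
                      compression = "none")
    } else {
      tiff::writeTIFF(image$pixels / (2^image$bit_depth - 1), path,
                      bits.per.sample = image$bit_depth)
    }
  } else if (ext == "png") {
    if (!identical(image$bit_depth, 8L)) {
      stop("PNG output supports 8-bit channels only; use TIFF", call. = FALSE)
    }
    png::writePNG(image$pixels / 255, path)
  } else {
    stop(sprintf("unsupported image extension '.%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Stack co-registered channels into a spectral cube
#'
#' The cube is the unit the pipeline consumes: an ordered stack of
#' co-registered single-channel images (order is semantic — it fixes the
#' loading indices reported downstream). Channels must share geometry and
#' carry unique names. No registration is performed; filter-wheel
#' acquisitions are assumed co-registered.
#'
#' @param images List of [channel_image()] objects (at least 2).
#' @return An object of class `spectral_cube` with fields `channels`,
#'   `n_channels`, `height`, `width`, `channel_names`.
#' @export
assemble_cube <- function(images) {
  if (!is.list(images) || length(images) < 2L) {
    stop("a spectral cube needs at least 2 channel images", call. = FALSE)
  }
  if (!all(vapply(images, is_channel_image, logical(1)))) {
    stop("all elements must be channel_image objects", call. = FALSE)
  }
  hs <- vapply(images, function(im) im$height, integer(1))
  ws <- vapply(images, function(im) im$width, integer(1))
  if (length(unique(hs)) > 1L || length(unique(ws)) > 1L) {
    geo <- paste(sprintf("%s: %dx%d",
                         vapply(images, function(im) im$channel_name, character(1)),
                         hs, ws), collapse = ", ")
    stop(sprintf("channel geometries differ (%s)", geo), call. = FALSE)
  }
  nms <- vapply(images, function(im) im$channel_name, character(1))
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate channel names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(channels = images, n_channels = length(images),
         height = hs[1L], width = ws[1L], channel_names = nms),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("<spectral_cube> %d channels (%s), %d x %d\n",
              x$n_channels, paste(x$channel_names, collapse = ", "),
              x$height, x$width))
  invisible(x)
}

#' Write an RGB composite to disk
#'
#' Writes the three 8-bit planes of an [compose_rgb()] result as a standard
#' RGB TIFF or PNG (by extension). Re-reading yields identical planes.
#'
#' @param rgb An `rgb_composite` (or a height x width x 3 array of integers
#'   in \[0, 255\]).
#' @param path Destination path ending in .tif/.tiff/.png.
#' @return `path`, invisibly.
#' @export
write_composite <- function(rgb, path) {
  if (inherits(rgb, "rgb_composite")) {
    arr <- array(0, c(nrow(rgb$planes[[1L]]), ncol(rgb$planes[[1L]]), 3L))
    for (i in 1:3) arr[, , i] <- rgb$planes[[i]]
  } else if (is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3L] == 3L) {
    arr <- rgb
  } else {
    stop("`rgb` must be an rgb_composite or an h x w x 3 array", call. = FALSE)
  }
  if (min(arr) < 0 || max(arr) > 255) {
    stop("composite planes must be 8-bit (values in [0, 255])", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(arr / 255, path)
  } else {
    stop(sprintf("unsupported composite extension '.%s' (use TIFF or PNG)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Read an RGB composite written by [write_composite()]
#'
#' @param path Path to an 8-bit RGB TIFF or PNG.
#' @return List of three integer matrices (red, green, blue planes).
#' @export
read_composite <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop(sprintf("unsupported image extension '.%s'", ext), call. = FALSE)
  }
  if (length(dim(arr)) != 3L || !dim(arr)[3L] %in% c(3L, 4L)) {
    stop(sprintf("'%s' is not an RGB image", path), call. = FALSE)
  }
  lapply(1:3, function(i) round(unclass_matrix(arr[, , i]) * 255))
}
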