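#' Load a greyscale microscopy image
#'
#' Reads a PNG or TIFF image and returns it as a [grey_image()]. Colour
#' inputs are reduced to one channel: by default the red channel is kept,
#' since in phalloidin-stained confocal scans of osteocyte networks the
#' signal of interest lives in the red channel. A mean-luminance reduction
#' is available for other stains.
#'
#' @param path Path to a PNG or TIFF file with 1 or 3 channels.
#' @param channel Either `"red"` (default) or `"mean"` (average of the
#'   three channels, rounded).
#' @param pixel_size_nm Physical pixel size to attach (nm/px).
#' @return A [grey_image()].
#' @export
load_grey <- function(path, channel = c("red", "mean"), pixel_size_nm = 150) {
  channel <- match.arg(channel)
  arr <- read_image_array(path)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc == 2L || nc > 4L) {
      stop(sprintf("unsupported channel count (%d) in %s", nc, path),
           call. = FALSE)
    }
    if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(arr)[3] == 1L) {
      arr <- arr[, , 1]
    } else if (channel == "red") {
      arr <- arr[, , 1]
    } else {
      arr <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    }
  }
  if (length(dim(arr)) != 2L) {
    stop(sprintf("not a 2D image: %s", path), call. = FALSE)
  }
  px <- round(pmin(pmax(arr * 255, 0), 255))
  grey_image(px, pixel_size_nm = pixel_size_nm)
}

#' Save a grey image
#'
#' Writes an 8-bit single-channel PNG or TIFF. Round-trips through
#' [load_grey()] are bit-identical.
#'
#' @param img A [grey_image()] or intensity matrix.
#' @param path Output path; format chosen from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
save_grey <- function(img, path) {
  px <- as_pixels(img)
  write_image_array(px / 255, path)
  invisible(path)
}

#' Load a 3-class segmentation mask
#'
#' Reads an indexed/greyscale PNG or TIFF whose pixel values encode the
#' three classes. The native dialect stores literal values 0/1/2 in an
#' 8-bit single-channel file; `value_map` adapts third-party masks that use
#' other codes (e.g. `c(0, 127, 255)`).
#'
#' @param path Path to the mask file.
#' @param value_map Integer vector of length 3 giving the file values that
#'   encode background, osteocyte and dendrite, in that order.
#' @return A [seg_mask()].
#' @export
load_mask <- function(path, value_map = c(0L, 1L, 2L)) {
  stopifnot(length(value_map) == 3L)
  arr <- read_image_array(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  vals <- round(arr * 255)
  bad <- setdiff(unique(as.vector(vals)), value_map)
  if (length(bad) > 0) {
    stop(sprintf("mask file %s contains values outside the mapping {%s}: %s",
                 path, paste(value_map, collapse = ","),
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  labels <- matrix(match(vals, value_map) - 1L, nrow = nrow(vals))
  seg_mask(labels)
}

#' Save a 3-class segmentation mask
#'
#' By default writes literal label values 0/1/2 into an 8-bit
#' single-channel file (bit-exact, toolchain-neutral). With
#' `palette = TRUE` an RGB visual rendering is written instead
#' (black background, red osteocytes, green dendrites); paletted exports
#' are for inspection and are not re-loadable with [load_mask()].
#'
#' @param mask A [seg_mask()] or label matrix.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param palette Write a colour visualisation instead of label values.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, palette = FALSE) {
  labels <- as_labels(mask)
  if (palette) {
    arr <- array(0, dim = c(nrow(labels), ncol(labels), 3))
    arr[, , 1][labels == 1L] <- 1
    arr[, , 2][labels == 2L] <- 1
    write_image_array(arr, path)
  } else {
    write_image_array(labels / 255, path)
  }
  invisible(path)
}

# ---- format backends ----------------------------------------------------

read_image_array <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  arr
}

write_image_array <- function(arr, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L,
                           compression = "none"),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  invisible(path)
}
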