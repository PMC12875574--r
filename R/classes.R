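#' @title Core containers
#' @description Lightweight S3 containers used throughout the package:
#'   `grey_image` holds a 2D 8-bit intensity grid plus its physical pixel
#'   size; `seg_mask` holds a 3-class label map over \{0 = background,
#'   1 = osteocyte, 2 = dendrite\}.
#' @name osteoconnect-classes
NULL

#' Class codes of a segmentation mask
#'
#' Integer label values used in [seg_mask()] objects.
#' @format Named integer vector with entries `background`, `osteocyte`,
#'   `dendrite`.
#' @export
MASK_CLASSES <- c(background = 0L, osteocyte = 1L, dendrite = 2L)

#' Construct a grey image
#'
#' @param pixels Numeric or integer matrix of intensities in `[0, 255]`.
#'   Rows index the image y axis (top to bottom), columns the x axis.
#' @param pixel_size_nm Physical size of one pixel in nanometres. The
#'   default of 150 nm/px matches a 75 um field imaged at 500x500 px.
#' @return A `grey_image` object.
#' @examples
#' img <- grey_image(matrix(0L, 8, 8))
#' dim(img$pixels)
#' @export
grey_image <- function(pixels, pixel_size_nm = 150) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (any(dim(pixels) < 1L)) stop("image dimensions must be >= 1", call. = FALSE)
  if (anyNA(pixels)) stop("image intensities must not be NA", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "grey_image")
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d px, %.0f nm/px, intensity range [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a 3-class segmentation mask
#'
#' @param labels Integer matrix over \{0, 1, 2\} (background, osteocyte,
#'   dendrite), same shape as the paired image.
#' @return A `seg_mask` object.
#' @examples
#' m <- seg_mask(matrix(0L, 8, 8))
#' table(m$labels)
#' @export
seg_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2))
  if (length(bad) > 0) {
    stop(sprintf("mask contains values outside {0,1,2}: %s",
                 paste(sort(bad), collapse = ", ")), call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2,
                      labels = names(MASK_CLASSES)))
  cat(sprintf("<seg_mask> %d x %d px: %s\n", nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Coerce grey_image | matrix -> integer pixel matrix
as_pixels <- function(img) {
  if (inherits(img, "grey_image")) return(img$pixels)
  if (is.matrix(img)) {
    storage.mode(img) <- "integer"
    return(img)
  }
  stop("expected a grey_image or a matrix", call. = FALSE)
}

# Coerce seg_mask | matrix -> integer label matrix
as_labels <- function(mask) {
  if (inherits(mask, "seg_mask")) return(mask$labels)
  if (is.matrix(mask)) return(seg_mask(mask)$labels)
  stop("expected a seg_mask or a matrix", call. = FALSE)
}

# Coerce to logical matrix (binary mask)
as_binary <- function(mask) {
  if (inherits(mask, "seg_mask")) return(mask$labels > 0L)
  if (is.matrix(mask)) {
    if (is.logical(mask)) return(mask)
    return(mask > 0)
  }
  stop("expected a binary matrix", call. = FALSE)
}

pixel_size_of <- function(img, default = 150) {
  if (inherits(img, "grey_image")) img$pixel_size_nm else default
}
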