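#' Inverse component-size penalty for fragmented dendrite masks
#'
#' Scores a binary dendrite mask by `lambda * sum over components of
#' 1 / size(component)`, the discrete form of the connected-component
#' regulariser used to discourage short, isolated dendrite fragments
#' during model training: merging two fragments of sizes a and b into one
#' of size a + b strictly lowers the penalty, since
#' `1/(a+b) < 1/a + 1/b`. An empty mask scores 0.
#'
#' @param mask Logical or 0/1 matrix of dendrite pixels.
#' @param lambda Penalty scale (>= 0).
#' @param connectivity 4 or 8 (see [label_components()]).
#' @param min_size_px Optional: components smaller than this are weighted
#'   maximally (as if of size 1). `NULL` disables the floor.
#' @param normalize `"none"` (default) or `"per_component_mean"`, which
#'   divides the sum by the number of components.
#' @return A nonnegative scalar.
#' @examples
#' m <- matrix(0, 4, 4); m[1:4, 1] <- 1  # one component of 4 px
#' component_size_penalty(m)             # 1/4
#' @export
component_size_penalty <- function(mask, lambda = 1, connectivity = 8,
                                   min_size_px = NULL,
                                   normalize = c("none",
                                                 "per_component_mean")) {
  normalize <- match.arg(normalize)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  lab <- label_components(as_binary(mask), connectivity)
  k <- max(lab)
  if (k == 0L) return(0)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  if (!is.null(min_size_px)) sizes[sizes < min_size_px] <- 1L
  pen <- lambda * sum(1 / sizes)
  if (normalize == "per_component_mean") pen <- pen / k
  pen
}

#' Dilate selected classes of a label mask
#'
#' Thickens the selected classes with a square kernel, the label-dilation
#' strategy used to compensate for under-annotated thin dendrites (typical
#' kernels: 2 x 2 and 3 x 3). Collisions between foreground classes are
#' resolved osteocyte-first: a dilated dendrite never overwrites an
#' osteocyte pixel, while a dilated osteocyte does overwrite dendrite
#' pixels. Pixels of the dilated class itself are never removed.
#'
#' A 2 x 2 kernel has no centre pixel; it is anchored on its bottom-right
#' element, so the original pixels are kept and growth is biased towards
#' the top-left by half a pixel relative to odd kernels.
#'
#' @param mask A [seg_mask()] or label matrix.
#' @param kernel_px Square kernel side (2 and 3 are the intended values;
#'   any >= 2 is accepted).
#' @param classes Class ids to dilate (nonempty subset of 1:2).
#' @return A [seg_mask()].
#' @export
dilate_labels <- function(mask, kernel_px = 3L, classes = 2L) {
  labels <- as_labels(mask)
  if (length(classes) == 0L) {
    stop("`classes` must name at least one class", call. = FALSE)
  }
  bad <- setdiff(classes, 1:2)
  if (length(bad)) {
    stop(sprintf("cannot dilate class id(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (kernel_px < 2) stop("`kernel_px` must be >= 2", call. = FALSE)
  kern <- se_box(as.integer(kernel_px))
  out <- labels
  for (k in sort(as.integer(classes))) {       # osteocyte (1) first
    grown <- binary_dilate(labels == k, kern)
    if (k == 1L) {
      out[grown] <- 1L                          # osteocyte-first precedence
    } else {
      out[grown & out != 1L] <- 2L              # never overwrite osteocytes
    }
  }
  # dilation must never remove a labelled pixel of a protected class
  out[labels == 1L] <- 1L
  seg_mask(out)
}
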