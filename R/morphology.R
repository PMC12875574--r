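#' @title Binary morphology helpers
#' @description Structuring elements and pixel-level primitives shared by
#'   the segmentation and connectomics stages: binary dilation, erosion
#'   and closing with explicit anchor control (needed for the even-sized
#'   2 x 2 and 4 x 4 elements), connected-component labelling with
#'   selectable 4/8 connectivity, and Zhang-Suen 2D thinning. The
#'   Euclidean distance transform is delegated to EBImage.
#' @name osteoconnect-morphology
NULL

#' Structuring elements
#'
#' `se_box(n)` is the n x n square; `se_ellipse4()` the discrete ellipse
#' inscribed in a 4 x 4 box (12 active pixels, corners off), used to dilate
#' osteocyte masks before component analysis; `se_cross2()` the 2 x 2
#' cross-shaped element (3 active pixels) used to dilate dendrite masks.
#' Even-sized elements have no centre pixel; they are anchored on the
#' pixel just right/below the geometric centre, so the origin always
#' belongs to the support (dilation never drops a pixel) and growth is
#' biased towards the top-left by half a pixel — immaterial for component
#' merging but documented for reproducibility.
#'
#' @param n Side length of the square element.
#' @return A 0/1 numeric matrix.
#' @export
se_box <- function(n = 3L) matrix(1, n, n)

#' @rdname se_box
#' @export
se_ellipse4 <- function() {
  i <- matrix(rep(1:4, 4), 4, 4)
  j <- t(i)
  k <- ((i - 2.5) / 2)^2 + ((j - 2.5) / 2)^2 <= 1
  matrix(as.numeric(k), 4, 4)
}

#' @rdname se_box
#' @export
se_cross2 <- function() rbind(c(0, 1), c(1, 1))

# Kernel support as (dr, dc) offsets relative to the anchor. The anchor
# is ceiling((side + 1) / 2): the centre for odd kernels; for even
# kernels the pixel just right/below centre, so the origin is part of
# the support (dilation stays extensive) and growth is biased towards
# the top-left by half a pixel, as documented in [se_box()].
kernel_offsets <- function(kern) {
  anchor <- c(ceiling((nrow(kern) + 1) / 2), ceiling((ncol(kern) + 1) / 2))
  sup <- which(kern > 0, arr.ind = TRUE)
  cbind(dr = sup[, 1] - anchor[1], dc = sup[, 2] - anchor[2])
}

# Minkowski dilation by shift-OR over the kernel offsets.
binary_dilate <- function(mask, kern) {
  m <- as_binary(mask)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  off <- kernel_offsets(kern)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(rs) < 1 || length(cs) < 1) next
    out[rs + dr, cs + dc] <- out[rs + dr, cs + dc] | m[rs, cs]
  }
  out
}

# Erosion over the same offset set. `pad` is the value assumed outside
# the image (background for plain erosion).
binary_erode <- function(mask, kern, pad = FALSE) {
  m <- as_binary(mask)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(TRUE, nr, nc)
  off <- kernel_offsets(kern)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    shifted <- matrix(pad, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    if (length(rs) >= 1 && length(cs) >= 1) {
      shifted[rs - dr, cs - dc] <- m[rs, cs]
    }
    out <- out & shifted
  }
  out
}

# Closing on a virtually extended canvas: the mask is embedded in a
# background border wide enough for the dilation to spill over, so the
# result is extensive everywhere (including at image borders) and an
# already-closed shape comes back unchanged.
binary_close <- function(mask, kern) {
  m <- as_binary(mask)
  pad <- max(dim(kern))
  nr <- nrow(m); nc <- ncol(m)
  big <- matrix(FALSE, nr + 2L * pad, nc + 2L * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- m
  out <- binary_erode(binary_dilate(big, kern), kern)
  out[pad + seq_len(nr), pad + seq_len(nc)]
}

#' Connected-component labelling
#'
#' Labels connected sets of foreground pixels with consecutive positive
#' integers (background stays 0). Labels are assigned in order of each
#' component's first pixel in column-major order, so the output is fully
#' deterministic.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 8 (default; diagonal neighbours connect, so a
#'   diagonally-touching dendrite trace is one process) or 4.
#' @return Integer matrix of component labels.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
#' max(label_components(m, 8))  # 1: diagonal contact
#' max(label_components(m, 4))  # 2
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  mask <- as_binary(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id[nb] > 0L
    from <- c(from, id[fg[ok]][hit])
    to <- c(to, id[nb][hit])
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = length(fg),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel by first occurrence in column-major pixel order
  relab <- match(memb, unique(memb))
  out[fg] <- relab
  out
}

#' Skeletonise a binary mask to 1-px width
#'
#' Zhang-Suen iterative thinning. Preserves 8-connectivity of each
#' component and retains line endpoints, so geodesic path lengths measured
#' on the skeleton track the centreline of elongated structures.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- as_binary(mask)
  nr <- nrow(m); nc <- ncol(m)
  # pad with one background pixel on each side
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- zs_deletable(p, step)
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1L), 2:(nc + 1L)]
}

# One Zhang-Suen sub-iteration: returns deletable-pixel mask.
zs_deletable <- function(p, step) {
  nr <- nrow(p); nc <- ncol(p)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  P1 <- p[ri, ci]
  P2 <- p[ri - 1L, ci];      P3 <- p[ri - 1L, ci + 1L]
  P4 <- p[ri, ci + 1L];      P5 <- p[ri + 1L, ci + 1L]
  P6 <- p[ri + 1L, ci];      P7 <- p[ri + 1L, ci - 1L]
  P8 <- p[ri, ci - 1L];      P9 <- p[ri - 1L, ci - 1L]
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
       (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
  if (step == 1) {
    cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
  } else {
    cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
  }
  del_core <- P1 & B >= 2 & B <= 6 & A == 1 & cond
  del <- matrix(FALSE, nr, nc)
  del[ri, ci] <- del_core
  del
}

# Euclidean distance transform (distance to nearest background pixel),
# via EBImage; returns a plain numeric matrix.
distance_transform <- function(mask) {
  m <- matrix(as.numeric(as_binary(mask)), nrow(mask))
  d <- EBImage::distmap(m, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask))
}
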