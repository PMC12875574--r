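#' Synthetic scene parameters
#'
#' Parameter set for the seeded synthetic osteocyte-network generator.
#' The generator emulates 2D confocal scans of phalloidin-stained cortical
#' bone: bright elliptical cell bodies, thin (1.5-3 px at 150 nm/px)
#' curvilinear dendritic processes, a ~3 px diffraction blur
#' (sigma = 1.5 px ~ 450 nm FWHM), additive noise, an illumination
#' gradient, and optional unlabelled artefacts (transiting blood vessels,
#' shrunken osteocytes) that act as distractors exactly as in real scans.
#'
#' Identical parameters and seed always produce byte-identical scenes.
#'
#' @param image_size Pixels per side of the square field (default 500,
#'   i.e. a 75 um field at 150 nm/px).
#' @param pixel_size_nm Physical pixel size (nm).
#' @param n_osteocytes Number of cell bodies; with
#'   `density_sampling = TRUE` it is the Poisson mean of the per-scene
#'   count.
#' @param density_sampling Draw the body count from a Poisson
#'   distribution (natural cohort-to-cohort variation).
#' @param body_axes_px Range of ellipse semi-axes for cell bodies (px).
#' @param dendrite_width_px Range of stroked dendrite widths (px).
#' @param connection_radius_px Maximum centre distance at which two
#'   bodies may be joined by a dendrite.
#' @param connection_prob Probability that an eligible pair is joined.
#' @param deadend_rate Expected dead-end dendrites per osteocyte
#'   (Poisson).
#' @param deadend_length_px Range of dead-end arc lengths (px).
#' @param min_separation_px Minimum centre-to-centre distance between
#'   bodies; the default, 4 x the largest semi-axis (= 2 x the largest
#'   full body axis), keeps bodies disjoint with a clear margin.
#' @param background_intensity,dendrite_intensity,body_intensity Clean
#'   render intensities (0-255). These are plausible-value choices for a
#'   confocal scan with moderate SNR, not measured values.
#' @param blur_sigma_px Gaussian PSF width (px); 0 disables blurring.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param illum_gradient Maximal fractional intensity fall-off across the
#'   field (0 disables).
#' @param blood_vessel,shrunken_osteocyte Render the named artefact into
#'   the image (never into the mask: artefacts are class 0 distractors).
#' @param avoid_overlaps If `TRUE`, dendrites are placed so that they
#'   keep a safety margin from all previously placed dendrites and from
#'   non-endpoint bodies (edges that cannot be routed are dropped, dead
#'   ends re-drawn or skipped). Produces "well separated" scenes on which
#'   graph recovery from the true mask is exact; crowded scans should
#'   leave it off, since real 2D projections do contain crossing
#'   canaliculi.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_size = 500L,
                         pixel_size_nm = 150,
                         n_osteocytes = 7,
                         density_sampling = FALSE,
                         body_axes_px = c(10, 20),
                         dendrite_width_px = c(1.5, 3),
                         connection_radius_px = 260,
                         connection_prob = 0.8,
                         deadend_rate = 20.9,
                         deadend_length_px = c(15, 60),
                         min_separation_px = NULL,
                         background_intensity = 10,
                         dendrite_intensity = 90,
                         body_intensity = 220,
                         blur_sigma_px = 1.5,
                         noise_sd = 5,
                         illum_gradient = 0.1,
                         blood_vessel = FALSE,
                         shrunken_osteocyte = FALSE,
                         avoid_overlaps = FALSE,
                         seed = NULL) {
  if (is.null(min_separation_px)) min_separation_px <- 4 * max(body_axes_px)
  p <- list(image_size = as.integer(image_size),
            pixel_size_nm = pixel_size_nm,
            n_osteocytes = n_osteocytes,
            density_sampling = isTRUE(density_sampling),
            body_axes_px = sort(body_axes_px),
            dendrite_width_px = sort(dendrite_width_px),
            connection_radius_px = connection_radius_px,
            connection_prob = connection_prob,
            deadend_rate = deadend_rate,
            deadend_length_px = sort(deadend_length_px),
            min_separation_px = min_separation_px,
            background_intensity = background_intensity,
            dendrite_intensity = dendrite_intensity,
            body_intensity = body_intensity,
            blur_sigma_px = blur_sigma_px,
            noise_sd = noise_sd,
            illum_gradient = illum_gradient,
            blood_vessel = isTRUE(blood_vessel),
            shrunken_osteocyte = isTRUE(shrunken_osteocyte),
            avoid_overlaps = isTRUE(avoid_overlaps),
            seed = seed)
  stopifnot(p$image_size >= 16L, p$pixel_size_nm > 0,
            p$n_osteocytes >= 0, all(p$body_axes_px > 0),
            all(p$dendrite_width_px > 0),
            p$connection_prob >= 0, p$connection_prob <= 1,
            p$deadend_rate >= 0, p$blur_sigma_px >= 0, p$noise_sd >= 0,
            p$illum_gradient >= 0, p$illum_gradient < 1)
  structure(p, class = "scene_params")
}

#' Cohort presets: young and aged osteocyte networks
#'
#' `young_scene_params()` encodes the reference condition: a mean of 7
#' osteocytes per 500 x 500 px field with a dead-end rate of 20.9 per
#' node (the per-image means of manually labelled validation data for
#' this imaging regime). `aged_scene_params()` derives the aged phenotype
#' from it: osteocyte density reduced by 38.03% and connection
#' probability by 43.3% (manually measured ageing changes), with dead
#' ends up and dead-end dendrite lengths down by configurable
#' direction-consistent factors.
#'
#' @param ... Overrides passed to [scene_params()].
#' @param density_drop,connectivity_drop Fractional decreases applied to
#'   the body count and connection probability.
#' @param deadend_gain Multiplier on the dead-end rate (> 1 = more
#'   blunted dendrites in the aged group).
#' @param length_scale Multiplier on dead-end dendrite lengths (< 1 =
#'   shorter processes in the aged group).
#' @return A `scene_params` list.
#' @export
young_scene_params <- function(...) {
  preset_params(list(n_osteocytes = 7, density_sampling = TRUE,
                     connection_prob = 0.8, deadend_rate = 20.9), ...)
}

# Merge preset defaults with user overrides (overrides win).
preset_params <- function(defaults, ...) {
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

#' @rdname young_scene_params
#' @export
aged_scene_params <- function(density_drop = 0.3803,
                              connectivity_drop = 0.433,
                              deadend_gain = 1.3,
                              length_scale = 0.75, ...) {
  preset_params(list(n_osteocytes = 7 * (1 - density_drop),
                     density_sampling = TRUE,
                     connection_prob = 0.8 * (1 - connectivity_drop),
                     deadend_rate = 20.9 * deadend_gain,
                     deadend_length_px = c(15, 60) * length_scale), ...)
}

#' @rdname young_scene_params
#' @details `sparse_scene_params()` is a validation preset: few, widely
#'   separated bodies, few dead ends, overlap avoidance on and image
#'   degradations off, so that the connectomics graph recovered from the
#'   true mask matches the generated ground truth exactly.
#' @export
sparse_scene_params <- function(...) {
  preset_params(list(n_osteocytes = 5, density_sampling = FALSE,
                     body_axes_px = c(10, 18), connection_radius_px = 240,
                     connection_prob = 0.6, deadend_rate = 2,
                     deadend_length_px = c(25, 60), min_separation_px = 140,
                     blur_sigma_px = 0, noise_sd = 0, illum_gradient = 0,
                     avoid_overlaps = TRUE), ...)
}

# ---- ground-truth network sampling -------------------------------------

#' Sample a ground-truth osteocyte network
#'
#' Places elliptical cell bodies with a minimum separation, joins nearby
#' pairs with smoothed random polyline dendrites, and attaches dead-end
#' dendrites (Poisson count per node). Fully determined by
#' `params$seed`.
#'
#' @param params A [scene_params()].
#' @return A `ground_truth_graph`: `nodes` (id, row, col, semi-axes,
#'   orientation, analytic area), `edges` (node_a, node_b, width_px,
#'   length_px, length_um), `deadends` (node, width_px, length_px,
#'   length_um), plus `edge_paths` / `deadend_paths` (lists of dense
#'   polylines in row/col coordinates) and the generating parameters.
#' @export
sample_network <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  size <- params$image_size
  n <- if (params$density_sampling) stats::rpois(1, params$n_osteocytes)
       else round(params$n_osteocytes)

  margin <- max(params$body_axes_px) + 3
  centres <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centres) < n) {
    attempts <- attempts + 1L
    if (attempts > 300L * max(n, 1L)) {
      stop(sprintf(
        "could not place %d osteocytes with min separation %.0f px in a %d px field",
        n, params$min_separation_px, size), call. = FALSE)
    }
    cand <- stats::runif(2, min = margin, max = size - margin)
    if (nrow(centres) == 0L ||
        all(sqrt(rowSums((centres - rep(cand, each = nrow(centres)))^2)) >=
            params$min_separation_px)) {
      centres <- rbind(centres, cand)
    }
  }

  nodes <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      a = numeric(0), b = numeric(0), theta = numeric(0),
                      area_px = numeric(0))
  if (n > 0L) {
    ax <- matrix(stats::runif(2 * n, params$body_axes_px[1],
                              params$body_axes_px[2]), n, 2)
    nodes <- data.frame(id = seq_len(n),
                        row = centres[, 1], col = centres[, 2],
                        a = pmax(ax[, 1], ax[, 2]),
                        b = pmin(ax[, 1], ax[, 2]),
                        theta = stats::runif(n, 0, pi))
    nodes$area_px <- round(pi * nodes$a * nodes$b)
  }

  occupied <- if (params$avoid_overlaps)
    matrix(FALSE, size, size) else NULL
  body_zone <- if (params$avoid_overlaps && n > 0L)
    body_proximity_zones(nodes, size,
                         pad = max(params$dendrite_width_px) / 2 + 4.5)
    else NULL

  ed_a <- integer(0); ed_b <- integer(0); ed_w <- numeric(0)
  ed_len <- numeric(0); edge_paths <- list()
  if (n >= 2L) {
    prs <- utils::combn(n, 2)
    for (q in seq_len(ncol(prs))) {
      i <- prs[1, q]; j <- prs[2, q]
      d <- sqrt((nodes$row[i] - nodes$row[j])^2 +
                (nodes$col[i] - nodes$col[j])^2)
      if (d > params$connection_radius_px) next
      if (stats::runif(1) > params$connection_prob) next
      w <- stats::runif(1, params$dendrite_width_px[1],
                        params$dendrite_width_px[2])
      placed <- place_edge_path(node_rec(nodes, i), node_rec(nodes, j),
                                w, size, params, occupied, body_zone,
                                exempt = c(i, j))
      if (is.null(placed)) next
      occupied <- placed$occupied
      edge_paths[[length(edge_paths) + 1L]] <- placed$path
      ed_a <- c(ed_a, i); ed_b <- c(ed_b, j); ed_w <- c(ed_w, w)
      ed_len <- c(ed_len, placed$length_px)
    }
  }

  de_node <- integer(0); de_w <- numeric(0); de_len <- numeric(0)
  deadend_paths <- list()
  if (n >= 1L && params$deadend_rate > 0) {
    for (i in seq_len(n)) {
      k <- stats::rpois(1, params$deadend_rate)
      if (k == 0L) next
      ni <- node_rec(nodes, i)
      # canaliculi radiate from the body: stratify launch angles around
      # the cell instead of drawing them independently
      base_ang <- stats::runif(1, 0, 2 * pi)
      for (q in seq_len(k)) {
        w <- stats::runif(1, params$dendrite_width_px[1],
                          params$dendrite_width_px[2])
        ang <- base_ang +
          2 * pi * (q - 1 + stats::runif(1, -0.3, 0.3)) / k
        placed <- place_deadend_path(ni, i, w, size, params,
                                     occupied, body_zone, ang)
        if (is.null(placed)) next
        occupied <- placed$occupied
        deadend_paths[[length(deadend_paths) + 1L]] <- placed$path
        de_node <- c(de_node, i); de_w <- c(de_w, w)
        de_len <- c(de_len, placed$length_px)
      }
    }
  }

  edges <- data.frame(node_a = ed_a, node_b = ed_b, width_px = ed_w,
                      length_px = ed_len,
                      length_um = ed_len * params$pixel_size_nm / 1000)
  deadends <- data.frame(node = de_node, width_px = de_w,
                         length_px = de_len,
                         length_um = de_len * params$pixel_size_nm / 1000)
  structure(list(nodes = nodes, edges = edges, deadends = deadends,
                 edge_paths = edge_paths, deadend_paths = deadend_paths,
                 params = params),
            class = "ground_truth_graph")
}

#' @export
print.ground_truth_graph <- function(x, ...) {
  cat(sprintf("<ground_truth_graph> %d nodes, %d edges, %d dead ends\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$deadends)))
  invisible(x)
}

# Plain-list view of one node row (avoids data.frame indexing overhead
# in the per-dendrite placement loops).
node_rec <- function(nodes, i) {
  list(row = nodes$row[i], col = nodes$col[i], a = nodes$a[i],
       b = nodes$b[i], theta = nodes$theta[i])
}

# Point on the ellipse boundary of node i in direction (ur, uc).
ellipse_boundary_point <- function(node, ur, uc) {
  ct <- cos(node$theta); st <- sin(node$theta)
  # rotate direction into the ellipse frame (axes a along theta)
  du <- ur * ct + uc * st
  dv <- -ur * st + uc * ct
  t <- 1 / sqrt((du / node$a)^2 + (dv / node$b)^2)
  c(node$row + t * ur, node$col + t * uc)
}

# Smooth polyline through control points; returns dense (~1 px step) path.
smooth_path <- function(ctrl) {
  k <- nrow(ctrl)
  if (k == 2L) {
    n_out <- max(2L, ceiling(sqrt(sum((ctrl[2, ] - ctrl[1, ])^2))))
    t <- seq(0, 1, length.out = n_out + 1L)
    return(cbind(ctrl[1, 1] + t * (ctrl[2, 1] - ctrl[1, 1]),
                 ctrl[1, 2] + t * (ctrl[2, 2] - ctrl[1, 2])))
  }
  chord <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  n_out <- max(8L, ceiling(chord[k]))
  tt <- seq(0, chord[k], length.out = n_out + 1L)
  cbind(stats::spline(chord, ctrl[, 1], xout = tt, method = "natural")$y,
        stats::spline(chord, ctrl[, 2], xout = tt, method = "natural")$y)
}

path_arclength <- function(path) {
  if (nrow(path) < 2L) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

clamp_path <- function(path, size) {
  cbind(pmin(pmax(path[, 1], 1.5), size - 0.5),
        pmin(pmax(path[, 2], 1.5), size - 0.5))
}

# Mark pixels within every body ellipse dilated by `pad` px; column k
# gives the zone of node k (stored as a list of pixel-index vectors).
body_proximity_zones <- function(nodes, size, pad = 3) {
  lapply(seq_len(nrow(nodes)), function(i) {
    nd <- nodes[i, ]
    r <- max(nd$a, nd$b) + pad
    rr <- max(1L, floor(nd$row - r)):min(size, ceiling(nd$row + r))
    cc <- max(1L, floor(nd$col - r)):min(size, ceiling(nd$col + r))
    gr <- matrix(rr, length(rr), length(cc))
    gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    e <- ellipse_field(gr - nd$row, gc - nd$col, nd$a + pad, nd$b + pad,
                       nd$theta)
    idx <- (gc[e <= 1] - 1L) * size + gr[e <= 1]
    as.integer(idx)
  })
}

ellipse_field <- function(dr, dc, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  du <- dr * ct + dc * st
  dv <- -dr * st + dc * ct
  (du / a)^2 + (dv / b)^2
}

# Pixel indices within `radius` of any path point (coarse disc stamping).
path_footprint <- function(path, radius, size) {
  pts <- resample_path(path, step = 1)
  r <- ceiling(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, ]
  pr <- rep(round(pts[, 1]), each = nrow(off)) + off$dr
  pc <- rep(round(pts[, 2]), each = nrow(off)) + off$dc
  ok <- pr >= 1 & pr <= size & pc >= 1 & pc <= size
  unique((pc[ok] - 1L) * size + pr[ok])
}

# Keep-out radius around an accepted path of width w: its own stroke
# half-width, the widest future stroke's half-width, and a 4 px gap that
# the 2x2/4x4 merging dilations plus 8-connectivity cannot bridge.
clearance_radius <- function(w, params) {
  w / 2 + max(params$dendrite_width_px) / 2 + 4
}

resample_path <- function(path, step = 0.25) {
  if (nrow(path) < 2L) return(path)
  seg <- sqrt(rowSums(diff(path)^2))
  keep <- c(TRUE, seg > 0)          # drop zero-length segments (clamping)
  path <- path[keep, , drop = FALSE]
  if (nrow(path) < 2L) return(path)
  s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  total <- s[length(s)]
  tt <- seq(0, total, by = step)
  if (tt[length(tt)] < total) tt <- c(tt, total)
  cbind(stats::approx(s, path[, 1], xout = tt)$y,
        stats::approx(s, path[, 2], xout = tt)$y)
}

# Attempt to route an edge dendrite between two node records.
place_edge_path <- function(ni, nj, w, size, params, occupied,
                            body_zone, exempt) {
  u <- c(nj$row - ni$row, nj$col - ni$col)
  u <- u / sqrt(sum(u^2))
  tries <- if (params$avoid_overlaps) 10L else 1L
  for (t in seq_len(tries)) {
    p1 <- ellipse_boundary_point(ni, u[1], u[2])
    p2 <- ellipse_boundary_point(nj, -u[1], -u[2])
    d <- sqrt(sum((p2 - p1)^2))
    n_ctrl <- sample(2:4, 1)
    frac <- seq_len(n_ctrl) / (n_ctrl + 1)
    perp <- c(-u[2], u[1])
    jit <- stats::rnorm(n_ctrl, 0, 0.06 * d)
    mid <- cbind(p1[1] + frac * (p2[1] - p1[1]) + jit * perp[1],
                 p1[2] + frac * (p2[2] - p1[2]) + jit * perp[2])
    ctrl <- rbind(p1, mid, p2)
    path <- clamp_path(smooth_path(ctrl), size)
    if (!params$avoid_overlaps) {
      return(list(path = path, length_px = path_arclength(path),
                  occupied = occupied))
    }
    if (path_is_clear(path, w, size, params, occupied, body_zone,
                      exempt_nodes = exempt)) {
      occupied[path_footprint(path, clearance_radius(w, params), size)] <- TRUE
      return(list(path = path, length_px = path_arclength(path),
                  occupied = occupied))
    }
  }
  NULL
}

# Attempt to place a dead-end dendrite leaving node i at (about) the
# requested launch angle; overlap-avoiding retries re-draw the angle.
place_deadend_path <- function(ni, i, w, size, params, occupied,
                               body_zone, angle) {
  tries <- if (params$avoid_overlaps) 30L else 1L
  for (t in seq_len(tries)) {
    ang <- if (t == 1L) angle else stats::runif(1, 0, 2 * pi)
    u <- c(cos(ang), sin(ang))
    len <- stats::runif(1, params$deadend_length_px[1],
                        params$deadend_length_px[2])
    p1 <- ellipse_boundary_point(ni, u[1], u[2])
    end <- p1 + len * u
    n_ctrl <- sample(1:2, 1)
    frac <- seq_len(n_ctrl) / (n_ctrl + 1)
    perp <- c(-u[2], u[1])
    jit <- stats::rnorm(n_ctrl, 0, 0.1 * len)
    mid <- cbind(p1[1] + frac * (end[1] - p1[1]) + jit * perp[1],
                 p1[2] + frac * (end[2] - p1[2]) + jit * perp[2])
    ctrl <- rbind(p1, mid, matrix(end, 1))
    path <- clamp_path(smooth_path(ctrl), size)
    if (!params$avoid_overlaps) {
      return(list(path = path, length_px = path_arclength(path),
                  occupied = occupied))
    }
    if (path_is_clear(path, w, size, params, occupied, body_zone,
                      exempt_nodes = i)) {
      occupied[path_footprint(path, clearance_radius(w, params), size)] <- TRUE
      return(list(path = path, length_px = path_arclength(path),
                  occupied = occupied))
    }
  }
  NULL
}

# TRUE when the path avoids existing dendrites and non-endpoint bodies.
path_is_clear <- function(path, w, size, params, occupied, body_zone,
                          exempt_nodes) {
  pts <- resample_path(path, step = 1)
  idx <- (round(pts[, 2]) - 1L) * size + round(pts[, 1])
  idx <- idx[idx >= 1 & idx <= size * size]
  if (any(occupied[idx])) return(FALSE)
  if (!is.null(body_zone)) {
    for (k in seq_along(body_zone)) {
      if (k %in% exempt_nodes) next
      if (any(idx %in% body_zone[[k]])) return(FALSE)
    }
  }
  TRUE
}

# ---- rendering ----------------------------------------------------------

#' Render a ground-truth network into an image and mask
#'
#' Rasterises cell bodies as filled ellipses (mask class 1) and dendrites
#' as stroked polylines of their sampled widths (mask class 2; body
#' pixels win ties), then produces the degraded image: clean render
#' scaled by the illumination field, convolved with a Gaussian PSF, plus
#' additive Gaussian noise, clipped to `[0, 255]`. The mask is the
#' pre-blur ground truth. Sub-pixel stroke widths are realised by
#' anti-aliased coverage, thresholded at 0.5 for the mask. Artefacts
#' (blood vessel, shrunken osteocytes) are rendered into the image only
#' and stay class 0 in the mask.
#'
#' @param graph A `ground_truth_graph` from [sample_network()].
#' @param params The [scene_params()] used to generate it.
#' @return List with `image` (a [grey_image()]) and `mask`
#'   (a [seg_mask()]).
#' @export
render_scene <- function(graph, params = graph$params) {
  stopifnot(inherits(graph, "ground_truth_graph"))
  if (!is.null(params$seed)) {
    set.seed((params$seed + 77003) %% 2147483647)
  }
  size <- params$image_size
  cov_d <- matrix(0, size, size)
  all_paths <- c(graph$edge_paths, graph$deadend_paths)
  all_widths <- c(graph$edges$width_px, graph$deadends$width_px)
  for (q in seq_along(all_paths)) {
    cov_d <- stroke_coverage(cov_d, all_paths[[q]], all_widths[q])
  }
  cov_b <- matrix(0, size, size)
  for (i in seq_len(nrow(graph$nodes))) {
    cov_b <- ellipse_coverage(cov_b, graph$nodes[i, ])
  }

  labels <- matrix(0L, size, size)
  labels[cov_d >= 0.5] <- 2L
  labels[cov_b >= 0.5] <- 1L
  mask <- seg_mask(labels)

  bg <- params$background_intensity
  img <- matrix(bg, size, size)
  img <- pmax(img, bg + (params$dendrite_intensity - bg) * cov_d)
  img <- pmax(img, bg + (params$body_intensity - bg) * cov_b)

  if (params$blood_vessel) {
    cov_v <- vessel_coverage(size)
    img <- pmax(img, bg + (180 - bg) * cov_v)
  }
  if (params$shrunken_osteocyte) {
    for (q in 1:2) {
      nd <- data.frame(row = stats::runif(1, 20, size - 20),
                       col = stats::runif(1, 20, size - 20),
                       a = stats::runif(1, 2, 4),
                       b = stats::runif(1, 2, 4),
                       theta = stats::runif(1, 0, pi))
      cov_s <- ellipse_coverage(matrix(0, size, size), nd)
      img <- pmax(img, bg + (60 - bg) * cov_s)
    }
  }

  if (params$illum_gradient > 0) {
    phi <- stats::runif(1, 0, 2 * pi)
    proj <- outer((seq_len(size) - 1) * cos(phi),
                  (seq_len(size) - 1) * sin(phi), "+")
    proj <- (proj - min(proj)) / max(max(proj) - min(proj), 1e-9)
    img <- img * (1 - params$illum_gradient * proj)
  }
  if (params$blur_sigma_px > 0) {
    img <- convolve_reflect(img, gaussian_kernel(params$blur_sigma_px))
  }
  if (params$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = grey_image(img, params$pixel_size_nm), mask = mask)
}

# Accumulate anti-aliased stroke coverage of one polyline into `cov`.
# Coverage = clamp(0.5 + (w/2 - distance to polyline), 0, 1); the path is
# processed in chunks so only local pixel neighbourhoods are touched.
stroke_coverage <- function(cov, path, w) {
  size <- nrow(cov)
  pts <- resample_path(path, step = 0.25)
  half <- w / 2
  chunk <- 16L
  n <- nrow(pts)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk, n)      # one point of overlap between chunks
    sub <- pts[s:e, , drop = FALSE]
    r0 <- max(1L, floor(min(sub[, 1]) - half - 1))
    r1 <- min(size, ceiling(max(sub[, 1]) + half + 1))
    c0 <- max(1L, floor(min(sub[, 2]) - half - 1))
    c1 <- min(size, ceiling(max(sub[, 2]) + half + 1))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    gr <- matrix(rr, length(rr), length(cc))
    gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    dmin <- matrix(Inf, length(rr), length(cc))
    for (k in seq_len(nrow(sub))) {
      dk <- sqrt((gr - sub[k, 1])^2 + (gc - sub[k, 2])^2)
      dmin <- pmin(dmin, dk)
    }
    loc <- pmin(pmax(0.5 + (half - dmin), 0), 1)
    cov[rr, cc] <- pmax(cov[rr, cc], loc)
  }
  cov
}

# Anti-aliased filled-ellipse coverage for one body.
ellipse_coverage <- function(cov, node) {
  size <- nrow(cov)
  r <- max(node$a, node$b) + 2
  rr <- max(1L, floor(node$row - r)):min(size, ceiling(node$row + r))
  cc <- max(1L, floor(node$col - r)):min(size, ceiling(node$col + r))
  gr <- matrix(rr, length(rr), length(cc))
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  e <- ellipse_field(gr - node$row, gc - node$col, node$a, node$b,
                     node$theta)
  # signed distance approximation: (1 - sqrt(e)) * min axis
  loc <- pmin(pmax(0.5 + (1 - sqrt(e)) * min(node$a, node$b), 0), 1)
  cov[rr, cc] <- pmax(cov[rr, cc], loc)
  cov
}

# A wide bright band transiting the field (image-only artefact).
vessel_coverage <- function(size) {
  ang <- stats::runif(1, 0, pi)
  offs <- stats::runif(1, 0.3, 0.7) * size
  u <- c(cos(ang), sin(ang))
  t <- seq(-size, 2 * size, by = 2)
  ctrl_t <- seq(-size, 2 * size, length.out = 5)
  wig <- stats::rnorm(5, 0, size * 0.05)
  wiggle <- stats::spline(ctrl_t, wig, xout = t)$y
  path <- cbind(offs * u[1] - t * u[2] + wiggle * u[1],
                offs * u[2] + t * u[1] + wiggle * u[2])
  keep <- path[, 1] > -20 & path[, 1] < size + 20 &
          path[, 2] > -20 & path[, 2] < size + 20
  if (!any(keep)) return(matrix(0, size, size))
  stroke_coverage(matrix(0, size, size), path[keep, , drop = FALSE],
                  w = stats::runif(1, 10, 18))
}

# ---- scene + cohort level ----------------------------------------------

#' Generate one synthetic scene
#'
#' Samples a ground-truth network and (optionally) renders it.
#'
#' @param params A [scene_params()].
#' @param render Render image and mask (set `FALSE` when only
#'   ground-truth graphs are needed, e.g. for large statistical
#'   simulations).
#' @return A `synthetic_scene`: `graph`, and when rendered `image` and
#'   `mask`.
#' @export
simulate_scene <- function(params = scene_params(), render = TRUE) {
  graph <- sample_network(params)
  out <- list(graph = graph, params = params)
  if (render) {
    r <- render_scene(graph, params)
    out$image <- r$image
    out$mask <- r$mask
  }
  structure(out, class = "synthetic_scene")
}

#' Generate a two-group cohort of synthetic scenes
#'
#' Per-scene seeds are derived deterministically from the master seed, so
#' the same call always reproduces the same cohort byte-for-byte. With
#' the default presets, group B encodes the aged phenotype direction:
#' lower osteocyte density, lower connectivity, shorter dendrites, more
#' dead ends.
#'
#' @param params_a,params_b [scene_params()] for the two groups
#'   (defaults: [young_scene_params()] and [aged_scene_params()]).
#' @param n_per_group Scenes per group (>= 1).
#' @param seed Master seed.
#' @param render Render images/masks (see [simulate_scene()]).
#' @return List with `group_a` and `group_b`, each a list of
#'   `synthetic_scene` objects.
#' @export
generate_cohort <- function(params_a = young_scene_params(),
                            params_b = aged_scene_params(),
                            n_per_group, seed = 1, render = TRUE) {
  stopifnot(n_per_group >= 1)
  set.seed(seed)
  seeds <- sample.int(2147483646, 2 * n_per_group)
  sim <- function(p, s) {
    p$seed <- s
    simulate_scene(p, render = render)
  }
  list(group_a = lapply(seeds[seq_len(n_per_group)],
                        function(s) sim(params_a, s)),
       group_b = lapply(seeds[n_per_group + seq_len(n_per_group)],
                        function(s) sim(params_b, s)))
}

#' Network metrics of a ground-truth graph
#'
#' Computes the same six summary metrics as [compute_metrics()], directly
#' from generated ground truth (no rasterisation or measurement error),
#' using each dendrite's drawn width as its diameter.
#'
#' @param graph A `ground_truth_graph`.
#' @return A `connectomics_metrics` list.
#' @export
graph_metrics <- function(graph) {
  stopifnot(inherits(graph, "ground_truth_graph"))
  n <- nrow(graph$nodes)
  um <- graph$params$pixel_size_nm / 1000
  ne <- nrow(graph$edges)
  all_w <- c(graph$edges$width_px, graph$deadends$width_px)
  connectomics_metrics(
    n_nodes = n,
    deadends_per_node = if (n) nrow(graph$deadends) / n else 0,
    connections_per_node = if (n) 2 * ne / n else 0,
    mean_connection_length_um = if (ne) mean(graph$edges$length_um) else 0,
    mean_connection_diameter_um = if (ne) mean(graph$edges$width_px) * um
                                  else 0,
    mean_network_diameter_um = if (length(all_w)) mean(all_w) * um else 0)
}
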