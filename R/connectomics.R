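#' Separate and dilate the two foreground classes
#'
#' Splits a 3-class mask into its osteocyte and dendrite binary masks and
#' dilates each: the osteocyte mask with the discrete ellipse inscribed in
#' a 4 x 4 box ([se_ellipse4()]), the dendrite mask with the 2 x 2 cross
#' element ([se_cross2()]). The dilation merges nearby fragments (e.g.
#' noisy dendrite predictions) that should represent a single entity, and
#' creates the pixel overlap used to detect dendrite-osteocyte contacts.
#'
#' @param mask A [seg_mask()] or label matrix.
#' @return List of logical matrices `osteocyte` and `dendrite`.
#' @export
dilate_classes <- function(mask) {
  labels <- as_labels(mask)
  list(osteocyte = binary_dilate(labels == 1L, se_ellipse4()),
       dendrite = binary_dilate(labels == 2L, se_cross2()))
}

# ---- skeleton geometry --------------------------------------------------

# Weighted pixel graph over skeleton coordinates (rows of [row, col]);
# 8-neighbour steps, axial weight 1, diagonal weight sqrt(2).
skeleton_pixel_graph <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(NULL)
  key <- paste(coords[, 1], coords[, 2])
  idx <- seq_len(n)
  names(idx) <- key
  from <- integer(0); to <- integer(0); w <- numeric(0)
  shifts <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_len(nrow(shifts))) {
    nb_key <- paste(coords[, 1] + shifts[k, 1], coords[, 2] + shifts[k, 2])
    j <- idx[nb_key]
    hit <- !is.na(j)
    from <- c(from, idx[key[hit]])
    to <- c(to, unname(j[hit]))
    w <- c(w, rep(sqrt(sum(shifts[k, ]^2)), sum(hit)))
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n,
                          directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# Longest shortest path (in px) between skeleton endpoints; Inf entries
# from disconnected pieces are ignored, so the value is the largest
# within-piece geodesic. Returns 0 for a single-pixel skeleton.
skeleton_geodesic_px <- function(coords, g = NULL) {
  n <- nrow(coords)
  if (n <= 1L) return(0)
  if (is.null(g)) g <- skeleton_pixel_graph(coords)
  deg <- igraph::degree(g)
  ends <- which(deg <= 1L)
  if (length(ends) < 2L) ends <- seq_len(n)      # loops: search all pixels
  d <- igraph::distances(g, v = ends, to = ends)
  d <- d[is.finite(d)]
  if (length(d) == 0L) return(0)
  max(d)
}

#' Measure the centreline length of a dendrite component
#'
#' The component is skeletonised to 1-px width and its length taken as
#' the longest geodesic path along the skeleton, with axial steps counting
#' 1 px and diagonal steps `sqrt(2)` px. A component whose skeleton
#' collapses to a single pixel is assigned one pixel of length.
#'
#' @param component Logical or 0/1 matrix holding one dendrite component.
#' @param pixel_size_nm Physical pixel size (nm).
#' @return Length in micrometres.
#' @examples
#' m <- matrix(0, 5, 12); m[3, 2:11] <- 1          # 10-px straight line
#' measure_length(m)                               # 9 steps = 1.35 um
#' @export
measure_length <- function(component, pixel_size_nm = 150) {
  m <- as_binary(component)
  if (!any(m)) stop("component is empty", call. = FALSE)
  skel <- skeletonize(m)
  coords <- which(skel, arr.ind = TRUE)
  px <- skeleton_geodesic_px(coords)
  if (px == 0) px <- 1
  px * pixel_size_nm / 1000
}

#' Measure the mean diameter of a dendrite component
#'
#' The Euclidean distance transform of the component is sampled on its
#' skeleton and the diameter estimated as
#' `2 * mean(EDT) - 0.5` pixels. The -0.5 px correction accounts for
#' discretisation: the EDT measures to background pixel centres and so
#' overshoots the mask boundary by half a pixel per side (-1 px), while
#' the skeleton of even-width runs sits half a pixel off the true
#' centreline (+0.5 px on average).
#'
#' @inheritParams measure_length
#' @return Mean diameter in micrometres.
#' @examples
#' m <- matrix(0, 7, 12); m[3:5, 2:11] <- 1        # 3-px-wide ribbon
#' measure_diameter(m)                             # ~0.45 um at 150 nm/px
#' @export
measure_diameter <- function(component, pixel_size_nm = 150) {
  m <- as_binary(component)
  if (!any(m)) stop("component is empty", call. = FALSE)
  skel <- skeletonize(m)
  dt <- distance_transform(m)
  est <- 2 * mean(dt[skel]) - 0.5
  max(est, 0.5) * pixel_size_nm / 1000
}

# ---- graph construction -------------------------------------------------

#' Build an osteocyte connectomics graph from a segmentation mask
#'
#' Osteocyte components become nodes and dendrite components become the
#' connections between them. Both classes are dilated
#' ([dilate_classes()]) and connected-component labelled; each dendrite
#' component is then classified by the set of osteocyte components its
#' dilated support overlaps:
#' \itemize{
#'   \item touching >= 2 osteocytes: one connection per osteocyte pair
#'     among the touched set (the shared dendrite component contains no
#'     osteocyte pixels, so every such pair has an independent route that
#'     does not pass through another osteocyte; routes via intermediate
#'     osteocytes are never added);
#'   \item touching exactly 1: a dead end (terminus connection) of that
#'     node;
#'   \item touching 0: an orphan fragment, recorded but connecting
#'     nothing.
#' }
#' Connection lengths are geodesic skeleton path lengths between the two
#' osteocyte contact points; diameters are distance-transform estimates
#' sampled along that path. Lengths and diameters are measured on the
#' original (undilated) dendrite pixels, so the merging dilation does not
#' bias them.
#'
#' @param mask A [seg_mask()] or label matrix.
#' @param pixel_size_nm Physical pixel size (nm).
#' @param connectivity Component connectivity, 8 (default) or 4.
#' @param unique_partners If `TRUE`, two distinct dendrite components
#'   joining the same node pair count as one connection (degree-style);
#'   the default counts routes, not neighbours.
#' @param deadend_mode `"component"` (default): each single-contact
#'   dendrite component is one dead end. `"endpoint"`: every free skeleton
#'   endpoint (not touching an osteocyte) of a contacting component counts,
#'   attributed to the nearest contacted node.
#' @return An `osteocyte_graph`: `nodes` (id, centroid_row, centroid_col,
#'   area_px), `edges` (node_a, node_b, dendrite_component, length_um,
#'   diameter_um), `deadend_counts` (named per-node vector),
#'   `dendrite_components` (component, n_px, n_contacts, type, length_um,
#'   diameter_um), and `pixel_size_nm`.
#' @export
build_graph <- function(mask, pixel_size_nm = 150, connectivity = 8,
                        unique_partners = FALSE,
                        deadend_mode = c("component", "endpoint")) {
  deadend_mode <- match.arg(deadend_mode)
  labels <- as_labels(mask)
  osteo_bin <- labels == 1L
  dend_bin <- labels == 2L
  dil <- dilate_classes(labels)
  osteo_lab <- label_components(dil$osteocyte, connectivity)
  dend_lab <- label_components(dil$dendrite, connectivity)
  n_nodes <- max(osteo_lab)
  n_dend <- max(dend_lab)

  # node table from original osteocyte pixels inside each dilated label
  nodes <- data.frame(id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0))
  if (n_nodes > 0L) {
    ocoord <- which(osteo_bin, arr.ind = TRUE)
    olab <- osteo_lab[osteo_bin]
    nodes <- data.frame(
      id = seq_len(n_nodes),
      centroid_row = as.numeric(tapply(ocoord[, 1], olab, mean)[as.character(seq_len(n_nodes))]),
      centroid_col = as.numeric(tapply(ocoord[, 2], olab, mean)[as.character(seq_len(n_nodes))]),
      area_px = as.integer(tabulate(olab, nbins = n_nodes)))
  }

  skel <- skeletonize(dend_bin)
  dt <- distance_transform(dend_bin)
  um <- pixel_size_nm / 1000

  deadends <- integer(n_nodes)
  edges <- list()
  comps <- list()
  if (n_dend > 0L) {
    dcoord_all <- which(dend_bin, arr.ind = TRUE)
    dlab_orig <- dend_lab[dend_bin]
    scoord_all <- which(skel, arr.ind = TRUE)
    slab <- dend_lab[skel]
    ov_all <- which(dil$dendrite & dil$osteocyte)
    ov_dlab <- dend_lab[ov_all]
    ov_olab <- osteo_lab[ov_all]
    nr <- nrow(labels)
    ov_row <- ((ov_all - 1L) %% nr) + 1L
    ov_col <- ((ov_all - 1L) %/% nr) + 1L

    for (j in seq_len(n_dend)) {
      sc <- scoord_all[slab == j, , drop = FALSE]
      g_j <- skeleton_pixel_graph(sc)
      touched <- sort(unique(ov_olab[ov_dlab == j]))
      k <- length(touched)
      len_px <- skeleton_geodesic_px(sc, g_j)
      if (len_px == 0) len_px <- 1
      diam_px <- if (nrow(sc) > 0) max(2 * mean(dt[sc]) - 0.5, 0.5) else 1
      type <- if (k >= 2L) "edge" else if (k == 1L) "deadend" else "orphan"
      comps[[j]] <- data.frame(
        component = j, n_px = sum(dlab_orig == j), n_contacts = k,
        type = type, length_um = len_px * um, diameter_um = diam_px * um)

      if (k >= 2L) {
        contact_px <- contact_points(touched, j, ov_dlab, ov_olab,
                                     ov_row, ov_col, sc)
        prs <- utils::combn(k, 2)
        for (q in seq_len(ncol(prs))) {
          a <- touched[prs[1, q]]; b <- touched[prs[2, q]]
          pl <- path_measure(g_j, sc, contact_px[prs[1, q], ],
                             contact_px[prs[2, q], ], dt, len_px, diam_px)
          edges[[length(edges) + 1L]] <- data.frame(
            node_a = a, node_b = b, dendrite_component = j,
            length_um = pl$len_px * um, diameter_um = pl$diam_px * um)
        }
      }
      if (deadend_mode == "component") {
        if (k == 1L) deadends[touched] <- deadends[touched] + 1L
      } else if (k >= 1L && nrow(sc) > 0L) {
        free <- free_endpoints(g_j, sc, dil$osteocyte)
        if (length(free) > 0L) {
          cent <- nodes[nodes$id %in% touched, , drop = FALSE]
          for (fe in free) {
            d2 <- (cent$centroid_row - sc[fe, 1])^2 +
                  (cent$centroid_col - sc[fe, 2])^2
            nn <- cent$id[which.min(d2)]
            deadends[nn] <- deadends[nn] + 1L
          }
        }
      }
    }
  }

  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = integer(0), node_b = integer(0),
               dendrite_component = integer(0), length_um = numeric(0),
               diameter_um = numeric(0))
  if (unique_partners && nrow(edges) > 1L) {
    edges <- edges[!duplicated(edges[, c("node_a", "node_b")]), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  comps <- if (length(comps)) do.call(rbind, comps) else
    data.frame(component = integer(0), n_px = integer(0),
               n_contacts = integer(0), type = character(0),
               length_um = numeric(0), diameter_um = numeric(0))
  names(deadends) <- if (n_nodes > 0L) as.character(seq_len(n_nodes))
                     else character(0)
  structure(list(nodes = nodes, edges = edges, deadend_counts = deadends,
                 dendrite_components = comps,
                 pixel_size_nm = pixel_size_nm),
            class = "osteocyte_graph")
}

# Per touched osteocyte: the contact-region centroid and the nearest
# skeleton pixel. Returns a matrix with one row per touched node:
# (skeleton vertex index, centroid row, centroid col).
contact_points <- function(touched, j, ov_dlab, ov_olab, ov_row, ov_col,
                           sc) {
  t(vapply(touched, function(a) {
    sel <- ov_dlab == j & ov_olab == a
    cr <- mean(ov_row[sel]); cc <- mean(ov_col[sel])
    c(which.min((sc[, 1] - cr)^2 + (sc[, 2] - cc)^2), cr, cc)
  }, numeric(3)))
}

# Length/diameter of the skeleton path between two contact points. The
# geodesic (axial step 1 px, diagonal sqrt(2) px) is completed at both
# ends by the straight-line gap between the skeleton terminus and the
# contact-region centroid, compensating the endpoint erosion of
# thinning. Falls back to the component-level values when the skeleton
# pieces are disconnected (possible when the merging dilation bridged
# fragments).
path_measure <- function(g, sc, cp_from, cp_to, dt, fallback_len,
                         fallback_diam) {
  v_from <- as.integer(cp_from[1]); v_to <- as.integer(cp_to[1])
  if (is.null(g) || nrow(sc) <= 1L || v_from == v_to) {
    return(list(len_px = fallback_len, diam_px = fallback_diam))
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = v_from, to = v_to, output = "both"))
  vp <- sp$vpath[[1]]
  if (length(vp) < 2L) {
    return(list(len_px = fallback_len, diam_px = fallback_diam))
  }
  len <- sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
  len <- len +
    sqrt((sc[v_from, 1] - cp_from[2])^2 + (sc[v_from, 2] - cp_from[3])^2) +
    sqrt((sc[v_to, 1] - cp_to[2])^2 + (sc[v_to, 2] - cp_to[3])^2)
  pxs <- sc[as.integer(vp), , drop = FALSE]
  diam <- max(2 * mean(dt[pxs]) - 0.5, 0.5)
  list(len_px = len, diam_px = diam)
}

# Skeleton endpoints (degree <= 1) not lying inside a dilated osteocyte.
free_endpoints <- function(g, sc, osteo_dil) {
  if (is.null(g)) {
    ends <- seq_len(nrow(sc))
  } else {
    ends <- which(igraph::degree(g) <= 1L)
  }
  ends[!osteo_dil[sc[ends, , drop = FALSE]]]
}

#' @export
print.osteocyte_graph <- function(x, ...) {
  cat(sprintf(
    "<osteocyte_graph> %d nodes, %d connections, %d dead ends, %d dendrite components\n",
    nrow(x$nodes), nrow(x$edges), sum(x$deadend_counts),
    nrow(x$dendrite_components)))
  invisible(x)
}

# ---- network metrics ----------------------------------------------------

#' Summary network metrics of an osteocyte graph
#'
#' The six per-image summary values: number of nodes, mean dead ends per
#' node, mean connections per node (`2 |edges| / n_nodes`), mean
#' connection length, mean connection diameter, and the mean diameter of
#' the whole dendrite network (averaged over all dendrite components —
#' connections, dead ends and orphans alike). A graph with no nodes
#' yields all zeros with a warning; a graph with no connections reports 0
#' for the connection length/diameter means.
#'
#' @param graph An `osteocyte_graph` from [build_graph()].
#' @return A `connectomics_metrics` named list.
#' @export
compute_metrics <- function(graph) {
  stopifnot(inherits(graph, "osteocyte_graph"))
  n <- nrow(graph$nodes)
  if (n == 0L) {
    warning("graph has no osteocyte nodes; all metrics set to 0",
            call. = FALSE)
    return(connectomics_metrics(0, 0, 0, 0, 0, 0))
  }
  ne <- nrow(graph$edges)
  connectomics_metrics(
    n_nodes = n,
    deadends_per_node = sum(graph$deadend_counts) / n,
    connections_per_node = 2 * ne / n,
    mean_connection_length_um = if (ne) mean(graph$edges$length_um) else 0,
    mean_connection_diameter_um = if (ne) mean(graph$edges$diameter_um)
                                  else 0,
    mean_network_diameter_um =
      if (nrow(graph$dendrite_components))
        mean(graph$dendrite_components$diameter_um) else 0)
}

connectomics_metrics <- function(n_nodes, deadends_per_node,
                                 connections_per_node,
                                 mean_connection_length_um,
                                 mean_connection_diameter_um,
                                 mean_network_diameter_um) {
  structure(list(n_nodes = n_nodes,
                 deadends_per_node = deadends_per_node,
                 connections_per_node = connections_per_node,
                 mean_connection_length_um = mean_connection_length_um,
                 mean_connection_diameter_um = mean_connection_diameter_um,
                 mean_network_diameter_um = mean_network_diameter_um),
            class = "connectomics_metrics")
}

#' @export
print.connectomics_metrics <- function(x, ...) {
  cat("<connectomics_metrics>\n")
  for (nm in names(x)) cat(sprintf("  %s: %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.connectomics_metrics <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Shortest path between two osteocytes, in connection hops
#'
#' Breadth-first shortest path on the connection graph. Unreachable pairs
#' return `Inf`.
#'
#' @param graph An `osteocyte_graph`.
#' @param node_a,node_b Node ids.
#' @return Hop count (0 for `node_a == node_b`), or `Inf`.
#' @export
shortest_path_length <- function(graph, node_a, node_b) {
  stopifnot(inherits(graph, "osteocyte_graph"))
  ids <- graph$nodes$id
  if (!(node_a %in% ids) || !(node_b %in% ids)) {
    stop("unknown node id", call. = FALSE)
  }
  g <- as_igraph(graph)
  d <- igraph::distances(g, v = as.character(node_a),
                         to = as.character(node_b), weights = NA)
  unname(d[1, 1])
}

#' Convert an osteocyte graph to igraph
#'
#' Vertices carry `name` (the node id), centroid and area attributes;
#' edges carry length, diameter and the originating dendrite component.
#'
#' @param graph An `osteocyte_graph`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "osteocyte_graph"))
  verts <- data.frame(name = as.character(graph$nodes$id),
                      centroid_row = graph$nodes$centroid_row,
                      centroid_col = graph$nodes$centroid_col,
                      area_px = graph$nodes$area_px,
                      stringsAsFactors = FALSE)
  ed <- graph$edges
  edf <- data.frame(from = as.character(ed$node_a),
                    to = as.character(ed$node_b),
                    length_um = ed$length_um,
                    diameter_um = ed$diameter_um,
                    dendrite_component = ed$dendrite_component,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = verts)
}

#' Export an osteocyte graph
#'
#' `write_connectome_graphml()` writes GraphML via igraph;
#' `write_connectome_json()` writes a plain JSON document with node,
#' edge, dead-end and dendrite-component tables.
#'
#' @param graph An `osteocyte_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectome_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_connectome_graphml
#' @export
write_connectome_json <- function(graph, path) {
  obj <- list(pixel_size_nm = graph$pixel_size_nm,
              nodes = graph$nodes,
              edges = graph$edges,
              deadend_counts = as.list(graph$deadend_counts),
              dendrite_components = graph$dendrite_components)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
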