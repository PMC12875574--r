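# Small hand-built scenes: blobs are osteocytes (class 1), lines are
# dendrites (class 2); expected topology is enumerable by eye.

blob <- function(m, rows, cols, class = 1L) {
  m[rows, cols] <- class
  m
}

test_that("class dilation merges nearby fragments and keeps masks apart", {
  empty <- dilate_classes(matrix(0L, 8, 8))
  expect_false(any(empty$osteocyte) || any(empty$dendrite))

  # two osteocyte blobs 2 px apart fuse into one component
  m <- matrix(0L, 16, 16)
  m <- blob(m, 5:8, 3:6); m <- blob(m, 5:8, 9:12)
  expect_equal(max(flood_fill_label(m == 1L, 8)), 2L)
  d <- dilate_classes(m)
  expect_equal(max(label_components(d$osteocyte, 8)), 1L)
  expect_identical(label_components(d$osteocyte, 8),
                   flood_fill_label(d$osteocyte, 8))
})

test_that("dilation never increases the component count of a class", {
  set.seed(15)
  for (r in 1:10) {
    m <- matrix(0L, 20, 20)
    m[random_mask(20, 20, 0.12)] <- 1L
    m[random_mask(20, 20, 0.08) & m == 0L] <- 2L
    d <- dilate_classes(m)
    expect_lte(max(label_components(d$osteocyte, 8)),
               max(flood_fill_label(m == 1L, 8)))
    expect_lte(max(label_components(d$dendrite, 8)),
               max(flood_fill_label(m == 2L, 8)))
  }
})

test_that("two blobs joined by one line give 2 nodes, 1 edge, 0 dead ends", {
  m <- matrix(0L, 20, 30)
  m <- blob(m, 8:12, 3:7)
  m <- blob(m, 8:12, 22:26)
  m <- blob(m, 10, 8:21, class = 2L)
  g <- build_graph(m, pixel_size_nm = 150)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(sum(g$deadend_counts), 0L)
  expect_equal(g$dendrite_components$type, "edge")
  # 14-px line spans ~13 steps plus the two contact completions
  expect_gt(g$edges$length_um, 1.5)
  expect_lt(g$edges$length_um, 3.0)
})

test_that("a protruding line is a dead end of its only node", {
  m <- matrix(0L, 20, 25)
  m <- blob(m, 8:12, 3:7)
  m <- blob(m, 10, 8:20, class = 2L)
  g <- build_graph(m)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(unname(g$deadend_counts["1"]), 1L)
  met <- compute_metrics(g)
  expect_equal(met$deadends_per_node, 1)
  expect_equal(met$connections_per_node, 0)
})

test_that("chained blobs connect pairwise, never transitively", {
  m <- matrix(0L, 20, 46)
  m <- blob(m, 8:12, 3:7)        # A
  m <- blob(m, 8:12, 21:25)      # B
  m <- blob(m, 8:12, 39:43)      # C
  m <- blob(m, 10, 8:20, class = 2L)   # A-B
  m <- blob(m, 10, 26:38, class = 2L)  # B-C
  g <- build_graph(m)
  expect_equal(nrow(g$nodes), 3L)
  pairs <- sort(unname(apply(g$edges[, c("node_a", "node_b")], 1,
                             function(r) paste(sort(r), collapse = "-"))))
  # nodes are labelled in column-major order: A=1, B=2, C=3
  expect_equal(pairs, c("1-2", "2-3"))
  expect_equal(shortest_path_length(g, 1, 3), 2)
  expect_equal(shortest_path_length(g, 1, 2), 1)
})

test_that("a dendrite touching three osteocytes forms a clique", {
  m <- matrix(0L, 40, 40)
  m <- blob(m, 3:7, 3:7)         # A (top-left)
  m <- blob(m, 3:7, 33:37)       # B (top-right)
  m <- blob(m, 33:37, 18:22)     # C (bottom-centre)
  m <- blob(m, 5, 8:32, class = 2L)       # horizontal bar A-B
  m <- blob(m, 6:32, 20, class = 2L)      # stem down to C
  g <- build_graph(m)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 3L)          # pairwise among the contacts
  expect_equal(sum(g$deadend_counts), 0L)
})

test_that("duplicate routes count as routes unless unique_partners", {
  m <- matrix(0L, 20, 30)
  m <- blob(m, 5:14, 3:7)
  m <- blob(m, 5:14, 22:26)
  m <- blob(m, 7, 8:21, class = 2L)
  m <- blob(m, 12, 8:21, class = 2L)
  g <- build_graph(m)
  expect_equal(nrow(g$edges), 2L)
  g1 <- build_graph(m, unique_partners = TRUE)
  expect_equal(nrow(g1$edges), 1L)
  met <- compute_metrics(g)
  expect_equal(met$connections_per_node, 2 * 2 / 2)
})

test_that("dead-end counting supports component and endpoint conventions", {
  # one Y-shaped dendrite component: one contact, two free tips
  m <- matrix(0L, 24, 28)
  m <- blob(m, 9:13, 3:6)
  m <- blob(m, 11, 7:14, class = 2L)
  for (k in 0:5) {
    m[11 - 1 - k, 15 + k] <- 2L   # upper branch
    m[11 + 1 + k, 15 + k] <- 2L   # lower branch
  }
  m[11, 15] <- 2L                  # junction
  g_comp <- build_graph(m)
  g_tip <- build_graph(m, deadend_mode = "endpoint")
  expect_equal(sum(g_comp$deadend_counts), 1L)
  expect_equal(sum(g_tip$deadend_counts), 2L)
})

test_that("centreline lengths follow straight and diagonal geometry", {
  line <- matrix(0, 5, 12); line[3, 2:11] <- 1
  expect_equal(measure_length(line, 150), 9 * 0.150)
  diag_m <- matrix(0, 14, 14)
  for (i in 1:10) diag_m[2 + i, 2 + i] <- 1
  expect_equal(measure_length(diag_m, 150), 9 * sqrt(2) * 0.150)
  expect_error(measure_length(matrix(0, 3, 3)), "empty")
})

test_that("diameters track drawn ribbon widths", {
  rib <- function(w) {
    m <- matrix(0, w + 6, 20); m[4:(3 + w), 3:18] <- 1; m
  }
  d3 <- measure_diameter(rib(3), 150)
  expect_lt(abs(d3 - 0.45), 0.08)          # within the half-pixel floor
  d1 <- measure_diameter(rib(1), 150)
  expect_gte(d1, 0.075); expect_lte(d1, 0.225)
  expect_lt(measure_diameter(rib(2), 150), measure_diameter(rib(4), 150))
})

test_that("summary metrics handle edge and empty graphs", {
  expect_warning(met0 <- compute_metrics(build_graph(matrix(0L, 10, 10))),
                 "no osteocyte nodes")
  expect_true(all(unlist(met0) == 0))
  # disconnected pair is unreachable; unknown ids are rejected
  m <- matrix(0L, 20, 30)
  m <- blob(m, 3:6, 3:6); m <- blob(m, 14:17, 24:27)
  g <- build_graph(m)
  expect_equal(shortest_path_length(g, 1, 2), Inf)
  expect_equal(shortest_path_length(g, 1, 1), 0)
  expect_error(shortest_path_length(g, 1, 9), "unknown node")
})

test_that("metrics are invariant to node relabelling (mirrored scene)", {
  sc <- simulate_scene(sparse_scene_params(seed = 12))
  g1 <- compute_metrics(build_graph(sc$mask$labels))
  g2 <- compute_metrics(build_graph(sc$mask$labels[nrow(sc$mask$labels):1, ]))
  # topology is exactly preserved; measured lengths may shift by the
  # half-pixel anchor bias of the even-sized dilation elements
  for (nm in c("n_nodes", "deadends_per_node", "connections_per_node")) {
    expect_equal(g1[[nm]], g2[[nm]], label = nm)
  }
  for (nm in c("mean_connection_length_um", "mean_connection_diameter_um",
               "mean_network_diameter_um")) {
    expect_equal(g1[[nm]], g2[[nm]], tolerance = 0.05, label = nm)
  }
})

test_that("graphs export to GraphML and JSON", {
  m <- matrix(0L, 20, 30)
  m <- blob(m, 8:12, 3:7); m <- blob(m, 8:12, 22:26)
  m <- blob(m, 10, 8:21, class = 2L)
  g <- build_graph(m)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  write_connectome_graphml(g, f1)
  back <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_equal(igraph::ecount(back), 1)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_connectome_json(g, f2)
  obj <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(nrow(obj$nodes), 2)
})
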