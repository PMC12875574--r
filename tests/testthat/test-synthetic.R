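test_that("identical parameters and seed reproduce scenes byte for byte", {
  p <- sparse_scene_params(seed = 9)
  s1 <- simulate_scene(p); s2 <- simulate_scene(p)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$mask$labels, s2$mask$labels)
  expect_identical(s1$graph$nodes, s2$graph$nodes)
  expect_identical(s1$graph$edges, s2$graph$edges)
  expect_identical(s1$graph$deadends, s2$graph$deadends)
  # a different seed gives a different scene
  s3 <- simulate_scene(sparse_scene_params(seed = 10))
  expect_false(identical(s1$image$pixels, s3$image$pixels))
})

test_that("degenerate and forced topologies come out as requested", {
  g0 <- sample_network(scene_params(n_osteocytes = 0, seed = 1))
  expect_equal(nrow(g0$nodes), 0L)
  expect_equal(nrow(g0$edges), 0L)
  g2 <- sample_network(scene_params(
    n_osteocytes = 2, connection_prob = 1, deadend_rate = 0,
    connection_radius_px = 800, seed = 4))
  expect_equal(nrow(g2$nodes), 2L)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(nrow(g2$deadends), 0L)
  expect_gt(g2$edges$length_um, 0)
})

test_that("infeasible packings error out after bounded retries", {
  expect_error(sample_network(scene_params(
    image_size = 64, n_osteocytes = 30, body_axes_px = c(6, 8),
    seed = 1)), "could not place")
})

test_that("ground-truth invariants hold across seeds", {
  for (s in c(2, 22, 222)) {
    g <- sample_network(young_scene_params(seed = s))
    if (nrow(g$edges) > 0) {
      expect_true(all(g$edges$node_a %in% g$nodes$id))
      expect_true(all(g$edges$node_b %in% g$nodes$id))
      expect_true(all(g$edges$node_a != g$edges$node_b))
      expect_true(all(g$edges$length_um > 0))
    }
    if (nrow(g$deadends) > 0) {
      expect_true(all(g$deadends$node %in% g$nodes$id))
      expect_true(all(g$deadends$length_um > 0))
    }
    # minimum separation respected
    if (nrow(g$nodes) >= 2) {
      d <- as.matrix(dist(g$nodes[, c("row", "col")]))
      diag(d) <- Inf
      expect_gte(min(d), g$params$min_separation_px)
    }
  }
})

test_that("rendered mask pixel counts match a rasterisation oracle", {
  size <- 64L
  params <- scene_params(image_size = size, n_osteocytes = 1,
                         blur_sigma_px = 0, noise_sd = 0,
                         illum_gradient = 0, seed = 1)
  # hand-built ground truth: one axis-aligned ellipse, one straight
  # horizontal dead-end dendrite of width 3
  nodes <- data.frame(id = 1L, row = 20, col = 20, a = 6, b = 4,
                      theta = 0, area_px = round(pi * 24))
  deadends <- data.frame(node = 1L, width_px = 3,
                         length_px = 15, length_um = 15 * 0.15)
  gt <- structure(list(
    nodes = nodes,
    edges = data.frame(node_a = integer(0), node_b = integer(0),
                       width_px = numeric(0), length_px = numeric(0),
                       length_um = numeric(0)),
    deadends = deadends,
    edge_paths = list(),
    deadend_paths = list(rbind(c(20, 30), c(20, 45))),
    params = params), class = "ground_truth_graph")
  r <- render_scene(gt, params)
  # ellipse oracle: pixel centres inside the implicit ellipse
  gr <- matrix(1:size, size, size)
  gc <- t(gr)
  inside <- ((gr - 20) / 6)^2 + ((gc - 20) / 4)^2 <= 1
  expect_equal(sum(r$mask$labels == 1L), sum(inside))
  expect_identical(which(r$mask$labels == 1L), which(inside))
  # stroke oracle: pixels within w/2 of the densely sampled centreline
  line_px <- brute_stroke_pixels(rbind(c(20, 30), c(20, 45)), 1.5, size)
  expect_identical(which(r$mask$labels == 2L), line_px)
})

test_that("without degradation, the image forms exactly on the mask", {
  sc <- simulate_scene(sparse_scene_params(seed = 6))
  bg <- sc$params$background_intensity
  fg_mask <- sc$mask$labels > 0L
  fg_img <- sc$image$pixels > bg
  # every labelled pixel is bright, and bright pixels beyond the mask are
  # only the anti-aliased sub-half-coverage rim
  expect_true(all(fg_img[fg_mask]))
  rim <- fg_img & !fg_mask
  near_fg <- osteoconnect:::binary_dilate(fg_mask, se_box(3))
  expect_true(all(near_fg[rim]))
})

test_that("artefacts perturb the image but never the mask", {
  base <- scene_params(image_size = 128, n_osteocytes = 2,
                       body_axes_px = c(6, 9), deadend_rate = 2,
                       seed = 13)
  g <- sample_network(base)
  plain <- render_scene(g, base)
  vessel <- base; vessel$blood_vessel <- TRUE
  withv <- render_scene(g, vessel)
  expect_identical(withv$mask$labels, plain$mask$labels)
  expect_false(identical(withv$image$pixels, plain$image$pixels))
  shr <- base; shr$shrunken_osteocyte <- TRUE
  withs <- render_scene(g, shr)
  expect_identical(withs$mask$labels, plain$mask$labels)
})

test_that("cohort generation is deterministic and encodes the phenotype", {
  c1 <- generate_cohort(n_per_group = 12, seed = 5, render = FALSE)
  c2 <- generate_cohort(n_per_group = 12, seed = 5, render = FALSE)
  n1 <- vapply(c1$group_a, function(s) nrow(s$graph$nodes), numeric(1))
  n2 <- vapply(c2$group_a, function(s) nrow(s$graph$nodes), numeric(1))
  expect_identical(n1, n2)
  expect_identical(c1$group_b[[3]]$graph$edges, c2$group_b[[3]]$graph$edges)
  # aged group is sparser on average (ground truth means)
  na <- mean(vapply(c1$group_a, function(s) nrow(s$graph$nodes), numeric(1)))
  nb <- mean(vapply(c1$group_b, function(s) nrow(s$graph$nodes), numeric(1)))
  expect_gt(na, nb)
  # identical params differ only by RNG stream
  cs <- generate_cohort(young_scene_params(), young_scene_params(),
                        n_per_group = 2, seed = 8, render = FALSE)
  expect_false(identical(cs$group_a[[1]]$graph$nodes,
                         cs$group_b[[1]]$graph$nodes))
})

test_that("more noise never helps segmentation on average", {
  quiet_p <- list(); noisy_p <- list()
  d_quiet <- c(); d_noisy <- c()
  for (s in 1:10) {
    base <- scene_params(image_size = 300, n_osteocytes = 4,
                         body_axes_px = c(8, 14), deadend_rate = 10,
                         noise_sd = 2, seed = 400 + s)
    g <- sample_network(base)
    r1 <- render_scene(g, base)
    noisy <- base; noisy$noise_sd <- 30
    r2 <- render_scene(g, noisy)
    m1 <- evaluate_segmentation(segment_image(r1$image), r1$mask)
    m2 <- evaluate_segmentation(segment_image(r2$image), r2$mask)
    d_quiet <- c(d_quiet, m1$dice_overall)
    d_noisy <- c(d_noisy, m2$dice_overall)
  }
  expect_gte(mean(d_quiet), mean(d_noisy))
})

test_that("ground-truth metrics summarise the generated graph", {
  g <- sample_network(sparse_scene_params(seed = 17))
  met <- graph_metrics(g)
  expect_equal(met$n_nodes, nrow(g$nodes))
  expect_equal(met$connections_per_node, 2 * nrow(g$edges) / nrow(g$nodes))
  expect_equal(met$deadends_per_node, nrow(g$deadends) / nrow(g$nodes))
  if (nrow(g$edges)) {
    expect_equal(met$mean_connection_length_um, mean(g$edges$length_um))
  }
})
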