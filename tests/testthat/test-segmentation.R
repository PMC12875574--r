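test_that("gaussian smoothing honours its limiting cases", {
  u <- grey_image(matrix(137L, 10, 10))
  expect_identical(gaussian_smooth(u, 2)$pixels, u$pixels)   # constant
  set.seed(2)
  img <- grey_image(matrix(sample(0:255, 100, TRUE), 10, 10))
  expect_identical(gaussian_smooth(img, 0)$pixels, img$pixels)
  expect_error(gaussian_smooth(img, -1), ">= 0")
})

test_that("an impulse smooths to the discrete kernel centre weight", {
  m <- matrix(0L, 25, 25); m[13, 13] <- 255L
  sm <- gaussian_smooth(grey_image(m), 2)
  k <- osteoconnect:::gaussian_kernel(2)
  centre <- k[ceiling(nrow(k) / 2), ceiling(ncol(k) / 2)]
  expect_equal(sm$pixels[13, 13], round(255 * centre))
  # and the response one pixel away matches the kernel's next weight
  expect_equal(sm$pixels[13, 14],
               round(255 * k[ceiling(nrow(k) / 2), ceiling(ncol(k) / 2) + 1]))
})

test_that("candidate split enumerates band membership exactly", {
  vals <- matrix(c(0L, 50L, 65L, 200L,
                   0L, 50L, 65L, 200L,
                   29L, 30L, 69L, 70L,
                   255L, 40L, 0L, 71L), 4, 4, byrow = TRUE)
  p <- segmentation_params(body_threshold = 70,
                           dendrite_noise_threshold = 40)
  cand <- split_candidates(vals, p)
  expect_identical(cand$osteocyte, vals >= 70)
  expect_identical(cand$dendrite, vals >= 40 & vals < 70)
  expect_false(any(cand$osteocyte & cand$dendrite))
  # empty image -> both masks empty
  z <- split_candidates(matrix(0L, 3, 3), p)
  expect_false(any(z$osteocyte) || any(z$dendrite))
  # constant bright image -> all osteocyte candidates
  b <- split_candidates(matrix(200L, 3, 3), p)
  expect_true(all(b$osteocyte) && !any(b$dendrite))
  # invert_split swaps the two roles
  ci <- split_candidates(vals, segmentation_params(
    body_threshold = 70, dendrite_noise_threshold = 40,
    invert_split = TRUE))
  expect_identical(ci$dendrite, cand$osteocyte)
  expect_identical(ci$osteocyte, cand$dendrite)
  expect_error(segmentation_params(dendrite_noise_threshold = 90),
               "below")
})

test_that("otsu equals the exhaustive variance maximiser", {
  # forced two-level split
  half <- matrix(c(rep(20L, 32), rep(220L, 32)), 8, 8)
  t_star <- otsu_threshold(half)
  expect_gte(t_star, 20); expect_lt(t_star, 220)
  expect_equal(t_star, brute_otsu(half))
  set.seed(31)
  for (r in 1:25) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_equal(otsu_threshold(img), brute_otsu(img))
  }
})

test_that("otsu clamp and degenerate inputs behave as specified", {
  low <- matrix(c(rep(10L, 8), rep(30L, 8)), 4, 4)
  expect_equal(otsu_threshold(low, clamp_min = 80), 80)
  expect_error(otsu_threshold(matrix(7L, 4, 4)), "constant")
  bin <- otsu_binarize(low, 80, max_value = 255)
  expect_true(all(bin %in% c(0L, 255L)))
  expect_false(any(bin > 0))                     # nothing above the clamp
})

test_that("canny finds step edges and ignores flat fields", {
  expect_false(any(canny_dendrites(matrix(100L, 16, 16), 70, 220)))
  step <- matrix(0L, 16, 16); step[, 9:16] <- 255L
  edges <- canny_dendrites(step, 70, 220)
  expect_true(all(rowSums(edges) == 1))          # 1-px vertical line
  expect_true(all(which(edges, arr.ind = TRUE)[, 2] %in% 8:9))
  expect_error(canny_dendrites(step, 220, 70), "strictly less")
})

test_that("canny covers a high-contrast dendrite after closing", {
  # bright 2-px-wide curvilinear process on dark background
  size <- 64
  path <- cbind(10 + (0:44) * 0.9, 8 + (0:44) + 4 * sin((0:44) / 7))
  truth <- matrix(FALSE, size, size)
  truth[brute_stroke_pixels(path, 1, size)] <- TRUE
  img <- matrix(0L, size, size); img[truth] <- 255L
  edges <- canny_dendrites(img, 70, 220)
  covered <- osteoconnect:::binary_close(edges, se_box(3))
  expect_gte(sum(covered & truth) / sum(truth), 0.5)
})

test_that("refine_and_merge closes gaps and gives osteocytes precedence", {
  dend <- matrix(FALSE, 5, 7); dend[3, c(2, 3, 5, 6)] <- TRUE
  osteo <- matrix(FALSE, 5, 7)
  out <- refine_and_merge(osteo, dend)
  expect_equal(out$labels[3, 4], 2L)             # gap filled
  # identical masks: dendrite class vanishes
  both <- matrix(FALSE, 5, 5); both[2:4, 2:4] <- TRUE
  out2 <- refine_and_merge(both, both)
  expect_false(any(out2$labels == 2L))
  expect_identical(out2$labels == 1L, both)
  # disjoint masks survive verbatim (closing cannot bridge them here)
  o <- matrix(FALSE, 8, 8); o[2, 2] <- TRUE
  d <- matrix(FALSE, 8, 8); d[7, 7] <- TRUE
  out3 <- refine_and_merge(o, d)
  expect_identical(out3$labels == 1L, o)
  expect_identical(out3$labels == 2L, d)
  expect_error(refine_and_merge(o, matrix(FALSE, 4, 4)), "shape")
})

test_that("the full pipeline is deterministic and classes partition", {
  expect_true(all(segment_image(grey_image(matrix(0L, 32, 32)))$labels == 0L))
  sc <- simulate_scene(young_scene_params(seed = 77))
  for (method in c("otsu", "canny")) {
    p <- segmentation_params(method)
    s1 <- segment_image(sc$image, p)
    s2 <- segment_image(sc$image, p)
    expect_identical(s1$labels, s2$labels)
    expect_true(all(s1$labels %in% 0:2))
  }
})

test_that("otsu and canny pipelines agree exactly on the osteocyte class", {
  sc <- simulate_scene(young_scene_params(seed = 78))
  s_otsu <- segment_image(sc$image, segmentation_params("otsu"))
  s_canny <- segment_image(sc$image, segmentation_params("canny"))
  expect_identical(s_otsu$labels == 1L, s_canny$labels == 1L)
})

test_that("parameter validation happens before any computation", {
  expect_error(segmentation_params(canny_low = 200, canny_high = 100),
               "strictly less")
  expect_error(segmentation_params(body_threshold = 300), "\\[0, 255\\]")
  expect_error(segmentation_params(closing_kernel_px = 0), ">= 1")
})
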