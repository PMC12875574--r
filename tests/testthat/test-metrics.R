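test_that("dice and iou reproduce their closed-form worked examples", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(dice(a, b), 0.5)       # 2*1 / (2+2)
  expect_equal(iou(a, b), 1 / 3)      # 1 / 3
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  disj <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2)
  expect_equal(dice(a, disj), 0)
  expect_equal(iou(a, disj), 0)
})

test_that("the both-empty convention defaults to 1 and is flaggable", {
  e <- matrix(FALSE, 3, 3)
  expect_equal(dice(e, e), 1)
  expect_equal(iou(e, e), 1)
  expect_true(is.nan(dice(e, e, empty_value = NaN)))
  expect_error(dice(e, matrix(FALSE, 2, 2)), "shape")
})

test_that("dice/iou match set-arithmetic brute force with the identity", {
  set.seed(41)
  for (r in 1:40) {
    p <- random_mask(8, 8, stats::runif(1, 0.1, 0.9))
    g <- random_mask(8, 8, stats::runif(1, 0.1, 0.9))
    d <- dice(p, g); j <- iou(p, g)
    expect_equal(d, brute_dice(p, g), tolerance = 1e-14)
    expect_equal(j, brute_iou(p, g), tolerance = 1e-14)
    expect_equal(d, dice(g, p))                     # symmetry
    expect_equal(j, iou(g, p))
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_lte(j, d + 1e-15)
  }
})

test_that("per-class evaluation matches manual enumeration on a 6x6 pair", {
  # ground truth: 2x2 osteocyte block, 3-px dendrite line
  gt <- matrix(0L, 6, 6)
  gt[2:3, 2:3] <- 1L
  gt[5, 2:4] <- 2L
  # prediction: osteocyte shifted by one column, dendrite 2/3 correct
  # plus one false positive
  pr <- matrix(0L, 6, 6)
  pr[2:3, 3:4] <- 1L
  pr[5, 3:4] <- 2L
  pr[1, 6] <- 2L
  m <- evaluate_segmentation(pr, gt)
  # osteocyte: |P|=4, |G|=4, |P&G|=2
  expect_equal(unname(m$dice_per_class["osteocyte"]), 2 * 2 / 8)
  expect_equal(unname(m$iou_per_class["osteocyte"]), 2 / 6)
  # dendrite: |P|=3, |G|=3, |P&G|=2
  expect_equal(unname(m$dice_per_class["dendrite"]), 2 * 2 / 6)
  expect_equal(unname(m$iou_per_class["dendrite"]), 2 / 4)
  expect_equal(m$mean_iou, mean(c(2 / 6, 2 / 4)))
  # overall foreground: |P|=7, |G|=7, |P&G|=4 (classes pooled)
  expect_equal(m$dice_overall, 2 * 4 / 14)
})

test_that("perfect and all-background predictions bound the metrics", {
  gt <- mask_from_sets(5, 5, osteo = 1:3, dend = 10:12)
  m1 <- evaluate_segmentation(gt, gt)
  expect_true(all(unlist(m1[c("dice_per_class", "iou_per_class")]) == 1))
  m0 <- evaluate_segmentation(mask_from_sets(5, 5), gt)
  expect_true(all(m0$dice_per_class == 0))
  expect_error(evaluate_segmentation(gt, gt, classes = 5), "unknown class")
})

test_that("background inclusion changes only the mean IoU pool", {
  gt <- mask_from_sets(6, 6, osteo = 1:4, dend = 20:22)
  pr <- mask_from_sets(6, 6, osteo = 2:5, dend = 21:23)
  m <- evaluate_segmentation(pr, gt)
  mb <- evaluate_segmentation(pr, gt, include_background = TRUE)
  expect_equal(m$iou_per_class[["osteocyte"]],
               mb$iou_per_class[["osteocyte"]])
  expect_length(mb$iou_per_class, 3)
  expect_equal(mb$mean_iou, mean(mb$iou_per_class))
})

test_that("batch evaluation reports both aggregation conventions", {
  set.seed(6)
  gts <- lapply(1:3, function(i)
    seg_mask(matrix(sample(0:2, 64, TRUE), 8, 8)))
  prs <- lapply(gts, function(g) {
    lab <- g$labels
    flip <- sample(length(lab), 8)
    lab[flip] <- (lab[flip] + 1L) %% 3L
    seg_mask(lab)
  })
  df <- evaluate_batch(prs, gts)
  expect_equal(nrow(df), 5)                  # 3 images + mean + pooled
  expect_setequal(df$image[4:5], c("mean", "pooled"))
  im <- df[df$image %in% as.character(1:3), ]
  expect_equal(df$mean_iou[df$image == "mean"], mean(im$mean_iou))
  # pooled row equals evaluation of the concatenated label maps
  pooled <- evaluate_segmentation(do.call(rbind, lapply(prs, function(x) x$labels)),
                                  do.call(rbind, lapply(gts, function(x) x$labels)))
  expect_equal(df$dice_overall[df$image == "pooled"], pooled$dice_overall)
})
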