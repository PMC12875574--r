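#' Dice score coefficient
#'
#' Spatial overlap between a predicted binary mask P and a ground-truth
#' mask G: `2|P n G| / (|P| + |G|)`. When both masks are empty the score
#' is 1 by convention (perfect agreement on "nothing present"); set
#' `empty_value = NaN` to flag that case instead.
#'
#' @param pred,truth Logical (or 0/1) matrices of equal shape.
#' @param empty_value Value returned when both masks are empty.
#' @return A number in `[0, 1]` (or `empty_value`).
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' dice(a, b)  # 2 * 1 / (2 + 2) = 0.5
#' @export
dice <- function(pred, truth, empty_value = 1) {
  pg <- check_pair(pred, truth)
  np <- sum(pg$p); ng <- sum(pg$g)
  if (np + ng == 0L) return(empty_value)
  2 * sum(pg$p & pg$g) / (np + ng)
}

#' Intersection over union (Jaccard index)
#'
#' `|P n G| / |P u G|`, with the same both-empty convention as [dice()].
#'
#' @inheritParams dice
#' @return A number in `[0, 1]` (or `empty_value`).
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' iou(a, b)  # 1 / 3
#' @export
iou <- function(pred, truth, empty_value = 1) {
  pg <- check_pair(pred, truth)
  u <- sum(pg$p | pg$g)
  if (u == 0L) return(empty_value)
  sum(pg$p & pg$g) / u
}

check_pair <- function(pred, truth) {
  p <- as_binary(pred); g <- as_binary(truth)
  if (!all(dim(p) == dim(g))) {
    stop("prediction and ground truth must share the same shape",
         call. = FALSE)
  }
  list(p = p, g = g)
}

#' Evaluate a 3-class segmentation against ground truth
#'
#' Per-class one-vs-rest Dice and IoU, their mean IoU, and an overall
#' foreground Dice. By default the mean IoU averages the osteocyte and
#' dendrite classes only (background excluded, matching the two-class
#' reporting convention for this task); `include_background = TRUE` adds
#' class 0. `dice_overall` is the Dice score of the union of all
#' foreground classes (any-structure vs any-structure), a single-number
#' summary of foreground localisation that ignores class confusion.
#'
#' @param pred,truth [seg_mask()] objects (or label matrices) of equal
#'   shape.
#' @param classes Integer class ids to evaluate (subset of 0:2).
#' @param include_background Include class 0 in `classes`/`mean_iou`.
#' @param empty_value Passed to [dice()]/[iou()].
#' @return A `seg_metrics` list: `dice_per_class`, `iou_per_class`
#'   (named numeric vectors), `mean_iou`, `dice_overall`.
#' @export
evaluate_segmentation <- function(pred, truth, classes = c(1L, 2L),
                                  include_background = FALSE,
                                  empty_value = 1) {
  p <- as_labels(pred); g <- as_labels(truth)
  if (!all(dim(p) == dim(g))) {
    stop("prediction and ground truth must share the same shape",
         call. = FALSE)
  }
  if (include_background) classes <- union(0L, classes)
  bad <- setdiff(classes, 0:2)
  if (length(bad)) {
    stop(sprintf("unknown class id(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cls_names <- names(MASK_CLASSES)[match(classes, MASK_CLASSES)]
  d <- vapply(classes, function(k) dice(p == k, g == k, empty_value),
              numeric(1))
  j <- vapply(classes, function(k) iou(p == k, g == k, empty_value),
              numeric(1))
  names(d) <- cls_names; names(j) <- cls_names
  structure(list(dice_per_class = d,
                 iou_per_class = j,
                 mean_iou = mean(j, na.rm = TRUE),
                 dice_overall = dice(p > 0L, g > 0L, empty_value)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat("<seg_metrics>\n")
  cat("  dice:", paste(sprintf("%s=%.3f", names(x$dice_per_class),
                               x$dice_per_class), collapse = "  "), "\n")
  cat("  iou: ", paste(sprintf("%s=%.3f", names(x$iou_per_class),
                               x$iou_per_class), collapse = "  "), "\n")
  cat(sprintf("  mean_iou=%.3f  dice_overall=%.3f\n",
              x$mean_iou, x$dice_overall))
  invisible(x)
}

#' Evaluate a batch of segmentations
#'
#' Per-image metrics plus both aggregation conventions: the per-image mean
#' of each metric and the pooled-pixel metric (all images concatenated
#' before computing overlap). The two differ when image difficulty varies.
#'
#' @param preds,truths Lists of masks of equal length.
#' @param classes Class ids to evaluate.
#' @return A data frame with one row per image plus `mean` and `pooled`
#'   summary rows; columns `image`, `dice_osteocyte`, `dice_dendrite`,
#'   `iou_osteocyte`, `iou_dendrite`, `mean_iou`, `dice_overall`.
#' @export
evaluate_batch <- function(preds, truths, classes = c(1L, 2L)) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1L)
  rows <- lapply(seq_along(preds), function(i) {
    m <- evaluate_segmentation(preds[[i]], truths[[i]], classes)
    metrics_row(as.character(i), m)
  })
  df <- do.call(rbind, rows)
  mean_row <- df[1, ]
  mean_row$image <- "mean"
  for (cn in setdiff(names(df), "image")) mean_row[[cn]] <- mean(df[[cn]])
  pool_p <- do.call(rbind, lapply(preds, as_labels))
  pool_g <- do.call(rbind, lapply(truths, as_labels))
  pooled <- metrics_row("pooled",
                        evaluate_segmentation(pool_p, pool_g, classes))
  rbind(df, mean_row, pooled)
}

metrics_row <- function(id, m) {
  data.frame(image = id,
             dice_osteocyte = unname(m$dice_per_class["osteocyte"]),
             dice_dendrite = unname(m$dice_per_class["dendrite"]),
             iou_osteocyte = unname(m$iou_per_class["osteocyte"]),
             iou_dendrite = unname(m$iou_per_class["dendrite"]),
             mean_iou = m$mean_iou,
             dice_overall = m$dice_overall,
             stringsAsFactors = FALSE)
}
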