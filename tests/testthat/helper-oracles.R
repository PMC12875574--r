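# Independent brute-force oracles used across the suite. These stay
# deliberately naive (per-pixel set arithmetic, explicit search,
# enumeration) and never share code with the implementation they check.

# Connected components by explicit stack-based flood fill, scanning in
# column-major order so labels are comparable with label_components().
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    offs <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Dice / IoU by explicit pixel-set arithmetic on index sets.
brute_dice <- function(p, g) {
  sp <- which(p); sg <- which(g)
  if (length(sp) + length(sg) == 0L) return(1)
  2 * length(intersect(sp, sg)) / (length(sp) + length(sg))
}

brute_iou <- function(p, g) {
  sp <- which(p); sg <- which(g)
  u <- length(union(sp, sg))
  if (u == 0L) return(1)
  length(intersect(sp, sg)) / u
}

# Otsu by exhaustive search over all 255 candidate splits, computing the
# between-class variance from raw values (no histogram); ties resolved
# towards the lowest threshold via strict improvement.
brute_otsu <- function(v) {
  v <- as.vector(v)
  best <- -Inf; t_best <- NA_integer_
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-9 * max(best, 1)) {
      best <- bcv
      t_best <- t
    }
  }
  t_best
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(n1 + n2, n1) group labelings.
perm_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  u_of <- function(idx) {
    xs <- comb[idx]; ys <- comb[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  centre <- n1 * n2 / 2
  labelings <- utils::combn(n1 + n2, n1)
  u_all <- apply(labelings, 2, u_of)
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

# Deterministic rasterisation oracle: pixels whose centre lies within
# `half` of a densely sampled polyline.
brute_stroke_pixels <- function(path, half, size) {
  s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  tt <- seq(0, s[length(s)], by = 0.05)
  pr <- stats::approx(s, path[, 1], xout = tt)$y
  pc <- stats::approx(s, path[, 2], xout = tt)$y
  hits <- matrix(FALSE, size, size)
  for (r in seq_len(size)) for (c in seq_len(size)) {
    if (min(sqrt((pr - r)^2 + (pc - c)^2)) <= half) hits[r, c] <- TRUE
  }
  which(hits)
}

# Small random binary mask.
random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Hand-buildable 3-class mask from a background matrix plus index sets.
mask_from_sets <- function(nr, nc, osteo = integer(0), dend = integer(0)) {
  m <- matrix(0L, nr, nc)
  m[osteo] <- 1L
  m[dend] <- 2L
  seg_mask(m)
}
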