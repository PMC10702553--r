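# Independent brute-force oracles used to cross-check the implementation.

# Confusion-matrix route to per-class Dice and binary accuracy.
conf_metrics_oracle <- function(pred, truth, code) {
  p <- factor(as.integer(pred) == code, levels = c(FALSE, TRUE))
  t <- factor(as.integer(truth) == code, levels = c(FALSE, TRUE))
  tab <- table(p, t)
  tp <- tab["TRUE", "TRUE"]
  fp <- tab["TRUE", "FALSE"]
  fn <- tab["FALSE", "TRUE"]
  tn <- tab["FALSE", "FALSE"]
  dice <- if (2 * tp + fp + fn == 0) 1.0 else 2 * tp / (2 * tp + fp + fn)
  list(dice = dice, accuracy = (tp + tn) / sum(tab))
}

# ICC(3,1) from an explicit two-way ANOVA fit (independent of the package's
# closed-form mean squares).
icc_oracle <- function(m) {
  df <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  fit <- stats::aov(value ~ subject + rater, data = df)
  tab <- summary(fit)[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16, !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    pos <- as.logical(bitwAnd(bits, 2^(seq_len(n) - 1)))
    sum(rk[pos])
  }, numeric(1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Eccentricity from the eigen-decomposition of the pixel-coordinate
# covariance (population scaling), independent of the package's closed form.
ecc_moment_oracle <- function(rows, cols) {
  n <- length(rows)
  cm <- cov(cbind(rows, cols)) * (n - 1) / n
  ev <- sort(eigen(cm, symmetric = TRUE)$values, decreasing = TRUE)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# Per-source BFS geodesic distances through a domain; assigns each domain
# pixel to the nearest seed component (ties -> smallest id). Slow, small
# images only.
geodesic_oracle <- function(seed_labels, domain) {
  nr <- nrow(seed_labels)
  nc <- ncol(seed_labels)
  ids <- sort(unique(seed_labels[seed_labels > 0]))
  dist_to <- lapply(ids, function(id) {
    d <- matrix(Inf, nr, nc)
    frontier <- which(seed_labels == id)
    d[frontier] <- 0
    level <- 0
    while (length(frontier) > 0) {
      level <- level + 1
      nxt <- integer(0)
      for (p in frontier) {
        r <- (p - 1) %% nr + 1
        c <- (p - 1) %/% nr + 1
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr
          cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          q <- (cc - 1) * nr + rr
          if (domain[q] && d[q] > level) {
            d[q] <- level
            nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
    d
  })
  out <- matrix(0L, nr, nc)
  for (p in which(domain)) {
    dd <- vapply(dist_to, function(d) d[p], numeric(1))
    if (all(is.infinite(dd))) next
    out[p] <- ids[which.min(dd)]
  }
  out
}

# Draw a mask containing a single rasterized circular annulus.
annulus_mask <- function(size, r, R, center = (size - 1) / 2, px = 0.05) {
  idx <- expand.grid(row = 0:(size - 1), col = 0:(size - 1))
  d2 <- (idx$row - center)^2 + (idx$col - center)^2
  m <- matrix(0L, size, size)
  m[d2 <= R^2] <- 1L
  m[d2 <= r^2] <- 2L
  label_mask(m, pixel_size_um = px)
}

# Strip mask classes/attributes down to the plain integer matrix.
mask_values <- function(m) matrix(as.integer(m), nrow(m), ncol(m))

# Match designed phantom fibers to extracted fibers by nearest centroid.
match_design <- function(design, fibers) {
  stopifnot(nrow(design) == nrow(fibers))
  idx <- vapply(seq_len(nrow(design)), function(i) {
    which.min((fibers$centroid_row - design$center_row[i])^2 +
              (fibers$centroid_col - design$center_col[i])^2)
  }, integer(1))
  stopifnot(!any(duplicated(idx)))
  idx
}
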