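# Independent oracles used to cross-check package computations. These are
# deliberately naive (brute force / textbook formulas) and share no code
# with the implementation paths they audit.

# digitized ellipsoid mask: voxel centers (0-based, times spacing) inside
# the analytic ellipsoid
ellipsoid_mask <- function(dims, center, radii, spacing = c(1, 1, 1)) {
  cx <- (seq_len(dims[1]) - 1) * spacing[1]
  cy <- (seq_len(dims[2]) - 1) * spacing[2]
  cz <- (seq_len(dims[3]) - 1) * spacing[3]
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  array(arr, dims)
}

ball_mask <- function(r = 10, margin = 3) {
  n <- 2 * (r + margin) + 1
  ellipsoid_mask(c(n, n, n), rep(r + margin, 3), rep(r, 3))
}

as_binary_mask <- function(vox, spacing = c(1, 1, 1)) {
  structure(list(voxels = vox, spacing_mm = as.numeric(spacing)),
            class = "binary_mask")
}

# O(n^2) brute-force diameters over mesh vertices, R loops only
oracle_diameters <- function(vertices, half_spacing) {
  n <- nrow(vertices)
  best <- c(0, 0, 0, 0)
  for (i in seq_len(n - 1)) {
    dv <- sweep(vertices[(i + 1):n, , drop = FALSE], 2, vertices[i, ])
    d2 <- rowSums(dv^2)
    best[1] <- max(best[1], d2)
    same_z <- abs(dv[, 3]) <= half_spacing[3]
    same_x <- abs(dv[, 1]) <= half_spacing[1]
    same_y <- abs(dv[, 2]) <= half_spacing[2]
    if (any(same_z)) best[2] <- max(best[2], d2[same_z])
    if (any(same_x)) best[3] <- max(best[3], d2[same_x])
    if (any(same_y)) best[4] <- max(best[4], d2[same_y])
  }
  sqrt(best)
}

# trapezoidal area under an ROC polyline
oracle_trapezoid_auc <- function(roc_points) {
  x <- roc_points$fpr; y <- roc_points$tpr
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

# textbook product-limit estimator (events precede censorings at ties)
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_i <- sum(time >= tt[i])
    d_i <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

# textbook two-group log-rank chi-square
oracle_logrank_chisq <- function(time, event, group) {
  g <- unique(group)
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) 0 else o_minus_e^2 / v
}
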