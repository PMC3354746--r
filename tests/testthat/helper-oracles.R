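# Independent oracles used by the tests. Each is a plain, brute-force
# computation kept deliberately separate from the package implementation.

# Optimal 2-cluster SSE of a 1-D sample by exhaustive search over the n-1
# contiguous splits of the sorted values (1-D optimal clusters are intervals).
best_split_sse <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (i in seq_len(n - 1)) {
    a <- xs[1:i]; b <- xs[(i + 1):n]
    s <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (s < best) best <- s
  }
  best
}

# Binary erosion/dilation with a 3x3 square on a logical matrix, written as
# plain shift compositions (out-of-bounds treated as background).
shift_mat <- function(m, dr, dc, fill = FALSE) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
  cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
erode3_ref <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) out <- out & shift_mat(m, dr, dc, FALSE)
  out
}
dilate3_ref <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) out <- out | shift_mat(m, dr, dc, FALSE)
  out
}

# One explicit step of the level-set curvature flow, written independently
# of the package operator (plain index arithmetic, replicate borders).
flow_step_ref <- function(a, h, dt) {
  sh <- function(x, dr = 0, dc = 0, ds = 0) {
    d <- dim(x)
    ri <- pmin(pmax(seq_len(d[1]) - dr, 1), d[1])
    ci <- pmin(pmax(seq_len(d[2]) - dc, 1), d[2])
    si <- pmin(pmax(seq_len(d[3]) - ds, 1), d[3])
    x[ri, ci, si, drop = FALSE]
  }
  rp <- sh(a, dr = -1); rm <- sh(a, dr = 1)
  cp <- sh(a, dc = -1); cm <- sh(a, dc = 1)
  sp <- sh(a, ds = -1); sm <- sh(a, ds = 1)
  Ix <- (rp - rm) / (2 * h[1]); Iy <- (cp - cm) / (2 * h[2])
  Iz <- (sp - sm) / (2 * h[3])
  Ixx <- (rp - 2 * a + rm) / h[1]^2
  Iyy <- (cp - 2 * a + cm) / h[2]^2
  Izz <- (sp - 2 * a + sm) / h[3]^2
  Ixy <- (sh(a, -1, -1) - sh(a, -1, 1) - sh(a, 1, -1) + sh(a, 1, 1)) / (4 * h[1] * h[2])
  Ixz <- (sh(a, dr = -1, ds = -1) - sh(a, dr = -1, ds = 1) -
            sh(a, dr = 1, ds = -1) + sh(a, dr = 1, ds = 1)) / (4 * h[1] * h[3])
  Iyz <- (sh(a, dc = -1, ds = -1) - sh(a, dc = -1, ds = 1) -
            sh(a, dc = 1, ds = -1) + sh(a, dc = 1, ds = 1)) / (4 * h[2] * h[3])
  g2 <- Ix^2 + Iy^2 + Iz^2
  num <- Ixx * (Iy^2 + Iz^2) + Iyy * (Ix^2 + Iz^2) + Izz * (Ix^2 + Iy^2) -
    2 * (Ix * Iy * Ixy + Ix * Iz * Ixz + Iy * Iz * Iyz)
  upd <- num / g2
  upd[g2 == 0] <- 0
  a + dt * upd
}
flow_ref <- function(a, h, dt, iters) {
  lo <- min(a); hi <- max(a)
  for (i in seq_len(iters)) a <- pmin(pmax(flow_step_ref(a, h, dt), lo), hi)
  a
}

# A noisy bright disk (stacked through all slices) on a dark background:
# the standard fixture for smoothing-filter behaviour.
noisy_disk_volume <- function(n = 64, seed = 99, sigma = 10) {
  set.seed(seed)
  ctr <- (n + 1) / 2
  rad <- n / 4
  sl <- outer(seq_len(n), seq_len(n),
              function(r, c) sqrt((r - ctr)^2 + (c - ctr)^2) <= rad)
  a <- array(rep(sl * 100, n), c(n, n, n)) + array(rnorm(n^3, 0, sigma), c(n, n, n))
  gray_volume(a, c(1, 1, 1))
}
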