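# Independent brute-force oracles. All are written as explicit loops with
# their own boundary handling (index clamping = edge replication), not as
# calls into the package's vectorized code paths.

# Clamped pixel lookup.
px <- function(m, i, j) {
  m[min(max(i, 1L), nrow(m)), min(max(j, 1L), ncol(m))]
}

oracle_heaviside <- function(t, eps) 0.5 * (1 + (2 / pi) * atan(t / eps))

# 3x3 neighborhood sum / (255 * 9) by direct loop.
oracle_alpha <- function(img, i, j) {
  s <- 0
  for (di in -1:1) for (dj in -1:1) s <- s + px(img, i + di, j + dj)
  s / (255 * 9)
}

oracle_cv_means <- function(img, phi, eps) {
  n1 <- d1 <- n2 <- d2 <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    h <- oracle_heaviside(phi[i, j], eps)
    n1 <- n1 + img[i, j] * h; d1 <- d1 + h
    n2 <- n2 + img[i, j] * (1 - h); d2 <- d2 + (1 - h)
  }
  gm <- mean(img)
  c(if (d1 < 1e-9) gm else n1 / d1, if (d2 < 1e-9) gm else n2 / d2)
}

oracle_cv_energy <- function(img, phi, mu, nu, l1, l2, eps) {
  cm <- oracle_cv_means(img, phi, eps)
  e <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    h <- oracle_heaviside(phi[i, j], eps)
    d <- eps / (pi * (eps^2 + phi[i, j]^2))
    gx <- (px(phi, i, j + 1) - px(phi, i, j - 1)) / 2
    gy <- (px(phi, i + 1, j) - px(phi, i - 1, j)) / 2
    g <- max(sqrt(gx^2 + gy^2), 1e-8)
    e <- e + mu * d * g + nu * h +
      l1 * (img[i, j] - cm[1])^2 * h + l2 * (img[i, j] - cm[2])^2 * (1 - h)
  }
  e
}

oracle_gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  list(k = k / sum(k), r = r)
}

# Kernel-weighted local means by quadruple loop with clamped taps.
oracle_lbf_fit <- function(img, phi, sigma, eps) {
  kk <- oracle_gauss_kernel(sigma)
  g1 <- g2 <- matrix(0, nrow(img), ncol(img))
  gm <- mean(img)
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    n1 <- d1 <- n2 <- d2 <- 0
    for (a in seq_along(kk$k)) for (b in seq_along(kk$k)) {
      w <- kk$k[a] * kk$k[b]
      y <- px(img, i + a - kk$r - 1, j + b - kk$r - 1)
      h <- oracle_heaviside(px(phi, i + a - kk$r - 1, j + b - kk$r - 1), eps)
      n1 <- n1 + w * y * h; d1 <- d1 + w * h
      n2 <- n2 + w * y * (1 - h); d2 <- d2 + w * (1 - h)
    }
    g1[i, j] <- if (d1 < 1e-9) gm else n1 / d1
    g2[i, j] <- if (d2 < 1e-9) gm else n2 / d2
  }
  list(g1 = g1, g2 = g2)
}

# Fitting part of the LBF energy by quadruple loop (penalties excluded).
oracle_lbf_energy_fit <- function(img, phi, g1, g2, sigma, l1, l2, eps) {
  kk <- oracle_gauss_kernel(sigma)
  e <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    for (a in seq_along(kk$k)) for (b in seq_along(kk$k)) {
      w <- kk$k[a] * kk$k[b]
      y <- px(img, i + a - kk$r - 1, j + b - kk$r - 1)
      h <- oracle_heaviside(px(phi, i + a - kk$r - 1, j + b - kk$r - 1), eps)
      e <- e + l1 * w * (y - g1[i, j])^2 * h +
        l2 * w * (y - g2[i, j])^2 * (1 - h)
    }
  }
  e
}

# Pearson chi-square on a 2x2 table, four explicit cells.
oracle_chisq_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    expct <- rs[i] * cs[j] / n
    stat <- stat + (tab[i, j] - expct)^2 / expct
  }
  unname(stat)
}

# t statistics from first principles.
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / sqrt(sum((d - mean(d))^2) / (length(d) - 1) / length(d))
}

oracle_pooled_t <- function(x, y) {
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Point-in-region pixel count for the phantom geometry.
oracle_phantom_area <- function(spec) {
  cr <- spec$center[1]; cc <- spec$center[2]
  a <- spec$body_axes[1]; b <- spec$body_axes[2]
  n <- 0
  for (i in seq_len(spec$height)) for (j in seq_len(spec$width)) {
    ell <- ((j - cc) / a)^2 + ((i - cr) / b)^2
    inner <- ((j - cc) / (0.6 * a))^2 + ((i - cr) / (0.6 * b))^2
    ring <- ell <= 1 && inner > 1
    proc <- abs(j - cc) <= spec$process_halfwidth &&
      i >= cr + b && i <= cr + b + spec$process_length
    if (ring || proc) n <- n + 1
  }
  n
}

# Chebyshev-distance suture bands by direct search over boundary pixels.
oracle_suture <- function(mask, band) {
  nr <- nrow(mask); nc <- ncol(mask)
  # boundary: pixels adjacent (8-neighborhood) to the opposite value
  cheb_to_opposite <- function(i, j) {
    best <- Inf
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (mask[a, b] != mask[i, j])
        best <- min(best, max(abs(a - i), abs(b - j)))
    }
    best
  }
  q1 <- q2 <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d <- cheb_to_opposite(i, j)
    if (d <= band) {
      if (mask[i, j] == 1) q1[i, j] <- 1 else q2[i, j] <- 1
    }
  }
  list(q1 = q1, q2 = q2)
}

# Energy history check: within tol of its running minimum after burn-in.
descent_after_burnin <- function(history, burnin = 5, tol = 1e-3) {
  if (length(history) <= burnin) return(TRUE)
  runmin <- cummin(history)
  idx <- (burnin + 1):length(history)
  all(history[idx] <= runmin[idx] + tol * pmax(abs(runmin[idx]), 1))
}

# Small phantom spec that keeps unit-test evolutions fast.
small_spec <- function(...) {
  phantom_spec(height = 64L, width = 64L, body_axes = c(14, 10),
               process_length = 8, process_halfwidth = 2, ...)
}
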