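# Independent reference implementations used to cross-check the package.
# These deliberately take different computational routes from the package
# code (all-pairs matrix algebra, direct quadrature, exhaustive scans).

# edge-repeating reflective index, iterated for large overhangs
reflect_index <- function(i, n) {
  while (any(i < 1 | i > n)) {
    i <- ifelse(i < 1, 1 - i, i)
    i <- ifelse(i > n, 2 * n + 1 - i, i)
  }
  i
}

# Brute-force non-local means with full-image search: builds the complete
# patch matrix and the all-pairs weighted distance matrix, then averages.
nlm_oracle <- function(values, guide, patch_size, h, a = 1) {
  d <- dim(values)
  r <- (patch_size - 1) / 2
  n <- prod(d)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g1 <- exp(-(-r:r)^2 / (2 * a^2))
  g1 <- g1 / sum(g1)
  gw <- apply(off, 1, function(o)
    g1[o[1] + r + 1] * g1[o[2] + r + 1] * g1[o[3] + r + 1])
  cent <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  P <- matrix(0, n, nrow(off))
  for (t in seq_len(nrow(off))) {
    ii <- reflect_index(cent$i + off$dx[t], d[1])
    jj <- reflect_index(cent$j + off$dy[t], d[2])
    kk <- reflect_index(cent$k + off$dz[t], d[3])
    P[, t] <- guide[cbind(ii, jj, kk)]
  }
  Pw <- sweep(P, 2, sqrt(gw), "*")
  sq <- rowSums(Pw^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Pw)
  W <- exp(-pmax(D2, 0) / h^2)
  array(as.vector((W %*% as.vector(values)) / rowSums(W)), d)
}

# Exhaustive Otsu: recompute class weights/means from scratch at every
# candidate bin edge (values below the edge vs the rest, edges assigned to
# the upper class as in the histogram convention).
otsu_oracle <- function(x, bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  best <- -Inf
  best_thr <- NA_real_
  for (b in 1:(bins - 1L)) {
    lo <- bin <= b
    n0 <- sum(lo)
    if (n0 == 0L || n0 == length(x)) next
    # class means over bin midpoints, as the histogram method defines them
    mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
    mu0 <- mean(mids[bin[lo]])
    mu1 <- mean(mids[bin[!lo]])
    w0 <- n0 / length(x)
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best) {
      best <- v
      best_thr <- breaks[b + 1L]
    }
  }
  best_thr
}

# E[f(z) | nu] for sigma = 1 by dense trapezoidal quadrature against the
# Rician density evaluated directly through R's Bessel function, on its own
# grid and range — independent of the package's tabulated quadrature
efz_oracle <- function(table, nu) {
  x <- seq(max(0, nu - 10), nu + 10, length.out = 20001L)
  dens <- x * exp(-(x - nu)^2 / 2) *
    besselI(x * nu, 0, expon.scaled = TRUE)
  fx <- approx(table$grid, table$f_values, xout = x, rule = 2)$y
  w <- c(diff(x) / 2, 0) + c(0, diff(x) / 2)
  sum(dens * fx * w) / sum(dens * w)
}

# small solid-ball phantom: intensity `level` inside a centred ball
ball_volume <- function(n, radius_frac, level) {
  cx <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  X <- array(rep(cx, times = n * n), c(n, n, n))
  Y <- array(rep(rep(cx, each = n), times = n), c(n, n, n))
  Z <- array(rep(cx, each = n * n), c(n, n, n))
  ball <- X^2 + Y^2 + Z^2 <= radius_frac^2
  out <- array(0, c(n, n, n))
  out[ball] <- level
  list(volume = mr_volume(out), inside = ball)
}
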