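# Straight-line per-pixel reference implementation of the AM-LMTP
# descriptor, kept deliberately naive and independent of the package's
# vectorized code paths. Everything here works one pixel at a time with
# explicit loops.

# population SD of the window centred at (y, x)
oracle_sigma <- function(m, y, x, window) {
  r <- (window - 1) / 2
  vals <- c()
  for (dy in -r:r) for (dx in -r:r) vals <- c(vals, m[y + dy, x + dx])
  mu <- sum(vals) / length(vals)
  sqrt(sum((vals - mu)^2) / length(vals))
}

# scalar bilinear interpolation at fractional (sy, sx)
oracle_bilinear <- function(m, sy, sx) {
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- min(y0 + 1, nrow(m)); x1 <- min(x0 + 1, ncol(m))
  fy <- sy - y0; fx <- sx - x0
  (1 - fy) * (1 - fx) * m[y0, x0] + (1 - fy) * fx * m[y0, x1] +
    fy * (1 - fx) * m[y1, x0] + fy * fx * m[y1, x1]
}

# the 8 circular neighbors of (y, x) at radius R; i = 1 at angle 0,
# counter-clockwise
oracle_neighbors <- function(m, y, x, R) {
  g <- numeric(8)
  for (i in 1:8) {
    ang <- 2 * pi * (i - 1) / 8
    g[i] <- oracle_bilinear(m, y + R * sin(ang), x + R * cos(ang))
  }
  g
}

# six pattern images at one scale over the region inset by `inset`
oracle_patterns <- function(m, window, alpha, beta_offset, inset = 3) {
  r <- (window - 1) / 2
  h <- nrow(m); w <- ncol(m)
  rows <- (inset + 1):(h - inset); cols <- (inset + 1):(w - inset)
  out <- list()
  for (a in 1:3) for (pol in c("up", "low"))
    out[[paste0("a", a, "_", pol)]] <- matrix(0, length(rows), length(cols))
  for (yi in seq_along(rows)) for (xi in seq_along(cols)) {
    y <- rows[yi]; x <- cols[xi]
    Tad <- alpha * oracle_sigma(m, y, x, window) + beta_offset
    g <- oracle_neighbors(m, y, x, r)
    for (a in 1:3) {
      up <- 0; low <- 0
      for (i in 1:8) {
        beta_i <- 1 + ((i + 8 + a - 1) %% 8)
        d <- g[beta_i] - g[i]
        if (d >= Tad) up <- up + 2^(i - 1)
        if (d <= -Tad) low <- low + 2^(i - 1)
      }
      out[[paste0("a", a, "_up")]][yi, xi] <- up
      out[[paste0("a", a, "_low")]][yi, xi] <- low
    }
  }
  out
}

# full feature vector: per (order, polarity), 3x3 histogram then 7x7
oracle_features <- function(m, alpha = 0.2, beta_offset = 5) {
  p3 <- oracle_patterns(m, 3, alpha, beta_offset)
  p7 <- oracle_patterns(m, 7, alpha, beta_offset)
  out <- c()
  for (key in c("a1_up", "a1_low", "a2_up", "a2_low", "a3_up", "a3_low")) {
    for (p in list(p3[[key]], p7[[key]])) {
      counts <- numeric(256)
      for (v in as.vector(p)) counts[v + 1] <- counts[v + 1] + 1
      out <- c(out, counts / sum(counts))
    }
  }
  out
}

# random test image with margin away from 0/255 (so shifts don't clip)
random_gray <- function(h, w, seed, lo = 0, hi = 255) {
  set.seed(seed)
  gray_image(matrix(sample(lo:hi, h * w, replace = TRUE), h, w))
}
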