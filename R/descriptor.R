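# Adaptive Multiscale Local Mesh Ternary Pattern (AM-LMTP).
#
# Per pixel: sample P = 8 neighbors on a circle of radius R (bilinear
# interpolation off the grid), form the mesh-pair differences
# d_i = g[beta(i, a)] - g[i] with beta = 1 + mod(i + P + a - 1, P),
# ternary-encode each difference against the pixel's adaptive threshold
# T = alpha * sigma + beta_offset (sigma = local population SD), and pack
# the +1 / -1 codes into separate 8-bit "upper" / "lower" patterns with
# binomial weights 2^(i-1). Orders a in {1,2,3} x two polarities give six
# pattern images per scale; 256-bin histograms at the 3x3 and 7x7 scales
# concatenate into a 3072-value feature vector.

#' Adaptive-threshold parameters
#'
#' The per-pixel ternary threshold is `T = alpha * sigma + beta_offset`,
#' where `sigma` is the local standard deviation. `alpha` scales the
#' threshold with local contrast (large alpha suppresses noise-driven
#' codes in busy regions); `beta_offset` floors the threshold so that
#' near-identical pixels in flat regions still encode as 0.
#'
#' @param alpha Non-negative scaling factor (default 0.2).
#' @param beta_offset Non-negative floor in intensity levels (default 5;
#'   3--10 is typical for 8-bit images).
#' @return A `threshold_params` list.
#' @export
threshold_params <- function(alpha = 0.2, beta_offset = 5) {
  if (alpha < 0 || beta_offset < 0)
    stop("`alpha` and `beta_offset` must be non-negative")
  structure(list(alpha = alpha, beta_offset = beta_offset),
            class = "threshold_params")
}

#' Mesh scale
#'
#' One sliding-window scale of the descriptor: a square window of odd
#' size, P = 8 neighbors sampled on a circle of radius `(window - 1) / 2`,
#' and the set of mesh orders. With the default orders {1, 2, 3} and the
#' two polarities there are six pattern images per scale.
#'
#' @param window Odd window size, 3 or 7 in the standard configuration.
#' @param orders Integer mesh orders (default 1:3).
#' @return A `mesh_scale` list with fields `window`, `radius`, `P`,
#'   `orders`.
#' @export
mesh_scale <- function(window = 3L, orders = 1:3) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd and >= 3")
  structure(list(window = window, radius = (window - 1L) %/% 2L,
                 P = 8L, orders = as.integer(orders)),
            class = "mesh_scale")
}

#' Local standard-deviation map
#'
#' Population standard deviation (divide by n) of the square window
#' centred at every fully-supported pixel.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param window Odd window size not exceeding either image dimension.
#' @return Numeric matrix of size `(H - window + 1) x (W - window + 1)`.
#' @export
local_std_map <- function(img, window = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd")
  m <- unclass(img) * 1.0
  h <- nrow(m); w <- ncol(m)
  if (window > min(h, w)) stop("window larger than image")
  r <- (window - 1L) %/% 2L
  oh <- h - 2L * r; ow <- w - 2L * r
  s1 <- matrix(0, oh, ow); s2 <- matrix(0, oh, ow)
  for (dy in -r:r) for (dx in -r:r) {
    blk <- m[(1 + r + dy):(h - r + dy), (1 + r + dx):(w - r + dx), drop = FALSE]
    s1 <- s1 + blk; s2 <- s2 + blk^2
  }
  n <- window^2
  v <- s2 / n - (s1 / n)^2
  v[v < 0] <- 0          # guard tiny negative round-off
  sqrt(v)
}

#' Adaptive ternary threshold
#'
#' `T = alpha * sigma + beta_offset`, in floating point. With the default
#' parameters a neighborhood of standard deviation 20 gives
#' `0.2 * 20 + 5 = 9`.
#'
#' @param sigma Local standard deviation(s), non-negative; scalar or
#'   matrix.
#' @param params A [threshold_params()].
#' @return Threshold(s), same shape as `sigma`.
#' @export
adaptive_threshold <- function(sigma, params = threshold_params()) {
  if (any(sigma < 0)) stop("`sigma` must be non-negative")
  params$alpha * sigma + params$beta_offset
}

#' Upper and lower bounds around a centre intensity
#'
#' The interval `[centre - T, centre + T]` delimits the ternary dead
#' zone around the centre pixel (e.g. centre 72 with T = 9 gives bounds
#' 81 and 63). Both bounds are clamped to \[0, 255\]. Exposed for
#' inspection and figures; the feature path itself thresholds mesh-pair
#' differences rather than centre comparisons.
#'
#' @param center Centre intensity in \[0, 255\].
#' @param T Non-negative threshold.
#' @return Named numeric vector `c(upper = ..., lower = ...)`.
#' @export
center_bounds <- function(center, T) {
  if (T < 0) stop("`T` must be non-negative")
  c(upper = min(center + T, 255), lower = max(center - T, 0))
}

#' Mesh neighbor pairing index
#'
#' For neighbor `i` of `P` and mesh order `a`, the partner index is
#' `beta = 1 + mod(i + P + a - 1, P)` — i.e. the neighbor `a` steps
#' around the circle.
#'
#' @param i Neighbor index in 1..P.
#' @param P Neighbor count (8).
#' @param a Mesh order (>= 1).
#' @return Partner index in 1..P.
#' @export
mesh_neighbor_index <- function(i, P = 8L, a = 1L) {
  if (any(i < 1L) || any(i > P)) stop("`i` must lie in 1..P")
  if (any(a < 1L)) stop("`a` must be >= 1")
  1L + (i + P + a - 1L) %% P
}

#' Sample the circular neighborhood of every interior pixel
#'
#' Neighbor `i` (1..8) sits at angle `2*pi*(i-1)/8` from the positive
#' x-axis, counter-clockwise, at radius R; off-grid positions are
#' bilinearly interpolated. For a single pixel pass scalar `x`, `y`.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param x Column index (scalar) of the centre pixel.
#' @param y Row index (scalar) of the centre pixel.
#' @param scale A [mesh_scale()].
#' @return Numeric vector of the P = 8 sampled intensities.
#' @export
sample_neighbors <- function(img, x, y, scale = mesh_scale(3L)) {
  m <- unclass(img) * 1.0
  R <- scale$radius
  if (y - R < 1 || y + R > nrow(m) || x - R < 1 || x + R > ncol(m))
    stop("pixel lacks full support at radius ", R)
  ang <- 2 * pi * (0:(scale$P - 1)) / scale$P
  sx <- x + R * cos(ang)
  sy <- y + R * sin(ang)
  drop(bilinear_sample(m, matrix(sy, 1), matrix(sx, 1)))
}

# neighbor sample maps over a rectangular valid region:
# list of P matrices, each (rows r0..r1) x (cols c0..c1)
neighbor_maps <- function(m, scale, r0, r1, c0, c1) {
  R <- scale$radius
  ang <- 2 * pi * (0:(scale$P - 1)) / scale$P
  yy <- matrix(rep(r0:r1, times = c1 - c0 + 1), r1 - r0 + 1)
  xx <- matrix(rep(c0:c1, each = r1 - r0 + 1), r1 - r0 + 1)
  lapply(seq_len(scale$P), function(i) {
    bilinear_sample(m, yy + R * sin(ang[i]), xx + R * cos(ang[i]))
  })
}

#' Ternary encoding of a difference
#'
#' `+1` if `diff >= T`, `-1` if `diff <= -T`, else `0`. Boundaries are
#' inclusive: a difference of exactly the threshold counts as
#' significant.
#'
#' @param diff Intensity difference(s).
#' @param T Non-negative threshold(s), scalar or same shape as `diff`.
#' @return Integer code(s) in \{-1, 0, +1\}.
#' @export
ternary_encode <- function(diff, T) {
  if (any(T < 0)) stop("`T` must be non-negative")
  (diff >= T) - (diff <= -T)
}

#' Compute the six mesh-pattern images at one scale
#'
#' For every pixel of the shared valid region and every order
#' `a` in `scale$orders`, the mesh differences
#' `d_i = g[beta(i,a)] - g[i]` are ternary-encoded against the pixel's
#' adaptive threshold (sigma taken over this scale's window); the `+1`
#' bits pack into the "upper" pattern and the `-1` bits into the "lower"
#' pattern with weights `2^(i-1)`.
#'
#' @param img A [gray_image()] (typically preprocessed).
#' @param scale A [mesh_scale()].
#' @param params A [threshold_params()].
#' @param inset Border inset defining the valid region (defaults to the
#'   scale's own radius; pass the maximum radius over all scales so all
#'   scales share one region).
#' @return Named list of six integer matrices (`a1_up`, `a1_low`,
#'   `a2_up`, `a2_low`, `a3_up`, `a3_low`), codes in \[0, 255\].
#' @export
compute_pattern_images <- function(img, scale = mesh_scale(3L),
                                   params = threshold_params(),
                                   inset = scale$radius) {
  m <- unclass(gray_image(unclass(img))) * 1.0
  h <- nrow(m); w <- ncol(m)
  R <- scale$radius
  inset <- max(as.integer(inset), R)
  if (h < 2L * inset + 1L || w < 2L * inset + 1L)
    stop(sprintf("image %dx%d too small for inset %d", h, w, inset))
  r0 <- inset + 1L; r1 <- h - inset; c0 <- inset + 1L; c1 <- w - inset
  # sigma over this scale's window, trimmed to the shared valid region
  sig <- local_std_map(m, scale$window)
  off <- inset - R
  sig <- sig[(1 + off):(nrow(sig) - off), (1 + off):(ncol(sig) - off),
             drop = FALSE]
  T <- adaptive_threshold(sig, params)
  nb <- neighbor_maps(m, scale, r0, r1, c0, c1)
  out <- list()
  for (a in scale$orders) {
    up <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    low <- up
    for (i in seq_len(scale$P)) {
      d <- nb[[mesh_neighbor_index(i, scale$P, a)]] - nb[[i]]
      wgt <- 2L^(i - 1L)
      up <- up + wgt * (d >= T)
      low <- low + wgt * (d <= -T)
    }
    out[[paste0("a", a, "_up")]] <- up
    out[[paste0("a", a, "_low")]] <- low
  }
  out
}

#' Average the six pattern images for display
#'
#' The per-pixel mean of the six mesh-pattern codes, rounded — a single
#' texture image used in figures. Features always use the six separate
#' histograms, never this average.
#'
#' @param patterns List of six equally-sized code matrices.
#' @return A [gray_image()].
#' @export
lmtp_visualization <- function(patterns) {
  dims <- vapply(patterns, dim, integer(2))
  if (any(dims != dims[, 1])) stop("pattern images must share one shape")
  acc <- Reduce(`+`, lapply(patterns, function(p) p * 1.0))
  clamp_gray(acc / length(patterns))
}

#' Histogram of a pattern image
#'
#' Counts of each code value over the valid region, L1-normalized to
#' frequencies by default (so images of different sizes are comparable).
#'
#' @param p Integer matrix of codes in \[0, bins - 1\].
#' @param bins Number of histogram bins (256 for 8-bit codes).
#' @param normalize If `TRUE` (default) return frequencies summing to 1;
#'   otherwise raw counts.
#' @return Numeric vector of length `bins`.
#' @export
pattern_histogram <- function(p, bins = 256L, normalize = TRUE) {
  v <- as.vector(p)
  if (any(v < 0) || any(v >= bins))
    stop("pattern codes must lie in [0, bins - 1]")
  h <- tabulate(v + 1L, nbins = bins)
  if (normalize) h / sum(h) else h
}

#' Extract the AM-LMTP feature vector
#'
#' Six pattern images (orders 1--3 x upper/lower) are computed at each
#' scale over the valid region shared by all scales (inset by the
#' largest radius), histogrammed into 256 bins, and concatenated in the
#' fixed layout: for each `(order, polarity)` in
#' `(1,up),(1,low),(2,up),(2,low),(3,up),(3,low)`, the 3x3-scale
#' histogram followed by the 7x7-scale histogram. With the default two
#' scales the vector has `6 x 512 = 3072` values; each 256-bin block is
#' L1-normalized.
#'
#' @param img A [gray_image()], at least 7x7.
#' @param scales List of [mesh_scale()]s (default 3x3 and 7x7).
#' @param params A [threshold_params()].
#' @param normalize Passed to [pattern_histogram()].
#' @return Named numeric vector (names like `a1_up_s3_b000`).
#' @export
extract_features <- function(img, scales = list(mesh_scale(3L), mesh_scale(7L)),
                             params = threshold_params(), normalize = TRUE) {
  img <- gray_image(unclass(img))
  rmax <- max(vapply(scales, function(s) s$radius, integer(1)))
  if (nrow(img) < 2L * rmax + 1L || ncol(img) < 2L * rmax + 1L)
    stop(sprintf("image %dx%d too small for the %dx%d window",
                 nrow(img), ncol(img), 2L * rmax + 1L, 2L * rmax + 1L))
  per_scale <- lapply(scales, function(s)
    compute_pattern_images(img, s, params, inset = rmax))
  orders <- scales[[1]]$orders
  keys <- as.vector(t(outer(orders, c("up", "low"),
                            function(a, p) paste0("a", a, "_", p))))
  out <- numeric(0)
  for (key in keys) {
    for (k in seq_along(scales)) {
      hst <- pattern_histogram(per_scale[[k]][[key]], normalize = normalize)
      names(hst) <- sprintf("%s_s%d_b%03d", key, scales[[k]]$window,
                            0:(length(hst) - 1))
      out <- c(out, hst)
    }
  }
  out
}

#' Extract features for every image of a labeled set
#'
#' @param set A `labeled_set`.
#' @param cfg A [preprocess_config()], applied to each image first; pass
#'   `NULL` to extract from the raw images.
#' @param params A [threshold_params()].
#' @param scales List of [mesh_scale()]s.
#' @return List with `features` (numeric matrix, one row per image),
#'   `labels`, `class_names`, `origin`.
#' @export
extract_feature_matrix <- function(set, cfg = preprocess_config(),
                                   params = threshold_params(),
                                   scales = list(mesh_scale(3L), mesh_scale(7L))) {
  stopifnot(inherits(set, "labeled_set"))
  feats <- lapply(set$images, function(im) {
    if (!is.null(cfg)) im <- preprocess_pipeline(im, cfg)
    extract_features(im, scales = scales, params = params)
  })
  x <- do.call(rbind, feats)
  rownames(x) <- NULL
  list(features = x, labels = set$labels, class_names = set$class_names,
       origin = set$origin)
}
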