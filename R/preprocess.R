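# Three-stage enhancement chain: CLAHE -> gamma correction -> Laplacian
# sharpening. All intermediate arithmetic is floating point; each stage
# rounds and clamps back to [0, 255] so its output is a valid gray image.

#' Preprocessing configuration
#'
#' Defaults are the tuned values of the published pipeline: CLAHE clip
#' limit 2.0 on an 8x8 tile grid, gamma 0.4 (gamma < 1 brightens), and a
#' second-order Laplacian sharpening with unit strength.
#'
#' @param clip_limit CLAHE contrast-limit factor (> 0); per-tile histogram
#'   bins are clipped at `clip_limit` times the mean bin height.
#' @param tile_grid Integer `c(rows, cols)` of local CLAHE regions.
#' @param gamma Power-law exponent (> 0).
#' @param levels Number of intensity levels L (256 for 8-bit input).
#' @param sharpen_order Laplacian derivative order (2: the standard
#'   4-neighbour second-difference kernel).
#' @param sharpen_strength Scale applied to the Laplacian response before
#'   subtraction; 0 disables sharpening.
#' @param clahe_mode `"clahe"` for contrast-limited equalization proper;
#'   `"minmax"` for the per-tile min--max stretch alternative (see
#'   [clahe()] for when that mode is useful).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(clip_limit = 2.0, tile_grid = c(8L, 8L),
                              gamma = 0.4, levels = 256L,
                              sharpen_order = 2L, sharpen_strength = 1.0,
                              clahe_mode = c("clahe", "minmax")) {
  clahe_mode <- match.arg(clahe_mode)
  if (clip_limit <= 0) stop("`clip_limit` must be positive")
  if (gamma <= 0) stop("`gamma` must be positive")
  if (sharpen_order != 2L)
    stop("only the second-order Laplacian is supported")
  structure(list(clip_limit = clip_limit,
                 tile_grid = as.integer(tile_grid),
                 gamma = gamma, levels = as.integer(levels),
                 max_intensity = as.integer(levels) - 1L,
                 sharpen_order = 2L, sharpen_strength = sharpen_strength,
                 clahe_mode = clahe_mode),
            class = "preprocess_config")
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of tiles; each tile's 256-bin
#' histogram is clipped at `clip_limit` times the mean bin height, the
#' clipped excess is redistributed uniformly, and the resulting CDF gives
#' that tile's intensity mapping. Pixels are remapped by bilinear
#' interpolation between the mappings of the four nearest tile centres,
#' which removes tile-boundary artifacts.
#'
#' The `"minmax"` mode replaces each tile's mapping with a plain min--max
#' stretch to the full range (a local contrast normalization); it is kept
#' as a documented alternative because the published formulation can be
#' read either way. Constant tiles map to themselves in this mode.
#'
#' @param img A [gray_image()].
#' @param cfg A [preprocess_config()].
#' @return A [gray_image()] of the same size.
#' @export
clahe <- function(img, cfg = preprocess_config()) {
  img <- gray_image(unclass(img))
  h <- nrow(img); w <- ncol(img)
  tr <- cfg$tile_grid[1]; tc <- cfg$tile_grid[2]
  if (tr > h || tc > w)
    stop(sprintf("tile grid %dx%d larger than image %dx%d", tr, tc, h, w))
  L <- cfg$levels
  # tile boundaries (as equal as possible)
  row_edges <- round(seq(0, h, length.out = tr + 1))
  col_edges <- round(seq(0, w, length.out = tc + 1))
  # per-tile lookup tables, L values each
  luts <- array(0, dim = c(tr, tc, L))
  centers_y <- numeric(tr); centers_x <- numeric(tc)
  for (i in seq_len(tr)) {
    rows <- (row_edges[i] + 1):row_edges[i + 1]
    centers_y[i] <- mean(range(rows))
    for (j in seq_len(tc)) {
      cols <- (col_edges[j] + 1):col_edges[j + 1]
      if (i == 1) centers_x[j] <- mean(range(cols))
      vals <- img[rows, cols]
      luts[i, j, ] <- tile_lut(vals, L, cfg$clip_limit, cfg$clahe_mode)
    }
  }
  # bilinear interpolation between tile mappings at pixel positions
  yy <- seq_len(h); xx <- seq_len(w)
  iy <- findInterval(yy, centers_y, all.inside = FALSE)
  ix <- findInterval(xx, centers_x, all.inside = FALSE)
  iy0 <- pmin(pmax(iy, 1L), tr); iy1 <- pmin(iy0 + 1L, tr)
  ix0 <- pmin(pmax(ix, 1L), tc); ix1 <- pmin(ix0 + 1L, tc)
  wy <- ifelse(iy0 == iy1, 0,
               (yy - centers_y[iy0]) / (centers_y[iy1] - centers_y[iy0]))
  wy <- pmin(pmax(wy, 0), 1)
  wx <- ifelse(ix0 == ix1, 0,
               (xx - centers_x[ix0]) / (centers_x[ix1] - centers_x[ix0]))
  wx <- pmin(pmax(wx, 0), 1)
  v <- as.vector(img) + 1L                       # 1-based LUT index
  ry0 <- rep(iy0, times = w); ry1 <- rep(iy1, times = w)
  cx0 <- rep(ix0, each = h); cx1 <- rep(ix1, each = h)
  gy <- rep(wy, times = w); gx <- rep(wx, each = h)
  lut_at <- function(r, c) luts[cbind(r, c, v)]
  out <- (1 - gy) * (1 - gx) * lut_at(ry0, cx0) +
         (1 - gy) * gx       * lut_at(ry0, cx1) +
         gy       * (1 - gx) * lut_at(ry1, cx0) +
         gy       * gx       * lut_at(ry1, cx1)
  clamp_gray(matrix(out, h, w))
}

# mapping table for one tile: value v (0..L-1) -> equalized intensity
tile_lut <- function(vals, L, clip_limit, mode) {
  if (mode == "minmax") {
    lo <- min(vals); hi <- max(vals)
    if (hi == lo) return(as.numeric(0:(L - 1)))      # flat tile: identity
    lut <- (0:(L - 1) - lo) / (hi - lo) * (L - 1)
    return(pmin(pmax(lut, 0), L - 1))
  }
  n <- length(vals)
  hst <- tabulate(as.vector(vals) + 1L, nbins = L)
  clip <- clip_limit * n / L
  excess <- sum(pmax(hst - clip, 0))
  hst <- pmin(hst, clip) + excess / L
  cdf <- cumsum(hst) / n
  cdf * (L - 1)
}

#' Gamma correction
#'
#' Power-law intensity mapping `round(N * (v / N)^gamma)`, clamped to
#' \[0, N\]. Exponents below 1 brighten the image, above 1 darken it; the
#' mapping is monotone non-decreasing and fixes 0 and N.
#'
#' @param img A [gray_image()].
#' @param gamma Positive exponent (default 0.4).
#' @param N Maximum intensity (default 255).
#' @return A [gray_image()].
#' @export
gamma_correct <- function(img, gamma = 0.4, N = 255L) {
  if (gamma <= 0) stop("`gamma` must be positive")
  img <- gray_image(unclass(img))
  clamp_gray(N * (unclass(img) / N)^gamma)
}

#' Laplacian sharpening
#'
#' Subtracts the scaled second-derivative response,
#' `out = clamp(in - strength * lap(in))`, where `lap` is the 4-neighbour
#' 3x3 Laplacian kernel `[[0,1,0],[1,-4,1],[0,1,0]]` with replicated
#' (reflect) border handling. Flat regions are unchanged; edges and fine
#' texture are accentuated.
#'
#' @param img A [gray_image()].
#' @param strength Non-negative scale on the Laplacian response.
#' @return A [gray_image()].
#' @export
laplacian_sharpen <- function(img, strength = 1.0) {
  img <- gray_image(unclass(img))
  m <- unclass(img) * 1.0
  h <- nrow(m); w <- ncol(m)
  p <- pad_replicate(m, 1L)
  lap <- p[1:h, 2:(w + 1)] + p[3:(h + 2), 2:(w + 1)] +
         p[2:(h + 1), 1:w] + p[2:(h + 1), 3:(w + 2)] - 4 * m
  clamp_gray(m - strength * lap)
}

#' Full preprocessing chain
#'
#' Applies CLAHE, then gamma correction, then Laplacian sharpening, each
#' with the parameters in `cfg`. Deterministic: the same image and
#' configuration always give the same output.
#'
#' @param img A [gray_image()].
#' @param cfg A [preprocess_config()].
#' @return A [gray_image()].
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  img <- clahe(img, cfg)
  img <- gamma_correct(img, gamma = cfg$gamma, N = cfg$max_intensity)
  laplacian_sharpen(img, strength = cfg$sharpen_strength)
}
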