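# Image IO, synthetic texture fixtures and augmentation.
#
# A grayscale image is represented throughout the package as an integer
# matrix (rows = image rows, columns = image columns) with values in
# [0, 255]. `gray_image()` validates and tags such a matrix.

#' Construct a grayscale image
#'
#' Validates an intensity matrix and returns it as a `gray_image`: an
#' integer matrix with values in \[0, 255\], the unit every pipeline stage
#' consumes and produces.
#'
#' @param pixels Numeric matrix of intensities; values must lie in
#'   \[0, 255\] and are stored as integers.
#' @return An integer matrix of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels)) stop("`pixels` must not contain NA")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers")
  out <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  class(out) <- c("gray_image", class(out))
  out
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# clamp + round a float matrix back into a valid gray image
clamp_gray <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 255] <- 255
  gray_image(m)
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Load an image file as grayscale
#'
#' Reads a PNG or JPEG file and reduces it to a single 8-bit luminance
#' channel. Color inputs are converted with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer.
#'
#' @param path Path to a PNG/JPEG/JPG file.
#' @param min_size Minimum height and width accepted (the descriptor's
#'   largest window is 7x7, so images must be at least 7 pixels a side).
#' @return A [gray_image()].
#' @export
load_image <- function(path, min_size = 7L) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path,
                                           "': ", conditionMessage(e)))
  dat <- EBImage::imageData(img)   # first dim = x (columns)
  if (length(dim(dat)) == 2L) {
    g <- round(t(dat) * 255)
  } else {
    nch <- dim(dat)[3]
    ch <- lapply(seq_len(min(nch, 3L)), function(k) round(t(dat[, , k]) * 255))
    if (nch >= 3L) {
      g <- round(0.299 * ch[[1]] + 0.587 * ch[[2]] + 0.114 * ch[[3]])
    } else {
      g <- ch[[1]]
    }
  }
  if (nrow(g) < min_size || ncol(g) < min_size)
    stop(sprintf("image '%s' is %dx%d; at least %dx%d required",
                 path, nrow(g), ncol(g), min_size, min_size))
  clamp_gray(g)
}

#' Save a grayscale image as PNG
#'
#' PNG is lossless, so `load_image(save_image(img, f))` reproduces `img`
#' exactly. Lossy formats are never written.
#'
#' @param img A [gray_image()] (or intensity matrix).
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- gray_image(unclass(img))
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Generate a synthetic texture fixture
#'
#' Produces one of three class-separable textures standing in for lesion
#' photographs, so the full pipeline can run without clinical data:
#' \describe{
#'   \item{smooth}{low-pass filtered Gaussian noise (gentle blotches)}
#'   \item{speckle}{impulsive high-frequency salt-and-pepper noise}
#'   \item{grating}{an oriented sinusoid plus mild noise}
#' }
#' The three classes differ in their second-order statistics: speckle has
#' a much larger mean local standard deviation than smooth, and grating
#' carries a dominant orientation.
#'
#' @param class_id One of `"smooth"`, `"speckle"`, `"grating"`.
#' @param size Integer vector `c(H, W)`, both at least 16.
#' @param seed Integer seed; output is deterministic in
#'   `(class_id, size, seed)`.
#' @return A [gray_image()] of the requested size.
#' @export
generate_texture_fixture <- function(class_id, size = c(32L, 32L), seed = 1L) {
  class_id <- match.arg(class_id, c("smooth", "speckle", "grating"))
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h < 16L || w < 16L) stop("fixture size must be at least 16x16")
  with_seed(seed, {
    base <- switch(class_id,
      smooth = {
        z <- matrix(rnorm(h * w), h, w)
        # 5x5 box blur (replicated borders) kills the high frequencies
        z <- box_blur(box_blur(z, 2L), 2L)
        128 + 55 * z / max(abs(z))
      },
      speckle = {
        z <- matrix(128, h, w)
        n_imp <- round(0.35 * h * w)
        idx <- sample.int(h * w, n_imp)
        z[idx] <- ifelse(runif(n_imp) < 0.5, 20, 235)
        z + matrix(rnorm(h * w, sd = 6), h, w)
      },
      grating = {
        xs <- matrix(rep(seq_len(w), each = h), h, w)
        ys <- matrix(rep(seq_len(h), times = w), h, w)
        theta <- pi / 5
        128 + 80 * sin(2 * pi * (cos(theta) * xs + sin(theta) * ys) / 6) +
          matrix(rnorm(h * w, sd = 8), h, w)
      })
    clamp_gray(base)
  })
}

# mean filter with edge-replicated borders; r = half-width
box_blur <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  pad <- pad_replicate(m, r)
  acc <- matrix(0, h, w)
  for (dy in -r:r) for (dx in -r:r)
    acc <- acc + pad[(1 + r + dy):(h + r + dy), (1 + r + dx):(w + r + dx)]
  acc / (2 * r + 1)^2
}

# replicate-pad a matrix by r pixels on every side
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

#' Build a labeled set of synthetic textures
#'
#' @param n_per_class Number of images generated per class.
#' @param classes Character vector of class identifiers; each must be a
#'   texture class understood by [generate_texture_fixture()].
#' @param size Image size `c(H, W)`.
#' @param seed Integer seed controlling all image content.
#' @return A `labeled_set`: list with `images` (list of [gray_image()]),
#'   `labels` (character), `class_names`, and `origin` (index of the
#'   source original, used to keep augmented variants with their parent
#'   during cross-validation).
#' @export
make_labeled_set <- function(n_per_class, classes = c("smooth", "speckle", "grating"),
                             size = c(32L, 32L), seed = 1L) {
  if (length(classes) < 1L) stop("`classes` must name at least one class")
  if (n_per_class < 1L) stop("`n_per_class` must be at least 1")
  images <- list(); labels <- character(0)
  k <- 0L
  for (cl in classes) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      images[[k]] <- generate_texture_fixture(cl, size, seed = seed * 10000L + k)
      labels[k] <- cl
    }
  }
  labeled_set(images, labels, class_names = classes)
}

#' Construct a labeled set from images and labels
#'
#' @param images List of [gray_image()] objects.
#' @param labels Character vector of class labels, parallel to `images`.
#' @param class_names Ordered distinct class labels.
#' @param origin Integer vector mapping each image to the index of the
#'   original it derives from (defaults to itself).
#' @return A `labeled_set` list.
#' @export
labeled_set <- function(images, labels, class_names = unique(labels),
                        origin = seq_along(images)) {
  if (length(images) != length(labels))
    stop("`images` and `labels` must have equal length")
  if (!all(labels %in% class_names))
    stop("every label must appear in `class_names`")
  structure(list(images = images, labels = as.character(labels),
                 class_names = as.character(class_names),
                 origin = as.integer(origin)),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set: %d images, %d classes (%s)>\n",
              length(x$images), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Augmentation policy
#'
#' Two label-preserving geometric transforms are used by default, yielding
#' exactly two variants per original: a horizontal flip and a +15 degree
#' rotation with reflect padding.
#'
#' @param variants_per_original Number of variants generated per original
#'   (0--3 supported with the built-in transform list).
#' @param seed Integer seed (reserved for stochastic transforms; the
#'   default transforms are deterministic).
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(variants_per_original = 2L, seed = 0L) {
  if (variants_per_original < 0L) stop("`variants_per_original` must be >= 0")
  structure(list(variants_per_original = as.integer(variants_per_original),
                 transforms = c("hflip", "rot15", "vflip")[
                   seq_len(min(variants_per_original, 3L))],
                 seed = as.integer(seed)),
            class = "augment_policy")
}

flip_h <- function(img) gray_image(unclass(img)[, ncol(img):1, drop = FALSE])
flip_v <- function(img) gray_image(unclass(img)[nrow(img):1, , drop = FALSE])

# rotate by `deg` about the image centre, bilinear, reflect padding
rotate_image <- function(img, deg = 15) {
  h <- nrow(img); w <- ncol(img)
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(rep(seq_len(h), times = w), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  # inverse map: rotate sample coordinates by -theta
  sy <- cy + (yy - cy) * cos(th) - (xx - cx) * sin(th)
  sx <- cx + (yy - cy) * sin(th) + (xx - cx) * cos(th)
  # reflect out-of-range coordinates back inside
  reflect <- function(v, n) {
    v <- abs(v - 1) %% (2 * (n - 1))
    ifelse(v > (n - 1), 2 * (n - 1) - v, v) + 1
  }
  sy <- reflect(sy, h); sx <- reflect(sx, w)
  clamp_gray(bilinear_sample(unclass(img), sy, sx))
}

# bilinear interpolation of matrix m at (possibly fractional) row/col grids
bilinear_sample <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  y0 <- pmin(pmax(floor(sy), 1), h); x0 <- pmin(pmax(floor(sx), 1), w)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- sy - y0; fx <- sx - x0
  idx <- function(r, c) m[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fy) * (1 - fx) * idx(y0, x0) + (1 - fy) * fx * idx(y0, x1) +
       fy * (1 - fx) * idx(y1, x0) + fy * fx * idx(y1, x1)
  matrix(v, nrow(sy), ncol(sy))
}

#' Augment a labeled set
#'
#' Applies the policy's transforms to every image, appending the variants
#' after the originals in deterministic order (all variants of image 1,
#' then of image 2, ...). Labels are copied and each variant records its
#' parent in `origin`, so cross-validation can keep variants out of the
#' fold that validates their original.
#'
#' @param set A `labeled_set`.
#' @param policy An [augment_policy()].
#' @return A `labeled_set` of size `|set| * (1 + variants_per_original)`.
#' @export
augment <- function(set, policy = augment_policy()) {
  stopifnot(inherits(set, "labeled_set"), inherits(policy, "augment_policy"))
  n <- length(set$images)
  if (n == 0L || policy$variants_per_original == 0L) return(set)
  images <- set$images; labels <- set$labels; origin <- set$origin
  k <- n
  for (i in seq_len(n)) {
    for (tr in policy$transforms) {
      k <- k + 1L
      images[[k]] <- switch(tr,
        hflip = flip_h(set$images[[i]]),
        vflip = flip_v(set$images[[i]]),
        rot15 = rotate_image(set$images[[i]], 15))
      labels[k] <- set$labels[i]
      origin[k] <- set$origin[i]
    }
  }
  labeled_set(images, labels, class_names = set$class_names, origin = origin)
}

#' Mean local standard deviation of an image
#'
#' Average over all fully-supported pixels of the population standard
#' deviation in a square window; a simple roughness summary used to
#' verify that the synthetic texture classes are statistically distinct.
#'
#' @param img A [gray_image()].
#' @param window Odd window size (default 3).
#' @return A single non-negative number.
#' @export
mean_local_sd <- function(img, window = 3L) {
  mean(local_std_map(img, window))
}
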