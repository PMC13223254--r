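test_that("local SD map is the population SD of each window", {
  expect_true(all(local_std_map(gray_image(matrix(50, 9, 9)), 3) == 0))
  m <- matrix(0, 3, 3); m[2, 2] <- 90
  # mean 10, variance (8*100 + 6400)/9 = 800
  expect_equal(local_std_map(gray_image(m), 3)[1, 1], sqrt(800),
               tolerance = 1e-12)
  img <- random_gray(12, 12, seed = 2, lo = 10, hi = 200)
  shifted <- gray_image(unclass(img) + 40)
  expect_equal(local_std_map(img, 5), local_std_map(shifted, 5),
               tolerance = 1e-9)
  expect_error(local_std_map(img, 4), "odd")
})

test_that("adaptive threshold follows T = alpha * sigma + beta_offset", {
  expect_equal(adaptive_threshold(20, threshold_params(0.2, 5)), 9)
  expect_equal(adaptive_threshold(0, threshold_params(0.2, 5)), 5)
  expect_equal(adaptive_threshold(10, threshold_params(0.1, 1)), 2)
  expect_error(adaptive_threshold(-1, threshold_params()), "non-negative")
})

test_that("centre bounds add and subtract the threshold with clamping", {
  expect_equal(center_bounds(72, 9), c(upper = 81, lower = 63))
  expect_equal(center_bounds(100, 0), c(upper = 100, lower = 100))
  expect_equal(center_bounds(250, 9), c(upper = 255, lower = 241))
})

test_that("mesh pairing index walks a steps around the circle", {
  expect_equal(mesh_neighbor_index(1, 8, 1), 2)
  expect_equal(mesh_neighbor_index(8, 8, 1), 1)
  expect_equal(mesh_neighbor_index(1, 8, 3), 4)
  for (a in 1:3) for (i in 1:8) {
    b <- mesh_neighbor_index(i, 8, a)
    expect_true(b >= 1 && b <= 8 && b != i)
  }
  expect_error(mesh_neighbor_index(9, 8, 1), "1..P")
})

test_that("circular sampling is exact on-grid and bilinear off-grid", {
  img <- random_gray(9, 9, seed = 4)
  m <- unclass(img)
  g <- sample_neighbors(img, 5, 5, mesh_scale(3))
  # axis neighbors at R = 1 are exact grid values
  expect_equal(g[1], m[5, 6])  # angle 0: +x
  expect_equal(g[3], m[6, 5])  # angle 90: +y (down the rows)
  expect_equal(g[5], m[5, 4])
  expect_equal(g[7], m[4, 5])
  const <- gray_image(matrix(42, 9, 9))
  expect_true(all(sample_neighbors(const, 5, 5, mesh_scale(7)) == 42))
  # linear ramp I(x, y) = x: diagonal sample at R = 3 reads x + 3 cos 45
  ramp <- gray_image(matrix(rep(1:15, each = 15), 15, 15))
  g7 <- sample_neighbors(ramp, 8, 8, mesh_scale(7))
  expect_equal(g7[2], 8 + 3 * cos(pi / 4), tolerance = 1e-9)
  expect_error(sample_neighbors(img, 1, 1, mesh_scale(7)), "support")
})

test_that("ternary encoding has an inclusive dead zone", {
  expect_equal(ternary_encode(15, 9), 1)
  expect_equal(ternary_encode(0, 9), 0)
  expect_equal(ternary_encode(-9, 9), -1)
  expect_equal(ternary_encode(9, 9), 1)
  expect_equal(ternary_encode(c(-20, -3, 0, 3, 20), 9), c(-1, 0, 0, 0, 1))
})

test_that("constant images give all-zero patterns; saturated codes pack to 255", {
  pats <- compute_pattern_images(gray_image(matrix(80, 11, 11)),
                                 mesh_scale(3), threshold_params(), inset = 3)
  expect_length(pats, 6)
  for (p in pats) expect_true(all(p == 0))
  # all eight codes +1 pack to sum(2^(0:7)) = 255
  expect_equal(sum(2^(0:7) * (rep(10, 8) >= 1)), 255)
})

test_that("pattern images match the per-pixel oracle on random images", {
  for (seed in 1:5) {
    img <- random_gray(12, 12, seed = 100 + seed)
    m <- unclass(img) * 1.0
    for (win in c(3L, 7L)) {
      got <- compute_pattern_images(img, mesh_scale(win), threshold_params(),
                                    inset = 3)
      want <- oracle_patterns(m, win, 0.2, 5, inset = 3)
      for (key in names(want))
        expect_equal(unname(got[[key]]), unname(want[[key]]),
                     ignore_attr = TRUE)
    }
  }
})

test_that("upper and lower bits are mutually exclusive at every pixel", {
  img <- random_gray(16, 16, seed = 31)
  for (win in c(3L, 7L)) {
    pats <- compute_pattern_images(img, mesh_scale(win), threshold_params(),
                                   inset = 3)
    for (a in 1:3) {
      up <- pats[[paste0("a", a, "_up")]]
      low <- pats[[paste0("a", a, "_low")]]
      expect_true(all(bitwAnd(as.integer(up), as.integer(low)) == 0))
    }
  }
})

test_that("raising alpha or beta_offset never adds nonzero codes", {
  img <- random_gray(14, 14, seed = 77)
  nonzero_count <- function(params) {
    pats <- compute_pattern_images(img, mesh_scale(3), params, inset = 3)
    sum(vapply(pats, function(p) sum(p != 0), numeric(1)))
  }
  alphas <- c(0, 0.1, 0.2, 0.5, 1)
  counts_a <- vapply(alphas, function(a) nonzero_count(threshold_params(a, 5)),
                     numeric(1))
  expect_true(all(diff(counts_a) <= 0))
  betas <- c(0, 2, 5, 10, 30)
  counts_b <- vapply(betas, function(b) nonzero_count(threshold_params(0.2, b)),
                     numeric(1))
  expect_true(all(diff(counts_b) <= 0))
})

test_that("visualization averages the six patterns and rounds", {
  p <- matrix(7L, 4, 4)
  expect_true(all(lmtp_visualization(rep(list(p), 6)) == 7))
  zeros <- rep(list(matrix(0L, 4, 4)), 6)
  expect_true(all(lmtp_visualization(zeros) == 0))
  mix <- c(rep(list(matrix(0L, 1, 1)), 5), list(matrix(6L, 1, 1)))
  expect_equal(as.integer(lmtp_visualization(mix)), 1L)
  expect_error(lmtp_visualization(c(zeros[1:5], list(matrix(0L, 3, 3)))),
               "shape")
})

test_that("pattern histograms count codes and normalize to 1", {
  expect_equal(pattern_histogram(matrix(0L, 5, 5))[1], 1)
  h <- pattern_histogram(matrix(c(3L, 3L, 7L, 255L), 2, 2))
  expect_equal(h[c(4, 8, 256)], c(0.5, 0.25, 0.25))
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(sum(pattern_histogram(matrix(c(1L, 2L), 1), normalize = FALSE)), 2)
  expect_error(pattern_histogram(matrix(300L, 1, 1)), "bins")
})

test_that("feature vector has the documented layout and geometry", {
  img <- generate_texture_fixture("grating", c(18, 18), 1)
  f <- extract_features(img)
  expect_length(f, 3072)
  blocks <- matrix(f, nrow = 256)
  expect_equal(colSums(blocks), rep(1, 12), tolerance = 1e-9)
  expect_equal(names(f)[1], "a1_up_s3_b000")
  expect_equal(names(f)[257], "a1_up_s7_b000")
  expect_equal(names(f)[513], "a1_low_s3_b000")
  # constant image: every block concentrates at code 0
  fc <- extract_features(gray_image(matrix(90, 16, 16)))
  expect_equal(unname(fc[seq(1, 3072, by = 256)]), rep(1, 12))
  expect_error(extract_features(gray_image(matrix(1, 6, 6))), "small")
})

test_that("features are shift-invariant when no pixel clips", {
  img <- random_gray(16, 16, seed = 55, lo = 10, hi = 200)
  f1 <- extract_features(img)
  f2 <- extract_features(gray_image(unclass(img) + 40))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("extract_feature_matrix stacks per-image vectors with labels", {
  s <- make_labeled_set(2, c("smooth", "speckle"), c(20, 20), 3)
  fm <- extract_feature_matrix(s, cfg = NULL)
  expect_equal(dim(fm$features), c(4L, 3072L))
  expect_identical(fm$labels, s$labels)
  expect_equal(fm$features[1, ], extract_features(s$images[[1]]))
})
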