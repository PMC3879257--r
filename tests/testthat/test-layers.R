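# S-layer maps, pooling, normalization, spatial pyramid.

make_linear_dict <- function(W, p = 1L, nch = 1L) {
  # bare filter dictionary without whitening (identity input space)
  d <- sparsehmax:::new_dictionary("ica", bases = t(W), filters = W)
  d$patch_side <- p
  d$n_channels <- nch
  d
}

test_that("a 1x1 filter S layer is pointwise scaling; output dims follow valid sliding", {
  img <- gray_image(matrix(c(1, 3, 2, 4), 2, 2))
  dict <- make_linear_dict(matrix(2, 1, 1))
  s <- s_layer_linear(img, dict)
  expect_equal(s$maps[1, , ], 2 * as.matrix(img))

  img2 <- test_image(12, 9)
  dict2 <- make_linear_dict(matrix(stats::rnorm(3 * 16), 3, 16), p = 4L)
  s2 <- s_layer_linear(img2, dict2)
  expect_equal(dim(s2$maps), c(3L, 9L, 6L))  # H - p + 1, W - p + 1
  s2b <- s_layer_linear(img2, dict2, stride = 2)
  expect_equal(dim(s2b$maps), c(3L, 5L, 3L))
  expect_error(s_layer_linear(test_image(3, 3), dict2), "exceeds")
})

test_that("map of the matching filter peaks where a basis is planted", {
  B <- planted_dictionary(p = 5L, n = 4L, seed = 70L)
  W <- t(B)  # orthonormal rows
  dict <- make_linear_dict(W, p = 5L)
  px <- matrix(0, 12, 12)
  px[4:8, 6:10] <- matrix(B[, 2], 5, 5)
  s <- s_layer_linear(gray_image(px), dict)
  peak <- which(s$maps[2, , ] == max(s$maps[2, , ]), arr.ind = TRUE)
  expect_equal(as.vector(peak), c(4L, 6L))
  expect_equal(max(s$maps[2, , ]), 1)  # unit basis, orthonormal filter
  # oracle: response at the peak equals the direct dot product
  expect_equal(s$maps[2, 4, 6], sum(W[2, ] * B[, 2]))
})

test_that("sparse S layer recovers a planted basis code and handles zero input", {
  B <- planted_dictionary(p = 4L, n = 6L, seed = 71L)
  dict <- sparsehmax:::new_dictionary("ssc", bases = B, lambda = 1e-4)
  dict$patch_side <- 4L; dict$n_channels <- 1L
  px <- matrix(0, 8, 8)
  px[3:6, 3:6] <- matrix(B[, 5], 4, 4)
  s <- s_layer_sparse(gray_image(px), dict)
  expect_equal(s$maps[5, 3, 3], 1, tolerance = 1e-3)
  others <- s$maps[-5, 3, 3]
  expect_lt(max(abs(others)), 0.01)
  z <- s_layer_sparse(gray_image(matrix(0, 8, 8)), dict)
  expect_true(all(z$maps == 0))
  # stride divides output dims (rounding down)
  s2 <- s_layer_sparse(gray_image(matrix(stats::rnorm(100), 10, 10)), dict,
                       stride = 2)
  expect_equal(dim(s2$maps)[2:3], c(4L, 4L))
})

test_that("code normalization clips at 0.2 and returns unit vectors", {
  v <- c(0, 0, 3, 0)
  out <- normalize_codes(matrix(v, ncol = 1))
  expect_equal(sqrt(sum(out^2)), 1, tolerance = 1e-9)
  expect_equal(out[3], 1)  # single nonzero entry: clip then renormalize to 1
  withr::with_seed(72, M <- matrix(stats::rnorm(20 * 15), 20, 15))
  N <- normalize_codes(M)
  expect_equal(sqrt(colSums(N^2)), rep(1, 15), tolerance = 1e-9)
  # intermediate clip: no renormalized entry may exceed what a 0.2-clipped
  # unit vector can produce
  expect_true(all(vapply(seq_len(15), function(j) {
    u <- M[, j] / sqrt(sum(M[, j]^2))
    u <- sign(u) * pmin(abs(u), 0.2)
    isTRUE(all.equal(N[, j], u / sqrt(sum(u^2)), tolerance = 1e-9))
  }, logical(1L))))
  # fixed point: already unit-norm with entries below the clip
  u <- rep(1 / sqrt(30), 30)
  expect_equal(as.vector(normalize_codes(matrix(u, ncol = 1))), u)
  # zero vector passes through
  expect_equal(as.vector(normalize_codes(matrix(0, 4, 1))), rep(0, 4))
})

test_that("pooling window arithmetic matches hand-computed values", {
  m <- array(0, c(1, 2, 2))
  m[1, , ] <- matrix(c(1, 2, -3, 0), 2, 2)  # window values {1, -3, 2, 0}
  stk <- feature_map_stack(m)
  expect_equal(c_layer_pool(stk, pooling_spec(2, "max"))$maps[1, 1, 1], 2)
  expect_equal(c_layer_pool(stk, pooling_spec(2, "average"))$maps[1, 1, 1], 0)
  expect_equal(c_layer_pool(stk, pooling_spec(2, "square"))$maps[1, 1, 1],
               sqrt(14))
  # constant map: max = avg = v, square = v * ratio
  cm <- feature_map_stack(array(1.5, c(1, 6, 6)))
  expect_equal(c_layer_pool(cm, pooling_spec(3, "max"))$maps[1, 1, 1], 1.5)
  expect_equal(c_layer_pool(cm, pooling_spec(3, "average"))$maps[1, 1, 1], 1.5)
  expect_equal(c_layer_pool(cm, pooling_spec(3, "square"))$maps[1, 1, 1],
               1.5 * 3)
  # 8x8, ratio 2, step 2 -> 4x4; trailing partial windows dropped
  stk8 <- feature_map_stack(array(stats::rnorm(2 * 8 * 8), c(2, 8, 8)))
  expect_equal(dim(c_layer_pool(stk8, pooling_spec(2))$maps), c(2L, 4L, 4L))
  stk9 <- feature_map_stack(array(stats::rnorm(9 * 9), c(1, 9, 9)))
  expect_equal(dim(c_layer_pool(stk9, pooling_spec(2))$maps), c(1L, 4L, 4L))
  # overlapping pooling with step < ratio
  expect_equal(dim(c_layer_pool(stk8, pooling_spec(4, step = 2))$maps),
               c(2L, 3L, 3L))
  expect_error(c_layer_pool(stk8, pooling_spec(9)), "ratio")
})

test_that("max pooling is invariant to permutations inside windows", {
  withr::with_seed(73, a <- array(stats::rnorm(2 * 6 * 6), c(2, 6, 6)))
  stk <- feature_map_stack(a)
  pooled <- c_layer_pool(stk, pooling_spec(3, "max"))
  perm <- a
  withr::with_seed(74, {
    for (ch in 1:2) {
      for (bi in 0:1) for (bj in 0:1) {
        w <- perm[ch, bi * 3 + 1:3, bj * 3 + 1:3]
        perm[ch, bi * 3 + 1:3, bj * 3 + 1:3] <- matrix(sample(w), 3, 3)
      }
    }
  })
  pooled2 <- c_layer_pool(feature_map_stack(perm), pooling_spec(3, "max"))
  expect_identical(pooled$maps, pooled2$maps)
})

test_that("translating input by one pooling ratio shifts pooled maps by one", {
  withr::with_seed(75, a <- array(stats::rnorm(1 * 12 * 12), c(1, 12, 12)))
  r <- 3L
  shifted <- array(0, dim(a))
  shifted[1, (r + 1):12, ] <- a[1, 1:(12 - r), ]
  for (mode in c("max", "average", "square")) {
    p0 <- c_layer_pool(feature_map_stack(a), pooling_spec(r, mode))$maps
    p1 <- c_layer_pool(feature_map_stack(shifted), pooling_spec(r, mode))$maps
    expect_equal(p1[1, 2:4, ], p0[1, 1:3, ], tolerance = 1e-12)
  }
})

test_that("pooled max of pointwise max dominates max of pooled maps (equality)", {
  withr::with_seed(76, {
    a <- array(stats::rnorm(3 * 8 * 8), c(3, 8, 8))
    b <- array(stats::rnorm(3 * 8 * 8), c(3, 8, 8))
  })
  spec <- pooling_spec(2, "max")
  pm <- c_layer_pool(feature_map_stack(pmax(a, b)), spec)$maps
  mp <- pmax(c_layer_pool(feature_map_stack(a), spec)$maps,
             c_layer_pool(feature_map_stack(b), spec)$maps)
  expect_identical(pm, mp)
})

test_that("spatial pyramid returns abs-max features in documented order", {
  # grids {1,2,4} -> 21 features per map
  withr::with_seed(77, stk <- feature_map_stack(array(stats::rnorm(2 * 8 * 8),
                                                      c(2, 8, 8))))
  f <- spatial_pyramid_pool(stk, pyramid_spec(c(1, 2, 4)))
  expect_length(f, 2 * 21)
  # single-cell grid on a signed map picks the largest |value|
  m <- array(0, c(1, 2, 2)); m[1, , ] <- matrix(c(-5, 0, 2, 1), 2, 2)
  expect_equal(spatial_pyramid_pool(feature_map_stack(m), pyramid_spec(1)), 5)
  z <- feature_map_stack(array(0, c(3, 4, 4)))
  expect_true(all(spatial_pyramid_pool(z, pyramid_spec(c(1, 2))) == 0))
  # map-major ordering: first 21 features come from map 1
  a <- array(0, c(2, 4, 4)); a[2, , ] <- 1
  f2 <- spatial_pyramid_pool(feature_map_stack(a), pyramid_spec(c(1, 2, 4)))
  expect_true(all(f2[1:21] == 0) && all(f2[22:42] == 1))
  expect_error(spatial_pyramid_pool(z, pyramid_spec(5)), "grid")
})

test_that("uneven pyramid cells cover the map with floor boundaries", {
  # 5x5 map, grid 2: cells split at floor(5/2) = 2
  m <- array(seq_len(25), c(1, 5, 5))
  f <- spatial_pyramid_pool(feature_map_stack(m), pyramid_spec(2))
  # row-major cells: [1:2,1:2], [1:2,3:5], [3:5,1:2], [3:5,3:5]
  expect_equal(f, c(max(m[1, 1:2, 1:2]), max(m[1, 1:2, 3:5]),
                    max(m[1, 3:5, 1:2]), max(m[1, 3:5, 3:5])))
})
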