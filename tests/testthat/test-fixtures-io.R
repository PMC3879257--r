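# Image I/O, geometric preprocessing, and the synthetic generators.

test_that("PGM round trip preserves raw values and PNG reads back luminance", {
  tmp <- withr::local_tempdir()
  # P5 binary PGM written by hand with known values
  pgm <- file.path(tmp, "tiny.pgm")
  con <- file(pgm, "wb")
  writeChar("P5\n2 2\n255\n", con, eos = NULL)
  writeBin(as.integer(c(0L, 64L, 128L, 255L)), con, size = 1L)
  close(con)
  img <- load_gray(pgm)
  expect_equal(as.matrix(img), matrix(c(0, 64, 128, 255), 2, 2, byrow = TRUE))

  # ascii P2 with a comment line
  pgm2 <- file.path(tmp, "tiny2.pgm")
  writeLines(c("P2", "# comment", "3 1", "255", "10 20 30"), pgm2)
  expect_equal(as.vector(as.matrix(load_gray(pgm2))), c(10, 20, 30))

  # gray RGB png: R=G=B=100/255 everywhere -> constant luminance
  png_path <- file.path(tmp, "gray.png")
  arr <- array(100 / 255, dim = c(4, 5, 3))
  png::writePNG(arr, png_path)
  img3 <- load_gray(png_path)
  expect_equal(dim(img3), c(4L, 5L))
  expect_true(all(abs(as.matrix(img3) - 100 / 255) < 1e-6))

  # write_gray round trip through png
  out <- file.path(tmp, "out.png")
  write_gray(img3, out, rescale = "none")
  expect_true(all(abs(as.matrix(load_gray(out)) - 100 / 255) < 1 / 255))
})

test_that("unreadable or truncated files raise an I/O error naming the path", {
  expect_error(load_gray(file.path(tempdir(), "nope_missing.png")), "nope_missing")
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "trunc.pgm")
  con <- file(bad, "wb")
  writeChar("P5\n4 4\n255\n", con, eos = NULL)
  writeBin(as.integer(c(1L, 2L)), con, size = 1L)  # 2 of 16 pixels
  close(con)
  expect_error(load_gray(bad), "trunc")
  bad2 <- file.path(tmp, "junk.png")
  writeBin(as.raw(1:10), bad2)
  expect_error(load_gray(bad2), "junk")
})

test_that("resizing targets the correct side and preserves aspect ratio", {
  img <- test_image(300, 600)
  r <- resize_shorter_side(img, 150)
  expect_equal(dim(r), c(150L, 300L))
  # already at target: unchanged object
  img2 <- test_image(120, 240)
  expect_identical(resize_shorter_side(img2, 120), img2)
  img3 <- test_image(240, 120)
  expect_identical(resize_shorter_side(img3, 120), img3)

  expect_equal(dim(resize_longer_side_cap(test_image(600, 300), 300)),
               c(300L, 150L))
  img4 <- test_image(200, 100)
  expect_identical(resize_longer_side_cap(img4, 300), img4)
  img5 <- test_image(300, 300)
  expect_identical(resize_longer_side_cap(img5, 300), img5)
})

test_that("sparse-composite images reconstruct exactly from ground-truth codes", {
  B <- planted_dictionary(p = 4L, n = 6L)
  gen <- synth_sparse_images(B, n_images = 3, image_side = 12,
                             actives_per_patch = 2, seed = 7)
  expect_length(gen$images, 3L)
  # reassemble every image from its codes and compare pixel-for-pixel
  p <- gen$patch_side
  tiles <- 12L %/% p
  for (im in seq_len(3L)) {
    recon <- matrix(0, 12, 12)
    q <- 0L
    for (tj in seq_len(tiles)) {
      for (ti in seq_len(tiles)) {
        q <- q + 1L
        recon[(ti - 1L) * p + seq_len(p), (tj - 1L) * p + seq_len(p)] <-
          matrix(B %*% gen$codes[, q, im], p, p)
      }
    }
    expect_equal(as.matrix(gen$images[[im]]), recon, tolerance = 1e-12)
  }
  # single basis, single active: patch is c * basis
  one <- synth_sparse_images(B[, 1, drop = FALSE], 1, 4, 1, seed = 3)
  cf <- one$codes[1, 1, 1]
  expect_equal(as.vector(as.matrix(one$images[[1]])), cf * B[, 1])
})

test_that("sparse-composite generator is seed-deterministic with super-Gaussian codes", {
  B <- planted_dictionary(p = 4L, n = 8L)
  g1 <- synth_sparse_images(B, 20, 16, 2, seed = 11)
  g2 <- synth_sparse_images(B, 20, 16, 2, seed = 11)
  expect_identical(g1, g2)
  expect_error(synth_sparse_images(B, 2, 16, 9, seed = 1), "actives_per_patch")
  # Laplace coefficients: excess kurtosis of active coefficients ~3 > 0
  cf <- as.vector(g1$codes)
  cf <- cf[cf != 0]
  kurt <- mean((cf - mean(cf))^4) / stats::var(cf)^2 - 3
  expect_gt(kurt, 0)
})

test_that("category generator produces separable labeled shapes", {
  gen0 <- synth_category_images(n_per_category = 3, image_side = 32,
                                noise_sd = 0, jitter = 0, seed = 1)
  # no jitter, no noise: all images of a category identical to the template
  for (cat in names(gen0$templates)) {
    idx <- which(gen0$labels == cat)
    for (i in idx) {
      expect_equal(as.matrix(gen0$images[[i]]), gen0$templates[[cat]])
    }
  }
  # disjoint templates, no noise: nearest-template classification is perfect
  gen <- synth_category_images(n_per_category = 5, image_side = 32,
                               noise_sd = 0, jitter = 2, seed = 2)
  tnames <- names(gen$templates)
  pred <- vapply(gen$images, function(img) {
    dists <- vapply(gen$templates, function(tm) {
      # account for jitter by correlating at best shift
      min(vapply(-2:2, function(dr) min(vapply(-2:2, function(dc) {
        sh <- sparsehmax:::shift_pixels(tm, dr, dc, 0)
        sum((as.matrix(img) - sh)^2)
      }, numeric(1L))), numeric(1L)))
    }, numeric(1L))
    tnames[which.min(dists)]
  }, character(1L))
  expect_equal(pred, gen$labels)
  # mean image approaches the template as n grows (law of large numbers)
  gen_big <- synth_category_images(categories = c("disk", "bar"),
                                   n_per_category = 200, image_side = 32,
                                   noise_sd = 0.3, jitter = 0, seed = 3)
  disk_mean <- Reduce(`+`, lapply(which(gen_big$labels == "disk"),
                                  function(i) as.matrix(gen_big$images[[i]]))) / 200
  expect_lt(max(abs(disk_mean - gen_big$templates$disk)), 4 * 0.3 / sqrt(200))
})

test_that("noise images have the requested spectrum statistics", {
  imgs <- synth_noise_images(4, 64, "white", seed = 5, contrast_sd = 0)
  expect_length(imgs, 4L)
  for (im in imgs) {
    expect_equal(mean(as.matrix(im)), 0, tolerance = 1e-12)
    expect_equal(stats::sd(as.matrix(im)), 1, tolerance = 1e-12)
  }
  # pink noise concentrates power at low spatial frequencies
  pink <- synth_noise_images(1, 64, "pink", seed = 5, contrast_sd = 0)[[1]]
  sp <- Mod(stats::fft(as.matrix(pink)))^2
  low <- sp[2:4, 1]; high <- sp[28:30, 1]
  expect_gt(mean(low), 10 * mean(high))
  expect_identical(synth_noise_images(2, 32, seed = 9),
                   synth_noise_images(2, 32, seed = 9))
})

test_that("distortions keep dimensions, honor magnitude bounds, and invert on the interior", {
  img <- test_image(30, 30, seed = 4)
  for (kind in c("scale", "rotate", "translate",
                 "occlude_horizontal", "occlude_vertical")) {
    d0 <- distort(img, distortion_spec(kind, 0))
    expect_identical(d0$pixels, img$pixels)
    d1 <- distort(img, distortion_spec(kind, switch(kind,
      scale = 0.3, rotate = 20, translate = 3,
      occlude_horizontal = 0.4, occlude_vertical = 0.4)))
    expect_equal(dim(d1), dim(img))
  }
  # full occlusion fills everything with the image mean
  full <- distort(img, distortion_spec("occlude_horizontal", 1))
  expect_true(all(full$pixels == mean(img$pixels)))
  custom <- distort(img, distortion_spec("occlude_vertical", 1, fill = 0.5))
  expect_true(all(custom$pixels == 0.5))
  # translate by (2, 0) then (-2, 0): interior rows restored exactly
  t1 <- distort(img, distortion_spec("translate", 2, direction = c(1, 0)))
  t2 <- distort(t1, distortion_spec("translate", -2, direction = c(1, 0)))
  expect_equal(t2$pixels[3:28, ], img$pixels[3:28, ])
  expect_error(distortion_spec("occlude_horizontal", 1.2), "fraction")
  expect_error(distortion_spec("scale", -1), "scale")
})
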