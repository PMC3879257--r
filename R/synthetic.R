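# Synthetic image generators and image distortions.
#
# These generators stand in for natural-image and object-category datasets:
# sparse-dictionary composites (for dictionary-recovery experiments), labeled
# shape categories (for selectivity experiments), and white / 1-f noise
# fields (for pooling-correlation statistics).

#' Distortion specification
#'
#' Describes one of the standard image distortions used to probe unit
#' invariance: scaling, rotation, translation, or band occlusion.
#'
#' @param kind One of `"scale"`, `"rotate"`, `"translate"`,
#'   `"occlude_horizontal"`, `"occlude_vertical"`.
#' @param magnitude Distortion strength. For `scale` it is the fractional
#'   size change (0 = identity, 0.2 = 20% larger, -0.2 = 20% smaller; must
#'   be > -1). For `rotate`, degrees. For `translate`, pixels (rounded to
#'   integers). For occlusions, the occluded fraction of the image in
#'   \[0, 1\].
#' @param direction Length-2 unit direction for `translate`
#'   (row, column); the shift is `round(magnitude * direction)`.
#' @param fill Fill value for exposed/occluded regions, or `NULL` to use
#'   the image mean.
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(kind = c("scale", "rotate", "translate",
                                     "occlude_horizontal", "occlude_vertical"),
                            magnitude, direction = c(0, 1), fill = NULL) {
  kind <- match.arg(kind)
  magnitude <- check_number(magnitude, "magnitude")
  if (kind == "scale" && magnitude <= -1) {
    stopf("scale magnitude must be > -1 (fractional size change)")
  }
  if (kind %in% c("occlude_horizontal", "occlude_vertical") &&
      (magnitude < 0 || magnitude > 1)) {
    stopf("occlusion magnitude must be a fraction in [0, 1]")
  }
  if (length(direction) != 2L || !is.numeric(direction)) {
    stopf("`direction` must be a numeric length-2 vector")
  }
  structure(list(kind = kind, magnitude = magnitude,
                 direction = as.numeric(direction), fill = fill),
            class = "distortion_spec")
}

#' Apply a distortion to an image
#'
#' Output always has the same dimensions as the input: scaling is followed
#' by center crop/pad, rotation keeps the original frame, translation shifts
#' by whole pixels, and occlusion overwrites a contiguous horizontal or
#' vertical band starting at the top/left edge. Exposed regions are filled
#' with the image mean unless the spec supplies a fill value. Zero magnitude
#' is the exact identity for every kind.
#'
#' @param img A [gray_image].
#' @param spec A [distortion_spec].
#' @return A [gray_image] with the same dimensions as `img`.
#' @export
distort <- function(img, spec) {
  if (!inherits(spec, "distortion_spec")) stopf("`spec` must be a distortion_spec")
  px <- as.matrix(img)
  d <- dim(px)
  fill <- spec$fill %||% mean(px)
  m <- spec$magnitude
  out <- switch(spec$kind,
    scale = {
      if (m == 0) px else {
        f <- 1 + m
        sc <- resize_to(img, d[1L] * f, d[2L] * f)
        center_embed(as.matrix(sc), d, fill)
      }
    },
    rotate = {
      if (m == 0) px else {
        e <- EBImage::rotate(as_ebimage(img), angle = m,
                             output.dim = c(d[2L], d[1L]), bg.col = fill)
        t(imageData(e))
      }
    },
    translate = {
      sh <- round(m * spec$direction)
      shift_pixels(px, sh[1L], sh[2L], fill)
    },
    occlude_horizontal = {
      nr <- round(m * d[1L])
      if (nr > 0) px[seq_len(nr), ] <- fill
      px
    },
    occlude_vertical = {
      ncol_occ <- round(m * d[2L])
      if (ncol_occ > 0) px[, seq_len(ncol_occ)] <- fill
      px
    }
  )
  gray_image(out, origin = sprintf("%s|%s(%g)", img$origin, spec$kind, m))
}

# Embed/crop matrix `src` centered in a target of size `d`, fill elsewhere.
center_embed <- function(src, d, fill) {
  out <- matrix(fill, d[1L], d[2L])
  sr <- dim(src)
  # Source and target center-aligned overlap.
  r_off <- floor((sr[1L] - d[1L]) / 2)
  c_off <- floor((sr[2L] - d[2L]) / 2)
  rows_t <- seq_len(d[1L]); cols_t <- seq_len(d[2L])
  rows_s <- rows_t + r_off;  cols_s <- cols_t + c_off
  ok_r <- rows_s >= 1L & rows_s <= sr[1L]
  ok_c <- cols_s >= 1L & cols_s <= sr[2L]
  out[rows_t[ok_r], cols_t[ok_c]] <- src[rows_s[ok_r], cols_s[ok_c]]
  out
}

# Integer-pixel shift with constant fill (exact, no interpolation).
shift_pixels <- function(px, dr, dc, fill) {
  d <- dim(px)
  out <- matrix(fill, d[1L], d[2L])
  src_r <- seq_len(d[1L]) - dr
  src_c <- seq_len(d[2L]) - dc
  ok_r <- src_r >= 1L & src_r <= d[1L]
  ok_c <- src_c >= 1L & src_c <= d[2L]
  out[which(ok_r), which(ok_c)] <- px[src_r[ok_r], src_c[ok_c]]
  out
}

rlaplace_ <- function(n, scale = 1) {
  # Difference of exponentials has a Laplace distribution.
  stats::rexp(n, rate = 1 / scale) - stats::rexp(n, rate = 1 / scale)
}

#' Generate images as sparse combinations of known dictionary bases
#'
#' Each image is tiled with non-overlapping patches; every patch is a linear
#' combination of `actives_per_patch` randomly chosen bases with
#' Laplace-distributed coefficients. The ground-truth codes are returned so
#' dictionary-recovery experiments can compare learned bases against the
#' generators. With `noise_sd = 0` the codes reconstruct the images exactly.
#'
#' @param dict_bases d x n matrix whose columns are the generating bases
#'   (d must be a perfect square, the patch side squared).
#' @param n_images Number of images to generate.
#' @param image_side Side length of each (square) image; must be a multiple
#'   of the patch side.
#' @param actives_per_patch Number of active bases per patch.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param coeff_scale Laplace scale parameter of the coefficients.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @return A list with `images` (list of [gray_image]), `codes`
#'   (n x n_patches x n_images array of ground-truth coefficients, patches
#'   ordered column-major over the tile grid), and `patch_side`.
#' @export
synth_sparse_images <- function(dict_bases, n_images, image_side,
                                actives_per_patch = 1, seed = 1,
                                coeff_scale = 1, noise_sd = 0) {
  if (!is.matrix(dict_bases)) stopf("`dict_bases` must be a matrix")
  d <- nrow(dict_bases); n <- ncol(dict_bases)
  p <- as.integer(round(sqrt(d)))
  if (p * p != d) stopf("basis dimension %d is not a perfect square", d)
  n_images <- check_count(n_images, "n_images")
  image_side <- check_count(image_side, "image_side")
  actives_per_patch <- check_count(actives_per_patch, "actives_per_patch")
  if (actives_per_patch > n) {
    stopf("actives_per_patch (%d) exceeds the number of bases (%d)",
          actives_per_patch, n)
  }
  if (image_side %% p != 0L) {
    stopf("image_side (%d) must be a multiple of the patch side (%d)",
          image_side, p)
  }
  tiles <- image_side %/% p
  n_patches <- tiles * tiles
  with_seed_(seed, {
    codes <- array(0, dim = c(n, n_patches, n_images))
    images <- vector("list", n_images)
    for (im in seq_len(n_images)) {
      S <- matrix(0, n, n_patches)
      for (q in seq_len(n_patches)) {
        idx <- sample.int(n, actives_per_patch)
        S[idx, q] <- rlaplace_(actives_per_patch, coeff_scale)
      }
      codes[, , im] <- S
      patches <- dict_bases %*% S  # d x n_patches
      px <- matrix(0, image_side, image_side)
      q <- 0L
      for (tj in seq_len(tiles)) {
        for (ti in seq_len(tiles)) {
          q <- q + 1L
          px[(ti - 1L) * p + seq_len(p), (tj - 1L) * p + seq_len(p)] <-
            matrix(patches[, q], p, p)
        }
      }
      if (noise_sd > 0) px <- px + matrix(stats::rnorm(length(px), sd = noise_sd),
                                          image_side, image_side)
      images[[im]] <- gray_image(px, origin = sprintf("synth_sparse[%d]", im))
    }
    list(images = images, codes = codes, patch_side = p)
  })
}

# Shape templates on a side x side grid: foreground 1, background 0.
# Templates are mutually distinctive (no template is a sub-pattern of
# another): vertical bar, diagonal X-cross, filled disk, and a ring whose
# radius differs from the disk's so it is not simply the disk's edge.
shape_template <- function(kind = c("bar", "cross", "disk", "ring"), side,
                           thickness = NULL, radius = NULL) {
  kind <- match.arg(kind)
  side <- check_count(side, "side", min = 8L)
  th <- thickness %||% max(2L, round(side / 10))
  c0 <- (side + 1) / 2
  px <- matrix(0, side, side)
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  half_len <- round(side / 3)
  switch(kind,
    bar = {
      px[abs(cols - c0) < th / 2 & abs(rows - c0) <= half_len] <- 1
    },
    cross = {
      # X shape: two diagonal strokes
      u <- rows - c0; v <- cols - c0
      reach <- pmax(abs(u), abs(v)) <= half_len
      px[(abs(u - v) < th / sqrt(2) | abs(u + v) < th / sqrt(2)) & reach] <- 1
    },
    disk = {
      r <- radius %||% round(side / 5)
      px[(rows - c0)^2 + (cols - c0)^2 <= r^2] <- 1
    },
    ring = {
      r <- radius %||% round(side / 3.2)
      d2 <- (rows - c0)^2 + (cols - c0)^2
      px[d2 <= (r + th / 2)^2 & d2 >= (r - th / 2)^2] <- 1
    }
  )
  px
}

#' Generate labeled shape-category images
#'
#' Each category is a fixed shape template (bar, cross, disk or ring by
#' default) rendered at a jittered position with additive Gaussian noise —
#' a controlled stand-in for aligned object categories in selectivity and
#' classification experiments.
#'
#' @param categories Character vector of shape kinds (>= 2), each one of
#'   `"bar"`, `"cross"`, `"disk"`, `"ring"`.
#' @param n_per_category Images per category.
#' @param image_side Side length of the square images.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param jitter Maximum absolute integer translation (pixels) of the
#'   template in each axis.
#' @param seed Integer seed.
#' @return A list with `images` (list of [gray_image]), `labels`
#'   (character vector), and `templates` (named list of template matrices).
#' @export
synth_category_images <- function(categories = c("bar", "cross", "disk", "ring"),
                                  n_per_category = 40, image_side = 64,
                                  noise_sd = 0.05, jitter = 3, seed = 1) {
  if (length(categories) < 2L) stopf("need at least 2 categories")
  n_per_category <- check_count(n_per_category, "n_per_category")
  image_side <- check_count(image_side, "image_side", min = 8L)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  jitter <- check_count(jitter, "jitter", min = 0L)
  templates <- lapply(categories, shape_template, side = image_side)
  names(templates) <- categories
  with_seed_(seed, {
    images <- list()
    labels <- character(0)
    for (cat in categories) {
      tmpl <- templates[[cat]]
      for (i in seq_len(n_per_category)) {
        sh <- if (jitter > 0) sample(seq(-jitter, jitter), 2L, replace = TRUE)
              else c(0L, 0L)
        px <- shift_pixels(tmpl, sh[1L], sh[2L], fill = 0)
        if (noise_sd > 0) {
          px <- px + matrix(stats::rnorm(length(px), sd = noise_sd),
                            image_side, image_side)
        }
        images[[length(images) + 1L]] <-
          gray_image(px, origin = sprintf("synth_cat[%s,%d]", cat, i))
        labels <- c(labels, cat)
      }
    }
    list(images = images, labels = labels, templates = templates)
  })
}

#' Generate white-noise or 1/f-noise images
#'
#' White noise has a flat spatial power spectrum; `"pink"` (1/f) noise has
#' amplitude inversely proportional to spatial frequency, the canonical
#' second-order statistic of natural scenes. By default the field is also
#' multiplied by a smooth log-normal contrast envelope, emulating the
#' spatially varying local contrast of natural scenes — the higher-order
#' (variance) dependency that nonlinear pooling converts into linear
#' correlations. A purely Gaussian field has no dependencies beyond second
#' order, so `contrast_sd = 0` gives the plain stationary noise. Images
#' are generated in the Fourier domain with random phases and normalized
#' to zero mean, unit variance.
#'
#' @param n_images Number of images.
#' @param side Side length of the square images.
#' @param spectrum `"white"` or `"pink"` (1/f amplitude).
#' @param seed Integer seed.
#' @param contrast_sd Log-scale standard deviation of the contrast
#'   envelope; 0 disables it.
#' @param contrast_scale Spatial correlation length of the envelope in
#'   pixels (default `3 * side / 8`).
#' @return A list of [gray_image].
#' @export
synth_noise_images <- function(n_images, side, spectrum = c("pink", "white"),
                               seed = 1, contrast_sd = 1,
                               contrast_scale = NULL) {
  spectrum <- match.arg(spectrum)
  n_images <- check_count(n_images, "n_images")
  side <- check_count(side, "side", min = 4L)
  contrast_sd <- check_number(contrast_sd, "contrast_sd", min = 0)
  L <- contrast_scale %||% (3 * side / 8)
  fr <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  f2 <- outer(fr^2, fr^2, "+")
  with_seed_(seed, {
    lapply(seq_len(n_images), function(im) {
      z <- matrix(stats::rnorm(side * side), side, side)
      if (spectrum == "pink") {
        amp <- 1 / sqrt(pmax(f2, (1 / side)^2))  # 1/f amplitude, DC clamped
        px <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / length(z)
      } else {
        px <- z
      }
      if (contrast_sd > 0) {
        e <- matrix(stats::rnorm(side * side), side, side)
        # Gaussian-spectrum field with spatial correlation length ~L.
        env <- Re(stats::fft(stats::fft(e) * exp(-f2 * (pi * L)^2),
                             inverse = TRUE)) / length(e)
        env <- exp(contrast_sd * env / stats::sd(env))
        px <- px * env
      }
      px <- (px - mean(px)) / stats::sd(px)
      gray_image(px, origin = sprintf("synth_noise[%s,%d]", spectrum, im))
    })
  })
}

#' Write a generated image set to a directory
#'
#' Writes each image as PNG plus a `labels.csv` manifest with columns
#' `filename,label`, the on-disk exchange format used by the command-line
#' tools.
#'
#' @param images List of [gray_image].
#' @param labels Character vector of labels (recycled `""` if `NULL`).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_image_set <- function(images, labels = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- labels %||% rep("", length(images))
  if (length(labels) != length(images)) stopf("labels length mismatch")
  fn <- sprintf("img_%05d.png", seq_along(images))
  for (i in seq_along(images)) {
    write_gray(images[[i]], file.path(dir, fn[i]))
  }
  manifest <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(filename = fn, label = labels),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read an image set written by [write_image_set()]
#'
#' @param dir Directory containing images and a `labels.csv` manifest.
#' @return A list with `images` and `labels`.
#' @export
read_image_set <- function(dir) {
  manifest <- file.path(dir, "labels.csv")
  if (!file.exists(manifest)) stopf("no labels.csv manifest in '%s'", dir)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  images <- lapply(file.path(dir, tab$filename), load_gray)
  list(images = images, labels = as.character(tab$label))
}
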