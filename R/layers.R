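# S-layer feature maps, C-layer pooling, and the terminal spatial pyramid.

#' Construct a feature map stack
#'
#' The content of any S or C layer: `n` unit maps over a common spatial
#' grid, plus geometry bookkeeping (window side and stride of the producing
#' operation, cumulative receptive-field side and cumulative subsampling
#' factor relative to the input image).
#'
#' @param maps n x H x W numeric array.
#' @param layer_label Label such as `"S1"`, `"C1"`.
#' @param geometry List with `rf_side` and `subsample` (both relative to
#'   the input image); optionally `window`, `stride`.
#' @return An object of class `feature_map_stack`.
#' @export
feature_map_stack <- function(maps, layer_label = "",
                              geometry = list(rf_side = 1L, subsample = 1L)) {
  if (!is.array(maps) || length(dim(maps)) != 3L) {
    stopf("`maps` must be an n x H x W array")
  }
  if (any(dim(maps) < 1L)) stopf("map stack dimensions must be >= 1")
  if (!all(is.finite(maps))) stopf("map stack contains non-finite values")
  structure(list(maps = maps, layer_label = as.character(layer_label),
                 geometry = geometry),
            class = "feature_map_stack")
}

#' @export
print.feature_map_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<feature_map_stack %s: %d maps of %d x %d (RF %d, subsample %d)>\n",
              if (nzchar(x$layer_label)) x$layer_label else "?",
              d[1L], d[2L], d[3L],
              x$geometry$rf_side %||% NA, x$geometry$subsample %||% NA))
  invisible(x)
}

#' @export
dim.feature_map_stack <- function(x) dim(x$maps)

# Lift a gray image to a 1-channel stack with identity geometry.
as_stack <- function(input) {
  if (inherits(input, "feature_map_stack")) return(input)
  a <- as_map_array(input)
  feature_map_stack(a, layer_label = "input",
                    geometry = list(rf_side = 1L, subsample = 1L))
}

# im2col: all valid windows of side p at the given stride, as columns.
# Column order: output position (oi, oj) column-major (oi fastest); row
# order matches sample_patches (channel-major, patch column-major).
im2col <- function(a, p, stride = 1L) {
  nch <- dim(a)[1L]; H <- dim(a)[2L]; W <- dim(a)[3L]
  if (p > H || p > W) stopf("window side %d exceeds map dimensions %d x %d", p, H, W)
  ri <- seq.int(1L, H - p + 1L, by = stride)
  ci <- seq.int(1L, W - p + 1L, by = stride)
  oh <- length(ri); ow <- length(ci)
  pos_r <- rep(ri, times = ow)
  pos_c <- rep(ci, each = oh)
  X <- extract_windows(a, pos_r, pos_c, p)
  list(X = X, oh = oh, ow = ow)
}

s_geometry <- function(g_in, window, stride) {
  list(rf_side = g_in$rf_side + (window - 1L) * g_in$subsample,
       subsample = g_in$subsample * stride,
       window = window, stride = stride)
}

#' Compute a linear (ICA) S layer
#'
#' Slides the dictionary window over the input at the given stride (valid
#' region, no padding) and applies the linear ICA inference `s = W x` in
#' the whitened space at every position, producing one map per filter.
#'
#' @param input A [gray_image] or [feature_map_stack].
#' @param dict An ICA (or any filter-carrying) dictionary whose
#'   `patch_side`/`n_channels` match the input.
#' @param stride Positive integer step between window positions.
#' @return A [feature_map_stack] with one map per filter.
#' @export
s_layer_linear <- function(input, dict, stride = 1L) {
  stride <- check_count(stride, "stride")
  stk <- as_stack(input)
  p <- dict$patch_side %||% infer_patch_side(dict, dim(stk$maps)[1L])
  if (dim(stk$maps)[1L] != (dict$n_channels %||% dim(stk$maps)[1L])) {
    stopf("input has %d channels but dictionary expects %d",
          dim(stk$maps)[1L], dict$n_channels)
  }
  cols <- im2col(stk$maps, p, stride)
  Wt <- effective_filters(dict)
  codes <- if (!is.null(dict$whitening)) {
    Wt %*% cols$X - as.vector(Wt %*% dict$whitening$mean)
  } else {
    Wt %*% cols$X
  }
  feature_map_stack(array(codes, dim = c(nrow(codes), cols$oh, cols$ow)),
                    layer_label = "S",
                    geometry = s_geometry(stk$geometry, p, stride))
}

infer_patch_side <- function(dict, n_channels) {
  d <- nrow(dict$bases)
  p <- as.integer(round(sqrt(d / n_channels)))
  if (p * p * n_channels != d) {
    stopf("cannot infer window side from basis dimension %d and %d channels",
          d, n_channels)
  }
  p
}

#' Compute a sparse-coding (or L2) S layer
#'
#' At each valid window position the code vector is inferred under the
#' dictionary's model: coordinate-descent lasso for SSC, the ridge closed
#' form for L2. Codes may be negative. One map per basis.
#'
#' @param input A [gray_image] or [feature_map_stack].
#' @param dict An SSC or L2 dictionary.
#' @param lambda Override of the dictionary's sparsity weight (SSC).
#' @param stride Positive integer step between window positions.
#' @param normalize Apply [normalize_codes()] to every position's code
#'   vector (the SIFT-style 0.2-clip normalization).
#' @return A [feature_map_stack].
#' @export
s_layer_sparse <- function(input, dict, lambda = NULL, stride = 1L,
                           normalize = FALSE) {
  stride <- check_count(stride, "stride")
  check_flag(normalize, "normalize")
  stk <- as_stack(input)
  p <- dict$patch_side %||% infer_patch_side(dict, dim(stk$maps)[1L])
  cols <- im2col(stk$maps, p, stride)
  codes <- switch(dict$method,
    ssc = infer_ssc(cols$X, dict$bases, lambda %||% dict$lambda)$codes,
    l2 = infer_l2(cols$X, dict$bases, dict$gamma)$codes,
    random_patch = infer_distance(cols$X, dict$bases, dict$sigma),
    ica = stop("use s_layer_linear() for ICA dictionaries", call. = FALSE),
    stopf("unsupported dictionary method '%s'", dict$method)
  )
  if (normalize) codes <- normalize_codes(codes)
  feature_map_stack(array(codes, dim = c(nrow(codes), cols$oh, cols$ow)),
                    layer_label = "S",
                    geometry = s_geometry(stk$geometry, p, stride))
}

#' Normalize code vectors with clipping
#'
#' The SIFT-style illumination normalization applied to inferred S codes:
#' each column is (1) scaled to unit L2 length, (2) clipped so no entry
#' magnitude exceeds `clip`, (3) rescaled to unit length. Zero columns pass
#' through unchanged.
#'
#' @param codes n x m matrix (columns are per-position code vectors).
#' @param clip Positive clipping threshold.
#' @return Matrix of the same shape.
#' @export
normalize_codes <- function(codes, clip = 0.2) {
  clip <- check_number(clip, "clip", min = 0, strict_min = TRUE)
  if (!is.matrix(codes)) codes <- matrix(codes, ncol = 1L)
  nrm <- col_norms(codes)
  nz <- nrm > 0
  if (!any(nz)) return(codes)
  codes[, nz] <- sweep(codes[, nz, drop = FALSE], 2L, nrm[nz], "/")
  codes[, nz] <- sign(codes[, nz, drop = FALSE]) *
    pmin(abs(codes[, nz, drop = FALSE]), clip)
  nrm2 <- col_norms(codes[, nz, drop = FALSE])
  codes[, nz] <- sweep(codes[, nz, drop = FALSE], 2L, nrm2, "/")
  codes
}

#' Pooling specification
#'
#' @param ratio Pooling window side (integer >= 1).
#' @param mode `"max"` (signed maximum), `"average"`, or `"square"`
#'   (root of the sum of squares in the window).
#' @param step Step between window starts; defaults to `ratio`
#'   (non-overlapping). `step < ratio` gives overlapping pooling.
#' @return An object of class `pooling_spec`.
#' @export
pooling_spec <- function(ratio, mode = c("max", "average", "square"),
                         step = ratio) {
  mode <- match.arg(mode)
  ratio <- check_count(ratio, "ratio")
  step <- check_count(step, "step")
  if (step > 2L * ratio) stopf("step (%d) must be <= 2 * ratio (%d)", step, 2L * ratio)
  structure(list(ratio = ratio, mode = mode, step = step),
            class = "pooling_spec")
}

#' Pool an S layer into a C layer
#'
#' Per map, slides a `ratio` x `ratio` window advanced by `step` (trailing
#' partial windows are dropped) and reduces it to a single value: the
#' signed maximum, the arithmetic mean, or the square root of the sum of
#' squares.
#'
#' @param S A [feature_map_stack].
#' @param spec A [pooling_spec] (or a bare ratio, meaning non-overlapping
#'   max pooling).
#' @return A [feature_map_stack] of pooled maps.
#' @export
c_layer_pool <- function(S, spec) {
  if (is.numeric(spec)) spec <- pooling_spec(spec)
  if (!inherits(spec, "pooling_spec")) stopf("`spec` must be a pooling_spec")
  a <- S$maps
  nch <- dim(a)[1L]; H <- dim(a)[2L]; W <- dim(a)[3L]
  r <- spec$ratio
  if (r > H || r > W) stopf("pooling ratio %d exceeds map dimensions %d x %d", r, H, W)
  ri <- seq.int(1L, H - r + 1L, by = spec$step)
  ci <- seq.int(1L, W - r + 1L, by = spec$step)
  oh <- length(ri); ow <- length(ci)
  acc <- switch(spec$mode,
    max = array(-Inf, dim = c(nch, oh, ow)),
    array(0, dim = c(nch, oh, ow)))
  for (dj in seq_len(r)) {
    for (di in seq_len(r)) {
      slice <- a[, ri + di - 1L, ci + dj - 1L, drop = FALSE]
      acc <- switch(spec$mode,
        max = pmax(acc, slice),
        average = acc + slice,
        square = acc + slice^2)
    }
  }
  out <- switch(spec$mode,
    max = acc,
    average = acc / r^2,
    square = sqrt(acc))
  g <- S$geometry
  feature_map_stack(out, layer_label = "C",
                    geometry = list(
                      rf_side = g$rf_side + (r - 1L) * g$subsample,
                      subsample = g$subsample * spec$step,
                      window = r, stride = spec$step))
}

#' Pyramid specification
#'
#' @param grids Vector of positive grid resolutions, e.g. `c(1, 2, 4)`.
#' @return An object of class `pyramid_spec`.
#' @export
pyramid_spec <- function(grids = c(1, 2, 4)) {
  if (length(grids) < 1L || any(grids < 1) || any(grids != as.integer(grids))) {
    stopf("`grids` must be a non-empty vector of positive integers")
  }
  structure(list(grids = as.integer(grids)), class = "pyramid_spec")
}

#' Spatial pyramid pooling over absolute responses
#'
#' For each grid resolution g, each map is partitioned into g x g cells
#' (boundaries at `floor(i * H / g)`, so cells may differ by one row or
#' column when the size is not divisible); the feature for a cell is the
#' maximum absolute response inside it. Features are concatenated
#' map-major, then grids in the order given, then cells row-major, giving
#' `n_maps * sum(g^2)` features (21 per map for grids 1, 2, 4).
#'
#' @param S A [feature_map_stack].
#' @param pyr A [pyramid_spec] (or vector of grid resolutions).
#' @return Numeric feature vector of length `n_maps * sum(grids^2)`.
#' @export
spatial_pyramid_pool <- function(S, pyr = pyramid_spec()) {
  if (is.numeric(pyr)) pyr <- pyramid_spec(pyr)
  a <- abs(S$maps)
  nch <- dim(a)[1L]; H <- dim(a)[2L]; W <- dim(a)[3L]
  if (any(pyr$grids > H) || any(pyr$grids > W)) {
    stopf("grid resolution %d exceeds map dimensions %d x %d",
          max(pyr$grids), H, W)
  }
  per_map <- sum(pyr$grids^2)
  out <- numeric(nch * per_map)
  k <- 0L
  for (ch in seq_len(nch)) {
    m <- a[ch, , ]
    for (g in pyr$grids) {
      rb <- floor(seq_len(g) * H / g)
      cb <- floor(seq_len(g) * W / g)
      r0 <- c(0L, rb[-g])
      c0 <- c(0L, cb[-g])
      for (i in seq_len(g)) {        # rows outer: row-major cell order
        for (j in seq_len(g)) {
          k <- k + 1L
          out[k] <- max(m[(r0[i] + 1L):rb[i], (c0[j] + 1L):cb[j]])
        }
      }
    }
  }
  out
}
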