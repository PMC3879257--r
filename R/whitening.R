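# Patch sampling and PCA whitening / dimension reduction.

#' Construct a patch set
#'
#' A d x m matrix whose columns are vectorized square patches (channel-major:
#' the p x p patch of channel 1 column-major, then channel 2, ...), the unit
#' of dictionary learning.
#'
#' @param data d x m numeric matrix of vectorized patches.
#' @param patch_side Patch side length p.
#' @param n_channels Number of source maps the patches were drawn from.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(data, patch_side, n_channels = 1L) {
  patch_side <- check_count(patch_side, "patch_side")
  n_channels <- check_count(n_channels, "n_channels")
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (nrow(data) != patch_side^2 * n_channels) {
    stopf("patch dimension %d does not equal patch_side^2 * n_channels = %d",
          nrow(data), patch_side^2 * n_channels)
  }
  if (ncol(data) < 1L) stopf("patch set must contain at least one patch")
  if (!all(is.finite(data))) stopf("patch set contains non-finite values")
  structure(list(data = data, patch_side = patch_side,
                 n_channels = n_channels),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set %d x %d (side %d, %d channels)>\n",
              nrow(x$data), ncol(x$data), x$patch_side, x$n_channels))
  invisible(x)
}

# Coerce a gray_image or feature_map_stack to an n x H x W array.
as_map_array <- function(maps) {
  if (is_gray_image(maps)) {
    px <- as.matrix(maps)
    array(px, dim = c(1L, nrow(px), ncol(px)))
  } else if (inherits(maps, "feature_map_stack")) {
    maps$maps
  } else if (is.array(maps) && length(dim(maps)) == 3L) {
    maps
  } else {
    stopf("expected a gray_image, feature_map_stack, or n x H x W array")
  }
}

#' Sample patches at random locations
#'
#' Draws square windows at uniformly random valid top-left positions (with
#' replacement). For a multi-map stack the same window is taken on every
#' map and the per-map patches are concatenated channel-major.
#'
#' @param maps A [gray_image] or [feature_map_stack] (or n x H x W array).
#' @param patch_side Window side length.
#' @param n_patches Number of patches to draw.
#' @param seed Integer seed; sampling is bit-reproducible.
#' @return A [patch_set].
#' @export
sample_patches <- function(maps, patch_side, n_patches, seed = 1) {
  a <- as_map_array(maps)
  patch_side <- check_count(patch_side, "patch_side")
  n_patches <- check_count(n_patches, "n_patches")
  nch <- dim(a)[1L]; H <- dim(a)[2L]; W <- dim(a)[3L]
  if (patch_side > H || patch_side > W) {
    stopf("patch_side %d exceeds map dimensions %d x %d", patch_side, H, W)
  }
  with_seed_(seed, {
    ri <- sample.int(H - patch_side + 1L, n_patches, replace = TRUE)
    ci <- sample.int(W - patch_side + 1L, n_patches, replace = TRUE)
    X <- extract_windows(a, ri, ci, patch_side)
    patch_set(X, patch_side, nch)
  })
}

# Gather windows at given top-left (row, col) positions into columns.
extract_windows <- function(a, ri, ci, p) {
  nch <- dim(a)[1L]
  m <- length(ri)
  X <- matrix(0, nch * p * p, m)
  r <- 0L
  for (ch in seq_len(nch)) {
    for (dj in seq_len(p)) {
      for (di in seq_len(p)) {
        r <- r + 1L
        X[r, ] <- a[cbind(ch, ri + di - 1L, ci + dj - 1L)]
      }
    }
  }
  # Reorder rows to channel-major vectorization: index (ch, dj, di) was
  # filled channel-outermost already, so rows are in order ch, dj, di with
  # di fastest — exactly the channel-major column-major patch layout.
  X
}

#' Fit a PCA whitening transform
#'
#' Projects onto the top-`k` principal axes of the patches with per-axis
#' scaling to unit variance (dimension reduction concurrent with
#' whitening). By default the patch mean is \emph{not} subtracted, so the
#' DC component survives as an ordinary direction; set `subtract_mean =
#' TRUE` for conventional centered PCA.
#'
#' @param X A [patch_set] (or plain d x m matrix).
#' @param k Retained dimension (<= d and <= the numerical rank).
#' @param subtract_mean Whether to center the patches first.
#' @param eps Variance floor added before the inverse square-root scaling.
#' @return An object of class `whitening_transform` with fields `mean`
#'   (zeros when centering is disabled), `forward` (k x d), `backward`
#'   (d x k), `k`, `eigenvalues`, and `var_retained`.
#' @export
fit_whitening <- function(X, k, subtract_mean = FALSE, eps = 1e-8) {
  M <- if (inherits(X, "patch_set")) X$data else X
  if (!is.matrix(M)) stopf("`X` must be a patch_set or matrix")
  d <- nrow(M); m <- ncol(M)
  k <- check_count(k, "k")
  check_flag(subtract_mean, "subtract_mean")
  if (k > d) stopf("k (%d) exceeds patch dimension (%d)", k, d)
  if (m <= k) stopf("need more patches (%d) than retained dimensions (%d)", m, k)
  mu <- if (subtract_mean) rowMeans(M) else rep(0, d)
  Mc <- M - mu
  C <- tcrossprod(Mc) / m
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  rank <- sum(ev > max(ev[1L], .Machine$double.eps) * d * .Machine$double.eps)
  if (k > rank) {
    stopf("k (%d) exceeds the numerical rank of the data (%d)", k, rank)
  }
  Vk <- eg$vectors[, seq_len(k), drop = FALSE]
  scale_fwd <- 1 / sqrt(ev[seq_len(k)] + eps)
  structure(list(
    mean = mu,
    forward = t(Vk) * scale_fwd,              # k x d
    backward = Vk * rep(1 / scale_fwd, each = d),  # d x k
    k = k,
    eigenvalues = ev,
    var_retained = sum(ev[seq_len(k)]) / sum(ev)
  ), class = "whitening_transform")
}

#' @export
print.whitening_transform <- function(x, ...) {
  cat(sprintf("<whitening_transform d=%d -> k=%d, %.1f%% variance retained%s>\n",
              ncol(x$forward), x$k, 100 * x$var_retained,
              if (all(x$mean == 0)) "" else ", centered"))
  invisible(x)
}

#' Apply a whitening transform
#'
#' @param transform A `whitening_transform` from [fit_whitening()].
#' @param X d x m matrix (or [patch_set]) of patches.
#' @return k x m matrix of whitened patches.
#' @export
apply_whitening <- function(transform, X) {
  M <- if (inherits(X, "patch_set")) X$data else X
  if (is.numeric(M) && !is.matrix(M)) M <- matrix(M, ncol = 1L)
  if (nrow(M) != ncol(transform$forward)) {
    stopf("patch dimension %d does not match transform dimension %d",
          nrow(M), ncol(transform$forward))
  }
  transform$forward %*% (M - transform$mean)
}

#' Invert a whitening transform
#'
#' Maps whitened coordinates back to the input space; the composition
#' `invert_whitening(T, apply_whitening(T, x))` equals the rank-k PCA
#' reconstruction of `x`.
#'
#' @param transform A `whitening_transform`.
#' @param Y k x m matrix of whitened vectors.
#' @return d x m matrix in the original patch space.
#' @export
invert_whitening <- function(transform, Y) {
  if (is.numeric(Y) && !is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  if (nrow(Y) != transform$k) {
    stopf("input dimension %d does not match retained dimension %d",
          nrow(Y), transform$k)
  }
  transform$backward %*% Y + transform$mean
}
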