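# Assembling S/C layers into a trainable hierarchy.

#' S-layer entry of an architecture
#'
#' @param method Dictionary learner: `"ica"`, `"ssc"`, `"l2"`, or
#'   `"random_patch"`.
#' @param n_bases Number of bases/filters.
#' @param window_side Patch side sampled on the previous layer.
#' @param lambda SSC sparsity weight (required for `"ssc"`).
#' @param gamma L2 weight (required for `"l2"`).
#' @param whitening_k Retained PCA dimension for the ICA path; defaults to
#'   `n_bases` (ICA requires them equal).
#' @param subtract_mean Center patches before whitening (ICA path). The
#'   default keeps the mean in, so a DC-like basis can emerge.
#' @param normalize Apply the 0.2-clip unit-norm code normalization to this
#'   layer's inferred codes.
#' @param stride Window stride when computing the maps.
#' @return An object of class `s_layer_spec`.
#' @export
s_layer_spec <- function(method = c("ica", "ssc", "l2", "random_patch"),
                         n_bases, window_side, lambda = NULL, gamma = NULL,
                         whitening_k = NULL, subtract_mean = FALSE,
                         normalize = FALSE, stride = 1L) {
  method <- match.arg(method)
  n_bases <- check_count(n_bases, "n_bases")
  window_side <- check_count(window_side, "window_side")
  if (method == "ssc" && is.null(lambda)) stopf("SSC layer needs `lambda`")
  if (!is.null(lambda)) lambda <- check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  if (method == "l2" && is.null(gamma)) stopf("L2 layer needs `gamma`")
  if (!is.null(gamma)) gamma <- check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  check_flag(subtract_mean, "subtract_mean")
  check_flag(normalize, "normalize")
  structure(list(kind = "S", method = method, n_bases = n_bases,
                 window_side = window_side, lambda = lambda, gamma = gamma,
                 whitening_k = whitening_k %||% if (method == "ica") n_bases else NULL,
                 subtract_mean = subtract_mean, normalize = normalize,
                 stride = check_count(stride, "stride")),
            class = "s_layer_spec")
}

#' Architecture specification
#'
#' An ordered, alternating list of S entries ([s_layer_spec()]) and C
#' entries ([pooling_spec()]), starting with S, plus a terminal pooling
#' rule: a [pyramid_spec()] (abs-max per pyramid cell) or `"global_max"`
#' (one abs-max feature per final map).
#'
#' @param layers List of alternating `s_layer_spec` / `pooling_spec`.
#' @param terminal A `pyramid_spec` or the string `"global_max"`.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(layers, terminal = pyramid_spec()) {
  if (length(layers) < 1L) stopf("architecture needs at least one layer")
  want_s <- TRUE
  for (i in seq_along(layers)) {
    ok <- if (want_s) inherits(layers[[i]], "s_layer_spec")
          else inherits(layers[[i]], "pooling_spec")
    if (!ok) {
      stopf("layer %d must be %s (architectures alternate S, C, ... starting with S)",
            i, if (want_s) "an s_layer_spec" else "a pooling_spec")
    }
    want_s <- !want_s
  }
  if (!(inherits(terminal, "pyramid_spec") ||
        (is.character(terminal) && terminal == "global_max"))) {
    stopf("`terminal` must be a pyramid_spec or \"global_max\"")
  }
  structure(list(layers = layers, terminal = terminal),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  s_i <- 0L; c_i <- 0L
  for (ly in x$layers) {
    if (inherits(ly, "s_layer_spec")) {
      s_i <- s_i + 1L
      cat(sprintf("  S%d: %s, %d bases, window %d%s%s\n", s_i, ly$method,
                  ly$n_bases, ly$window_side,
                  if (!is.null(ly$lambda)) sprintf(", lambda %.3g", ly$lambda) else "",
                  if (ly$normalize) ", normalized" else ""))
    } else {
      c_i <- c_i + 1L
      cat(sprintf("  C%d: %s pooling, ratio %d, step %d\n", c_i, ly$mode,
                  ly$ratio, ly$step))
    }
  }
  cat("  terminal:",
      if (is.character(x$terminal)) x$terminal
      else paste0("pyramid {", paste(x$terminal$grids, collapse = ","), "}"), "\n")
  invisible(x)
}

#' Bundled architecture presets
#'
#' * `"exp1-5layer"`: S1-ICA / C1 / S2-ICA / C2 / S3-ICA with global
#'   abs-max terminal — the five-layer hierarchy used for unsupervised
#'   feature emergence and selectivity probes.
#' * `"archI-4layer"`: S1-ICA / C1 / S2-SSC with a {4,2,1} pyramid
#'   terminal — the four-layer classification architecture.
#' * `"archII-6layer"`: S1-ICA / C1 / S2-SSC / C2 (overlapping, step 2) /
#'   S3-SSC with a pyramid terminal — the six-layer classification
#'   architecture.
#'
#' Default sizes follow the reference setup (36/100/40 ICA bases, pooling
#' ratios 3 and 2, windows 10 and 4); pass overrides to scale experiments
#' down.
#'
#' @param name Preset name.
#' @param n_bases Integer vector overriding the per-S-layer basis counts.
#' @param windows Integer vector overriding per-S-layer window sides.
#' @param ratios Integer vector overriding the pooling ratios.
#' @param lambda SSC sparsity weight(s) for the SSC presets.
#' @param grids Pyramid grids for the pyramid-terminal presets.
#' @return An [architecture_spec()].
#' @export
hmax_preset <- function(name = c("exp1-5layer", "archI-4layer", "archII-6layer"),
                        n_bases = NULL, windows = NULL, ratios = NULL,
                        lambda = 0.15, grids = c(4, 2, 1)) {
  name <- match.arg(name)
  lam <- rep(lambda, length.out = 2L)
  switch(name,
    "exp1-5layer" = {
      nb <- n_bases %||% c(36L, 100L, 40L)
      wd <- windows %||% c(10L, 4L, 4L)
      rt <- ratios %||% c(3L, 2L)
      architecture_spec(list(
        s_layer_spec("ica", nb[1L], wd[1L]),
        pooling_spec(rt[1L]),
        s_layer_spec("ica", nb[2L], wd[2L]),
        pooling_spec(rt[2L]),
        s_layer_spec("ica", nb[3L], wd[3L])
      ), terminal = "global_max")
    },
    "archI-4layer" = {
      nb <- n_bases %||% c(8L, 1024L)
      wd <- windows %||% c(10L, 4L)
      rt <- ratios %||% c(3L)
      architecture_spec(list(
        s_layer_spec("ica", nb[1L], wd[1L]),
        pooling_spec(rt[1L]),
        s_layer_spec("ssc", nb[2L], wd[2L], lambda = lam[1L], normalize = TRUE)
      ), terminal = pyramid_spec(grids))
    },
    "archII-6layer" = {
      nb <- n_bases %||% c(8L, 256L, 1024L)
      wd <- windows %||% c(10L, 4L, 4L)
      rt <- ratios %||% c(3L, 2L)
      architecture_spec(list(
        s_layer_spec("ica", nb[1L], wd[1L]),
        pooling_spec(rt[1L]),
        s_layer_spec("ssc", nb[2L], wd[2L], lambda = lam[1L], normalize = TRUE),
        pooling_spec(rt[2L], step = 2L),
        s_layer_spec("ssc", nb[3L], wd[3L], lambda = lam[2L], normalize = TRUE)
      ), terminal = pyramid_spec(grids))
    }
  )
}

#' Train a sparse HMAX hierarchy without labels
#'
#' Greedy layerwise training: for each S layer in turn, the C maps of the
#' previous stage are computed for (a subset of) the training images,
#' `n_patches_per_layer` windows are sampled at random locations, a PCA
#' whitening transform is fitted when the layer is ICA, and the layer's
#' dictionary is learned. No labels are consumed and no layer is revisited.
#'
#' @param spec An [architecture_spec()] (or preset name for [hmax_preset()]).
#' @param images List of [gray_image] training images.
#' @param n_patches_per_layer Patches sampled for each S layer's learner.
#' @param seed Integer master seed; per-layer seeds are derived from it.
#' @param n_images_per_layer Optional cap on how many images feed each
#'   layer's patch sampling (all by default).
#' @param ssc_iters Alternations for SSC/L2 dictionary learning.
#' @param verbose Print per-layer progress.
#' @return An object of class `sparse_hmax`.
#' @export
train_unsupervised <- function(spec, images, n_patches_per_layer = 20000,
                               seed = 1, n_images_per_layer = NULL,
                               ssc_iters = 20, verbose = FALSE) {
  if (is.character(spec)) spec <- hmax_preset(spec)
  if (!inherits(spec, "architecture_spec")) stopf("`spec` must be an architecture_spec")
  if (is_gray_image(images)) images <- list(images)
  if (length(images) < 1L) stopf("need at least one training image")
  n_patches_per_layer <- check_count(n_patches_per_layer, "n_patches_per_layer")
  seed <- check_count(seed, "seed", min = 0L)

  trained <- vector("list", length(spec$layers))
  log <- list()
  # Per-image current representation (input stacks).
  current <- lapply(images, as_stack)
  s_i <- 0L
  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    if (inherits(ly, "pooling_spec")) {
      ok <- vapply(current, function(s) !is.null(s) &&
                     min(dim(s$maps)[2:3]) >= ly$ratio, logical(1L))
      current[!ok] <- list(NULL)
      current[ok] <- lapply(current[ok], c_layer_pool, spec = ly)
      trained[[li]] <- ly
      next
    }
    s_i <- s_i + 1L
    layer_seed <- (seed + 7919L * s_i) %% .Machine$integer.max
    # Drop images whose maps are smaller than the sampling window.
    ok <- vapply(current, function(s) !is.null(s) &&
                   min(dim(s$maps)[2:3]) >= ly$window_side, logical(1L))
    if (!any(ok)) {
      stopf("S%d: no image is large enough for window side %d", s_i, ly$window_side)
    }
    if (any(!ok)) {
      warning(sprintf("S%d: skipping %d image(s) smaller than the %d-pixel window",
                      s_i, sum(!ok), ly$window_side), call. = FALSE)
    }
    src_idx <- which(ok)
    if (!is.null(n_images_per_layer) && length(src_idx) > n_images_per_layer) {
      src_idx <- with_seed_(layer_seed,
                            sort(sample(src_idx, n_images_per_layer)))
    }
    # Spread the patch budget over the source images.
    n_img <- length(src_idx)
    per_img <- diff(floor(seq(0, n_patches_per_layer, length.out = n_img + 1L)))
    chunks <- vector("list", n_img)
    for (i in seq_len(n_img)) {
      if (per_img[i] == 0L) next
      chunks[[i]] <- sample_patches(current[[src_idx[i]]], ly$window_side,
                                    per_img[i],
                                    seed = (layer_seed + i) %% .Machine$integer.max)$data
    }
    X <- do.call(cbind, chunks[!vapply(chunks, is.null, logical(1L))])
    nch <- dim(current[[src_idx[1L]]]$maps)[1L]
    if (verbose) {
      message(sprintf("S%d [%s]: %d patches of %d x %d x %d", s_i, ly$method,
                      ncol(X), ly$window_side, ly$window_side, nch))
    }
    dict <- switch(ly$method,
      ica = {
        wt <- fit_whitening(X, k = ly$whitening_k,
                            subtract_mean = ly$subtract_mean)
        Xw <- apply_whitening(wt, X)
        learn_ica(Xw, n_components = ly$whitening_k, seed = layer_seed,
                  whitening = wt)
      },
      ssc = learn_ssc(X, n_bases = ly$n_bases, lambda = ly$lambda,
                      n_iters = ssc_iters, seed = layer_seed),
      l2 = learn_l2(X, n_bases = ly$n_bases, gamma = ly$gamma,
                    n_iters = ssc_iters, seed = layer_seed),
      random_patch = {
        srcs <- current[src_idx]
        random_patch_bases(srcs, n_bases = ly$n_bases,
                           patch_side = ly$window_side, seed = layer_seed)
      }
    )
    dict$patch_side <- ly$window_side
    dict$n_channels <- nch
    trained[[li]] <- list(spec = ly, dict = dict)
    log[[paste0("S", s_i)]] <- list(
      seed = layer_seed, n_patches = ncol(X), n_images = n_img,
      objective_trace = dict$meta$objective_trace,
      ica_converged = dict$meta$converged)
    # Compute this layer's maps for all usable images.
    current[!ok] <- list(NULL)
    current[which(ok)] <- lapply(current[which(ok)], function(s) {
      compute_s_maps(s, ly, dict, s_i)
    })
  }
  structure(list(spec = spec, layers = trained, training_log = log,
                 seed = seed, version = 1L),
            class = "sparse_hmax")
}

compute_s_maps <- function(stk, ly, dict, s_index) {
  out <- if (ly$method == "ica") {
    s <- s_layer_linear(stk, dict, stride = ly$stride)
    if (ly$normalize) {
      d <- dim(s$maps)
      codes <- normalize_codes(matrix(s$maps, d[1L], d[2L] * d[3L]))
      s$maps <- array(codes, d)
    }
    s
  } else {
    s_layer_sparse(stk, dict, stride = ly$stride, normalize = ly$normalize)
  }
  out$layer_label <- paste0("S", s_index)
  out
}

#' @export
print.sparse_hmax <- function(x, ...) {
  cat("<sparse_hmax model>\n")
  print(x$spec)
  invisible(x)
}

#' Run the S/C cascade on one image
#'
#' @param model A trained `sparse_hmax`.
#' @param image A [gray_image].
#' @param upto Optional layer label (`"S2"`, `"C1"`, ...) at which to stop.
#' @return Named list of [feature_map_stack]s (`S1`, `C1`, `S2`, ...).
#' @export
forward_pass <- function(model, image, upto = NULL) {
  stk <- as_stack(image)
  out <- list()
  s_i <- 0L; c_i <- 0L
  for (li in seq_along(model$layers)) {
    entry <- model$layers[[li]]
    if (inherits(entry, "pooling_spec")) {
      c_i <- c_i + 1L
      lab <- paste0("C", c_i)
      if (min(dim(stk$maps)[2:3]) < entry$ratio) {
        stopf("image too small at %s: maps are %d x %d but pooling ratio is %d",
              lab, dim(stk$maps)[2L], dim(stk$maps)[3L], entry$ratio)
      }
      stk <- c_layer_pool(stk, entry)
      stk$layer_label <- lab
    } else {
      s_i <- s_i + 1L
      lab <- paste0("S", s_i)
      if (min(dim(stk$maps)[2:3]) < entry$spec$window_side) {
        stopf("image too small at %s: maps are %d x %d but window side is %d (minimal input side ~%d)",
              lab, dim(stk$maps)[2L], dim(stk$maps)[3L],
              entry$spec$window_side, minimal_input_side(model))
      }
      stk <- compute_s_maps(stk, entry$spec, entry$dict, s_i)
    }
    out[[lab]] <- stk
    if (!is.null(upto) && identical(lab, upto)) return(out)
  }
  if (!is.null(upto)) stopf("layer '%s' not present in this architecture", upto)
  out
}

# Smallest square input that survives every window/pooling stage.
minimal_input_side <- function(model) {
  side <- 1L
  for (entry in rev(model$layers)) {
    if (inherits(entry, "pooling_spec")) {
      side <- (side - 1L) * entry$step + entry$ratio
    } else {
      side <- (side - 1L) * entry$spec$stride + entry$spec$window_side
    }
  }
  side
}

#' Extract the terminal feature vector of an image
#'
#' Runs the full cascade and applies the architecture's terminal pooling:
#' abs-max over each spatial-pyramid cell, or a single abs-max per map for
#' `"global_max"`.
#'
#' @param model A trained `sparse_hmax`.
#' @param image A [gray_image].
#' @return Numeric feature vector.
#' @export
extract_features <- function(model, image) {
  maps <- forward_pass(model, image)
  top <- maps[[length(maps)]]
  if (is.character(model$spec$terminal)) {
    apply(abs(top$maps), 1L, max)
  } else {
    spatial_pyramid_pool(top, model$spec$terminal)
  }
}

#' Maximum absolute response of one unit to an image
#'
#' The scalar used throughout the selectivity analyses: the maximum of the
#' absolute responses of the unit's map across all positions.
#'
#' @param model A trained `sparse_hmax`.
#' @param layer Layer label, e.g. `"S3"`.
#' @param unit Unit (map) index within the layer.
#' @param image A [gray_image].
#' @return A single number.
#' @export
unit_response <- function(model, layer, unit, image) {
  maps <- forward_pass(model, image, upto = layer)
  stk <- maps[[layer]]
  if (is.null(stk)) stopf("layer '%s' not present", layer)
  unit <- check_count(unit, "unit")
  if (unit > dim(stk$maps)[1L]) {
    stopf("unit %d out of range: layer %s has %d maps", unit, layer,
          dim(stk$maps)[1L])
  }
  max(abs(stk$maps[unit, , ]))
}

#' Responses of every unit in a layer to a set of images
#'
#' Convenience wrapper building the units x images response matrix of
#' [unit_response()] values used by the selectivity analyses.
#'
#' @param model A trained `sparse_hmax`.
#' @param layer Layer label.
#' @param images List of [gray_image].
#' @return units x images numeric matrix.
#' @export
layer_responses <- function(model, layer, images) {
  if (is_gray_image(images)) images <- list(images)
  cols <- vapply(images, function(img) {
    stk <- forward_pass(model, img, upto = layer)[[layer]]
    apply(abs(stk$maps), 1L, max)
  }, numeric(n_units_at(model, layer)))
  matrix(cols, ncol = length(images))
}

n_units_at <- function(model, layer) {
  s_i <- 0L; c_i <- 0L; n <- NA_integer_
  for (entry in model$layers) {
    if (inherits(entry, "pooling_spec")) {
      c_i <- c_i + 1L
      if (identical(layer, paste0("C", c_i))) return(n)
    } else {
      s_i <- s_i + 1L
      n <- n_bases_of(entry$dict)
      if (identical(layer, paste0("S", s_i))) return(n)
    }
  }
  stopf("layer '%s' not present", layer)
}

#' Visualize a unit's basis in image space
#'
#' Recursive back-projection: starting from the unit's basis at its layer,
#' coefficients over previous-layer units are distributed uniformly across
#' each pooling window (every position in a window receives the same
#' activation, so the patch is enlarged to counterbalance pooling
#' shrinkage), combined linearly through the lower-layer bases, and finally
#' mapped through the whitening back-projection to the pixel plane. The
#' output side equals the unit's cumulative receptive-field side.
#'
#' @param model A trained `sparse_hmax`.
#' @param layer S-layer index (1-based) or label like `"S3"`.
#' @param unit Unit index within that layer.
#' @return A [gray_image] of the unit's preferred pattern.
#' @export
visualize_basis <- function(model, layer, unit) {
  s_index <- if (is.character(layer)) {
    as.integer(sub("^S", "", layer))
  } else as.integer(layer)
  if (is.na(s_index) || s_index < 1L) stopf("`layer` must name an S layer")
  s_entries <- Filter(function(e) !inherits(e, "pooling_spec"), model$layers)
  if (s_index > length(s_entries)) {
    stopf("layer S%d not present (model has %d S layers)", s_index,
          length(s_entries))
  }
  # Positions of S and C entries in the layer list.
  entries <- model$layers
  s_pos <- which(!vapply(entries, inherits, logical(1L), "pooling_spec"))
  unit <- check_count(unit, "unit")
  top_dict <- entries[[s_pos[s_index]]]$dict
  if (unit > n_bases_of(top_dict)) {
    stopf("unit %d out of range: S%d has %d bases", unit, s_index,
          n_bases_of(top_dict))
  }
  # Start: one activation of 1 for the chosen unit at a single position.
  act <- array(0, dim = c(n_bases_of(top_dict), 1L, 1L))
  act[unit, 1L, 1L] <- 1
  li <- s_pos[s_index]
  repeat {
    entry <- entries[[li]]
    act <- backproject_s(act, entry)
    li <- li - 1L
    if (li < 1L) break
    # Pooling expansion: every position in a window inherits the C value.
    pool <- entries[[li]]
    act <- backproject_pool(act, pool)
    li <- li - 1L
  }
  gray_image(act[1L, , ], origin = sprintf("basis S%d/%d", s_index, unit))
}

# S-layer back-projection: activations over S units at positions ->
# activation maps over the layer's input channels.
backproject_s <- function(act, entry) {
  dict <- entry$dict
  p <- dict$patch_side
  nch <- dict$n_channels
  stride <- entry$spec$stride
  # Bases in the layer's input space (de-whitened for ICA).
  B <- dict$bases                      # d x n, d = p^2 * nch
  n <- ncol(B)
  h <- dim(act)[2L]; w <- dim(act)[3L]
  side_h <- (h - 1L) * stride + p
  side_w <- (w - 1L) * stride + p
  out <- array(0, dim = c(nch, side_h, side_w))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      a <- act[, i, j]
      nz <- which(a != 0)
      if (length(nz) == 0L) next
      patch <- B[, nz, drop = FALSE] %*% a[nz]   # d x 1
      patch <- array(patch, dim = c(p, p, nch))  # column-major: di, dj, ch
      r0 <- (i - 1L) * stride; c0 <- (j - 1L) * stride
      for (ch in seq_len(nch)) {
        out[ch, r0 + seq_len(p), c0 + seq_len(p)] <-
          out[ch, r0 + seq_len(p), c0 + seq_len(p)] + patch[, , ch]
      }
    }
  }
  out
}

# C-layer back-projection: every S position inside a pooling window is
# assigned the window's activation (overlapping windows accumulate).
backproject_pool <- function(act, pool) {
  nch <- dim(act)[1L]; h <- dim(act)[2L]; w <- dim(act)[3L]
  r <- pool$ratio; st <- pool$step
  side_h <- (h - 1L) * st + r
  side_w <- (w - 1L) * st + r
  out <- array(0, dim = c(nch, side_h, side_w))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r0 <- (i - 1L) * st; c0 <- (j - 1L) * st
      out[, r0 + seq_len(r), c0 + seq_len(r)] <-
        out[, r0 + seq_len(r), c0 + seq_len(r)] + act[, i, j]
    }
  }
  out
}

# Note: basis patches are stored channel-major (ch outer), but the
# column-major array() fill above needs di, dj, ch order; reorder rows.
# B's rows are ordered (ch, dj, di) with di fastest; array(d, c(p, p, nch))
# expects di fastest, then dj, then ch — identical ordering, no reorder.

#' Contact sheet of basis visualizations
#'
#' Arranges unit visualizations of one layer on a grid in a single image
#' (each tile min-max normalized independently, 1-pixel separator).
#'
#' @param model A trained `sparse_hmax`.
#' @param layer S-layer index or label.
#' @param units Unit indices (default: all units of the layer).
#' @param ncol Number of tiles per row.
#' @return A [gray_image] montage.
#' @export
basis_contact_sheet <- function(model, layer, units = NULL, ncol = NULL) {
  s_index <- if (is.character(layer)) as.integer(sub("^S", "", layer)) else layer
  s_entries <- Filter(function(e) !inherits(e, "pooling_spec"), model$layers)
  n <- n_bases_of(s_entries[[s_index]]$dict)
  units <- units %||% seq_len(n)
  tiles <- lapply(units, function(u) {
    px <- as.matrix(visualize_basis(model, s_index, u))
    rng <- range(px)
    if (rng[2L] > rng[1L]) (px - rng[1L]) / (rng[2L] - rng[1L]) else px * 0
  })
  side <- max(vapply(tiles, nrow, integer(1L)))
  nc <- ncol %||% ceiling(sqrt(length(tiles)))
  nr <- ceiling(length(tiles) / nc)
  sheet <- matrix(1, nr * (side + 1L) + 1L, nc * (side + 1L) + 1L)
  for (t in seq_along(tiles)) {
    i <- (t - 1L) %/% nc; j <- (t - 1L) %% nc
    tl <- tiles[[t]]
    sheet[i * (side + 1L) + 1L + seq_len(nrow(tl)),
          j * (side + 1L) + 1L + seq_len(ncol(tl))] <- tl
  }
  gray_image(sheet, origin = sprintf("contact_sheet S%d", s_index))
}

#' Save a trained model
#'
#' Serializes the full model (architecture, whitening transforms,
#' dictionaries, training log) to a single RDS container; the round trip
#' through [load_model()] is bit-exact.
#'
#' @param model A `sparse_hmax`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "sparse_hmax")) stopf("`model` must be a sparse_hmax")
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the saved model.
#' @return A `sparse_hmax`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("no such model file: '%s'", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stopf("corrupt model file '%s': %s",
                                              path, conditionMessage(e)))
  if (!inherits(model, "sparse_hmax")) stopf("'%s' is not a sparse_hmax model", path)
  if (!identical(model$version, 1L)) {
    stopf("model version %s not supported by this build", model$version)
  }
  model
}
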