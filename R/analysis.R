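# Quantitative probes: pooling-induced correlation statistics, ROC/AUC
# selectivity, category assignment, detector thresholds, invariance curves.

#' Pooling-induced correlation statistics
#'
#' Reproduces the correlation study of linear-filter responses before and
#' after pooling. S1 maps are computed by linear filtering in the whitened
#' space (an ICA dictionary); C1 maps by pooling at each requested (mode,
#' ratio). For random in-map locations, Pearson correlation coefficients
#' are collected for three pairing cases:
#' \enumerate{
#'   \item different filters at the same location (n(n-1) coefficients,
#'     the off-diagonal of the n x n correlation matrix),
#'   \item the same filter at two locations separated by `offset` in both
#'     coordinates (n coefficients, the diagonal of the cross-location
#'     correlation matrix),
#'   \item different filters at different locations (n(n-1) coefficients).
#' }
#' On C1 maps the offset is divided by the pooling ratio (minimum 1) to
#' keep the image-plane separation comparable. Whitening makes the S1
#' responses uncorrelated; max pooling induces clear correlations in all
#' three cases, while average pooling leaves the two different-location
#' cases near zero.
#'
#' @param filters An ICA dictionary ([learn_ica()]) with its whitening
#'   transform and `patch_side` set.
#' @param images List of [gray_image].
#' @param ratios Integer vector of pooling ratios for the C1 sweeps.
#' @param modes Character vector among `"max"`, `"average"`, `"square"`.
#' @param offset Location offset in S1-map pixels (image plane). The
#'   default 16 is divisible by every default ratio, so the image-plane
#'   separation is identical on S1 and every C1 sweep, and exceeds the
#'   default filter side, so paired windows never overlap.
#' @param n_locations Sample locations per image per layer.
#' @param seed Integer seed for location sampling.
#' @return An object of class `correlation_report`: list with
#'   `coefficients` (long data.frame: layer, mode, ratio, case, value) and
#'   `summary` (mean |coefficient| and count per collection).
#' @export
correlation_study <- function(filters, images, ratios = c(2, 4, 8, 16),
                              modes = c("max", "average", "square"),
                              offset = 16, n_locations = 500, seed = 1) {
  if (!inherits(filters, "shx_dictionary")) stopf("`filters` must be a dictionary")
  if (is_gray_image(images)) images <- list(images)
  if (length(images) < 1L) stopf("need at least one image")
  offset <- check_count(offset, "offset")
  n_locations <- check_count(n_locations, "n_locations")
  modes <- match.arg(modes, several.ok = TRUE)

  s1 <- lapply(images, function(img) s_layer_linear(img, filters))
  coef_rows <- list()

  collect <- function(stacks, off, layer, mode, ratio, loc_seed) {
    A_list <- list(); B_list <- list()
    for (ii in seq_along(stacks)) {
      a <- stacks[[ii]]$maps
      H <- dim(a)[2L]; W <- dim(a)[3L]
      if (H - off < 1L || W - off < 1L) {
        stopf("offset %d too large for %s maps of size %d x %d", off, layer, H, W)
      }
      pair <- with_seed_((loc_seed + ii) %% .Machine$integer.max, {
        ri <- sample.int(H - off, n_locations, replace = TRUE)
        ci <- sample.int(W - off, n_locations, replace = TRUE)
        list(ri = ri, ci = ci)
      })
      n <- dim(a)[1L]
      # responses at base and offset locations: samples x filters
      A_list[[ii]] <- t(matrix(a[cbind(rep(seq_len(n), each = n_locations),
                                       rep(pair$ri, times = n),
                                       rep(pair$ci, times = n))],
                               n_locations, n))
      B_list[[ii]] <- t(matrix(a[cbind(rep(seq_len(n), each = n_locations),
                                       rep(pair$ri + off, times = n),
                                       rep(pair$ci + off, times = n))],
                               n_locations, n))
    }
    A <- t(do.call(cbind, A_list))   # samples x filters
    B <- t(do.call(cbind, B_list))
    C_same <- stats::cor(A)
    C_cross <- stats::cor(A, B)
    off_diag <- function(M) M[row(M) != col(M)]
    list(
      data.frame(layer = layer, mode = mode, ratio = ratio,
                 case = "diff_filter_same_loc", value = off_diag(C_same)),
      data.frame(layer = layer, mode = mode, ratio = ratio,
                 case = "same_filter_diff_loc", value = diag(C_cross)),
      data.frame(layer = layer, mode = mode, ratio = ratio,
                 case = "diff_filter_diff_loc", value = off_diag(C_cross))
    )
  }

  coef_rows <- c(coef_rows, collect(s1, offset, "S1", NA_character_,
                                    NA_integer_, seed))
  for (mode in modes) {
    for (ratio in ratios) {
      pooled <- lapply(s1, c_layer_pool, spec = pooling_spec(ratio, mode))
      off_c <- max(1L, as.integer(round(offset / ratio)))
      coef_rows <- c(coef_rows,
                     collect(pooled, off_c, "C1", mode, ratio,
                             seed + 131L * ratio))
    }
  }
  coefficients <- do.call(rbind, coef_rows)
  if (any(coefficients$value < -1 - 1e-8 | coefficients$value > 1 + 1e-8)) {
    stopf("internal error: correlation coefficient outside [-1, 1]")
  }
  summary <- stats::aggregate(value ~ layer + mode + ratio + case,
                              data = transform(coefficients,
                                               mode = ifelse(is.na(mode), "none", mode),
                                               ratio = ifelse(is.na(ratio), 0L, ratio)),
                              FUN = function(v) mean(abs(v)), na.action = NULL)
  names(summary)[names(summary) == "value"] <- "mean_abs"
  counts <- stats::aggregate(value ~ layer + mode + ratio + case,
                             data = transform(coefficients,
                                              mode = ifelse(is.na(mode), "none", mode),
                                              ratio = ifelse(is.na(ratio), 0L, ratio)),
                             FUN = length, na.action = NULL)
  summary$n_coef <- counts$value
  structure(list(coefficients = coefficients, summary = summary,
                 offset = offset, n_locations = n_locations),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Mean |coefficient| for one collection of a correlation report.
report_mean_abs <- function(report, layer, case, mode = "none", ratio = 0L) {
  s <- report$summary
  hit <- s$layer == layer & s$case == case & s$mode == mode & s$ratio == ratio
  if (!any(hit)) stopf("no such collection in report")
  s$mean_abs[hit]
}

#' ROC curve and AUC for one unit
#'
#' AUC is the tie-aware Mann–Whitney statistic
#' `P(pos > neg) + 0.5 P(pos == neg)`, computed from ranks; the ROC curve
#' is built by sweeping a threshold over the pooled unique response values
#' (rule: positive iff response >= threshold), anchored at (0,0) and (1,1).
#' The threshold-sweep area and the rank statistic agree exactly under
#' this convention.
#'
#' @param pos_responses Responses to positive-class stimuli.
#' @param neg_responses Responses to negative-class stimuli.
#' @param unit Optional unit identifier stored in the result.
#' @return An object of class `unit_selectivity` with `auc` and `roc`
#'   (data.frame of fpr, tpr).
#' @export
roc_auc <- function(pos_responses, neg_responses, unit = NA_integer_) {
  if (length(pos_responses) < 1L || length(neg_responses) < 1L) {
    stopf("both response collections must be non-empty")
  }
  np <- length(pos_responses); nn <- length(neg_responses)
  r <- rank(c(pos_responses, neg_responses))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(pos_responses, neg_responses)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(pos_responses >= t), numeric(1L)))
  fpr <- c(0, vapply(thr, function(t) mean(neg_responses >= t), numeric(1L)))
  structure(list(unit = unit, auc = auc,
                 roc = data.frame(fpr = fpr, tpr = tpr),
                 threshold = NA_real_, accuracy = NA_real_),
            class = "unit_selectivity")
}

#' @export
print.unit_selectivity <- function(x, ...) {
  cat(sprintf("<unit_selectivity unit %s: AUC %.4f%s>\n",
              as.character(x$unit), x$auc,
              if (is.finite(x$accuracy)) sprintf(", accuracy %.3f", x$accuracy) else ""))
  invisible(x)
}

#' Most selective unit for a target label
#'
#' Scans every unit's one-vs-rest AUC for the target label and returns the
#' winner (ties broken by the lowest unit index).
#'
#' @param responses units x images response matrix.
#' @param labels Label per image (length = ncol(responses)).
#' @param target_label The positive-class label.
#' @return A `unit_selectivity` for the winning unit.
#' @export
most_selective_unit <- function(responses, labels, target_label) {
  if (!is.matrix(responses)) stopf("`responses` must be a units x images matrix")
  if (length(labels) != ncol(responses)) stopf("one label per image required")
  if (!target_label %in% labels) stopf("label '%s' absent from `labels`", target_label)
  pos <- labels == target_label
  aucs <- apply(responses, 1L, function(v) roc_auc(v[pos], v[!pos])$auc)
  best <- which.max(aucs)  # which.max returns the first (lowest) maximizer
  out <- roc_auc(responses[best, pos], responses[best, !pos], unit = best)
  out
}

#' Per-unit one-vs-rest AUC table
#'
#' @param responses units x images response matrix.
#' @param labels Label per image.
#' @return data.frame with unit, label, auc (one row per unit x label).
#' @export
unit_auc_table <- function(responses, labels) {
  cats <- sort(unique(labels))
  do.call(rbind, lapply(cats, function(cat) {
    pos <- labels == cat
    data.frame(unit = seq_len(nrow(responses)), label = cat,
               auc = apply(responses, 1L, function(v) roc_auc(v[pos], v[!pos])$auc))
  }))
}

#' AUC-based category assignment and max-response prediction
#'
#' Two-stage readout of an unsupervised layer: (1) each unit is assigned
#' the category for which its one-vs-rest AUC on the training responses is
#' maximal (ties: first category in sorted order); (2) each test image is
#' predicted as the assigned category of the unit with the highest
#' response (ties: lowest unit index).
#'
#' @param train_responses units x images training response matrix.
#' @param train_labels Training label per image.
#' @param test_responses units x images test response matrix.
#' @param test_labels Optional test labels; when given, accuracy is
#'   reported.
#' @return List with `unit_labels`, `predicted`, and `accuracy` (NA
#'   without test labels).
#' @export
assign_and_predict <- function(train_responses, train_labels, test_responses,
                               test_labels = NULL) {
  if (length(unique(train_labels)) < 2L) stopf("need at least 2 categories")
  if (nrow(train_responses) != nrow(test_responses)) {
    stopf("train and test response matrices must have the same unit count")
  }
  cats <- sort(unique(train_labels))
  auc_mat <- vapply(cats, function(cat) {
    pos <- train_labels == cat
    if (!any(pos) || all(pos)) stopf("category '%s' missing or exhaustive in training", cat)
    apply(train_responses, 1L, function(v) roc_auc(v[pos], v[!pos])$auc)
  }, numeric(nrow(train_responses)))
  auc_mat <- matrix(auc_mat, nrow = nrow(train_responses),
                    dimnames = list(NULL, cats))
  unit_labels <- cats[apply(auc_mat, 1L, which.max)]
  best_unit <- apply(test_responses, 2L, which.max)
  predicted <- unit_labels[best_unit]
  accuracy <- if (!is.null(test_labels)) mean(predicted == test_labels) else NA_real_
  list(unit_labels = unit_labels, predicted = predicted, accuracy = accuracy,
       unit_auc = auc_mat)
}

#' Select a detection threshold on a response scale
#'
#' Tests `n_thresholds` equally spaced thresholds between the minimum and
#' maximum training activation (rule: positive iff activation > threshold)
#' and returns the accuracy-maximizing threshold, the lowest such value on
#' ties. A degenerate min == max range yields that single threshold.
#'
#' @param train_activations Activations on the training set.
#' @param train_is_positive Logical vector, TRUE for positive samples.
#' @param n_thresholds Number of candidate thresholds.
#' @return List with `threshold`, `accuracy`, and the candidate grid.
#' @export
select_threshold <- function(train_activations, train_is_positive,
                             n_thresholds = 20) {
  if (!any(train_is_positive) || all(train_is_positive)) {
    stopf("need at least one positive and one negative training sample")
  }
  n_thresholds <- check_count(n_thresholds, "n_thresholds", min = 1L)
  lo <- min(train_activations); hi <- max(train_activations)
  grid <- if (lo == hi) lo else seq(lo, hi, length.out = n_thresholds)
  acc <- vapply(grid, function(t) {
    mean((train_activations > t) == train_is_positive)
  }, numeric(1L))
  best <- which.max(acc)  # first maximizer = lowest threshold on ties
  list(threshold = grid[best], accuracy = acc[best], grid = grid,
       grid_accuracy = acc)
}

#' Mean unit activation across a distortion sweep
#'
#' Applies a distortion of each magnitude to every image, measures the
#' unit's max-abs response, and averages across images — the invariance
#' curve of that unit, optionally compared against a detection threshold.
#'
#' @param model A trained `sparse_hmax`.
#' @param layer Layer label, e.g. `"S3"`.
#' @param unit Unit index.
#' @param images List of [gray_image].
#' @param distortion_kind Passed to [distortion_spec()].
#' @param magnitudes Sorted vector of distortion magnitudes.
#' @param threshold Optional detection threshold.
#' @param fill Optional fill value forwarded to the distortion.
#' @return data.frame with magnitude and mean_activation; if a threshold
#'   is given, attribute `frac_above` holds the fraction of magnitudes
#'   whose mean stays above it.
#' @export
invariance_curve <- function(model, layer, unit, images, distortion_kind,
                             magnitudes, threshold = NULL, fill = NULL) {
  if (is_gray_image(images)) images <- list(images)
  if (length(images) < 1L) stopf("need at least one image")
  if (is.unsorted(magnitudes)) stopf("`magnitudes` must be sorted increasingly")
  means <- vapply(magnitudes, function(m) {
    spec <- distortion_spec(distortion_kind, m, fill = fill)
    mean(vapply(images, function(img) {
      unit_response(model, layer, unit, distort(img, spec))
    }, numeric(1L)))
  }, numeric(1L))
  out <- data.frame(magnitude = magnitudes, mean_activation = means)
  if (!is.null(threshold)) {
    attr(out, "frac_above") <- mean(means > threshold)
    attr(out, "threshold") <- threshold
  }
  out
}
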