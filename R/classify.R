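# Feature-level classification: random balanced splits, one-vs-rest linear
# SVM, and the mean +/- std evaluation protocol.

#' Split specification
#'
#' @param n_train_per_category Training images drawn per category.
#' @param n_splits Number of random splits.
#' @param seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(n_train_per_category, n_splits = 10, seed = 1) {
  structure(list(
    n_train_per_category = check_count(n_train_per_category, "n_train_per_category"),
    n_splits = check_count(n_splits, "n_splits"),
    seed = check_count(seed, "seed", min = 0L)),
    class = "split_spec")
}

#' Random balanced train/test splits
#'
#' For each split, exactly `n_train_per_category` indices per category are
#' drawn without replacement for training; the remainder go to testing.
#'
#' @param labels Label per sample.
#' @param spec A [split_spec()].
#' @return List of `n_splits` lists with integer `train` and `test`.
#' @export
make_splits <- function(labels, spec) {
  if (!inherits(spec, "split_spec")) stopf("`spec` must be a split_spec")
  tab <- table(labels)
  small <- names(tab)[tab <= spec$n_train_per_category]
  if (length(small) > 0L) {
    stopf("category '%s' has only %d samples; need more than n_train_per_category = %d",
          small[1L], tab[small[1L]], spec$n_train_per_category)
  }
  idx_by_cat <- split(seq_along(labels), labels)
  with_seed_(spec$seed, {
    lapply(seq_len(spec$n_splits), function(s) {
      train <- sort(unlist(lapply(idx_by_cat, function(ix) {
        sample(ix, spec$n_train_per_category)
      }), use.names = FALSE))
      list(train = train, test = setdiff(seq_along(labels), train))
    })
  })
}

#' Train a one-vs-rest linear SVM
#'
#' Fits one binary linear SVM (hinge loss, L2 regularization, via
#' \pkg{e1071}) per category against the rest; prediction takes the argmax
#' of the per-class decision values.
#'
#' @param features samples x d numeric feature matrix.
#' @param labels Label per sample (>= 2 classes).
#' @param cost SVM cost parameter (inverse regularization strength).
#' @return An object of class `linear_ovr_svm`.
#' @export
train_linear_classifier <- function(features, labels, cost = 1) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!all(is.finite(features))) stopf("features must be finite")
  cats <- sort(unique(as.character(labels)))
  if (length(cats) < 2L) stopf("need at least 2 classes, got %d", length(cats))
  cost <- check_number(cost, "cost", min = 0, strict_min = TRUE)
  fits <- lapply(cats, function(cat) {
    y <- factor(ifelse(labels == cat, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(features, y, kernel = "linear", cost = cost,
                      scale = FALSE, fitted = FALSE)
    # libsvm orients decision values by order of appearance in the data;
    # normalize so larger decision value always means "this category".
    dv <- as.numeric(attr(stats::predict(fit, features,
                                         decision.values = TRUE),
                          "decision.values"))
    orient <- mean(dv[y == "pos"]) - mean(dv[y == "neg"])
    list(fit = fit, sign = if (orient >= 0) 1 else -1)
  })
  names(fits) <- cats
  structure(list(fits = fits, categories = cats, cost = cost),
            class = "linear_ovr_svm")
}

#' @export
predict.linear_ovr_svm <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  scores <- vapply(object$fits, function(f) {
    f$sign * as.numeric(attr(stats::predict(f$fit, newdata,
                                            decision.values = TRUE),
                             "decision.values"))
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata),
                   dimnames = list(NULL, object$categories))
  object$categories[apply(scores, 1L, which.max)]
}

#' Evaluate features under the random-split protocol
#'
#' For each split: train the one-vs-rest linear SVM on the training rows,
#' predict the test rows, record accuracy; report mean and standard
#' deviation across splits.
#'
#' @param features samples x d feature matrix.
#' @param labels Label per sample.
#' @param spec A [split_spec()].
#' @param cost SVM cost parameter.
#' @return List with `accuracies` (per split), `mean`, `sd`, and a
#'   Table-style `formatted` string in percent with two decimals.
#' @export
evaluate_protocol <- function(features, labels, spec, cost = 1) {
  if (!is.matrix(features)) features <- as.matrix(features)
  splits <- make_splits(labels, spec)
  accs <- vapply(splits, function(sp) {
    clf <- train_linear_classifier(features[sp$train, , drop = FALSE],
                                   labels[sp$train], cost = cost)
    mean(predict(clf, features[sp$test, , drop = FALSE]) == labels[sp$test])
  }, numeric(1L))
  sd_val <- if (length(accs) > 1L) stats::sd(accs) else 0
  list(accuracies = accs, mean = mean(accs), sd = sd_val,
       formatted = sprintf("%.2f±%.2f", 100 * mean(accs), 100 * sd_val))
}

#' Concatenate feature blocks from several models
#'
#' Feature-level merge of two (or more) architectures: plain column
#' concatenation with per-block provenance retained as an attribute.
#'
#' @param ... samples x d feature matrices with equal row counts.
#' @param block_names Optional names recorded per block.
#' @return Combined feature matrix with attribute `blocks`.
#' @export
concat_features <- function(..., block_names = NULL) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1L]]) && !is.matrix(blocks[[1L]])) {
    blocks <- blocks[[1L]]
  }
  blocks <- lapply(blocks, as.matrix)
  nr <- unique(vapply(blocks, nrow, integer(1L)))
  if (length(nr) != 1L) stopf("all feature blocks must have the same row count")
  out <- do.call(cbind, blocks)
  nm <- block_names %||% paste0("block", seq_along(blocks))
  attr(out, "blocks") <- data.frame(name = nm,
                                    ncol = vapply(blocks, ncol, integer(1L)))
  out
}
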