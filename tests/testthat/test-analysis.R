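# ROC/AUC selectivity, category readout, thresholds, correlation probes.

test_that("AUC equals the tie-aware rank statistic and the pairwise oracle", {
  expect_equal(roc_auc(c(2, 3), c(0, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 5), rep(1, 7))$auc, 0.5)
  withr::with_seed(100, {
    for (trial in 1:10) {
      pos <- sample(0:10, 8, replace = TRUE)   # discrete => ties occur
      neg <- sample(0:10, 11, replace = TRUE)
      expect_equal(roc_auc(pos, neg)$auc, brute_auc(pos, neg))
    }
  })
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(101, {
    pos <- stats::rnorm(40, mean = 1)
    neg <- stats::rnorm(60)
  })
  ours <- roc_auc(pos, neg)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curves are monotone, anchored, and AUC is monotone-transform invariant", {
  withr::with_seed(102, {
    pos <- stats::rnorm(30, 0.5)
    neg <- stats::rnorm(30)
  })
  sel <- roc_auc(pos, neg)
  expect_true(all(diff(sel$roc$fpr) >= 0))
  expect_true(all(diff(sel$roc$tpr) >= 0))
  expect_equal(sel$roc$fpr[1], 0); expect_equal(sel$roc$tpr[1], 0)
  expect_equal(utils::tail(sel$roc$fpr, 1), 1)
  expect_equal(utils::tail(sel$roc$tpr, 1), 1)
  expect_equal(roc_auc(exp(pos), exp(neg))$auc, sel$auc)
  expect_equal(roc_auc(pos^3, neg^3)$auc, sel$auc)
})

test_that("most selective unit matches an exhaustive per-unit scan", {
  labels <- rep(c("a", "b"), each = 10)
  withr::with_seed(103, R <- matrix(stats::runif(8 * 20), 8, 20))
  R[5, labels == "a"] <- R[5, labels == "a"] + 2  # plant a selective unit
  best <- most_selective_unit(R, labels, "a")
  aucs <- apply(R, 1, function(v) brute_auc(v[labels == "a"], v[labels != "a"]))
  expect_equal(best$unit, which.max(aucs))
  expect_equal(best$auc, max(aucs))
  # all-constant responses: AUC 0.5 everywhere, unit 1 wins the tie
  const <- matrix(1, 4, 20)
  expect_equal(most_selective_unit(const, labels, "b")$unit, 1L)
  expect_equal(most_selective_unit(const, labels, "b")$auc, 0.5)
  expect_error(most_selective_unit(R, labels, "zebra"), "absent")
})

test_that("assignment and prediction recover a block-diagonal response structure", {
  labels <- rep(c("a", "b", "c"), each = 6)
  R <- matrix(0, 3, 18)
  R[1, labels == "a"] <- 1
  R[2, labels == "b"] <- 1
  R[3, labels == "c"] <- 1
  res <- assign_and_predict(R, labels, R, labels)
  expect_equal(res$accuracy, 1)
  expect_equal(res$unit_labels, c("a", "b", "c"))
  # response tie on a test column: lowest unit index wins
  tied <- matrix(1, 3, 1)
  res2 <- assign_and_predict(R, labels, tied, "a")
  expect_equal(res2$predicted, "a")
  expect_error(assign_and_predict(R, rep("a", 18), R), "2 categories")
})

test_that("uniform random responses predict at chance level", {
  k <- 13L
  labels <- rep(letters[seq_len(k)], each = 8)
  withr::with_seed(104, {
    accs <- vapply(1:30, function(i) {
      Rtr <- matrix(stats::runif(40 * length(labels)), 40)
      Rte <- matrix(stats::runif(40 * length(labels)), 40)
      assign_and_predict(Rtr, labels, Rte, labels)$accuracy
    }, numeric(1L))
  })
  expect_equal(mean(accs), 1 / k, tolerance = 0.35)
})

test_that("threshold selection scans the documented grid and maximizes accuracy", {
  act <- 0:19
  is_pos <- act >= 12
  res <- select_threshold(act, is_pos, n_thresholds = 20)
  expect_equal(res$grid, as.numeric(0:19))
  expect_equal(res$accuracy, 1)
  # oracle: exhaustive scan over the same grid
  withr::with_seed(105, {
    a <- stats::rnorm(50)
    p <- a + stats::rnorm(50) > 0.3
  })
  if (any(p) && !all(p)) {
    res2 <- select_threshold(a, p)
    accs <- vapply(res2$grid, function(t) mean((a > t) == p), numeric(1L))
    expect_equal(res2$accuracy, max(accs))
    expect_equal(res2$threshold, res2$grid[which.max(accs)])
  }
  # degenerate constant activations
  res3 <- select_threshold(rep(2, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(res3$threshold, 2)
  expect_error(select_threshold(1:5, rep(TRUE, 5)), "positive")
})

test_that("correlation collections have documented sizes and sane baselines", {
  # white-noise images, identity-free check of collection sizes and the
  # near-zero baseline for independent responses
  imgs <- synth_noise_images(6, 64, "white", seed = 106, contrast_sd = 0)
  X <- do.call(cbind, lapply(1:6, function(i)
    sample_patches(imgs[[i]], 6, 800, seed = 200 + i)$data))
  wt <- fit_whitening(X, k = 8)
  dict <- suppressWarnings(learn_ica(apply_whitening(wt, X), 8, seed = 107,
                                     whitening = wt))
  dict$patch_side <- 6L; dict$n_channels <- 1L
  rep <- correlation_study(dict, imgs, ratios = 2, modes = "max",
                           offset = 8, n_locations = 2000, seed = 108)
  s <- rep$summary
  n <- 8
  expect_equal(s$n_coef[s$layer == "S1" & s$case == "diff_filter_same_loc"],
               n * (n - 1))
  expect_equal(s$n_coef[s$layer == "S1" & s$case == "same_filter_diff_loc"], n)
  expect_equal(s$n_coef[s$layer == "S1" & s$case == "diff_filter_diff_loc"],
               n * (n - 1))
  expect_true(all(abs(rep$coefficients$value) <= 1))
  # whitened same-location responses on white noise are uncorrelated
  expect_lt(s$mean_abs[s$layer == "S1" & s$case == "diff_filter_same_loc"],
            0.03)
})

test_that("correlation coefficients are invariant to per-filter affine rescaling", {
  imgs <- synth_noise_images(3, 48, "white", seed = 109, contrast_sd = 0)
  X <- do.call(cbind, lapply(1:3, function(i)
    sample_patches(imgs[[i]], 5, 600, seed = 300 + i)$data))
  wt <- fit_whitening(X, k = 6)
  dict <- suppressWarnings(learn_ica(apply_whitening(wt, X), 6, seed = 110,
                                     whitening = wt))
  dict$patch_side <- 5L; dict$n_channels <- 1L
  r1 <- correlation_study(dict, imgs, ratios = 2, modes = "max",
                          offset = 6, n_locations = 500, seed = 111)
  dict2 <- dict
  scale <- c(3, 0.5, 2, 1, 10, 0.1)
  dict2$filters <- dict$filters * scale
  r2 <- correlation_study(dict2, imgs, ratios = 2, modes = "max",
                          offset = 6, n_locations = 500, seed = 111)
  # positive rescaling of filter responses leaves Pearson coefficients alone
  expect_equal(r1$coefficients$value, r2$coefficients$value, tolerance = 1e-9)
})

test_that("invariance curves start at the undistorted response and ignore image order", {
  gen <- synth_category_images(n_per_category = 4, image_side = 48,
                               noise_sd = 0.02, jitter = 1, seed = 112)
  spec <- architecture_spec(list(s_layer_spec("ica", 6, 5), pooling_spec(2),
                                 s_layer_spec("ica", 8, 3)),
                            terminal = "global_max")
  model <- train_unsupervised(spec, gen$images, n_patches_per_layer = 2000,
                              seed = 113)
  imgs <- gen$images[1:4]
  curve <- invariance_curve(model, "S2", 2, imgs, "rotate", c(0, 10, 20),
                            threshold = 0.01)
  undistorted <- mean(vapply(imgs, function(im)
    unit_response(model, "S2", 2, im), numeric(1L)))
  expect_equal(curve$mean_activation[1], undistorted)
  curve2 <- invariance_curve(model, "S2", 2, rev(imgs), "rotate", c(0, 10, 20))
  expect_equal(curve$mean_activation, curve2$mean_activation)
  expect_equal(attr(curve, "frac_above"),
               mean(curve$mean_activation > 0.01))
})
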