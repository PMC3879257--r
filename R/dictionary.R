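# Dictionary learning (ICA, standard sparse coding, L2, random patches)
# and code inference under each model.
#
# Conventions: bases B are columns (d x n, reconstruction), filters W are
# rows (n x d, inference). For ICA the filters live in the whitened space
# and have orthonormal rows; image-space bases are obtained through the
# whitening back-projection.

new_dictionary <- function(method, bases, filters = NULL, whitening = NULL,
                           lambda = NULL, gamma = NULL, sigma = NULL,
                           patch_side = NULL, n_channels = NULL,
                           meta = list()) {
  structure(list(method = method, bases = bases, filters = filters,
                 whitening = whitening, lambda = lambda, gamma = gamma,
                 sigma = sigma, patch_side = patch_side,
                 n_channels = n_channels, meta = meta),
            class = "shx_dictionary")
}

#' @export
print.shx_dictionary <- function(x, ...) {
  cat(sprintf("<dictionary [%s] %d bases, dim %d%s>\n",
              x$method, ncol(x$bases), nrow(x$bases),
              if (!is.null(x$whitening)) sprintf(", whitened k=%d", x$whitening$k) else ""))
  invisible(x)
}

n_bases_of <- function(dict) ncol(dict$bases)

# Flip signs so each basis column's largest-magnitude entry is positive;
# filters (and any code convention) flip together.
canonicalize_signs <- function(B, W = NULL) {
  sgn <- apply(B, 2L, function(b) {
    s <- sign(b[which.max(abs(b))]); if (s == 0) 1 else s
  })
  B <- sweep(B, 2L, sgn, "*")
  if (!is.null(W)) W <- sweep(W, 1L, sgn, "*")
  list(B = B, W = W)
}

take_data <- function(X) {
  if (inherits(X, "patch_set")) X$data
  else if (is.matrix(X)) X
  else if (is.numeric(X)) matrix(X, ncol = 1L)
  else stopf("expected a patch_set, matrix, or numeric vector")
}

#' Learn an ICA dictionary on whitened patches
#'
#' Maximum-likelihood ICA under a smooth sparse (log-cosh) prior with the
#' constraint that the filter rows are orthonormal in the whitened space.
#' Solved by the symmetric fixed-point iteration; because the data are
#' whitened, the orthonormal-row constraint is enforced exactly at every
#' step by symmetric decorrelation.
#'
#' @param Xw k x m matrix of whitened patches (use [apply_whitening()]);
#'   the retained dimension k must equal `n_components`.
#' @param n_components Number of filters/bases to learn (= k).
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the filter update.
#' @param seed Integer seed for the (orthonormalized Gaussian) init.
#' @param whitening Optional `whitening_transform` stored with the
#'   dictionary so image-space bases/filters can be derived.
#' @return A dictionary with `method = "ica"`, orthonormal-row `filters`
#'   (n x k, whitened space) and `bases` (the corresponding whitened-space
#'   basis columns, or image-space columns when `whitening` is supplied).
#' @export
learn_ica <- function(Xw, n_components, max_iter = 400, tol = 1e-5, seed = 1,
                      whitening = NULL) {
  Xw <- take_data(Xw)
  n <- check_count(n_components, "n_components")
  k <- nrow(Xw); m <- ncol(Xw)
  if (k != n) {
    stopf("whitened dimension (%d) must equal n_components (%d); whiten with k = n_components",
          k, n)
  }
  if (m < 2L * n) stopf("too few samples (%d) for %d components", m, n)
  sym_orth <- function(W) {
    # (W W^T)^{-1/2} W via eigendecomposition
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-12))) %*% W
  }
  W <- with_seed_(seed, matrix(stats::rnorm(n * k), n, k))
  W <- sym_orth(W)
  converged <- FALSE
  iter_used <- max_iter
  for (it in seq_len(max_iter)) {
    WX <- W %*% Xw                    # n x m source estimates
    G <- tanh(WX)                     # log-cosh score
    Wn <- (G %*% t(Xw)) / m - (rowMeans(1 - G^2)) * W
    Wn <- sym_orth(Wn)
    # Row-wise alignment with previous iterate (sign-insensitive).
    delta <- max(abs(1 - abs(rowSums(Wn * W))))
    W <- Wn
    if (delta < tol) { converged <- TRUE; iter_used <- it; break }
  }
  if (!converged) {
    warning(sprintf("ICA did not converge in %d iterations (last delta %.2e); returning best iterate",
                    max_iter, delta), call. = FALSE)
  }
  Bw <- t(W)  # orthonormal W => whitened-space bases are the filter rows
  canon <- canonicalize_signs(Bw, W)
  Bw <- canon$B; W <- canon$W
  bases <- if (!is.null(whitening)) whitening$backward %*% Bw else Bw
  new_dictionary("ica", bases = bases, filters = W, whitening = whitening,
                 meta = list(converged = converged, iterations = iter_used,
                             seed = seed))
}

# Image-space linear filter rows for an ICA dictionary: W_total x = W (P (x - mu)).
effective_filters <- function(dict) {
  if (is.null(dict$filters)) stopf("dictionary has no filters")
  if (!is.null(dict$whitening)) dict$filters %*% dict$whitening$forward
  else dict$filters
}

#' Infer codes under the ICA model
#'
#' ICA inference is a single linear map: `s = W x` in the whitened space.
#' Raw-space patches are whitened first when the dictionary carries a
#' whitening transform.
#'
#' @param X Patches: a [patch_set], d x m matrix, or single vector. Columns
#'   must be in the dictionary's input space (raw patches when the
#'   dictionary has a whitening transform, whitened otherwise).
#' @param dict An ICA dictionary from [learn_ica()].
#' @return A `code_set` with `codes` (n x m) and the model log-likelihood
#'   surrogate as `objective` (negative mean log-cosh of the sources).
#' @export
infer_ica <- function(X, dict) {
  if (is.null(dict$filters)) stopf("dictionary has no filters; ICA inference needs W")
  M <- take_data(X)
  S <- if (!is.null(dict$whitening)) {
    dict$filters %*% apply_whitening(dict$whitening, M)
  } else {
    dict$filters %*% M
  }
  code_set(S, objective = mean(log(cosh(S))))
}

#' Construct a code set
#'
#' @param codes n x m matrix of coefficients (columns match patch columns).
#' @param objective Final objective value of the producing inference/learning.
#' @return An object of class `code_set`.
#' @export
code_set <- function(codes, objective = NA_real_) {
  if (!is.matrix(codes)) codes <- matrix(codes, ncol = 1L)
  if (!all(is.finite(codes))) stopf("codes contain non-finite values")
  structure(list(codes = codes, objective = as.numeric(objective)),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set %d x %d, objective %.6g, %.1f%% active>\n",
              nrow(x$codes), ncol(x$codes), x$objective,
              100 * mean(abs(x$codes) > 1e-12)))
  invisible(x)
}

ssc_objective <- function(X, B, S, lambda) {
  sum((X - B %*% S)^2) + lambda * sum(abs(S))
}

#' Infer sparse codes (L1-regularized)
#'
#' Solves, for each column x of `X`, the lasso-type problem
#' \deqn{\min_s \|x - B s\|_2^2 + \lambda \|s\|_1}
#' by cyclic coordinate descent (exact soft-threshold updates), iterated to
#' the stated tolerance. All columns are updated jointly, one coordinate at
#' a time, so the inner loop is matrix-vector work.
#'
#' @param X Patches ([patch_set], matrix, or vector).
#' @param B d x n basis matrix with (near) unit-norm columns, or a
#'   dictionary object.
#' @param lambda Positive L1 weight.
#' @param max_iter Maximum full coordinate sweeps.
#' @param tol Convergence tolerance on the largest coefficient change.
#' @return A `code_set`; `objective` is the summed objective over columns.
#' @export
infer_ssc <- function(X, B, lambda, max_iter = 1000, tol = 1e-10) {
  if (inherits(B, "shx_dictionary")) {
    lambda <- if (missing(lambda)) B$lambda else lambda
    B <- B$bases
  }
  lambda <- check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  M <- take_data(X)
  d <- nrow(B); n <- ncol(B); m <- ncol(M)
  if (nrow(M) != d) stopf("patch dimension %d does not match basis dimension %d",
                          nrow(M), d)
  G <- crossprod(B)            # n x n
  diagG <- pmax(diag(G), 1e-12)
  Ct <- crossprod(B, M)        # n x m
  S <- matrix(0, n, m)
  GS <- matrix(0, n, m)        # running G %*% S
  thr <- lambda / 2
  for (sweep_i in seq_len(max_iter)) {
    max_delta <- 0
    for (j in seq_len(n)) {
      # partial residual correlation for coordinate j across all columns
      rho <- Ct[j, ] - GS[j, ] + diagG[j] * S[j, ]
      s_new <- sign(rho) * pmax(abs(rho) - thr, 0) / diagG[j]
      delta <- s_new - S[j, ]
      md <- max(abs(delta))
      if (md > 0) {
        GS <- GS + outer(G[, j], delta)
        S[j, ] <- s_new
        if (md > max_delta) max_delta <- md
      }
    }
    if (max_delta < tol) break
  }
  code_set(S, objective = ssc_objective(M, B, S, lambda))
}

#' Learn a sparse-coding dictionary (SSC)
#'
#' Alternating minimization of
#' \deqn{\min_{B,S} \|X - B S\|_F^2 + \lambda \|S\|_1,\quad \|b_j\|_2 = 1,}
#' the standard sparse-coding objective: codes by coordinate-descent lasso
#' ([infer_ssc()]), bases by exact per-column minimization under the
#' unit-norm constraint. Overcomplete dictionaries (n > d) are allowed.
#' The objective is non-increasing across alternations; unused bases are
#' re-seeded from the worst-reconstructed patch.
#'
#' @param X Training patches ([patch_set] or d x m matrix).
#' @param n_bases Number of basis columns to learn.
#' @param lambda Positive sparsity weight.
#' @param n_iters Number of alternations.
#' @param seed Integer seed (initial bases are random training patches).
#' @param verbose Print the objective per alternation.
#' @return A dictionary with `method = "ssc"`; `meta$objective_trace`
#'   records the objective after each alternation.
#' @export
learn_ssc <- function(X, n_bases, lambda, n_iters = 30, seed = 1,
                      verbose = FALSE) {
  ps <- if (inherits(X, "patch_set")) X else NULL
  M <- take_data(X)
  n_bases <- check_count(n_bases, "n_bases")
  lambda <- check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  n_iters <- check_count(n_iters, "n_iters")
  d <- nrow(M); m <- ncol(M)
  if (m < n_bases) stopf("need at least n_bases (%d) training patches, got %d",
                         n_bases, m)
  B <- with_seed_(seed, {
    idx <- sample.int(m, n_bases, replace = FALSE)
    B0 <- M[, idx, drop = FALSE]
    # Degenerate (zero) picks replaced by random directions.
    zero <- col_norms(B0) < 1e-12
    if (any(zero)) B0[, zero] <- matrix(stats::rnorm(d * sum(zero)), d)
    B0
  })
  B <- sweep(B, 2L, col_norms(B), "/")
  trace <- numeric(n_iters)
  S <- NULL
  update_columns <- function(B, S) {
    # Exact column-wise basis update: b_j <- R_j s_j / ||R_j s_j||
    R <- M - B %*% S
    for (j in seq_len(n_bases)) {
      sj <- S[j, ]
      if (all(sj == 0)) next
      Rj <- R + outer(B[, j], sj)
      bj <- as.vector(Rj %*% sj)
      nb <- sqrt(sum(bj^2))
      if (nb > 1e-12) {
        bj <- bj / nb
        R <- Rj - outer(bj, sj)
        B[, j] <- bj
      }
    }
    B
  }
  for (it in seq_len(n_iters)) {
    S <- infer_ssc(M, B, lambda)$codes
    B <- update_columns(B, S)
    obj <- ssc_objective(M, B, S, lambda)
    # Re-seed degenerate bases from the worst-reconstructed patches:
    # unused columns, and near-duplicates of an earlier column (the
    # collapsed local minimum of alternating minimization). A re-seed is
    # kept only when re-inference improves the objective, so the recorded
    # trace stays non-increasing.
    dead <- rowSums(abs(S)) == 0
    Gb <- abs(crossprod(B))
    dup <- vapply(seq_len(n_bases), function(j) {
      j > 1L && any(Gb[seq_len(j - 1L), j] > 0.999)
    }, logical(1L))
    reseed <- which(dead | dup)
    if (length(reseed) > 0L && it < n_iters) {
      B2 <- B
      errs <- colSums((M - B %*% S)^2)
      ord <- order(errs, decreasing = TRUE)
      for (i in seq_along(reseed)) {
        cand <- M[, ord[min(i, length(ord))]]
        if (sqrt(sum(cand^2)) > 1e-12) {
          B2[, reseed[i]] <- cand / sqrt(sum(cand^2))
        }
      }
      S2 <- infer_ssc(M, B2, lambda)$codes
      obj2 <- ssc_objective(M, B2, S2, lambda)
      if (obj2 <= obj) { B <- B2; S <- S2; obj <- obj2 }
    }
    trace[it] <- obj
    if (verbose) message(sprintf("  SSC iter %d: objective %.6g", it, trace[it]))
  }
  canon <- canonicalize_signs(B)
  new_dictionary("ssc", bases = canon$B, lambda = lambda,
                 patch_side = ps$patch_side, n_channels = ps$n_channels,
                 meta = list(objective_trace = trace, seed = seed))
}

#' Infer codes under the L2-regularized model
#'
#' Closed-form ridge inference: `s = (B'B + gamma I)^{-1} B' x`.
#'
#' @param X Patches ([patch_set], matrix, or vector).
#' @param B d x n basis matrix or a dictionary object.
#' @param gamma Positive L2 weight.
#' @return A `code_set`; `objective` is the summed L2 objective.
#' @export
infer_l2 <- function(X, B, gamma) {
  if (inherits(B, "shx_dictionary")) {
    gamma <- if (missing(gamma)) B$gamma else gamma
    B <- B$bases
  }
  gamma <- check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  M <- take_data(X)
  n <- ncol(B)
  S <- solve(crossprod(B) + diag(gamma, n), crossprod(B, M))
  code_set(S, objective = sum((M - B %*% S)^2) + gamma * sum(S^2))
}

#' Learn a dictionary under L2 regularization
#'
#' Same alternating scheme as [learn_ssc()] but with the closed-form ridge
#' inference of [infer_l2()]; the resulting codes are dense.
#'
#' @inheritParams learn_ssc
#' @param gamma Positive L2 weight.
#' @return A dictionary with `method = "l2"`.
#' @export
learn_l2 <- function(X, n_bases, gamma, n_iters = 30, seed = 1,
                     verbose = FALSE) {
  ps <- if (inherits(X, "patch_set")) X else NULL
  M <- take_data(X)
  n_bases <- check_count(n_bases, "n_bases")
  gamma <- check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  d <- nrow(M); m <- ncol(M)
  if (m < n_bases) stopf("need at least n_bases (%d) training patches", n_bases)
  B <- with_seed_(seed, {
    idx <- sample.int(m, n_bases, replace = FALSE)
    B0 <- M[, idx, drop = FALSE]
    zero <- col_norms(B0) < 1e-12
    if (any(zero)) B0[, zero] <- matrix(stats::rnorm(d * sum(zero)), d)
    B0
  })
  B <- sweep(B, 2L, col_norms(B), "/")
  trace <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    S <- infer_l2(M, B, gamma)$codes
    R <- M - B %*% S
    for (j in seq_len(n_bases)) {
      sj <- S[j, ]
      if (all(abs(sj) < 1e-14)) next
      Rj <- R + outer(B[, j], sj)
      bj <- as.vector(Rj %*% sj)
      nb <- sqrt(sum(bj^2))
      if (nb > 1e-12) {
        bj <- bj / nb
        R <- Rj - outer(bj, sj)
        B[, j] <- bj
      }
    }
    trace[it] <- sum((M - B %*% S)^2) + gamma * sum(S^2)
    if (verbose) message(sprintf("  L2 iter %d: objective %.6g", it, trace[it]))
  }
  canon <- canonicalize_signs(B)
  new_dictionary("l2", bases = canon$B, gamma = gamma,
                 patch_side = ps$patch_side, n_channels = ps$n_channels,
                 meta = list(objective_trace = trace, seed = seed))
}

#' Extract random patches as dictionary bases
#'
#' The classic HMAX prototype scheme: raw patches sampled at random
#' locations of the input maps become the bases (unit-normalized). When a
#' list of stacks/images is given, source images are drawn uniformly.
#'
#' @param maps A [gray_image]/[feature_map_stack] or a list of them.
#' @param n_bases Number of patches to extract.
#' @param patch_side Window side length.
#' @param seed Integer seed.
#' @return A dictionary with `method = "random_patch"`.
#' @export
random_patch_bases <- function(maps, n_bases, patch_side, seed = 1) {
  n_bases <- check_count(n_bases, "n_bases")
  sources <- if (is.list(maps) && !is_gray_image(maps) &&
                 !inherits(maps, "feature_map_stack")) maps else list(maps)
  counts <- with_seed_(seed,
    tabulate(sample.int(length(sources), n_bases, replace = TRUE),
             nbins = length(sources)))
  cols <- vector("list", length(sources))
  nch <- NULL
  for (i in seq_along(sources)) {
    if (counts[i] == 0L) next
    ps <- sample_patches(sources[[i]], patch_side, counts[i],
                         seed = seed + i)
    nch <- ps$n_channels
    cols[[i]] <- ps$data
  }
  B <- do.call(cbind, cols[!vapply(cols, is.null, logical(1L))])
  nz <- col_norms(B)
  nz[nz < 1e-12] <- 1
  B <- sweep(B, 2L, nz, "/")
  new_dictionary("random_patch", bases = B, patch_side = patch_side,
                 n_channels = nch, meta = list(seed = seed))
}

#' Distance-based responses to dictionary bases
#'
#' The original HMAX S2 rule: the response to basis `b_i` is a Gaussian
#' function of the Euclidean distance, `exp(-||x - b_i||^2 / (2 sigma^2))`,
#' so shorter distance means higher response and responses lie in (0, 1].
#'
#' @param X Patches ([patch_set], matrix, or vector).
#' @param bases d x n basis matrix or a dictionary object.
#' @param sigma Positive kernel width; defaults to the median inter-basis
#'   Euclidean distance.
#' @return n x m matrix of responses.
#' @export
infer_distance <- function(X, bases, sigma = NULL) {
  if (inherits(bases, "shx_dictionary")) bases <- bases$bases
  M <- take_data(X)
  if (is.null(sigma)) {
    Db <- as.matrix(stats::dist(t(bases)))
    sigma <- stats::median(Db[upper.tri(Db)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  sigma <- check_number(sigma, "sigma", min = 0, strict_min = TRUE)
  # ||x - b||^2 = ||x||^2 + ||b||^2 - 2 b'x, computed blockwise
  d2 <- outer(colSums(bases^2), colSums(M^2), "+") - 2 * crossprod(bases, M)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}
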