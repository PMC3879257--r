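# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form so it shares no
# code path with the implementation it checks.

# Mean matched |cosine| between learned and true basis columns under the
# best one-to-one assignment (exact enumeration for n <= 8, greedy above).
match_mean_cos <- function(B_learned, B_true) {
  Cm <- abs(crossprod(
    sweep(B_learned, 2L, sqrt(colSums(B_learned^2)), "/"),
    sweep(B_true, 2L, sqrt(colSums(B_true^2)), "/")))
  n <- ncol(B_true)
  stopifnot(ncol(B_learned) >= n)
  if (n <= 8L) {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      }
      out
    }
    best <- -Inf
    for (p in perms(seq_len(ncol(B_learned)))[]) {
      # assign learned p[j] to true j (only first n entries used)
      val <- mean(Cm[cbind(p[seq_len(n)], seq_len(n))])
      if (val > best) best <- val
    }
    best
  } else {
    s <- 0
    M <- Cm
    for (i in seq_len(n)) {
      ix <- which(M == max(M), arr.ind = TRUE)[1L, ]
      s <- s + M[ix[1L], ix[2L]]
      M[ix[1L], ] <- -Inf
      M[, ix[2L]] <- -Inf
    }
    s / n
  }
}

# Brute-force global minimum of ||x - B s||^2 + lambda ||s||_1 by
# enumerating sign/support patterns and solving each orthant's quadratic.
brute_l1_objective <- function(x, B, lambda) {
  n <- ncol(B)
  obj <- function(s) sum((x - B %*% s)^2) + lambda * sum(abs(s))
  best <- obj(rep(0, n))
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), n)))
  for (r in seq_len(nrow(patterns))) {
    sg <- patterns[r, ]
    A <- which(sg != 0)
    if (length(A) == 0L) next
    BA <- B[, A, drop = FALSE]
    G <- crossprod(BA)
    rhs <- crossprod(BA, x) - lambda * sg[A] / 2
    sA <- tryCatch(solve(G, rhs), error = function(e) NULL)
    if (is.null(sA)) next
    s <- rep(0, n)
    s[A] <- sA
    best <- min(best, obj(s))
  }
  best
}

# O(n^2) pairwise AUC with the tie convention P(pos > neg) + 0.5 P(==).
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# A small orthonormal "Gabor-like" planted dictionary of p x p patches.
planted_dictionary <- function(p = 8L, n = 8L, seed = 42L) {
  withr::with_seed(seed, {
    d <- p * p
    qr.Q(qr(matrix(stats::rnorm(d * n), d, n)))
  })
}

# Deterministic tiny test image.
test_image <- function(nr = 20L, nc = nr, seed = 1L) {
  withr::with_seed(seed, gray_image(matrix(stats::runif(nr * nc), nr, nc)))
}
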