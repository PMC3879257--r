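# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stopf("`%s` must be >= %g", name, min)
  if (x > max) stopf("`%s` must be <= %g", name, max)
  as.numeric(x)
}

# Column-wise L2 norms of a matrix.
col_norms <- function(M) sqrt(colSums(M^2))

#' Amari index between an estimated and a true unmixing
#'
#' Permutation- and scale-invariant distance between the product of an
#' estimated unmixing matrix `W` and a true mixing matrix `A`. The index is
#' 0 when `W %*% A` is a scaled permutation matrix (perfect source recovery)
#' and approaches 1 for an uninformative estimate. Used to score ICA
#' recovery of planted mixtures.
#'
#' @param W n x n estimated unmixing matrix.
#' @param A n x n true mixing matrix.
#' @return A number in \[0, 1\].
#' @export
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  n <- nrow(P)
  if (n != ncol(P)) stopf("W %%*%% A must be square")
  row_term <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  col_term <- sum(colSums(sweep(P, 2L, apply(P, 2L, max), "/")) - 1)
  (row_term + col_term) / (2 * n * (n - 1))
}
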