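#' Dynamic time warping distance
#'
#' Distance between two series under dynamic time warping with local cost
#' (x - y)^2, steps (1,0)/(0,1)/(1,1), matched endpoints and no warping
#' window. The squared form (the sum of squared differences along the
#' optimal path) is the quantity the k-means objective minimizes; the
#' default returns its square root.
#'
#' @param a,b Numeric series (length >= 1, possibly unequal).
#' @param squared Return the squared DTW cost instead of its root.
#' @return A non-negative scalar.
#' @export
dtw_distance <- function(a, b, squared = FALSE) {
  if (length(a) == 0 || length(b) == 0)
    abort("dtw_distance requires non-empty series",
          class = "trajclust_domain_error")
  d2 <- cpp_dtw_sq(as.numeric(a), as.numeric(b))
  if (squared) d2 else sqrt(d2)
}

#' Optimal warping path
#'
#' @param a,b Numeric series.
#' @return Tibble (index_a, index_b) of 1-based aligned index pairs from
#'   (1, 1) to (length(a), length(b)).
#' @export
dtw_path <- function(a, b) {
  p <- cpp_dtw_path(as.numeric(a), as.numeric(b))
  tibble(index_a = p[, 1], index_b = p[, 2])
}

#' DTW barycenter averaging (DBA)
#'
#' Iteratively refines a centroid series: every member series is aligned to
#' the current barycenter along its optimal warping path, and each
#' barycenter coordinate is replaced by the mean of all member values
#' aligned to it, until the largest coordinate change falls below `tol` or
#' `max_iter` is reached.
#'
#' @param X Numeric matrix, one equal-length series per row (>= 1 row).
#' @param init Initial barycenter; defaults to the element-wise mean.
#' @param max_iter,tol Convergence controls.
#' @return Numeric vector with attributes `cost` (total squared DTW of the
#'   set to the barycenter) and `n_iter`.
#' @export
dba_barycenter <- function(X, init = NULL, max_iter = 30L, tol = 1e-8) {
  X <- rbind(X)
  if (nrow(X) == 0)
    abort("dba_barycenter requires a non-empty set",
          class = "trajclust_domain_error")
  bary <- if (is.null(init)) colMeans(X) else as.numeric(init)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    nxt <- cpp_dba_update(X, bary)
    delta <- max(abs(nxt - bary))
    bary <- nxt
    if (delta < tol || iter >= max_iter) break
  }
  attr(bary, "cost") <- sum(cpp_dtw_cross(X, rbind(bary)))
  attr(bary, "n_iter") <- iter
  bary
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical partitions, ~0 = chance-level agreement.
#'
#' @param a,b Label vectors of equal length.
#' @return A scalar in (-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
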