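#' k-means clustering under dynamic time warping
#'
#' Lloyd-style k-means on fixed-length series where assignment uses squared
#' DTW distance and centroids are refined by DTW barycenter averaging (DBA).
#' Seeding is k-means++-style with squared DTW distances; the best of
#' `n_init` restarts (by inertia) is returned. Empty clusters are repaired
#' by reseeding from the point farthest from its current centroid. Cluster
#' labels are re-ordered by descending cluster size, so cluster 1 is always
#' the largest. Ties in assignment go to the lowest cluster index; the whole
#' fit is deterministic given `seed`.
#'
#' @param X Numeric matrix, one series per row (row names carry user ids).
#' @param k Number of clusters, 1 <= k <= nrow(X).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts (default 5).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param dba_iter DBA refinement iterations per centroid update.
#' @return A `dtw_kmeans` object: `k`, `centroids` (k x L), `cluster`
#'   (integer vector named by row names), `inertia` (total within-cluster
#'   squared DTW), `inertia_root` (same with unsquared DTW), `sizes`,
#'   `n_iter`, `converged`, `inertia_history`, `seed`.
#' @export
kmeans_dtw <- function(X, k, seed = 1L, n_init = 5L, max_iter = 50L,
                       dba_iter = 10L) {
  X <- rbind(X)
  n <- nrow(X)
  if (k < 1 || k > n)
    abort(sprintf("k must satisfy 1 <= k <= n (k=%d, n=%d)", k, n),
          class = "trajclust_domain_error")
  fit <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (rep in seq_len(n_init)) {
      cand <- kmeans_dtw_once(X, k, max_iter, dba_iter)
      if (is.null(best) || cand$inertia < best$inertia) best <- cand
    }
    best
  })

  # relabel so cluster 1 is the largest
  sizes <- tabulate(fit$cluster, nbins = k)
  ord <- order(-sizes, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cluster <- relabel[fit$cluster]
  centroids <- fit$centroids[ord, , drop = FALSE]
  names(cluster) <- rownames(X)

  structure(list(
    k = k, centroids = centroids, cluster = cluster,
    sizes = tabulate(cluster, nbins = k),
    inertia = fit$inertia,
    inertia_root = sum(sqrt(fit$point_cost)),
    n_iter = fit$n_iter, converged = fit$converged,
    inertia_history = fit$history, seed = as.integer(seed)
  ), class = "dtw_kmeans")
}

kmeanspp_seed <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- cpp_dtw_cross(X, X[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        pool <- setdiff(seq_len(n), idx[seq_len(j - 1)])
        idx[j] <- if (length(pool) == 1) pool else sample(pool, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, cpp_dtw_cross(X, X[idx[j], , drop = FALSE])[, 1])
    }
  }
  X[idx, , drop = FALSE]
}

kmeans_dtw_once <- function(X, k, max_iter, dba_iter) {
  n <- nrow(X)
  centroids <- kmeanspp_seed(X, k)
  assign_prev <- integer(n)
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cross <- cpp_dtw_cross(X, centroids)
    cl <- max.col(-cross, ties.method = "first")
    # empty-cluster repair: reseed from the point farthest from its centroid
    point_cost <- cross[cbind(seq_len(n), cl)]
    for (c in which(tabulate(cl, nbins = k) == 0)) {
      far <- which.max(point_cost)
      centroids[c, ] <- X[far, ]
      cl[far] <- c
      point_cost[far] <- 0
    }
    history <- c(history, sum(point_cost))
    if (all(cl == assign_prev)) { converged <- TRUE; break }
    if (iter >= max_iter) break
    assign_prev <- cl
    for (c in seq_len(k)) {
      members <- X[cl == c, , drop = FALSE]
      centroids[c, ] <- as.numeric(
        dba_barycenter(members, init = centroids[c, ], max_iter = dba_iter))
    }
  }
  cross <- cpp_dtw_cross(X, centroids)
  cl <- max.col(-cross, ties.method = "first")
  point_cost <- cross[cbind(seq_len(n), cl)]
  list(centroids = centroids, cluster = cl, inertia = sum(point_cost),
       point_cost = point_cost, n_iter = iter, converged = converged,
       history = history)
}

#' @export
print.dtw_kmeans <- function(x, ...) {
  cat(sprintf("DTW k-means: k = %d, n = %d, inertia = %.4f (%s, %d iter)\n",
              x$k, length(x$cluster), x$inertia,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn kmeans_dtw Per-cluster summary: size and cohort share.
#' @param x,object A `dtw_kmeans` fit.
#' @param ... Unused.
#' @export
tidy.dtw_kmeans <- function(x, ...) {
  tibble(
    cluster = seq_len(x$k),
    size = x$sizes,
    share = x$sizes / sum(x$sizes)
  )
}

#' @describeIn kmeans_dtw One-row model summary.
#' @export
glance.dtw_kmeans <- function(x, ...) {
  tibble(k = x$k, n = length(x$cluster), inertia = x$inertia,
         inertia_root = x$inertia_root, n_iter = x$n_iter,
         converged = x$converged, seed = x$seed)
}

#' @describeIn kmeans_dtw Assignments as a tibble (user_id, cluster), or
#'   joined onto `data` by `user_id` when supplied.
#' @param data Optional tibble with a `user_id` column.
#' @export
augment.dtw_kmeans <- function(x, data = NULL, ...) {
  asg <- tibble(user_id = names(x$cluster), cluster = unname(x$cluster))
  if (is.null(data)) return(asg)
  left_join(data, asg, by = "user_id")
}

#' @describeIn kmeans_dtw Centroid trajectories, one line per cluster.
#' @export
autoplot.dtw_kmeans <- function(object, ...) {
  L <- ncol(object$centroids)
  df <- tidyr::expand_grid(cluster = seq_len(object$k), point = seq_len(L))
  df$value <- as.vector(t(object$centroids))
  ggplot2::ggplot(df, ggplot2::aes(.data$point, .data$value,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "trajectory point (biweekly grid)",
                  y = "z-normalized weight", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Elbow scan over candidate cluster counts
#'
#' Fits [kmeans_dtw()] for each k in `k_range` and reports both inertia
#' curves (squared and unsquared total within-cluster DTW distance). The
#' suggested k is the knee of the unsquared curve on the log scale: the k
#' at the largest vertical distance below the chord joining the curve's
#' endpoints (a "kneedle"-style rule). The log scale makes the rule respond
#' to relative inertia improvements, so a structureless geometric decay --
#' log-linear -- has no knee anywhere, while a curve that flattens after
#' the true cluster count bends maximally there. The full curve is always
#' returned so the choice can be overridden visually. The suggestion is
#' flagged low-confidence when the knee is shallow (maximum chord distance
#' below `min_knee_depth` on the normalized log scale, a level structureless
#' single-cluster data stays under) or when `k_range`
#' has fewer than three values.
#'
#' @param X Numeric matrix of series (rows).
#' @param k_range Candidate cluster counts (default 2:10).
#' @param seed Seed passed to every fit.
#' @param min_knee_depth Chord distance (normalized log-inertia scale)
#'   below which the knee is flagged low-confidence.
#' @param ... Passed to [kmeans_dtw()].
#' @return An `elbow_scan` object: tibble (k, inertia, inertia_root) plus
#'   attributes `suggested_k` and `low_confidence`.
#' @export
elbow_scan <- function(X, k_range = 2:10, seed = 1L, min_knee_depth = 0.25,
                       ...) {
  k_range <- sort(unique(as.integer(k_range)))
  fits <- purrr::map(k_range, ~ kmeans_dtw(X, .x, seed = seed, ...))
  scan <- tibble(
    k = k_range,
    inertia = purrr::map_dbl(fits, "inertia"),
    inertia_root = purrr::map_dbl(fits, "inertia_root")
  )
  if (length(k_range) < 3) {
    suggested <- k_range[1]
    low_conf <- TRUE
  } else {
    s <- log(pmax(scan$inertia_root, .Machine$double.xmin))
    rng <- max(s) - min(s)
    if (rng < 1e-12) {
      suggested <- k_range[1]
      low_conf <- TRUE
    } else {
      s <- (s - min(s)) / rng
      k <- as.numeric(k_range)
      chord <- s[1] + (s[length(s)] - s[1]) * (k - k[1]) / (k[length(k)] - k[1])
      depth <- chord - s
      suggested <- k_range[which.max(depth)]
      low_conf <- max(depth) < min_knee_depth
    }
  }
  structure(scan, class = c("elbow_scan", class(scan)),
            suggested_k = suggested, low_confidence = low_conf)
}

#' Suggested k from an elbow scan
#' @param scan An `elbow_scan` object.
#' @return Integer k (attribute `low_confidence` preserved on the scan).
#' @export
suggested_k <- function(scan) attr(scan, "suggested_k")

#' @describeIn elbow_scan Inertia-vs-k curve with the suggested knee marked.
#' @param object An `elbow_scan`.
#' @export
autoplot.elbow_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "suggested_k"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "number of clusters k", y = "inertia (sum of squared DTW)") +
    ggplot2::theme_minimal()
}
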