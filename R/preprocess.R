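#' Regularize an irregular weight series onto an even time grid
#'
#' Duplicate-day observations are first collapsed to their mean. The series
#' is then evaluated at `grid_len` equally spaced time points spanning
#' \[first day, last day\] of the observed record: linear interpolation
#' between observed points (used directly for short series, < 30
#' observations, and as equal-interval resampling of the piecewise-linear
#' interpolant for longer ones -- the two branches coincide by design, which
#' keeps the treatment of short and long records consistent).
#'
#' @param weights Tibble (day, weight_kg) or a list with `day` and
#'   `weight_kg`; at least two distinct days after deduplication.
#' @param grid_len Number of grid points (default 30).
#' @return Numeric vector of length `grid_len`.
#' @export
regularize <- function(weights, grid_len = 30L) {
  d <- tibble(day = weights$day, weight_kg = weights$weight_kg) |>
    group_by(.data$day) |>
    summarise(weight_kg = mean(.data$weight_kg), .groups = "drop") |>
    arrange(.data$day)
  if (nrow(d) < 2)
    abort("regularize requires at least 2 distinct observation days",
          class = "trajclust_insufficient_data")
  grid <- seq(d$day[1], d$day[nrow(d)], length.out = grid_len)
  approx(d$day, d$weight_kg, xout = grid, method = "linear")$y
}

#' Centered moving average (valid mode)
#'
#' Element j of the output is the arithmetic mean of inputs
#' j .. j + window - 1, so the output is shorter by window - 1. With the
#' default 30-point grid and window 15 this yields a 16-point series.
#'
#' @param values Numeric vector, length >= `window`.
#' @param window Window size in observations (default 15).
#' @return Numeric vector of length `length(values) - window + 1`.
#' @export
moving_average <- function(values, window = 15L) {
  n <- length(values)
  if (n < window)
    abort(sprintf("moving_average needs length >= window (%d < %d)", n, window),
          class = "trajclust_insufficient_data")
  cs <- c(0, cumsum(values))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' z-normalize a series (population SD)
#'
#' Rescales to mean 0 and population SD 1 so that clustering compares
#' trajectory shape, not absolute weight. A numerically constant series
#' (SD < 1e-12) is mapped to all zeros and flagged degenerate.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector with attribute `degenerate` (logical).
#' @export
z_normalize <- function(values) {
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s < 1e-12) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (values - m) / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Standardize one weight series for clustering
#'
#' Full preprocessing chain: regularize to a `grid_len`-point even grid,
#' smooth with a centered moving average of `window` observations, then
#' z-normalize (population SD). Defaults (30, 15) produce the 16-point
#' mean-0/SD-1 trajectory used by the cluster model.
#'
#' @param weights Tibble (day, weight_kg).
#' @param grid_len Pre-smoothing grid length (default 30).
#' @param window Moving-average window (default 15).
#' @return Numeric vector of length `grid_len - window + 1` with attributes
#'   `degenerate` and `provenance` (list: resampled_from, grid_len, window).
#' @export
preprocess_series <- function(weights, grid_len = 30L, window = 15L) {
  t_i <- length(unique(weights$day))
  out <- z_normalize(moving_average(regularize(weights, grid_len), window))
  attr(out, "provenance") <- list(resampled_from = t_i, grid_len = grid_len,
                                  window = window, interpolated = t_i < 30)
  out
}

#' Standardize every eligible user's weight series
#'
#' @param cohort Cohort tibble (rows are users with a `weights` list-column).
#' @param grid_len,window See [preprocess_series()].
#' @return A numeric matrix (users x trajectory length) with `user_id` row
#'   names and a logical `degenerate` attribute per row.
#' @export
preprocess_cohort <- function(cohort, grid_len = 30L, window = 15L) {
  series <- purrr::map(cohort$weights, preprocess_series,
                       grid_len = grid_len, window = window)
  mat <- do.call(rbind, purrr::map(series, as.numeric))
  rownames(mat) <- cohort$user_id
  attr(mat, "degenerate") <- purrr::map_lgl(series, ~ attr(.x, "degenerate"))
  mat
}
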