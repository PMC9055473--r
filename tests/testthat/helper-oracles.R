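# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (no dynamic programming, no cpp).

# All monotone warping paths from (1,1) to (n,m) with steps (1,0)/(0,1)/(1,1),
# as lists of 2-column index matrices. Memoized per shape.
.path_cache <- new.env(parent = emptyenv())
enumerate_warping_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  recurse <- function(i, j) {
    if (i == 1 && j == 1) return(list(matrix(c(1, 1), ncol = 2)))
    out <- list()
    if (i > 1 && j > 1)
      out <- c(out, lapply(recurse(i - 1, j - 1), rbind, c(i, j)))
    if (i > 1)
      out <- c(out, lapply(recurse(i - 1, j), rbind, c(i, j)))
    if (j > 1)
      out <- c(out, lapply(recurse(i, j - 1), rbind, c(i, j)))
    out
  }
  paths <- recurse(n, m)
  .path_cache[[key]] <- paths
  paths
}

# Brute-force DTW by exhaustive path enumeration (squared cost).
dtw_sq_bruteforce <- function(a, b) {
  paths <- enumerate_warping_paths(length(a), length(b))
  min(vapply(paths, function(p) {
    sum((a[p[, 1]] - b[p[, 2]])^2)
  }, numeric(1)))
}

# All series of the given lengths over a small value alphabet.
series_universe <- function(lengths, values) {
  out <- list()
  for (L in lengths) {
    grid <- do.call(expand.grid, rep(list(values), L))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ])))
  }
  out
}

# Direct piecewise-linear evaluation at a time point (independent of approx()).
pwl_eval <- function(days, values, t) {
  if (t <= days[1]) return(values[1])
  if (t >= days[length(days)]) return(values[length(values)])
  i <- max(which(days <= t))
  if (days[i] == t) return(values[i])
  frac <- (t - days[i]) / (days[i + 1] - days[i])
  values[i] + frac * (values[i + 1] - values[i])
}

weights_tbl <- function(days, kg) tibble::tibble(day = as.integer(days), weight_kg = kg)

# A minimal hand-built lifelog cohort row set for eligibility tests.
manual_cohort <- function(users) {
  empty_meals <- tibble::tibble(day = integer(), meal_id = integer())
  empty_msg <- tibble::tibble(day = integer(), direction = character())
  empty_steps <- tibble::tibble(day = integer(), step_count = integer())
  tibble::tibble(
    user_id = purrr::map_chr(users, "user_id"),
    archetype = NA_character_,
    sex = "female",
    age = purrr::map_dbl(users, ~ .x$age %||% 40),
    height_cm = purrr::map_dbl(users, ~ .x$height_cm %||% 166.4),
    enrollment_day = 0L,
    weights = purrr::map(users, ~ .x$weights %||% weights_tbl(c(0, 110), c(90, 85))),
    meals = purrr::map(users, ~ .x$meals %||% empty_meals),
    messages = purrr::map(users, ~ empty_msg),
    steps = purrr::map(users, ~ empty_steps)
  )
}

`%||%` <- rlang::`%||%`
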