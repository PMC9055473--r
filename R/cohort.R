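#' Body mass index
#'
#' @param weight_kg Weight in kilograms (> 0).
#' @param height_cm Height in centimetres (> 0).
#' @return BMI in kg/m^2, vectorized.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_cm <= 0, na.rm = TRUE))
    abort("compute_bmi requires positive weight and height",
          class = "trajclust_domain_error")
  weight_kg / (height_cm / 100)^2
}

#' Height plausibility check
#'
#' Heights below 125 cm or above 230 cm (a loosened census-protocol screen)
#' fail; the bounds themselves pass. Missing heights fail.
#'
#' @param height_cm Height in cm (may be `NA`).
#' @param range Inclusive plausible range, default `c(125, 230)`.
#' @return Logical vector: `TRUE` = pass.
#' @export
check_height <- function(height_cm, range = c(125, 230)) {
  !is.na(height_cm) & height_cm >= range[1] & height_cm <= range[2]
}

#' Initial program weight
#'
#' The initial weight is the first weight actually logged around program
#' start -- not any self-reported sign-up weight: the earliest log with day
#' index inside `window` (default 2 weeks before enrollment through the end
#' of program week 1, day 7 inclusive).
#'
#' @param weights Tibble (day, weight_kg), sorted by day.
#' @param window Integer day window, default `c(-14, 7)`.
#' @return One-row tibble (day, weight_kg), or `NULL` when no log falls in
#'   the window.
#' @export
extract_initial_weight <- function(weights, window = c(-14L, 7L)) {
  w <- weights[weights$day >= window[1] & weights$day <= window[2], ]
  if (nrow(w) == 0) return(NULL)
  w[which.min(w$day), c("day", "weight_kg")]
}

#' Final program weight
#'
#' The last weight logged during the final program week (week 16 = days
#' 105-111 under the week convention week w = days \[7(w-1), 7w-1\]), falling
#' back to the last log of the following week (days 112-118) only when the
#' final week has none.
#'
#' @param weights Tibble (day, weight_kg), sorted by day.
#' @param program_weeks Program length in weeks (default 16).
#' @return One-row tibble (day, weight_kg), or `NULL`.
#' @export
extract_final_weight <- function(weights, program_weeks = 16L) {
  wk <- function(w) weights[weights$day >= 7L * (w - 1L) &
                              weights$day <= 7L * w - 1L, ]
  w <- wk(program_weeks)
  if (nrow(w) == 0) w <- wk(program_weeks + 1L)
  if (nrow(w) == 0) return(NULL)
  w[which.max(w$day), c("day", "weight_kg")]
}

#' Detect physiologically inconsistent weight records
#'
#' Flags every consecutive pair of weight logs whose BMI difference is
#' >= 3.5 kg/m^2 within 30 days, or >= 7.0 kg/m^2 within 60 days. A user
#' with any flagged pair is excluded from analysis.
#'
#' @param weights Tibble (day, weight_kg), sorted by day.
#' @param height_cm The user's height in cm.
#' @param bmi_jump_1mo,bmi_jump_2mo BMI-change thresholds (kg/m^2).
#' @param gap_1mo,gap_2mo Calendar-day readings of 1 and 2 months.
#' @return Tibble of flagged pairs (day_from, day_to, bmi_change, gap_days);
#'   zero rows when the series is consistent.
#' @export
detect_inconsistent_weights <- function(weights, height_cm,
                                        bmi_jump_1mo = 3.5, bmi_jump_2mo = 7.0,
                                        gap_1mo = 30L, gap_2mo = 60L) {
  n <- nrow(weights)
  if (n < 2) {
    return(tibble(day_from = integer(), day_to = integer(),
                  bmi_change = numeric(), gap_days = integer()))
  }
  bmi <- compute_bmi(weights$weight_kg, height_cm)
  dbmi <- abs(diff(bmi))
  gap <- diff(weights$day)
  hit <- (dbmi >= bmi_jump_1mo & gap <= gap_1mo) |
         (dbmi >= bmi_jump_2mo & gap <= gap_2mo)
  tibble(
    day_from = weights$day[-n][hit], day_to = weights$day[-1][hit],
    bmi_change = dbmi[hit], gap_days = as.integer(gap[hit])
  )
}

#' Eligibility criteria for the 16-week cohort
#'
#' Bundles the thresholds of the eligibility cascade. The minimal
#' self-monitoring rule (`meal_rule`) requires at least `min_meals_per_week`
#' meal logs in every program week; set `"off"` to disable the stage.
#'
#' @param adult_age Minimum age in years (default 18).
#' @param min_bmi Minimum initial BMI in kg/m^2 (default 25, the overweight
#'   criterion).
#' @param height_range Plausible height range in cm.
#' @param initial_window Day window for the initial weight.
#' @param program_weeks Program length in weeks.
#' @param meal_rule `"every_week"` or `"off"`.
#' @param min_meals_per_week Meal logs required per week under the rule.
#' @return A `cohort_criteria` list.
#' @export
cohort_criteria <- function(adult_age = 18, min_bmi = 25,
                            height_range = c(125, 230),
                            initial_window = c(-14L, 7L),
                            program_weeks = 16L,
                            meal_rule = c("every_week", "off"),
                            min_meals_per_week = 1L) {
  structure(
    list(adult_age = adult_age, min_bmi = min_bmi,
         height_range = height_range, initial_window = initial_window,
         program_weeks = program_weeks, meal_rule = match.arg(meal_rule),
         min_meals_per_week = min_meals_per_week),
    class = "cohort_criteria")
}

meal_adherence_ok <- function(meals, criteria) {
  wk <- pmin(meals$day %/% 7L + 1L, .Machine$integer.max)
  counts <- tabulate(wk[wk >= 1 & wk <= criteria$program_weeks],
                     nbins = criteria$program_weeks)
  all(counts >= criteria$min_meals_per_week)
}

#' Apply the eligibility cascade
#'
#' Filters a lifelog cohort through ordered exclusion stages, mirroring a
#' study-flow diagram: (1) at least one weight log; (2) plausible height;
#' (3) target weight not above initial weight (a no-op unless the cohort
#' carries a `target_weight_kg` column); (4) adult age present; (5) initial
#' BMI at or above the overweight criterion (also fails when no initial
#' weight falls in the window); (6) final weight available under the
#' final-week/fallback rule; (7) no inconsistent weight records; (8) minimal
#' meal-logging adherence. The first failing stage is the user's exclusion
#' reason.
#'
#' @param cohort A lifelog cohort tibble (see [generate_cohort()]).
#' @param criteria A [cohort_criteria()].
#' @return A list: `included` (filtered cohort tibble), `records` (one
#'   eligibility record per input user), and `flow` (per-stage accounting
#'   with `n_in = n_excluded + n_out` at every stage).
#' @export
apply_eligibility <- function(cohort, criteria = cohort_criteria()) {
  n <- nrow(cohort)
  has_target <- "target_weight_kg" %in% names(cohort)

  init <- purrr::map(cohort$weights, extract_initial_weight,
                     window = criteria$initial_window)
  fin <- purrr::map(cohort$weights, extract_final_weight,
                    program_weeks = criteria$program_weeks)
  init_day <- purrr::map_int(init, ~ if (is.null(.x)) NA_integer_ else as.integer(.x$day))
  init_kg <- purrr::map_dbl(init, ~ if (is.null(.x)) NA_real_ else .x$weight_kg)
  fin_day <- purrr::map_int(fin, ~ if (is.null(.x)) NA_integer_ else as.integer(.x$day))
  fin_kg <- purrr::map_dbl(fin, ~ if (is.null(.x)) NA_real_ else .x$weight_kg)
  init_bmi <- ifelse(!is.na(init_kg) & !is.na(cohort$height_cm) & cohort$height_cm > 0,
                     init_kg / (cohort$height_cm / 100)^2, NA_real_)

  stage_fail <- list(
    no_weight_logs = purrr::map_int(cohort$weights, nrow) == 0,
    height_out_of_range = !check_height(cohort$height_cm, criteria$height_range),
    target_above_initial = if (has_target)
      !is.na(cohort$target_weight_kg) & !is.na(init_kg) &
        cohort$target_weight_kg > init_kg
      else rep(FALSE, n),
    not_adult = is.na(cohort$age) | cohort$age < criteria$adult_age,
    bmi_below_threshold = is.na(init_bmi) | init_bmi < criteria$min_bmi,
    no_final_weight = is.na(fin_kg),
    inconsistent_weight = purrr::map2_lgl(
      cohort$weights, cohort$height_cm,
      function(w, h) {
        if (nrow(w) < 2 || is.na(h) || h <= 0) return(FALSE)
        nrow(detect_inconsistent_weights(w, h)) > 0
      }),
    insufficient_meal_adherence = if (criteria$meal_rule == "every_week")
      !purrr::map_lgl(cohort$meals, meal_adherence_ok, criteria = criteria)
      else rep(FALSE, n)
  )
  if (!has_target) stage_fail$target_above_initial <- NULL

  alive <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flow <- purrr::imap(stage_fail, function(fail, stage) {
    n_in <- sum(alive)
    drop <- alive & fail
    reason[drop] <<- stage
    alive <<- alive & !drop
    tibble(stage = stage, n_in = n_in, n_excluded = sum(drop),
           n_out = n_in - sum(drop), exclusion_reason = stage)
  })

  records <- tibble(
    user_id = cohort$user_id,
    initial_day = init_day, initial_weight_kg = init_kg,
    final_day = fin_day, final_weight_kg = fin_kg,
    initial_bmi = init_bmi,
    included = alive, exclusion_reason = reason
  )
  list(included = cohort[alive, ], records = records, flow = bind_rows(flow))
}

# ---- lifelog interchange -------------------------------------------------

#' Write a lifelog cohort as JSON lines
#'
#' One user per line; event streams as parallel arrays. The companion
#' reader is [read_lifelogs()].
#'
#' @param cohort Cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lifelogs <- function(cohort, path) {
  lines <- purrr::map_chr(seq_len(nrow(cohort)), function(i) {
    rec <- list(
      user_id = cohort$user_id[i],
      archetype = if ("archetype" %in% names(cohort)) cohort$archetype[i] else NULL,
      sex = cohort$sex[i], age = cohort$age[i],
      height_cm = cohort$height_cm[i],
      enrollment_day = cohort$enrollment_day[i],
      weights = as.list(cohort$weights[[i]]),
      meals = as.list(cohort$meals[[i]]),
      messages = as.list(cohort$messages[[i]]),
      steps = as.list(cohort$steps[[i]])
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a lifelog cohort from JSON lines
#'
#' @param path File written by [write_lifelogs()].
#' @return A cohort tibble.
#' @export
read_lifelogs <- function(path) {
  lines <- readLines(path)
  rows <- purrr::map(lines, jsonlite::fromJSON)
  stream <- function(r, nm, cols) {
    x <- r[[nm]]
    if (is.null(x) || length(x) == 0 || length(x[[1]]) == 0) {
      out <- purrr::map(cols, ~ vector(mode = .x, length = 0))
      names(out) <- names(cols)
      return(as_tibble(out))
    }
    as_tibble(x)
  }
  tibble(
    user_id = purrr::map_chr(rows, "user_id"),
    archetype = purrr::map_chr(rows, ~ .x$archetype %||% NA_character_),
    sex = purrr::map_chr(rows, ~ .x$sex %||% NA_character_),
    age = purrr::map_dbl(rows, ~ .x$age %||% NA_real_),
    height_cm = purrr::map_dbl(rows, ~ .x$height_cm %||% NA_real_),
    enrollment_day = purrr::map_int(rows, ~ as.integer(.x$enrollment_day %||% 0L)),
    weights = purrr::map(rows, stream, "weights",
                         c(day = "integer", weight_kg = "numeric")),
    meals = purrr::map(rows, stream, "meals",
                       c(day = "integer", meal_id = "integer")),
    messages = purrr::map(rows, stream, "messages",
                          c(day = "integer", direction = "character")),
    steps = purrr::map(rows, stream, "steps",
                       c(day = "integer", step_count = "integer"))
  )
}
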