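#' Archetype names for simulated weight-loss trajectories
#'
#' Five latent trajectory shapes observed in 16-week mobile weight-management
#' cohorts: a sharp steady decrease, a moderate decrease that plateaus, a
#' "yo-yo" course that rebounds after a mid-program nadir, a stable-or-
#' increasing course, and a non-converging remainder.
#'
#' @export
trajectory_archetypes <- c(
  "sharp_decrease", "moderate_decrease", "yo_yo", "stable_increase", "other"
)

#' Parametric mean trajectory for an archetype
#'
#' Returns a function of program time (in weeks, continuous, 0 = enrollment)
#' giving the expected fractional weight change relative to baseline. The
#' shapes are parametric stand-ins calibrated qualitatively to published
#' cluster prototypes: no generative model for the real trajectories has been
#' published, so these curves are simulation devices, not estimates.
#'
#' * `sharp_decrease`: exponential decay reaching -10% at the final week
#'   (monotone non-increasing).
#' * `moderate_decrease`: fast decay to -4% by the nadir week, then plateau.
#' * `yo_yo`: the moderate curve up to the nadir week, then a linear rebound
#'   to -1% at the final week.
#' * `stable_increase`: linear gain to +2%.
#' * `other`: sum of two sinusoids (non-converging).
#'
#' @param name One of [trajectory_archetypes].
#' @param program_weeks Program length in weeks (default 16).
#' @param nadir_week Week of the yo-yo nadir (default 8).
#' @return A vectorized function `f(t_weeks) -> fractional change`.
#' @export
archetype_curve <- function(name, program_weeks = 16, nadir_week = 8) {
  name <- match.arg(name, trajectory_archetypes)
  W <- program_weeks
  moderate <- function(t) {
    ifelse(t <= nadir_week,
           -0.04 * (1 - exp(-t / 2.5)) / (1 - exp(-nadir_week / 2.5)),
           -0.04)
  }
  switch(name,
    sharp_decrease = function(t) -0.10 * (1 - exp(-t / 5)) / (1 - exp(-W / 5)),
    moderate_decrease = moderate,
    yo_yo = function(t) {
      ifelse(t <= nadir_week,
             moderate(t),
             -0.04 + 0.03 * (t - nadir_week) / (W - nadir_week))
    },
    stable_increase = function(t) 0.02 * t / W,
    other = function(t) 0.02 * sin(2 * pi * t / 10) + 0.012 * sin(2 * pi * t / 4.2)
  )
}

# Default per-archetype weekly adherence rates. Meal rates are full weekly
# curves: identical in week 1, peaking in weeks 2-4, then decaying at
# archetype-dependent speed so the moderate-vs-yo-yo gap is largest at week 4
# and shrinks afterwards. Other rates are flat weekly (or daily) means that
# echo published per-cluster medians.
default_adherence_params <- function(program_weeks = 16) {
  stopifnot(program_weeks >= 1)
  pad <- function(x) {
    if (program_weeks <= 16) x[seq_len(program_weeks)]
    else c(x, rep(x[16], program_weeks - 16))
  }
  meal <- list(
    sharp_decrease    = c(14, 18, 20, 20, 19, 18.5, 18, 18, 17.5, 17.5,
                          17.5, 17.5, 17.5, 17.5, 17, 17),
    moderate_decrease = c(14, 17, 18, 18, 17.5, 17, 16.5, 16, 15.5, 15,
                          14.5, 14, 13.5, 13, 12.5, 12),
    yo_yo             = c(14, 16.5, 16, 13.5, 13.5, 13.25, 13, 12.75, 12.5,
                          12.5, 12.5, 12.5, 12.5, 12.5, 12.5, 12.5),
    stable_increase   = c(14, 16, 16, 15, 14, 13.5, 13, 12.5, 12, 11.5,
                          11, 10.5, 10, 10, 9.5, 9.5),
    other             = c(14, 16, 16.5, 15.5, 15, 14.5, 14, 13.5, 13, 13,
                          12.5, 12, 12, 11.5, 11, 11)
  )
  weight_rate <- c(sharp_decrease = 4.9, moderate_decrease = 4.4, yo_yo = 4.0,
                   stable_increase = 4.2, other = 3.6)
  msg_sent <- c(sharp_decrease = 2.1, moderate_decrease = 2.1, yo_yo = 1.9,
                stable_increase = 1.9, other = 1.9)
  msg_recv <- c(sharp_decrease = 3.0, moderate_decrease = 3.0, yo_yo = 2.8,
                stable_increase = 2.8, other = 2.8)
  steps_mean <- c(sharp_decrease = 5469, moderate_decrease = 5191, yo_yo = 5102,
                  stable_increase = 5070, other = 4810)
  purrr::map(
    rlang::set_names(trajectory_archetypes),
    function(a) list(
      meal_rate_weekly   = pad(meal[[a]]),
      weight_rate_weekly = rep(weight_rate[[a]], program_weeks),
      msg_sent_rate      = msg_sent[[a]],
      msg_recv_rate      = msg_recv[[a]],
      steps_mean         = steps_mean[[a]],
      steps_sd           = 2500,
      steps_logged_prob  = 0.8
    )
  )
}

#' Configuration for the synthetic lifelog generator
#'
#' @param n_users Number of users to simulate.
#' @param archetype_weights Named numeric vector of five mixture
#'   probabilities over [trajectory_archetypes]; must be non-negative and
#'   sum to 1 (within 1e-12). Defaults echo the published cluster shares.
#' @param program_weeks Program length in weeks (default 16).
#' @param weight_noise_sd SD (kg) of Gaussian measurement noise added to each
#'   weight log; 0.5 kg emulates day-to-day scale and hydration variability.
#' @param baseline_bmi_mean,baseline_bmi_sd Baseline BMI distribution
#'   (kg/m^2), truncated below at `baseline_bmi_min`.
#' @param baseline_bmi_min Lower truncation for baseline BMI; default 26 keeps
#'   the simulated cohort in the overweight range targeted by the program.
#' @param height_mean,height_sd Height distribution (cm).
#' @param age_mean,age_sd Age distribution (years), truncated below at 18.
#' @param female_prop Proportion of female users.
#' @param nadir_week Yo-yo nadir week (default 8).
#' @param adherence_params Per-archetype weekly log-rate curves; see
#'   `default_adherence_params()`.
#' @param violation_rates Named probabilities for injected protocol
#'   violations: `height_out_of_range`, `no_weight_logs`,
#'   `missing_final_weight`, `inconsistent_weight`. All default to 0.
#' @param seed Integer seed; all generation is deterministic given the seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_users = 500,
                         archetype_weights = c(
                           sharp_decrease = 0.8596, moderate_decrease = 0.0634,
                           yo_yo = 0.0292, stable_increase = 0.0305,
                           other = 0.0173),
                         program_weeks = 16,
                         weight_noise_sd = 0.5,
                         baseline_bmi_mean = 33.6, baseline_bmi_sd = 5.9,
                         baseline_bmi_min = 26,
                         height_mean = 166.4, height_sd = 7.4,
                         age_mean = 43.9, age_sd = 10.9,
                         female_prop = 0.92,
                         nadir_week = 8,
                         adherence_params = default_adherence_params(program_weeks),
                         violation_rates = c(
                           height_out_of_range = 0, no_weight_logs = 0,
                           missing_final_weight = 0, inconsistent_weight = 0),
                         seed = 1L) {
  cfg <- list(
    n_users = n_users, archetype_weights = archetype_weights,
    program_weeks = program_weeks, weight_noise_sd = weight_noise_sd,
    baseline_bmi_mean = baseline_bmi_mean, baseline_bmi_sd = baseline_bmi_sd,
    baseline_bmi_min = baseline_bmi_min,
    height_mean = height_mean, height_sd = height_sd,
    age_mean = age_mean, age_sd = age_sd, female_prop = female_prop,
    nadir_week = nadir_week, adherence_params = adherence_params,
    violation_rates = violation_rates, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid synth_config field `%s`: %s", field, why),
          class = "trajclust_config_error")
  }
  w <- cfg$archetype_weights
  if (length(w) != 5 || !setequal(names(w), trajectory_archetypes))
    bad("archetype_weights", "must be named over the five archetypes")
  if (any(w < 0)) bad("archetype_weights", "must be non-negative")
  if (abs(sum(w) - 1) > 1e-12) bad("archetype_weights", "must sum to 1")
  if (cfg$n_users < 0) bad("n_users", "must be >= 0")
  if (cfg$program_weeks < 1) bad("program_weeks", "must be >= 1")
  if (cfg$weight_noise_sd < 0) bad("weight_noise_sd", "must be >= 0")
  for (a in trajectory_archetypes) {
    p <- cfg$adherence_params[[a]]
    if (is.null(p)) bad("adherence_params", paste("missing archetype", a))
    rates <- c(p$meal_rate_weekly, p$weight_rate_weekly, p$msg_sent_rate,
               p$msg_recv_rate, p$steps_mean)
    if (any(rates < 0)) bad("adherence_params", paste(a, "has a negative rate"))
  }
  vr <- cfg$violation_rates
  need <- c("height_out_of_range", "no_weight_logs", "missing_final_weight",
            "inconsistent_weight")
  if (!all(need %in% names(vr)))
    bad("violation_rates", "must name all four violation types")
  if (any(vr < 0 | vr > 1)) bad("violation_rates", "must lie in [0, 1]")
  cfg
}

empty_cohort <- function() {
  tibble(
    user_id = character(), archetype = character(), sex = character(),
    age = numeric(), height_cm = numeric(), baseline_weight_kg = numeric(),
    enrollment_day = integer(),
    weights = list(), meals = list(), messages = list(), steps = list()
  )
}

rnorm_trunc <- function(n, mean, sd, lower) {
  # inverse-CDF sampling of the lower-truncated normal
  u <- runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

week_days <- function(w) (7L * (w - 1L)):(7L * w - 1L)

#' Generate a synthetic lifelog cohort
#'
#' Draws `n_users` users: a latent trajectory archetype, demographics,
#' day-stamped weight logs following the archetype mean curve applied to the
#' user's baseline weight plus Gaussian noise, and app-use events (meal logs,
#' coach messages sent/received, daily steps) at per-archetype weekly Poisson
#' rates with day-level jitter. Every user logs a weight on day 0 and at
#' least once in the final program week, so that downstream final-weight
#' availability is governed solely by [inject_violations()].
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per user: demographics, the latent
#'   `archetype` label (ground truth for benchmarking), and list-columns
#'   `weights` (day, weight_kg), `meals` (day, meal_id), `messages`
#'   (day, direction), `steps` (day, step_count).
#' @export
generate_cohort <- function(config) {
  config <- validate_synth_config(config)
  if (config$n_users == 0) return(empty_cohort())
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_users
  W <- cfg$program_weeks
  last_week_days <- week_days(W)
  archetype <- sample(trajectory_archetypes, n, replace = TRUE,
                      prob = cfg$archetype_weights[trajectory_archetypes])
  sex <- ifelse(runif(n) < cfg$female_prop, "female", "male")
  age <- rnorm_trunc(n, cfg$age_mean, cfg$age_sd, 18)
  height_cm <- rnorm(n, cfg$height_mean, cfg$height_sd)
  bmi <- rnorm_trunc(n, cfg$baseline_bmi_mean, cfg$baseline_bmi_sd,
                     cfg$baseline_bmi_min)
  baseline_kg <- bmi * (height_cm / 100)^2

  rows <- purrr::map(seq_len(n), function(i) {
    a <- archetype[i]
    curve <- archetype_curve(a, W, cfg$nadir_week)
    p <- cfg$adherence_params[[a]]

    wdays <- integer(0)
    for (w in seq_len(W)) {
      cnt <- min(7L, rpois(1, p$weight_rate_weekly[w]))
      if (cnt > 0) wdays <- c(wdays, sample(week_days(w), cnt))
    }
    wdays <- union(wdays, 0L)                       # day-0 weigh-in always
    if (!any(wdays %in% last_week_days))            # guarantee final-week log
      wdays <- c(wdays, sample(last_week_days, 1))
    wdays <- sort(unique(wdays))
    wkg <- baseline_kg[i] * (1 + curve(wdays / 7)) +
      rnorm(length(wdays), 0, cfg$weight_noise_sd)

    mday <- integer(0)
    for (w in seq_len(W)) {
      cnt <- rpois(1, p$meal_rate_weekly[w])
      if (cnt > 0) mday <- c(mday, sort(sample(week_days(w), cnt, replace = TRUE)))
    }
    sent <- integer(0); recv <- integer(0)
    for (w in seq_len(W)) {
      cs <- rpois(1, p$msg_sent_rate)
      cr <- rpois(1, p$msg_recv_rate)
      if (cs > 0) sent <- c(sent, sort(sample(week_days(w), cs, replace = TRUE)))
      if (cr > 0) recv <- c(recv, sort(sample(week_days(w), cr, replace = TRUE)))
    }
    all_days <- 0:(7L * W - 1L)
    logged <- all_days[runif(length(all_days)) < p$steps_logged_prob]
    steps <- pmax(0, round(rnorm(length(logged), p$steps_mean, p$steps_sd)))

    msg <- tibble(day = c(sent, recv),
                  direction = rep(c("sent", "received"),
                                  c(length(sent), length(recv))))
    msg <- msg[order(msg$day), ]
    list(
      weights = tibble(day = wdays, weight_kg = wkg),
      meals = tibble(day = mday, meal_id = seq_along(mday)),
      messages = msg,
      steps = tibble(day = logged, step_count = as.integer(steps))
    )
  })

  tibble(
    user_id = sprintf("u%05d", seq_len(n)),
    archetype = archetype, sex = sex, age = age, height_cm = height_cm,
    baseline_weight_kg = baseline_kg, enrollment_day = 0L,
    weights = purrr::map(rows, "weights"),
    meals = purrr::map(rows, "meals"),
    messages = purrr::map(rows, "messages"),
    steps = purrr::map(rows, "steps")
  )
}

#' Inject protocol violations into a synthetic cohort
#'
#' Flags an independent Bernoulli draw of users for each configured violation
#' and modifies their logs so that the matching eligibility stage must
#' exclude them: height pushed outside \[125, 230\] cm; all weight logs
#' removed; final-week (and later) weight logs removed; or an extra weight
#' log inserted 10 days after the first log with a jump of +4.5 BMI units
#' (tripping the consecutive-record consistency rule, which flags BMI changes
#' >= 3.5 kg/m^2 within 30 days, with margin for measurement noise). A user flagged for `no_weight_logs` is not
#' additionally given weight-based violations.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param config The [synth_config()] whose `violation_rates` and `seed`
#'   drive the draw (the seed is offset so the draw is independent of
#'   generation).
#' @return A list with `cohort` (modified tibble) and `manifest`, a tibble
#'   (user_id, violation) with one row per injected violation.
#' @export
inject_violations <- function(cohort, config) {
  config <- validate_synth_config(config)
  rates <- config$violation_rates
  if (nrow(cohort) == 0 || all(rates == 0))
    return(list(cohort = cohort,
                manifest = tibble(user_id = character(), violation = character())))
  withr::with_seed(config$seed + 1L, inject_violations_impl(cohort, config))
}

inject_violations_impl <- function(cohort, cfg) {
  n <- nrow(cohort)
  rates <- cfg$violation_rates
  final_start <- 7L * (cfg$program_weeks - 1L)
  flags <- list(
    height_out_of_range  = runif(n) < rates[["height_out_of_range"]],
    no_weight_logs       = runif(n) < rates[["no_weight_logs"]],
    missing_final_weight = runif(n) < rates[["missing_final_weight"]],
    inconsistent_weight  = runif(n) < rates[["inconsistent_weight"]]
  )
  flags$missing_final_weight <- flags$missing_final_weight & !flags$no_weight_logs
  flags$inconsistent_weight  <- flags$inconsistent_weight & !flags$no_weight_logs

  low <- runif(n, 100, 124.5)
  high <- runif(n, 230.5, 260)
  pick_low <- runif(n) < 0.5
  for (i in seq_len(n)) {
    if (flags$height_out_of_range[i])
      cohort$height_cm[i] <- if (pick_low[i]) low[i] else high[i]
    if (flags$no_weight_logs[i])
      cohort$weights[[i]] <- cohort$weights[[i]][0, ]
    if (flags$missing_final_weight[i]) {
      wt <- cohort$weights[[i]]
      cohort$weights[[i]] <- wt[wt$day < final_start, ]
    }
    if (flags$inconsistent_weight[i]) {
      wt <- cohort$weights[[i]]
      if (nrow(wt) > 0) {
        jump <- 4.5 * (cohort$height_cm[i] / 100)^2
        extra <- tibble(day = wt$day[1] + 10L,
                        weight_kg = wt$weight_kg[1] + jump)
        wt <- bind_rows(wt, extra)
        cohort$weights[[i]] <- wt[order(wt$day, method = "radix"), ]
      }
    }
  }
  manifest <- purrr::imap(flags, function(f, nm) {
    tibble(user_id = cohort$user_id[f], violation = nm)
  })
  list(cohort = cohort, manifest = bind_rows(manifest))
}
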