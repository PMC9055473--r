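test_that("config validation names the offending field", {
  expect_error(synth_config(n_users = -1), "n_users")
  expect_error(synth_config(archetype_weights = c(
    sharp_decrease = 0.5, moderate_decrease = 0.5, yo_yo = 0.1,
    stable_increase = 0, other = -0.1)), "archetype_weights")
  w <- c(sharp_decrease = 0.3, moderate_decrease = 0.3, yo_yo = 0.2,
         stable_increase = 0.1, other = 0.0999)
  expect_error(synth_config(archetype_weights = w), "sum to 1")
  expect_error(synth_config(program_weeks = 0), "program_weeks")
  expect_error(synth_config(violation_rates = c(
    height_out_of_range = 1.2, no_weight_logs = 0, missing_final_weight = 0,
    inconsistent_weight = 0)), "violation_rates")
})

test_that("an empty cohort is generated for n_users = 0", {
  coh <- generate_cohort(synth_config(n_users = 0))
  expect_equal(nrow(coh), 0)
  expect_true(all(c("user_id", "archetype", "weights", "meals") %in% names(coh)))
})

test_that("archetype curves have the shapes they claim", {
  t <- seq(0, 16, by = 0.25)
  sharp <- archetype_curve("sharp_decrease")(t)
  expect_true(all(diff(sharp) <= 0))
  expect_equal(sharp[length(sharp)], -0.10, tolerance = 1e-12)

  yy <- archetype_curve("yo_yo")
  wk <- 1:16
  nadir <- which.min(yy(wk))
  expect_equal(nadir, 8)
  expect_true(all(diff(yy(seq(8, 16, 0.5))) > 0))

  yy12 <- archetype_curve("yo_yo", nadir_week = 12)
  expect_equal(which.min(yy12(wk)), 12)
})

test_that("noise-free single-archetype series follow the mean curve exactly", {
  cfg <- synth_config(
    n_users = 60, weight_noise_sd = 0,
    archetype_weights = c(sharp_decrease = 1, moderate_decrease = 0,
                          yo_yo = 0, stable_increase = 0, other = 0),
    seed = 42)
  coh <- generate_cohort(cfg)
  curve <- archetype_curve("sharp_decrease")
  for (i in seq_len(nrow(coh))) {
    w <- coh$weights[[i]]
    expected <- coh$baseline_weight_kg[i] * (1 + curve(w$day / 7))
    expect_equal(w$weight_kg, expected, tolerance = 1e-12)
    expect_true(all(diff(w$weight_kg) <= 0))
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_users = 200, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synth_config(n_users = 200, seed = 10)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("every user has a day-0 weigh-in and a final-week weight log", {
  coh <- generate_cohort(synth_config(n_users = 150, seed = 3))
  final_days <- 105:111
  for (w in coh$weights) {
    expect_true(0 %in% w$day)
    expect_true(any(w$day %in% final_days))
    expect_false(is.unsorted(w$day))
  }
})

test_that("meal adherence gap between archetypes peaks at week 4", {
  for (pair in list(c("sharp_decrease", "yo_yo"),
                    c("moderate_decrease", "yo_yo"))) {
    w <- rlang::set_names(rep(0, 5), trajectory_archetypes)
    w[pair] <- 0.5
    coh <- generate_cohort(synth_config(n_users = 600, archetype_weights = w,
                                        seed = 21))
    usage <- summarize_usage(coh)
    weekly <- tidyr::unnest(usage[, c("user_id", "weekly")], "weekly")
    weekly$archetype <- coh$archetype[match(weekly$user_id, coh$user_id)]
    gap <- tapply(weekly$meal_records,
                  list(weekly$week, weekly$archetype), mean)
    diff_curve <- gap[, pair[1]] - gap[, pair[2]]
    expect_equal(unname(which.max(diff_curve)), 4)
  }
})

test_that("violation injection is an identity at rate zero", {
  cfg <- synth_config(n_users = 50, seed = 2)
  coh <- generate_cohort(cfg)
  out <- inject_violations(coh, cfg)
  expect_identical(out$cohort, coh)
  expect_equal(nrow(out$manifest), 0)
})

test_that("a unit height-violation rate pushes every height out of range", {
  cfg <- synth_config(n_users = 50, seed = 2, violation_rates = c(
    height_out_of_range = 1, no_weight_logs = 0, missing_final_weight = 0,
    inconsistent_weight = 0))
  out <- inject_violations(generate_cohort(cfg), cfg)
  expect_true(all(out$cohort$height_cm < 125 | out$cohort$height_cm > 230))
  expect_equal(sort(out$manifest$user_id), sort(out$cohort$user_id))
})

test_that("injected weight jumps trip the inconsistency detector", {
  cfg <- synth_config(n_users = 300, seed = 14, violation_rates = c(
    height_out_of_range = 0, no_weight_logs = 0, missing_final_weight = 0,
    inconsistent_weight = 0.1))
  out <- inject_violations(generate_cohort(cfg), cfg)
  flagged <- out$manifest$user_id[out$manifest$violation == "inconsistent_weight"]
  # the manifest is the realized Bernoulli draw: plausible count, exact match
  expect_gt(length(flagged), 300 * 0.1 / 2)
  expect_lt(length(flagged), 300 * 0.1 * 2)
  for (u in out$cohort$user_id) {
    i <- match(u, out$cohort$user_id)
    hits <- detect_inconsistent_weights(out$cohort$weights[[i]],
                                        out$cohort$height_cm[i])
    if (u %in% flagged) expect_gt(nrow(hits), 0)
    else expect_equal(nrow(hits), 0)
  }
})

test_that("lifelogs survive a JSONL round trip", {
  coh <- generate_cohort(synth_config(n_users = 12, seed = 4))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_lifelogs(coh, path)
  back <- read_lifelogs(path)
  expect_equal(back$user_id, coh$user_id)
  expect_equal(back$height_cm, coh$height_cm, tolerance = 1e-12)
  for (i in seq_len(nrow(coh))) {
    expect_equal(back$weights[[i]]$day, coh$weights[[i]]$day)
    expect_equal(back$weights[[i]]$weight_kg, coh$weights[[i]]$weight_kg,
                 tolerance = 1e-12)
    expect_equal(back$messages[[i]]$direction, coh$messages[[i]]$direction)
  }
})
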