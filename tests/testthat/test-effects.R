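test_that("the KS screen separates normal from skewed samples", {
  withr::with_seed(51, {
    expect_gt(ks_normality(rnorm(10000)), 0.05)
    expect_lt(ks_normality(rexp(10000)), 1e-6)
  })
  expect_equal(ks_normality(rep(2, 100)), 0)
  expect_error(ks_normality(c(1, 2)), class = "trajclust_domain_error")
})

test_that("Cohen's d matches hand computation and flags degenerate SDs", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohen_d(x, x), 0)
  expect_equal(cohen_d(c(0, 1), c(1, 2)), -sqrt(2))
  expect_warning(d <- cohen_d(c(1, 1), c(1, 1)), "pooled SD")
  expect_true(is.nan(d))
})

test_that("eta squared equals the hand SS decomposition", {
  expect_equal(eta_squared(c(1, 2, 1, 2), rep(c("a", "b"), each = 2)), 0)
  expect_equal(eta_squared(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # groups [1,2,3], [2,3,4], [3,4,5]: SS_between 6, SS_total 12
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  expect_equal(eta_squared(vals, grp), 0.5)
  expect_error(eta_squared(1:3, c("a", "a", "b")),
               class = "trajclust_domain_error")
})

test_that("chi-square association matches first principles on small tables", {
  perfect <- rbind(c(10, 0), c(0, 10))
  res <- chi_square_with_v(perfect)
  expect_equal(res$effect_type, "phi")
  expect_equal(res$effect_value, 1)
  # an outer-product (independent) table has zero association
  indep <- outer(c(2, 3), c(4, 6))
  expect_equal(chi_square_with_v(indep)$effect_value, 0, tolerance = 1e-12)
  expect_equal(chi_square_with_v(indep)$statistic, 0, tolerance = 1e-12)
  # signed phi
  res2 <- chi_square_with_v(rbind(c(0, 10), c(10, 0)))
  expect_equal(res2$effect_value, -1)
  expect_error(chi_square_with_v(rbind(c(0, 0), c(1, 2))),
               class = "trajclust_domain_error")
})

test_that("group comparison routes by normality and applies the dual rule", {
  withr::with_seed(52, {
    normal <- rnorm(300)
    res_n <- group_comparison(normal, rep(1:3, 100))
    expect_equal(res_n$test_name, "anova")
    skewed <- rexp(300)
    res_s <- group_comparison(skewed, rep(1:3, 100))
    expect_equal(res_s$test_name, "kruskal_wallis")
    # strong but tiny-effect association at huge n stays "not significant"
    big <- rnorm(30000)
    grp <- rep(1:3, 10000)
    big[grp == 1] <- big[grp == 1] + 0.05
    res_b <- group_comparison(big, grp, route = "anova")
    expect_lt(res_b$p_value, 0.05)
    expect_lt(res_b$effect_value, 0.01)
    expect_false(res_b$significant)
  })
})

test_that("a generator-imposed meal gap dominates the cross-sectional effects", {
  w <- c(sharp_decrease = 0.4, moderate_decrease = 0.3, yo_yo = 0.3,
         stable_increase = 0, other = 0)
  coh <- generate_cohort(synth_config(n_users = 900, archetype_weights = w,
                                      seed = 53))
  usage <- summarize_usage(coh)
  asg <- tibble::tibble(
    user_id = coh$user_id,
    cluster = match(coh$archetype, trajectory_archetypes))
  res <- compare_clusters_cross_sectional(usage, NULL, asg)
  meal <- res[res$variable == "meal_records_per_week", ]
  expect_true(meal$significant)
  expect_equal(which.max(res$effect_value),
               which(res$variable == "meal_records_per_week"))
  # permuting cluster labels destroys the association
  asg_perm <- asg
  asg_perm$cluster <- withr::with_seed(54, sample(asg$cluster))
  res_p <- compare_clusters_cross_sectional(usage, NULL, asg_perm)
  expect_false(any(res_p$significant))
  expect_true(all(res_p$effect_value < 0.01))
})

test_that("weekly effects are exactly null for identical groups", {
  coh <- generate_cohort(synth_config(n_users = 100, seed = 55))
  usage <- summarize_usage(coh)
  # two "clusters" holding literally the same users' data
  dup <- dplyr::bind_rows(usage, dplyr::mutate(usage, user_id = paste0(user_id, "b")))
  asg <- tibble::tibble(user_id = dup$user_id,
                        cluster = rep(2:3, each = nrow(usage)))
  wk <- weekly_effect_trajectory(dup, asg, anova_clusters = 2:3,
                                 pairs = list(c(2, 3)),
                                 variables = "meal_records")
  d_curve <- wk$effect_value[wk$comparison == "d_2_vs_3"]
  expect_true(all(abs(d_curve) < 1e-12))
})

test_that("weeks with an empty group are flagged, not fatal", {
  coh <- generate_cohort(synth_config(n_users = 30, seed = 56))
  usage <- summarize_usage(coh)
  asg <- tibble::tibble(user_id = usage$user_id,
                        cluster = c(3L, rep(2L, nrow(usage) - 1)))
  # cluster 3 has a single member: every weekly cell lacks n >= 2
  wk <- weekly_effect_trajectory(usage, asg, anova_clusters = 2:3,
                                 pairs = list(c(2, 3)),
                                 variables = "meal_records")
  expect_true(all(is.na(wk$effect_value)))
  expect_equal(nrow(wk), 32)
})

test_that("the weekly meal-gap d curve peaks at the configured gap week", {
  w <- c(sharp_decrease = 0, moderate_decrease = 0.5, yo_yo = 0.5,
         stable_increase = 0, other = 0)
  coh <- generate_cohort(synth_config(n_users = 600, archetype_weights = w,
                                      seed = 57))
  usage <- summarize_usage(coh)
  asg <- tibble::tibble(
    user_id = coh$user_id,
    cluster = ifelse(coh$archetype == "moderate_decrease", 2L, 3L))
  wk <- weekly_effect_trajectory(usage, asg, anova_clusters = 2:3,
                                 pairs = list(c(2, 3)),
                                 variables = "meal_records")
  peaks <- effect_peaks(wk)
  pk <- peaks[peaks$comparison == "d_2_vs_3", ]
  expect_lte(abs(pk$peak_week - 4), 1)
})
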