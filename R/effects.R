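#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of a sample against a normal with the sample's own
#' mean and SD (parameters estimated from the data; no small-sample
#' correction is applied, and the resulting p-values are used only to route
#' between parametric and rank-based group tests, not reported as exact).
#' A numerically constant sample is returned as p = 0 so it routes to the
#' nonparametric branch.
#'
#' @param x Numeric sample, n >= 3.
#' @return The KS p-value.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3)
    abort("ks_normality requires n >= 3", class = "trajclust_domain_error")
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(0)
  suppressWarnings(ks.test(x, "pnorm", mean(x), s)$p.value)
}

#' Cohen's d (pooled SD)
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y Numeric samples, each n >= 2.
#' @return Scalar d; `NaN` with a warning when the pooled SD is zero.
#' @export
cohen_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    abort("cohen_d requires n >= 2 per group", class = "trajclust_domain_error")
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp < 1e-12) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NaN)
  }
  (mean(x) - mean(y)) / sp
}

#' Eta squared from a one-way layout
#'
#' `SS_between / SS_total` from the one-way ANOVA decomposition.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, >= 2 groups with n >= 2 each.
#' @return Scalar in \[0, 1\]; `NaN` with a warning when total SS is zero.
#' @export
eta_squared <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    abort("eta_squared requires >= 2 groups with n >= 2 each",
          class = "trajclust_domain_error")
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  if (ss_total < 1e-12) {
    warning("zero total SS; eta squared undefined")
    return(NaN)
  }
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  sum(gn * (gm - grand)^2) / ss_total
}

#' Chi-square association with Cramer's V or phi
#'
#' Pearson chi-square (no continuity correction) on an r x c count table,
#' with Cramer's V = sqrt(chi2 / (N * min(r - 1, c - 1))). For a 2 x 2
#' table the signed phi coefficient
#' `(ad - bc) / sqrt(r1 r2 c1 c2)` is reported instead.
#'
#' @param table Non-negative integer matrix with all row/column margins > 0.
#' @return Tibble: statistic, df, p_value, effect_type ("cramers_v" or
#'   "phi"), effect_value.
#' @export
chi_square_with_v <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort("contingency table needs non-negative counts and positive margins",
          class = "trajclust_domain_error")
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  N <- sum(table)
  if (all(dim(table) == c(2, 2))) {
    eff_type <- "phi"
    eff <- (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1]) /
      sqrt(prod(rowSums(table)) * prod(colSums(table)))
  } else {
    eff_type <- "cramers_v"
    eff <- sqrt(unname(ht$statistic) / (N * (min(dim(table)) - 1)))
  }
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, effect_type = eff_type, effect_value = eff)
}

# Dual significance rule: p < alpha AND effect above the small threshold
# for its type.
effect_significant <- function(p, type, value,
                               alpha = 0.05,
                               small = c(cohen_d = 0.2, eta_squared = 0.01,
                                         cramers_v = 0.01, phi = 0.01)) {
  !is.na(p) & !is.na(value) & p < alpha & abs(value) > small[[type]]
}

#' Compare a continuous variable across clusters
#'
#' A KS normality screen (p > .05 = treat as normal) routes to a one-way
#' ANOVA or a Kruskal-Wallis test; eta squared is computed from the ANOVA
#' decomposition in either case so effect sizes stay comparable across
#' variables. The dual significance rule (p < .05 and eta^2 above the
#' small threshold 0.01) is applied.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 groups, n >= 2 each).
#' @param route `"auto"` (KS-routed), or force `"anova"` / `"kruskal"`.
#' @return One-row tibble: ks_p, test_name, statistic, p_value,
#'   effect_type, effect_value, significant.
#' @export
group_comparison <- function(values, groups, route = c("auto", "anova", "kruskal")) {
  route <- match.arg(route)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  ks_p <- if (route == "auto") ks_normality(values) else NA_real_
  use_anova <- switch(route, auto = ks_p > 0.05, anova = TRUE, kruskal = FALSE)
  if (use_anova) {
    fit <- summary(aov(values ~ groups))[[1]]
    test <- "anova"; statistic <- fit[["F value"]][1]; p <- fit[["Pr(>F)"]][1]
  } else {
    kw <- kruskal.test(values, groups)
    test <- "kruskal_wallis"; statistic <- unname(kw$statistic); p <- kw$p.value
  }
  eta <- eta_squared(values, groups)
  tibble(ks_p = ks_p, test_name = test, statistic = statistic, p_value = p,
         effect_type = "eta_squared", effect_value = eta,
         significant = effect_significant(p, "eta_squared", eta))
}

#' Cross-sectional cluster comparison
#'
#' For each continuous usage/outcome variable: a KS normality screen routes
#' to one-way ANOVA (normal) or Kruskal-Wallis (otherwise), with eta squared
#' from the ANOVA decomposition in both cases for comparability; per-cluster
#' medians and IQRs are attached. The weight-change class is compared with a
#' chi-square test and Cramer's V. Significance uses the dual rule: p < .05
#' and an effect above the small threshold for its type (eta^2 0.01,
#' Cramer's V 0.01, |d| 0.2).
#'
#' @param usage Usage summaries from [summarize_usage()].
#' @param outcomes Weight outcomes from [weight_outcomes()] (or `NULL` to
#'   skip the class comparison).
#' @param assignments Tibble (user_id, cluster) or named vector.
#' @param variables Continuous columns of `usage`/`outcomes` to compare.
#' @return A tibble with one row per variable: test_name, statistic,
#'   p_value, effect_type, effect_value, significant, and a `per_cluster`
#'   list-column of median/IQR summaries.
#' @export
compare_clusters_cross_sectional <- function(
    usage, outcomes, assignments,
    variables = c("meal_records_per_week", "weight_records_per_week",
                  "messages_sent_per_week", "messages_received_per_week",
                  "steps_per_day")) {
  if (!is.data.frame(assignments))
    assignments <- tibble(user_id = names(assignments),
                          cluster = unname(assignments))
  d <- left_join(usage, assignments, by = "user_id")
  if (any(is.na(d$cluster)))
    abort("every usage row needs a cluster assignment",
          class = "trajclust_domain_error")

  rows <- purrr::map(variables, function(v) {
    vals <- d[[v]]
    ok <- !is.na(vals)
    vals <- vals[ok]; cl <- factor(d$cluster[ok])
    res <- group_comparison(vals, cl)
    per_cluster <- tibble(
      cluster = as.integer(levels(cl)),
      n = as.integer(table(cl)),
      median = as.numeric(tapply(vals, cl, median)),
      iqr = as.numeric(tapply(vals, cl, stats::IQR))
    )
    mutate(res, variable = v, per_cluster = list(per_cluster),
           .before = 1)
  })
  out <- bind_rows(rows)

  if (!is.null(outcomes)) {
    tab <- contingency_table(assignments, outcomes[, c("user_id", "class")])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    chi <- chi_square_with_v(tab)
    out <- bind_rows(out, tibble(
      variable = "weight_change_class", test_name = "chi_square",
      ks_p = NA_real_, statistic = chi$statistic, p_value = chi$p_value,
      effect_type = chi$effect_type, effect_value = chi$effect_value,
      significant = effect_significant(chi$p_value, chi$effect_type,
                                       chi$effect_value),
      per_cluster = list(NULL)
    ))
  }
  out
}

#' Weekly effect-size trajectories
#'
#' Week-by-week comparison of app-use variables across the three converging
#' clusters: per week, a one-way ANOVA with eta squared across the cluster
#' triple, and pooled two-sample t tests with Cohen's d for each configured
#' cluster pair. Emits the 16-point effect-size curve per variable and
#' comparison plus the week at which each curve peaks.
#'
#' @param usage Usage summaries from [summarize_usage()] (the `weekly`
#'   list-column supplies the per-week values).
#' @param assignments Tibble (user_id, cluster) or named vector.
#' @param anova_clusters Clusters entering the weekly ANOVA (default 1:3).
#' @param pairs List of length-2 cluster vectors for the t tests (default
#'   list(c(1, 3), c(2, 3))).
#' @param variables Weekly variables to compare.
#' @return A `weekly_effects` tibble: week, variable, comparison, test_name,
#'   statistic, p_value, effect_type, effect_value, significant; weeks where
#'   a group is empty are flagged via `NA` effects. The `peaks` attribute
#'   tibble gives the argmax week of |effect| per variable/comparison.
#' @export
weekly_effect_trajectory <- function(
    usage, assignments,
    anova_clusters = 1:3,
    pairs = list(c(1, 3), c(2, 3)),
    variables = c("meal_records", "weight_records", "messages_sent",
                  "messages_received", "steps_per_day")) {
  if (!is.data.frame(assignments))
    assignments <- tibble(user_id = names(assignments),
                          cluster = unname(assignments))
  long <- usage |>
    select("user_id", "weekly") |>
    tidyr::unnest("weekly") |>
    left_join(assignments, by = "user_id")
  W <- max(long$week)

  one_cell <- function(wk, v, comparison, clusters) {
    d <- long[long$week == wk & long$cluster %in% clusters, ]
    vals <- d[[v]]; cl <- d$cluster
    ok <- !is.na(vals); vals <- vals[ok]; cl <- cl[ok]
    counts <- table(factor(cl, levels = clusters))
    base <- tibble(week = wk, variable = v, comparison = comparison)
    if (any(counts < 2)) {
      return(mutate(base, test_name = NA_character_, statistic = NA_real_,
                    p_value = NA_real_, effect_type = NA_character_,
                    effect_value = NA_real_, significant = NA))
    }
    if (length(clusters) == 2) {
      g1 <- vals[cl == clusters[1]]; g2 <- vals[cl == clusters[2]]
      d_eff <- cohen_d(g1, g2)
      tt <- t.test(g1, g2, var.equal = TRUE)
      mutate(base, test_name = "t_test", statistic = unname(tt$statistic),
             p_value = tt$p.value, effect_type = "cohen_d",
             effect_value = d_eff,
             significant = effect_significant(tt$p.value, "cohen_d", d_eff))
    } else {
      fit <- summary(aov(vals ~ factor(cl)))[[1]]
      eta <- eta_squared(vals, cl)
      mutate(base, test_name = "anova", statistic = fit[["F value"]][1],
             p_value = fit[["Pr(>F)"]][1], effect_type = "eta_squared",
             effect_value = eta,
             significant = effect_significant(fit[["Pr(>F)"]][1],
                                              "eta_squared", eta))
    }
  }

  comparisons <- c(
    list(list(id = paste0("anova_", paste(anova_clusters, collapse = "")),
              clusters = anova_clusters)),
    purrr::map(pairs, ~ list(id = paste0("d_", .x[1], "_vs_", .x[2]),
                             clusters = .x))
  )
  grid <- tidyr::expand_grid(week = seq_len(W), variable = variables,
                             cmp = comparisons)
  out <- purrr::pmap(grid, function(week, variable, cmp) {
    one_cell(week, variable, cmp$id, cmp$clusters)
  }) |> bind_rows()

  usable <- filter(out, !is.na(.data$effect_value))
  peaks <- if (nrow(usable) == 0) {
    tibble(variable = character(), comparison = character(),
           peak_week = integer(), peak_effect = numeric())
  } else {
    usable |>
      group_by(.data$variable, .data$comparison) |>
      summarise(peak_week = .data$week[which.max(abs(.data$effect_value))],
                peak_effect = max(abs(.data$effect_value)), .groups = "drop")
  }
  structure(out, class = c("weekly_effects", class(out)), peaks = peaks)
}

#' Peak weeks of weekly effect curves
#' @param x A `weekly_effects` object.
#' @return Tibble (variable, comparison, peak_week, peak_effect).
#' @export
effect_peaks <- function(x) attr(x, "peaks")

#' @describeIn weekly_effect_trajectory Effect-size curves over program
#'   weeks, faceted by variable.
#' @param object A `weekly_effects` object.
#' @param ... Unused.
#' @export
autoplot.weekly_effects <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$week, abs(.data$effect_value),
                               colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$variable, scales = "free_y") +
    ggplot2::labs(x = "program week", y = "|effect size|") +
    ggplot2::theme_minimal()
}
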