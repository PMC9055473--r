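#' Weight-change classes
#'
#' Six classes partitioning the percent-change line, from a gain of more
#' than 2% through a loss of more than 15%.
#'
#' @export
weight_change_classes <- c(
  "gain_gt2", "stable", "loss_2_5", "loss_5_10", "loss_10_15", "loss_gt15"
)

#' Percent weight change
#'
#' @param initial_kg Initial weight (> 0).
#' @param final_kg Final weight.
#' @return Signed percent change, `100 * (final - initial) / initial`
#'   (negative = loss). Vectorized.
#' @export
percent_change <- function(initial_kg, final_kg) {
  if (any(initial_kg <= 0, na.rm = TRUE))
    abort("percent_change requires positive initial weight",
          class = "trajclust_domain_error")
  100 * (final_kg - initial_kg) / initial_kg
}

#' Classify percent weight change
#'
#' Partition: gain > +2%; stable (-2, +2\]; loss 2-5% = (-5, -2\]; loss
#' 5-10% = (-10, -5\]; loss 10-15% = (-15, -10\]; loss > 15% = (-Inf, -15\].
#' Boundaries belong to the larger-loss side (-2 exactly is a 2-5% loss,
#' +2 exactly is stable), a fixed convention resolving the overlapping
#' prose ranges.
#'
#' @param percent Signed percent change (vectorized).
#' @return Factor with levels [weight_change_classes].
#' @export
classify_weight_change <- function(percent) {
  # right-closed intervals put every boundary in the larger-loss class
  cls <- cut(percent,
             breaks = c(-Inf, -15, -10, -5, -2, 2, Inf),
             labels = c("loss_gt15", "loss_10_15", "loss_5_10", "loss_2_5",
                        "stable", "gain_gt2"),
             right = TRUE)
  factor(as.character(cls), levels = weight_change_classes)
}

#' Per-user app-use summary
#'
#' Weekly counts of meal logs, weight logs and sent/received messages over
#' the 16 program weeks, their program-level per-week rates (weekly totals
#' divided by 16, the full program denominator), and mean steps per logged
#' day.
#'
#' @param cohort Cohort tibble.
#' @param program_weeks Program length (default 16).
#' @return A tibble with one row per user: `meal_records_per_week`,
#'   `weight_records_per_week`, `messages_sent_per_week`,
#'   `messages_received_per_week`, `steps_per_day`, and a `weekly`
#'   list-column of per-week breakdown tibbles (week, meal_records,
#'   weight_records, messages_sent, messages_received, steps_per_day).
#' @export
summarize_usage <- function(cohort, program_weeks = 16L) {
  W <- program_weeks
  wk_counts <- function(days) {
    w <- days %/% 7L + 1L
    tabulate(w[w >= 1 & w <= W], nbins = W)
  }
  weekly <- purrr::pmap(
    list(cohort$meals, cohort$weights, cohort$messages, cohort$steps),
    function(meals, weights, messages, steps) {
      sent <- messages$day[messages$direction == "sent"]
      recv <- messages$day[messages$direction == "received"]
      sw <- steps$day %/% 7L + 1L
      keep <- sw >= 1 & sw <= W
      spd <- rep(NA_real_, W)
      if (any(keep)) {
        agg <- tapply(steps$step_count[keep], sw[keep], mean)
        spd[as.integer(names(agg))] <- as.numeric(agg)
      }
      tibble(
        week = seq_len(W),
        meal_records = wk_counts(meals$day),
        weight_records = wk_counts(weights$day),
        messages_sent = wk_counts(sent),
        messages_received = wk_counts(recv),
        steps_per_day = spd
      )
    })
  tibble(
    user_id = cohort$user_id,
    meal_records_per_week = purrr::map_dbl(weekly, ~ sum(.x$meal_records) / W),
    weight_records_per_week = purrr::map_dbl(weekly, ~ sum(.x$weight_records) / W),
    messages_sent_per_week = purrr::map_dbl(weekly, ~ sum(.x$messages_sent) / W),
    messages_received_per_week = purrr::map_dbl(weekly, ~ sum(.x$messages_received) / W),
    steps_per_day = purrr::map2_dbl(
      cohort$steps, weekly,
      ~ if (nrow(.x) == 0) NA_real_ else mean(.x$step_count)),
    weekly = weekly
  )
}

#' Weight outcomes for an analyzed cohort
#'
#' Joins the eligibility records' initial/final weights into percent change
#' and class for the included users.
#'
#' @param records Eligibility records from [apply_eligibility()].
#' @return Tibble (user_id, initial_weight_kg, final_weight_kg,
#'   percent_change, class) for included users.
#' @export
weight_outcomes <- function(records) {
  inc <- records[records$included, ]
  pct <- percent_change(inc$initial_weight_kg, inc$final_weight_kg)
  tibble(
    user_id = inc$user_id,
    initial_weight_kg = inc$initial_weight_kg,
    final_weight_kg = inc$final_weight_kg,
    percent_change = pct,
    class = classify_weight_change(pct)
  )
}

#' Class-by-cluster contingency table
#'
#' Counts users per (weight-change class, cluster) cell. Both inputs must
#' cover exactly the same users.
#'
#' @param assignments Tibble (user_id, cluster) or a named vector.
#' @param classes Tibble (user_id, class) or a named factor.
#' @return Integer matrix (classes x clusters) with `margins` attribute
#'   (list: row, col, total).
#' @export
contingency_table <- function(assignments, classes) {
  if (!is.data.frame(assignments))
    assignments <- tibble(user_id = names(assignments),
                          cluster = unname(assignments))
  if (!is.data.frame(classes))
    classes <- tibble(user_id = names(classes), class = unname(classes))
  if (!setequal(assignments$user_id, classes$user_id) ||
      anyDuplicated(assignments$user_id) || anyDuplicated(classes$user_id))
    abort("assignments and classes must cover the same user set",
          class = "trajclust_domain_error")
  m <- left_join(classes, assignments, by = "user_id")
  cls <- factor(m$class, levels = weight_change_classes)
  tab <- table(class = cls, cluster = m$cluster)
  out <- unclass(as.matrix(tab))
  attr(out, "margins") <- list(row = rowSums(out), col = colSums(out),
                               total = sum(out))
  out
}
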