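#' Balanced five-archetype recovery benchmark
#'
#' Generates a synthetic cohort with equal shares of the five trajectory
#' archetypes and low measurement noise, preprocesses every user's weight
#' series, and returns the trajectory matrix together with the ground-truth
#' labels. This is the package's standing benchmark for cluster recovery:
#' balanced shares keep all five classes populated at moderate n.
#'
#' @param n_users Cohort size (default 500, 100 per archetype in
#'   expectation).
#' @param weight_noise_sd Measurement noise SD in kg (default 0.1).
#' @param seed Generator seed (default 7).
#' @return A list: `X` (n x 16 matrix), `labels` (archetype per row),
#'   `cohort` (the generated lifelogs).
#' @export
trajectory_benchmark <- function(n_users = 500, weight_noise_sd = 0.1,
                                 seed = 7L) {
  cfg <- synth_config(
    n_users = n_users,
    archetype_weights = rlang::set_names(rep(0.2, 5), trajectory_archetypes),
    weight_noise_sd = weight_noise_sd,
    seed = seed
  )
  cohort <- generate_cohort(cfg)
  X <- preprocess_cohort(cohort)
  list(X = X, labels = cohort$archetype, cohort = cohort)
}

#' Run the full trajectory-phenotyping pipeline
#'
#' Orchestrates every stage end to end: simulate (or read) lifelogs, apply
#' the eligibility cascade, standardize the weight series, scan for the
#' number of clusters and fit the final DTW k-means model, class the
#' weight-change outcomes, and compare app-use characteristics across
#' clusters cross-sectionally and week by week. All artifacts are written
#' as plain text (CSV/JSON) under `out_dir`; runs are deterministic given
#' the seed.
#'
#' @param synth A [synth_config()], or `NULL` when `lifelog_path` is given.
#' @param lifelog_path JSONL lifelog file to read instead of simulating.
#' @param criteria Eligibility [cohort_criteria()].
#' @param grid_len,window Preprocessing parameters.
#' @param k Number of clusters; `NULL` to use the elbow suggestion.
#' @param k_range Candidate k values for the elbow scan.
#' @param seed Seed for clustering (and violation injection).
#' @param n_init k-means restarts.
#' @param out_dir Output directory, created if needed; `NULL` writes
#'   nothing.
#' @return A list with `cohort`, `eligibility` (records + flow), `X`,
#'   `scan`, `model`, `outcomes`, `usage`, `cross_sectional`, `weekly`, and
#'   `manifest`.
#' @export
run_pipeline <- function(synth = synth_config(), lifelog_path = NULL,
                         criteria = cohort_criteria(),
                         grid_len = 30L, window = 15L,
                         k = NULL, k_range = 2:10,
                         seed = 1L, n_init = 5L,
                         out_dir = NULL) {
  cohort <- if (!is.null(lifelog_path)) read_lifelogs(lifelog_path)
            else {
              raw <- generate_cohort(synth)
              inject_violations(raw, synth)$cohort
            }

  elig <- apply_eligibility(cohort, criteria)
  if (nrow(elig$included) < max(k_range))
    abort("analyzed cohort smaller than the largest candidate k",
          class = "trajclust_domain_error")

  X <- preprocess_cohort(elig$included, grid_len = grid_len, window = window)
  scan <- elbow_scan(X, k_range = k_range, seed = seed, n_init = n_init)
  k_final <- k %||% suggested_k(scan)
  model <- kmeans_dtw(X, k_final, seed = seed, n_init = n_init)

  outcomes <- weight_outcomes(elig$records)
  usage <- summarize_usage(elig$included, program_weeks = criteria$program_weeks)
  assignments <- augment(model)
  cross <- compare_clusters_cross_sectional(usage, outcomes, assignments)
  weekly <- weekly_effect_trajectory(usage, assignments)

  manifest <- list(
    seed = as.integer(seed), k = k_final,
    n_input = nrow(cohort), n_analyzed = nrow(elig$included),
    grid_len = grid_len, window = window,
    package_version = as.character(utils::packageVersion("trajclust"))
  )
  result <- list(cohort = cohort, eligibility = elig, X = X, scan = scan,
                 model = model, outcomes = outcomes, usage = usage,
                 cross_sectional = cross, weekly = weekly,
                 manifest = manifest)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  readr::write_csv(result$eligibility$flow, p("cohort_flow.csv"))
  X <- as_tibble(as.data.frame(result$X), rownames = "user_id")
  readr::write_csv(X, p("processed_series.csv"))
  readr::write_csv(augment(result$model), p("assignments.csv"))
  readr::write_csv(as_tibble(result$scan), p("elbow_scan.csv"))
  readr::write_csv(result$outcomes, p("outcomes.csv"))
  readr::write_csv(select(result$cross_sectional, -"per_cluster"),
                   p("cross_sectional.csv"))
  readr::write_csv(as_tibble(result$weekly), p("weekly_effects.csv"))

  model <- result$model
  jsonlite::write_json(
    list(k = model$k, centroids = model$centroids,
         assignments = as.list(model$cluster), sizes = model$sizes,
         inertia = model$inertia, inertia_root = model$inertia_root,
         seed = model$seed, converged = model$converged),
    p("model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
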