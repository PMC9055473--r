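#' Published weight-class by cluster counts
#'
#' Cross-tabulation of weight-change class by trajectory cluster as printed
#' for a large commercial 16-week mobile program cohort (N = 13,140; five
#' clusters of sizes 11,295 / 833 / 384 / 401 / 227). The published table
#' omits the "lost 5-10%" class row; [complete_class_table()] recovers it by
#' margin subtraction from the cluster totals. Shipped as a plain-text
#' fixture so the association strength can be recomputed offline.
#'
#' @return A list: `counts` (5 x 5 integer matrix of the printed class
#'   rows) and `cluster_totals` (length-5 integer vector).
#' @export
reference_class_counts <- function() {
  path <- system.file("extdata", "reference_class_counts.csv",
                      package = "trajclust", mustWork = TRUE)
  raw <- utils::read.csv(path, row.names = 1)
  counts <- as.matrix(raw[rownames(raw) != "cluster_total", ])
  totals <- as.integer(raw["cluster_total", ])
  storage.mode(counts) <- "integer"
  names(totals) <- colnames(counts)
  list(counts = counts, cluster_totals = totals)
}

#' Complete a class table with a margin-subtracted row
#'
#' Recovers the withheld "lost 5-10%" row as cluster totals minus the sum
#' of the printed rows, and orders the six classes canonically.
#'
#' @param ref A list as returned by [reference_class_counts()].
#' @return A 6 x 5 integer matrix over [weight_change_classes].
#' @export
complete_class_table <- function(ref = reference_class_counts()) {
  derived <- ref$cluster_totals - colSums(ref$counts)
  if (any(derived < 0))
    abort("printed rows exceed cluster totals; table inconsistent",
          class = "trajclust_domain_error")
  full <- rbind(ref$counts, loss_5_10 = derived)
  full[weight_change_classes, , drop = FALSE]
}

#' Association strength in the published class-by-cluster table
#'
#' Reconstructs the full six-class table and computes the chi-square test
#' with Cramer's V via [chi_square_with_v()].
#'
#' @return Tibble: statistic, df, p_value, effect_type, effect_value.
#' @export
reference_association <- function() {
  chi_square_with_v(complete_class_table())
}

#' Membership shares in the published clustering
#'
#' @return Tibble (cluster, n, share_pct) from the printed cluster sizes.
#' @export
reference_cluster_shares <- function() {
  tot <- reference_class_counts()$cluster_totals
  tibble(cluster = seq_along(tot), n = as.integer(tot),
         share_pct = unname(100 * tot / sum(tot)))
}
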