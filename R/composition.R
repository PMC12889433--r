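#' Per-cluster condition enrichment scores
#'
#' For every cluster, the naive enrichment score is the fraction of its cells
#' carrying the condition of interest; normalized scores divide by the mean
#' naive score across clusters, so that overall differences in cell numbers
#' between conditions cancel and the normalized scores average to exactly 1.
#'
#' @param cells Cell table: one row per cell with at least `cluster` and
#'   `condition` columns.
#' @param condition_of_interest Condition whose enrichment is scored
#'   (default `"AD"`).
#' @return A tibble of class `enrichment_result` with one row per cluster:
#'   `cluster`, `n_cells`, `n_condition`, `naive_score`, `normalized_score`.
#' @examples
#' cells <- tibble::tibble(
#'   cluster = rep(c("A", "B"), c(10, 20)),
#'   condition = c(rep("AD", 5), rep("healthy", 5),
#'                 rep("AD", 5), rep("healthy", 15)))
#' cluster_enrichment(cells)
#' @export
cluster_enrichment <- function(cells, condition_of_interest = "AD") {
  if (!all(c("cluster", "condition") %in% names(cells))) {
    abort("`cells` needs `cluster` and `condition` columns")
  }
  if (nrow(cells) == 0) abort("`cells` is empty")
  res <- cells |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_condition = sum(.data$condition == condition_of_interest),
      .groups = "drop"
    ) |>
    dplyr::mutate(naive_score = .data$n_condition / .data$n_cells)
  m <- mean(res$naive_score)
  if (m == 0) {
    abort(sprintf("no cells with condition '%s' in any cluster; normalization undefined",
                  condition_of_interest))
  }
  res <- dplyr::mutate(res, normalized_score = .data$naive_score / m)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Exponential BAM2:BAM1 enrichment score
#'
#' The per-patient score `exp((n_cd206 - n_mhcii) / n_total)`, where
#' `n_cd206` counts CD206-high (BAM2) cells, `n_mhcii` counts MHCII-high
#' (BAM1) cells, and `n_total` is the patient's total cell count. The score
#' is 1 when the two subsets are balanced, above 1 when BAM2 dominates, and
#' satisfies the reciprocity `score(a, b, N) * score(b, a, N) = 1`.
#'
#' @param n_cd206,n_mhcii,n_total Non-negative counts (vectorised);
#'   `n_total` must be positive and at least `max(n_cd206, n_mhcii)`.
#' @return Positive numeric vector.
#' @examples
#' bam_ratio_score(10, 5, 100)  # exp(0.05)
#' @export
bam_ratio_score <- function(n_cd206, n_mhcii, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive")
  if (any(n_cd206 < 0) || any(n_mhcii < 0)) abort("counts must be non-negative")
  if (any(n_total < pmax(n_cd206, n_mhcii))) {
    abort("`n_total` must be at least max(n_cd206, n_mhcii)")
  }
  exp((n_cd206 - n_mhcii) / n_total)
}

#' Filter patients by target-label cell fraction
#'
#' Retains only patients for whom at least `min_fraction` of cells carry one
#' of the target labels (boundary inclusive: a patient at exactly the
#' threshold is kept). Used to drop donors whose cell capture was too poorly
#' distributed across clusters to estimate macrophage frequencies.
#'
#' @param cells Cell table with `patient_id` and `cluster` columns.
#' @param target_labels Non-empty character vector of cluster labels that
#'   count toward the fraction (e.g. the macrophage clusters).
#' @param min_fraction Retention threshold in (0, 1); default 0.001 (0.1%).
#' @return The cell table restricted to retained patients, rows untouched.
#' @export
filter_patients <- function(cells, target_labels, min_fraction = 0.001) {
  if (length(target_labels) == 0) abort("`target_labels` must be non-empty")
  if (min_fraction <= 0 || min_fraction >= 1) {
    abort("`min_fraction` must lie in (0, 1)")
  }
  if (!all(c("patient_id", "cluster") %in% names(cells))) {
    abort("`cells` needs `patient_id` and `cluster` columns")
  }
  keep <- cells |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(frac = mean(.data$cluster %in% target_labels),
                     .groups = "drop") |>
    dplyr::filter(.data$frac >= min_fraction) |>
    dplyr::pull("patient_id")
  dplyr::filter(cells, .data$patient_id %in% keep)
}

#' Per-cluster signature-score ratio and assignment
#'
#' Scores each cell for two gene programs and assigns each cluster to the
#' program with the larger exponentiated score. A set's per-cell score is the
#' mean expression of its genes minus the mean expression of a size-matched,
#' seeded random background set; scores are exponentiated and the per-cell
#' ratio `exp(score_a - score_b)` is averaged within clusters.
#'
#' @param expression Genes x cells numeric matrix with gene ids as rownames.
#' @param clusters Cluster label per cell (length `ncol(expression)`).
#' @param set_a,set_b Non-empty gene sets; all genes must be present in the
#'   expression index (missing genes are reported by name).
#' @param seed Seed for the background-set draw.
#' @return Tibble with `cluster`, `n_cells`, `ratio` (mean per-cell
#'   `exp(score_a)/exp(score_b)`), and `assignment`
#'   (`"set_a"`, `"set_b"`, or `"tie"`).
#' @export
signature_ratio <- function(expression, clusters, set_a, set_b, seed = 1L) {
  if (length(set_a) == 0 || length(set_b) == 0) abort("gene sets must be non-empty")
  if (is.null(rownames(expression))) abort("`expression` needs gene rownames")
  if (length(clusters) != ncol(expression)) {
    abort("`clusters` must have one label per expression column")
  }
  missing <- setdiff(union(set_a, set_b), rownames(expression))
  if (length(missing) > 0) {
    abort(sprintf("genes absent from expression index: %s",
                  paste(missing, collapse = ", ")))
  }
  score_set <- function(genes) {
    genes <- unique(genes)
    fg <- colMeans(expression[genes, , drop = FALSE])
    pool <- setdiff(rownames(expression), genes)
    if (length(pool) == 0) return(fg)
    bg_genes <- withr::with_seed(seed,
      sample(pool, min(length(genes), length(pool))))
    fg - colMeans(expression[bg_genes, , drop = FALSE])
  }
  ratio_cell <- exp(score_set(set_a) - score_set(set_b))
  tibble(cluster = as.character(clusters), ratio_cell = ratio_cell) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     ratio = mean(.data$ratio_cell), .groups = "drop") |>
    dplyr::mutate(assignment = dplyr::case_when(
      abs(.data$ratio - 1) <= 1e-12 ~ "tie",
      .data$ratio > 1 ~ "set_a",
      TRUE ~ "set_b"
    ))
}

#' Hampel-filter flags for per-cluster expression deltas
#'
#' Flags clusters whose healthy-to-AD expression change lies beyond
#' `median +/- k * MAD` (MAD scaled by 1.4826). When the MAD is zero but
#' deltas differ, every delta unequal to the median is flagged by its sign;
#' when all deltas are equal nothing is flagged.
#'
#' @param per_cluster_delta Named numeric vector of deltas, or a data frame
#'   with `cluster` and `delta` columns. At least three clusters required.
#' @param k Threshold multiplier (default 3).
#' @return Tibble with `cluster`, `delta`, `flag` (`"none"`, `"enriched"`,
#'   `"depleted"`); the median, MAD and thresholds are attached as
#'   attributes `center`, `mad`, `lower`, `upper`.
#' @export
gwas_delta_flags <- function(per_cluster_delta, k = 3) {
  deltas <- as_named_numeric(per_cluster_delta)
  if (length(deltas) < 3) abort("need at least 3 clusters for a Hampel filter")
  m <- median(deltas)
  s <- mad(deltas)  # constant 1.4826
  if (s == 0) {
    flag <- dplyr::case_when(deltas > m ~ "enriched",
                             deltas < m ~ "depleted",
                             TRUE ~ "none")
    lower <- upper <- m
  } else {
    lower <- m - k * s
    upper <- m + k * s
    flag <- dplyr::case_when(deltas > upper ~ "enriched",
                             deltas < lower ~ "depleted",
                             TRUE ~ "none")
  }
  out <- tibble(cluster = names(deltas), delta = unname(deltas), flag = flag)
  attr(out, "center") <- m
  attr(out, "mad") <- s
  attr(out, "lower") <- lower
  attr(out, "upper") <- upper
  out
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$cluster, .data$normalized_score),
                               y = .data$normalized_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized enrichment score") +
    ggplot2::theme_minimal()
}
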