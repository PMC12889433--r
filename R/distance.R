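#' Healthy-to-AD transition distances per cell type
#'
#' Quantifies how strongly each cell type changes state in disease: within
#' each cell type, the Euclidean distance between every healthy x AD sample
#' pair is computed (samples are not paired across conditions). Distances use
#' the squared expansion `||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b` via one
#' cross-product, with negative rounding artifacts clamped at zero before
#' the square root. Distance distributions are compared across cell types by
#' two-sided Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment.
#'
#' @param features Features x samples numeric matrix (transcript counts or
#'   Compass penalties, possibly pseudobulked).
#' @param labels Condition per sample (`"healthy"` / `"AD"`).
#' @param strata Cell type per sample; `NULL` treats all samples as one
#'   stratum. Every stratum must contain both conditions.
#' @param conditions Length-2 character vector naming the two conditions
#'   (first = reference).
#' @return An object of class `transition_distance`: list with `distances`
#'   (tibble `cell_type`, `distance`), `summary` (per cell type: `n_pairs`,
#'   `mean`, `median`, `q25`, `q75`) and `comparisons` (pairwise cell-type
#'   tests: `type_a`, `type_b`, `p`, `p_adj`).
#' @examples
#' m <- matrix(rnorm(40), 4, 10)
#' td <- transition_distance(m, rep(c("healthy", "AD"), each = 5))
#' td$summary
#' @export
transition_distance <- function(features, labels,
                                strata = NULL,
                                conditions = c("healthy", "AD")) {
  if (!is.matrix(features)) abort("`features` must be a matrix")
  if (length(labels) != ncol(features)) {
    abort("`labels` must have one condition per sample")
  }
  if (is.null(strata)) strata <- rep("all", ncol(features))
  if (length(strata) != ncol(features)) {
    abort("`strata` must have one cell type per sample")
  }
  labels <- as.character(labels)

  dist_by_type <- purrr::map(split(seq_along(strata), strata), function(idx) {
    ia <- idx[labels[idx] == conditions[1]]
    ib <- idx[labels[idx] == conditions[2]]
    if (length(ia) == 0 || length(ib) == 0) {
      abort(sprintf("stratum '%s' lacks one of the conditions", strata[idx[1]]))
    }
    cross_distances(features[, ia, drop = FALSE], features[, ib, drop = FALSE])
  })

  distances <- purrr::imap_dfr(dist_by_type, function(d, ct) {
    tibble(cell_type = ct, distance = as.vector(d))
  })
  summary <- distances |>
    dplyr::group_by(cell_type = .data$cell_type) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean = mean(.data$distance),
      median = median(.data$distance),
      q25 = quantile(.data$distance, 0.25),
      q75 = quantile(.data$distance, 0.75),
      .groups = "drop"
    )
  types <- names(dist_by_type)
  comparisons <- if (length(types) >= 2) {
    pairs <- utils::combn(types, 2)
    res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      pv <- suppressWarnings(
        wilcox.test(dist_by_type[[a]], dist_by_type[[b]], exact = FALSE)$p.value)
      tibble(type_a = a, type_b = b, p = pv)
    })
    dplyr::mutate(res, p_adj = p.adjust(.data$p, method = "BH"))
  } else {
    tibble(type_a = character(), type_b = character(),
           p = numeric(), p_adj = numeric())
  }
  structure(list(distances = distances, summary = summary,
                 comparisons = comparisons),
            class = "transition_distance")
}

# All pairwise Euclidean distances between columns of A and columns of B via
# the Gram expansion; clamped at zero before the square root.
cross_distances <- function(A, B) {
  d2 <- outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' @export
print.transition_distance <- function(x, ...) {
  cat("<transition_distance>\n")
  print(x$summary)
  if (nrow(x$comparisons) > 0) {
    cat("pairwise comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Boxplot of transition-distance distributions
#'
#' @param object A [transition_distance()] result.
#' @param ... Unused.
#' @return A ggplot object with one box per cell type.
#' @export
autoplot.transition_distance <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$cell_type, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "healthy-to-AD pairwise distance") +
    ggplot2::theme_minimal()
}
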