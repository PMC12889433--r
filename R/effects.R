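#' Per-reaction effect sizes between two sample groups
#'
#' Cohen's d per reaction: the difference of group means divided by the
#' pooled (n-1 weighted) standard deviation, with a two-sided Wilcoxon
#' rank-sum p-value per reaction and Benjamini-Hochberg adjustment across all
#' reactions in the comparison. A reaction with zero pooled SD but unequal
#' means gets a signed-infinity sentinel (excluded from downstream
#' summaries).
#'
#' @param flux A `flux_matrix` (from [penalty_to_flux()]) or a numeric
#'   reactions x samples matrix.
#' @param group_a,group_b Column selectors for the two groups: character
#'   sample ids, integer indices or logical masks. Both groups need at least
#'   two samples.
#' @return Tibble of class `reaction_effects`: `reaction_id`, `cohen_d`,
#'   `p`, `p_adj`, `n_a`, `n_b`.
#' @examples
#' m <- matrix(c(0, 2, 1, 3), 1, 4,
#'             dimnames = list("r1", paste0("s", 1:4)))
#' reaction_effects(m, c("s1", "s2"), c("s3", "s4"))$cohen_d  # -1/sqrt(2)
#' @export
reaction_effects <- function(flux, group_a, group_b) {
  values <- if (inherits(flux, "flux_matrix")) flux$values else flux
  if (!is.matrix(values)) abort("`flux` must be a matrix or flux_matrix")
  sel <- function(g) {
    if (is.character(g)) match(g, colnames(values)) else which(
      if (is.logical(g)) g else seq_len(ncol(values)) %in% g)
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (anyNA(ia) || anyNA(ib)) abort("unknown sample ids in group selection")
  if (length(ia) < 2 || length(ib) < 2) abort("each group needs >= 2 samples")
  if (length(intersect(ia, ib)) > 0) abort("groups must be disjoint")

  A <- values[, ia, drop = FALSE]; B <- values[, ib, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  na <- length(ia); nb <- length(ib)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- ifelse(sp > 0, (ma - mb) / sp,
              ifelse(ma == mb, 0, sign(ma - mb) * Inf))
  if (any(is.infinite(d))) {
    warn(sprintf("%d reaction(s) with zero pooled SD and unequal means; d set to signed infinity",
                 sum(is.infinite(d))))
  }
  p <- vapply(seq_len(nrow(values)), function(i) {
    suppressWarnings(wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  out <- tibble(
    reaction_id = rownames(values) %||% sprintf("R%04d", seq_len(nrow(values))),
    cohen_d = unname(d),
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    n_a = na,
    n_b = nb
  )
  class(out) <- c("reaction_effects", class(out))
  out
}

#' Subsystem (pathway) enrichment summaries from reaction effects
#'
#' Summarises per-reaction Cohen's d values by metabolic subsystem: only
#' subsystems with at least `min_reactions` member reactions qualify; a
#' qualifying subsystem is enriched when the absolute median d exceeds
#' `d_threshold`, with direction given by the median's sign. The count of
#' member reactions significant at `p_adj < 0.1` is carried through.
#' Reactions with non-finite d are excluded before summarising.
#'
#' @param effects A [reaction_effects()] tibble.
#' @param subsystem_map Reaction-to-subsystem map: a data frame with
#'   `reaction_id` and `subsystem` columns or a named character vector.
#'   Every reaction in `effects` must be mapped.
#' @param min_reactions Minimum member reactions (default 3).
#' @param d_threshold Absolute median-d threshold for the enriched flag
#'   (default 0.1).
#' @return Tibble of class `subsystem_summary`: `subsystem`, `n_reactions`,
#'   `median_d`, `direction` (-1/0/1), `enriched`, `n_significant`. The
#'   number of subsystems excluded for size is attached as attribute
#'   `n_excluded`.
#' @export
subsystem_summarize <- function(effects, subsystem_map, min_reactions = 3L,
                                d_threshold = 0.1) {
  if (is.data.frame(subsystem_map)) {
    if (!all(c("reaction_id", "subsystem") %in% names(subsystem_map))) {
      abort("`subsystem_map` needs `reaction_id` and `subsystem` columns")
    }
    map <- setNames(as.character(subsystem_map$subsystem),
                    subsystem_map$reaction_id)
  } else {
    map <- subsystem_map
  }
  unmapped <- setdiff(effects$reaction_id, names(map))
  if (length(unmapped) > 0) {
    abort(sprintf("reactions without subsystem: %s",
                  paste(unmapped, collapse = ", ")))
  }
  dat <- dplyr::mutate(as_tibble(effects),
                       subsystem = unname(map[.data$reaction_id]))
  dat <- dplyr::filter(dat, is.finite(.data$cohen_d))
  all_ss <- dat |>
    dplyr::group_by(.data$subsystem) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      median_d = median(.data$cohen_d),
      n_significant = sum(.data$p_adj < 0.1, na.rm = TRUE),
      .groups = "drop"
    )
  out <- all_ss |>
    dplyr::filter(.data$n_reactions >= min_reactions) |>
    dplyr::mutate(direction = sign(.data$median_d),
                  enriched = abs(.data$median_d) > d_threshold) |>
    dplyr::select("subsystem", "n_reactions", "median_d", "direction",
                  "enriched", "n_significant")
  attr(out, "n_excluded") <- nrow(all_ss) - nrow(out)
  class(out) <- c("subsystem_summary", class(out))
  out
}

#' Dot plot of subsystem enrichment
#'
#' @param object A [subsystem_summarize()] result.
#' @param ... Unused.
#' @return A ggplot object: subsystems ordered by median Cohen's d, enriched
#'   pathways highlighted, the `|d|` threshold drawn as dashed lines.
#' @export
autoplot.subsystem_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$median_d,
                               y = stats::reorder(.data$subsystem, .data$median_d),
                               colour = .data$enriched)) +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_reactions)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "median Cohen's d", y = NULL) +
    ggplot2::theme_minimal()
}
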