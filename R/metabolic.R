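#' Metacell pseudobulking
#'
#' Randomly partitions cells into disjoint metacells of exactly `group_size`
#' within each stratum (typically cell type x condition) and aggregates the
#' feature matrix per metacell, to improve per-sample estimate robustness.
#' Leftover cells that do not fill a complete group are dropped; a stratum
#' smaller than `group_size` yields zero metacells with a warning.
#'
#' @param mat Features x cells numeric matrix (column names are cell ids).
#' @param strata Data frame with one row per cell giving the stratification
#'   columns (e.g. `cell_type`, `condition`), or a vector of stratum labels.
#' @param group_size Cells per metacell (default 10).
#' @param seed Seed for the random partition.
#' @param agg Aggregation: `"sum"` (default, counts-like) or `"mean"`.
#' @return A list with `values` (features x metacells matrix), `metacells`
#'   (tibble: `sample_id`, stratification columns, `n_cells`) and
#'   `membership` (tibble mapping each cell to its metacell, `NA` if
#'   dropped).
#' @examples
#' m <- matrix(1, 2, 25, dimnames = list(c("f1", "f2"), paste0("c", 1:25)))
#' pb <- pseudobulk(m, rep("a", 25), group_size = 10, seed = 1)
#' ncol(pb$values)  # 2 metacells; 5 cells dropped
#' @export
pseudobulk <- function(mat, strata, group_size = 10L, seed = 1L,
                       agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  if (group_size < 1) abort("`group_size` must be >= 1")
  if (!is.data.frame(strata)) strata <- tibble(stratum = as.character(strata))
  if (nrow(strata) != ncol(mat)) {
    abort("`strata` must have one row per matrix column")
  }
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("cell%05d", seq_len(ncol(mat)))

  key <- do.call(paste, c(as.list(strata), sep = "\r"))
  groups <- split(seq_len(ncol(mat)), key)

  withr::with_seed(as.integer(seed), {
    blocks <- purrr::imap(groups, function(idx, k) {
      n_full <- length(idx) %/% group_size
      if (n_full == 0) {
        warn(sprintf("stratum '%s' has %d < %d cells; zero metacells",
                     gsub("\r", "/", k), length(idx), group_size))
        return(NULL)
      }
      shuffled <- sample(idx)
      kept <- shuffled[seq_len(n_full * group_size)]
      assign <- rep(seq_len(n_full), each = group_size)
      list(stratum_key = k, cells = kept, assign = assign, n_groups = n_full)
    })
  })
  blocks <- purrr::compact(blocks)
  if (length(blocks) == 0) {
    return(list(values = mat[, 0, drop = FALSE],
                metacells = tibble(sample_id = character()),
                membership = tibble(cell = colnames(mat),
                                    metacell = NA_character_)))
  }

  mc_id <- 0L
  values_list <- list(); meta_list <- list()
  membership <- setNames(rep(NA_character_, ncol(mat)), colnames(mat))
  for (b in blocks) {
    strat_row <- strata[match(b$stratum_key, key), , drop = FALSE]
    for (g in seq_len(b$n_groups)) {
      mc_id <- mc_id + 1L
      id <- sprintf("mc%05d", mc_id)
      cols <- b$cells[b$assign == g]
      sub <- mat[, cols, drop = FALSE]
      values_list[[id]] <- if (agg == "sum") rowSums(sub) else rowMeans(sub)
      meta_list[[id]] <- dplyr::bind_cols(tibble(sample_id = id),
                                          as_tibble(strat_row),
                                          tibble(n_cells = length(cols)))
      membership[cols] <- id
    }
  }
  values <- do.call(cbind, values_list)
  rownames(values) <- rownames(mat)
  list(
    values = values,
    metacells = dplyr::bind_rows(meta_list),
    membership = tibble(cell = names(membership),
                        metacell = unname(membership))
  )
}

#' Convert Compass penalties to normalised flux estimates
#'
#' Flux is the negative logarithm of one plus the penalty; the raw flux
#' matrix is then min-fixed (the global minimum subtracted so the minimum is
#' zero) and each reaction row z-scored across samples. Constant rows cannot
#' be z-scored; they are set to zero and flagged. Because z-scoring is
#' shift-invariant per reaction, the min-fix provably does not change the
#' final output; both steps are retained to mirror the standard
#' post-processing and can be toggled.
#'
#' @param pm A `penalty_matrix` or a non-negative numeric matrix
#'   (reactions x samples).
#' @param min_fix,zscore Logical toggles for the two normalisation steps.
#' @return An object of class `flux_matrix`: list with `values`, logical
#'   `constant` flags per reaction, `provenance` (character vector of applied
#'   steps), and the `reactions`/`samples` annotations when available.
#' @examples
#' penalty_to_flux(matrix(c(0, exp(1) - 1), 1, 2))$provenance
#' @export
penalty_to_flux <- function(pm, min_fix = TRUE, zscore = TRUE) {
  if (inherits(pm, "penalty_matrix")) {
    values <- pm$values; reactions <- pm$reactions; samples <- pm$samples
  } else {
    values <- pm; reactions <- NULL; samples <- NULL
  }
  if (!is.matrix(values) || !is.numeric(values)) abort("penalties must be a numeric matrix")
  if (any(values < 0)) abort("penalties must be non-negative")

  flux <- -log1p(values)
  provenance <- "raw"
  if (min_fix) {
    flux <- flux - min(flux)
    provenance <- c(provenance, "min_fixed")
  }
  constant <- logical(nrow(flux))
  if (zscore) {
    mu <- rowMeans(flux)
    sdv <- apply(flux, 1, sd)
    constant <- sdv == 0 | !is.finite(sdv)
    flux <- (flux - mu) / ifelse(constant, 1, sdv)
    flux[constant, ] <- 0
    provenance <- c(provenance, "z_scored")
  }
  structure(list(values = flux, constant = constant, provenance = provenance,
                 reactions = reactions, samples = samples),
            class = "flux_matrix")
}

#' @export
print.flux_matrix <- function(x, ...) {
  cat("<flux_matrix> ", nrow(x$values), " reactions x ", ncol(x$values),
      " samples [", paste(x$provenance, collapse = " -> "), "], ",
      sum(x$constant), " constant\n", sep = "")
  invisible(x)
}
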