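#' Synthetic Compass-style reaction-penalty matrix
#'
#' Draws non-negative penalties `exp(Normal(location + shift, scale))` for
#' every reaction x cell pair. A shift from `config$shift_map` is applied
#' only to cells of the named cell type in AD condition for reactions of the
#' named subsystem, emulating condition-specific metabolic dysregulation
#' concentrated in designated pathways.
#'
#' @param config A [synthetic_config()].
#' @param cell_labels Tibble with one row per sample/cell: `sample_id`,
#'   `cell_type`, `condition` (and optionally more annotation columns).
#' @return A list with `penalties` (a `penalty_matrix`) and `ground_truth`
#'   (tibble of the true per-(subsystem, cell type) log-penalty shifts).
#' @examples
#' cfg <- synthetic_config(seed = 1, n_reactions = 20L,
#'                         subsystem_sizes = c(10L, 10L))
#' labs <- tibble::tibble(sample_id = paste0("s", 1:6),
#'                        cell_type = rep(c("BAM2", "microglia"), 3),
#'                        condition = rep(c("healthy", "AD"), each = 3))
#' pen <- gen_penalty_matrix(cfg, labs)
#' dim(pen$penalties$values)
#' @export
gen_penalty_matrix <- function(config, cell_labels) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(c("sample_id", "cell_type", "condition") %in% names(cell_labels))) {
    abort("`cell_labels` needs columns sample_id, cell_type, condition")
  }
  check_condition(cell_labels$condition)
  if (config$penalty_scale < 0) abort("`penalty_scale` must be non-negative")

  reactions <- tibble(
    reaction_id = sprintf("R%04d", seq_len(config$n_reactions)),
    subsystem = rep(sprintf("SS%02d", seq_along(config$subsystem_sizes)),
                    times = config$subsystem_sizes)
  )
  n_r <- nrow(reactions)
  n_s <- nrow(cell_labels)

  # log-penalty means: location everywhere, plus shift on matched
  # (subsystem, cell type) pairs for AD samples only
  mu <- matrix(config$penalty_location, n_r, n_s)
  shift_map <- config$shift_map
  if (!is.null(shift_map) && nrow(shift_map) > 0) {
    for (i in seq_len(nrow(shift_map))) {
      rows <- reactions$subsystem == shift_map$subsystem[i]
      cols <- cell_labels$cell_type == shift_map$cell_type[i] &
        cell_labels$condition == "AD"
      mu[rows, cols] <- mu[rows, cols] + shift_map$shift[i]
    }
  }

  values <- withr::with_seed(derive_seed(config$seed, "penalty"), {
    matrix(exp(rnorm(n_r * n_s, mean = mu, sd = config$penalty_scale)),
           n_r, n_s,
           dimnames = list(reactions$reaction_id, cell_labels$sample_id))
  })

  pm <- new_penalty_matrix(values, reactions, cell_labels)
  gt <- if (is.null(shift_map)) {
    tibble(subsystem = character(), cell_type = character(), shift = numeric())
  } else {
    as_tibble(shift_map)
  }
  list(penalties = pm, ground_truth = gt)
}

#' Penalty matrix container
#'
#' Reactions x samples non-negative penalties plus the reaction-to-subsystem
#' map and sample annotations.
#'
#' @param values Numeric matrix (reactions x samples), non-negative, with
#'   dimnames.
#' @param reactions Tibble with `reaction_id`, `subsystem` (one subsystem per
#'   reaction).
#' @param samples Tibble with `sample_id` plus annotation columns.
#' @return An object of class `penalty_matrix`.
#' @export
new_penalty_matrix <- function(values, reactions, samples) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) abort("penalties must be non-negative")
  if (nrow(values) != nrow(reactions)) abort("reaction annotation mismatch")
  if (ncol(values) != nrow(samples)) abort("sample annotation mismatch")
  if (anyDuplicated(reactions$reaction_id)) abort("duplicate reaction ids")
  if (anyNA(reactions$subsystem)) abort("every reaction needs a subsystem")
  structure(list(values = values, reactions = as_tibble(reactions),
                 samples = as_tibble(samples)),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat("<penalty_matrix> ", nrow(x$values), " reactions x ", ncol(x$values),
      " samples, ", length(unique(x$reactions$subsystem)), " subsystems\n",
      sep = "")
  invisible(x)
}
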