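# Readers and writers for the package's tabular and image containers. Tables
# are plain comma-separated text with a header row; penalty matrices travel
# as a values table plus a two-column reaction-to-subsystem file; image
# stacks as multi-page TIFF (channel-major pages) with a JSON sidecar
# holding channel names, shape, pixel size and intensity scale.

#' Write / read a cell or clinical table
#'
#' @param x A data frame.
#' @param path Output CSV path.
#' @return `write_table_csv()` returns `path` invisibly; `read_table_csv()`
#'   returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a penalty matrix
#'
#' Values go to `<stem>_values.csv` (reaction_id column + one column per
#' sample), the subsystem map to `<stem>_subsystems.csv`, sample annotations
#' to `<stem>_samples.csv`.
#'
#' @param pm A `penalty_matrix`.
#' @param stem Path stem (no extension).
#' @return `write_penalty_matrix()` returns the stem invisibly;
#'   `read_penalty_matrix()` returns a `penalty_matrix`.
#' @export
write_penalty_matrix <- function(pm, stem) {
  stopifnot(inherits(pm, "penalty_matrix"))
  vals <- as_tibble(pm$values, rownames = "reaction_id")
  readr::write_csv(vals, paste0(stem, "_values.csv"))
  readr::write_csv(pm$reactions, paste0(stem, "_subsystems.csv"))
  readr::write_csv(pm$samples, paste0(stem, "_samples.csv"))
  invisible(stem)
}

#' @rdname write_penalty_matrix
#' @export
read_penalty_matrix <- function(stem) {
  vals <- readr::read_csv(paste0(stem, "_values.csv"), show_col_types = FALSE)
  m <- as.matrix(vals[, -1])
  rownames(m) <- vals$reaction_id
  new_penalty_matrix(
    m,
    readr::read_csv(paste0(stem, "_subsystems.csv"), show_col_types = FALSE),
    readr::read_csv(paste0(stem, "_samples.csv"), show_col_types = FALSE)
  )
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...).
#' Intensities are stored as 32-bit float after division by a recorded scale
#' so the round trip is lossless up to float precision; the sidecar
#' `<path>.json` records channels, shape, pixel size and the scale.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$intensities)
  # TIFF samples live in [0, 1]: store min/max-normalised values and record
  # the affine transform in the sidecar
  lo <- min(stack$intensities)
  hi <- max(stack$intensities)
  scale <- if (hi > lo) hi - lo else 1
  pages <- list()
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <- (stack$intensities[ch, z, , ] - lo) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(channels = stack$channels, shape = d,
         pixel_size_um = stack$pixel_size_um, offset = lo, scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape)
  arr <- array(0, dim = d)
  k <- 0L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      k <- k + 1L
      arr[ch, z, , ] <- pages[[k]] * meta$scale + meta$offset
    }
  }
  new_image_stack(arr, channels = meta$channels,
                  pixel_size_um = meta$pixel_size_um)
}

#' Write generator ground truth as JSON
#'
#' Mask matrices are summarised (areas, coverage, particle counts survive;
#' pixel lattices do not belong in the record).
#'
#' @param ground_truth A generator ground-truth object (tibble or list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  if (is.list(gt) && !is.data.frame(gt)) {
    gt <- gt[!vapply(gt, is.matrix, logical(1))]
  }
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
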