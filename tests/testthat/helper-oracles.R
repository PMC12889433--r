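# Independent oracles and small config builders used across tests.

# Brute-force per-pair Euclidean distances between columns of A and B.
loop_distances <- function(A, B) {
  out <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      out[i, j] <- sqrt(sum((A[, i] - B[, j])^2))
    }
  }
  out
}

# Flood-fill connected-component count (8- or 4-connectivity), independent of
# the package's labeling code.
flood_fill_count <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  seen <- matrix(FALSE, ny, nx)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(offs))) {
          ii <- p[1] + offs[k, 1]; jj <- p[2] + offs[k, 2]
          if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  count
}

# Small cohort / image configs for fast tests; dots override the defaults.
small_cohort_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_patients_per_condition = 10L,
         cells_per_patient_range = c(200L, 400L)),
    list(...))
  do.call(synthetic_config, args)
}

small_image_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, image_shape = c(4L, 128L, 128L),
         n_vessels = 2L, n_plaques = 12L),
    list(...))
  do.call(synthetic_config, args)
}
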