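#' Synthetic two-channel fluorescence stack with known coverage
#'
#' Builds a z-stack with a "vessel" channel (curvilinear random-walk tubes)
#' and a "plaque" channel (dense-core super-Gaussian blobs), over a smooth
#' low-frequency background, degraded by Poisson shot noise plus Gaussian
#' read noise.
#' Plaques are placed by rejection sampling against the noiseless vessel mask
#' until the realised plaque-on-vessel coverage is within one percentage
#' point of `plaque_on_vessel_target`; an unreachable target is an error.
#' The returned ground truth records the exact noiseless vessel-mask area,
#' coverage and plaque particle count.
#'
#' @param config A [synthetic_config()].
#' @return A list with `stack` (an `image_stack`) and `ground_truth` (list
#'   with `vessel_mask`, `plaque_mask`, `vessel_area_px`, `coverage_pct`,
#'   `n_particles`, `amplitude`).
#' @examples
#' cfg <- synthetic_config(seed = 1, image_shape = c(4L, 96L, 96L),
#'                         n_vessels = 2L, n_plaques = 4L,
#'                         plaque_on_vessel_target = 0.2)
#' img <- gen_image_stack(cfg)
#' img$ground_truth$coverage_pct
#' @export
gen_image_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nz <- config$image_shape[1]; ny <- config$image_shape[2]; nx <- config$image_shape[3]
  A <- image_amplitude(config$snr)
  target <- config$plaque_on_vessel_target

  withr::with_seed(derive_seed(config$seed, "image"), {
    ## --- noiseless 2-D vessel signal -------------------------------------
    vessel2d <- matrix(0, ny, nx)
    vessel_z <- integer(0)
    if (config$n_vessels > 0) {
      path <- matrix(0, ny, nx)
      for (v in seq_len(config$n_vessels)) {
        path <- path | draw_vessel_path(ny, nx)
      }
      w <- config$vessel_width_px
      if (w %% 2 == 0) w <- w + 1L
      tube <- EBImage::dilate(matrix(as.numeric(path), ny, nx),
                              EBImage::makeBrush(w, "disc"))
      vessel2d <- A * as.matrix(EBImage::gblur(tube, sigma = 1))
    }
    vessel_mask <- vessel2d >= A / 2
    v_area <- sum(vessel_mask)

    ## --- plaque placement -------------------------------------------------
    plaque2d <- matrix(0, ny, nx)
    n_placed <- 0L

    if (target > 0 && v_area == 0) {
      abort("coverage target infeasible: no vessel pixels to cover")
    }

    if (target >= 0.995 && v_area > 0) {
      # full coverage: plaque blankets the vessel (and a 2 px margin)
      blanket <- EBImage::dilate(matrix(as.numeric(vessel_mask), ny, nx),
                                 EBImage::makeBrush(5, "disc"))
      plaque2d <- A * as.matrix(blanket)
      n_placed <- 1L
    } else if (config$n_plaques > 0) {
      # keep off-vessel plaques clear of the vessel (and vice versa)
      margin <- config$plaque_radius_px + 3L
      near_vessel <- if (v_area > 0) {
        as.matrix(EBImage::dilate(matrix(as.numeric(vessel_mask), ny, nx),
                                  EBImage::makeBrush(2L * margin + 1L, "disc"))) > 0
      } else {
        matrix(FALSE, ny, nx)
      }
      occupied <- matrix(FALSE, ny, nx)  # keeps off-vessel blobs disjoint
      vessel_idx <- which(vessel_mask)
      coverage <- function() {
        if (v_area == 0) 0 else sum((plaque2d >= A / 2) & vessel_mask) / v_area
      }
      budget <- 40L * max(config$n_plaques, 1L)
      while (n_placed < config$n_plaques && budget > 0) {
        budget <- budget - 1L
        deficit <- target - coverage()
        if (deficit > 0.005 && length(vessel_idx) > 0) {
          # on-vessel placement; shrink the last blobs to land inside +-1 pp
          r_need <- sqrt(deficit * v_area / pi)
          r_use <- max(2, min(config$plaque_radius_px, round(r_need)))
          ctr <- arrayInd(sample(vessel_idx, 1L), c(ny, nx))
          cand <- stamp_blob(plaque2d, ctr[1], ctr[2], A, r_use)
          new_cov <- sum((cand >= A / 2) & vessel_mask) / v_area
          if (new_cov <= target + 0.009) {
            plaque2d <- cand
            n_placed <- n_placed + 1L
          }
        } else {
          free <- which(!near_vessel & !occupied)
          if (length(free) == 0) break  # off-vessel space exhausted; stop placing
          ctr <- arrayInd(sample(free, 1L), c(ny, nx))
          plaque2d <- stamp_blob(plaque2d, ctr[1], ctr[2], A,
                                 config$plaque_radius_px)
          occupied <- occupied |
            (outer((seq_len(ny) - ctr[1])^2, (seq_len(nx) - ctr[2])^2, "+") <=
               (2 * config$plaque_radius_px + 2)^2)
          n_placed <- n_placed + 1L
        }
      }
      if (v_area > 0 && abs(coverage() - target) > 0.01) {
        abort(sprintf(
          "coverage target infeasible: realised %.1f%% vs target %.1f%% with %d plaques",
          100 * coverage(), 100 * target, config$n_plaques))
      }
    }
    plaque_mask <- plaque2d >= A / 2
    cov_pct <- if (v_area == 0) 0 else 100 * sum(plaque_mask & vessel_mask) / v_area
    n_particles <- if (any(plaque_mask)) {
      max(label_mask(plaque_mask, connectivity = 8L))
    } else 0L

    ## --- assemble 3-D, add background and noise ---------------------------
    zc_v <- sample.int(nz, 1L); zc_p <- sample.int(nz, 1L)
    zprof <- function(zc) exp(-((seq_len(nz) - zc)^2) / (2 * 1.5^2))
    bg_v <- smooth_background(ny, nx, 0.1 * A)
    bg_p <- smooth_background(ny, nx, 0.1 * A)

    arr <- array(0, dim = c(2L, nz, ny, nx))
    pv <- zprof(zc_v); pp <- zprof(zc_p)
    for (z in seq_len(nz)) {
      arr[1, z, , ] <- bg_v + vessel2d * pv[z]
      arr[2, z, , ] <- bg_p + plaque2d * pp[z]
    }
    sigma_read <- 2
    noisy <- array(rpois(length(arr), arr) + rnorm(length(arr), 0, sigma_read),
                   dim = dim(arr))

    stack <- new_image_stack(noisy, channels = c("vessel", "plaque"),
                             pixel_size_um = config$pixel_size_um)
    list(
      stack = stack,
      ground_truth = list(
        vessel_mask = vessel_mask,
        plaque_mask = plaque_mask,
        vessel_area_px = v_area,
        coverage_pct = cov_pct,
        n_particles = n_particles,
        amplitude = A
      )
    )
  })
}

# One random-walk centerline entering from a random border point.
draw_vessel_path <- function(ny, nx) {
  for (attempt in 1:20) {
    side <- sample(4L, 1L)
    pos <- switch(side,
      c(1, runif(1, 1, nx)),        # top
      c(ny, runif(1, 1, nx)),       # bottom
      c(runif(1, 1, ny), 1),        # left
      c(runif(1, 1, ny), nx))       # right
    ang <- switch(side,
      runif(1, pi / 4, 3 * pi / 4),          # heading down
      runif(1, -3 * pi / 4, -pi / 4),        # heading up
      runif(1, -pi / 4, pi / 4),             # heading right
      runif(1, 3 * pi / 4, 5 * pi / 4))      # heading left
    m <- matrix(FALSE, ny, nx)
    steps <- 0L
    while (pos[1] >= 1 && pos[1] <= ny && pos[2] >= 1 && pos[2] <= nx &&
           steps < 2L * (ny + nx)) {
      m[round(pos[1]), round(pos[2])] <- TRUE
      ang <- ang + rnorm(1, 0, 0.12)
      pos <- pos + c(sin(ang), cos(ang))
      steps <- steps + 1L
    }
    if (steps >= min(ny, nx) / 2) return(m)
  }
  m
}

# Add a dense-core blob of peak `A` and half-maximum radius `radius` at
# (cy, cx): a super-Gaussian (order 2) profile with the steep edge of a
# fibrillar plaque core. Fields combine by maximum so overlapping blobs keep
# a bounded peak.
stamp_blob <- function(field, cy, cx, A, radius) {
  ny <- nrow(field); nx <- ncol(field)
  r <- ceiling(1.8 * radius)
  ys <- max(1, cy - r):min(ny, cy + r)
  xs <- max(1, cx - r):min(nx, cx + r)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  field[ys, xs] <- pmax(field[ys, xs],
                        A * exp(-log(2) * (d2 / radius^2)^2))
  field
}

# Smooth low-frequency background: a few broad Gaussians scaled to `peak`.
smooth_background <- function(ny, nx, peak) {
  bg <- matrix(0, ny, nx)
  for (i in 1:3) {
    cy <- runif(1, 1, ny); cx <- runif(1, 1, nx)
    s <- runif(1, 0.3, 0.6) * max(ny, nx)
    d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
    bg <- bg + exp(-d2 / (2 * s^2))
  }
  if (max(bg) > 0) bg <- bg / max(bg) * peak
  bg
}

#' Image stack container
#'
#' Channel-first intensity lattice (`channel x z x y x x`) with channel names
#' and physical pixel size.
#'
#' @param intensities 4-D non-negative numeric array.
#' @param channels Character vector naming the first dimension.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @return An object of class `image_stack`.
#' @export
new_image_stack <- function(intensities, channels, pixel_size_um = 1) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 4L)
  if (length(channels) != dim(intensities)[1]) {
    abort("`channels` must name the first array dimension")
  }
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0")
  structure(list(intensities = intensities, channels = channels,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat("<image_stack> ", d[1], " channel(s) [", paste(x$channels, collapse = ", "),
      "], z=", d[2], ", ", d[3], "x", d[4], " px @ ", x$pixel_size_um,
      " um/px\n", sep = "")
  invisible(x)
}
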