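# Morphological quantification: % area, particle counting and the
# plaque-on-vessel (CAA%) macro. Planes are plain numeric matrices (y, x);
# masks are logical matrices carrying a provenance attribute.

ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

#' Maximum-intensity z-projection
#'
#' @param stack An `image_stack`.
#' @param channel Channel name or index.
#' @return Numeric matrix (y, x): the per-pixel maximum over z.
#' @export
max_project <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- if (is.character(channel)) match(channel, stack$channels) else channel
  if (is.na(ch) || ch < 1 || ch > length(stack$channels)) {
    abort(sprintf("channel '%s' not found (have: %s)", channel,
                  paste(stack$channels, collapse = ", ")))
  }
  a <- stack$intensities[ch, , , , drop = TRUE]
  if (length(dim(a)) == 2) return(a)           # single z slice
  plane <- a[1, , ]
  for (z in seq_len(dim(a)[1])[-1]) plane <- pmax(plane, a[z, , ])
  plane
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the plane with a
#' ball-shaped (non-flat) structuring element of the given radius and
#' subtracts it, clipping at zero. The background is estimated on a
#' 3x3-mean-smoothed copy so the ball does not ride on noise minima, and the
#' ball's height profile is scaled to the plane's dynamic range (so the
#' operation commutes with any positive rescaling of the intensities). A
#' radius at least as large as the image behaves as global-minimum
#' subtraction (with a warning).
#'
#' @param plane Numeric matrix.
#' @param radius Ball radius in pixels (>= 1; default 50).
#' @param smooth Smooth the background-estimation copy first (default TRUE).
#' @return Background-subtracted plane, non-negative.
#' @export
subtract_background <- function(plane, radius = 50L, smooth = TRUE) {
  if (radius < 1) abort("`radius` must be >= 1")
  if (radius >= min(dim(plane))) {
    warn("ball radius >= image size; subtracting the global minimum")
    return(plane - min(plane))
  }
  est <- plane
  if (smooth) {
    est <- ebi_mat(EBImage::filter2(plane, matrix(1 / 9, 3, 3),
                                    boundary = "replicate"))
  }
  rng <- diff(range(est))
  if (rng == 0) return(plane - plane[1])
  # ball height spans the dynamic range over the ball radius
  bg <- cpp_ball_opening(est, as.integer(radius), rng / radius)
  pmax(plane - bg, 0)
}

#' Disk median filter
#'
#' Per-pixel median over a disk of the given radius; edges are handled by
#' reflection.
#'
#' @param plane Numeric matrix.
#' @param radius Disk radius in pixels (>= 1).
#' @return Filtered plane.
#' @export
median_filter <- function(plane, radius = 2L) {
  if (radius < 1) abort("`radius` must be >= 1")
  cpp_disk_median(plane, as.integer(radius))
}

#' Threshold a plane into a binary region mask
#'
#' Pixels at or above the threshold become foreground. The default mode is a
#' fixed absolute threshold, so that sections compared against each other are
#' thresholded identically; Otsu's method is available as an explicit
#' opt-in.
#'
#' @param plane Numeric matrix.
#' @param threshold Absolute intensity threshold (required for
#'   `method = "fixed"`).
#' @param method `"fixed"` (default) or `"otsu"`.
#' @return Logical matrix of class `region_mask`; provenance (threshold and
#'   operations applied) is kept in the `provenance` attribute. An
#'   all-foreground or all-background result triggers a warning.
#' @export
make_mask <- function(plane, threshold = NULL, method = c("fixed", "otsu")) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(plane)
    if (diff(rng) == 0) {
      threshold <- rng[1]
    } else {
      norm <- (plane - rng[1]) / diff(rng)
      threshold <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) *
        diff(rng) + rng[1]
    }
  }
  if (is.null(threshold) || !is.finite(threshold)) {
    abort("`threshold` must be a finite value (or use method = 'otsu')")
  }
  mask <- plane >= threshold
  if (all(mask) || !any(mask)) {
    warn(sprintf("mask is all-%s at threshold %g",
                 if (all(mask)) "foreground" else "background", threshold))
  }
  new_region_mask(mask, list(threshold = threshold, method = method))
}

new_region_mask <- function(mask, provenance = list()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(mask, provenance = provenance, class = c("region_mask", "matrix", "array"))
}

#' Binary erosion / dilation
#'
#' Applies binary erosion or dilation with a 3x3 square structuring element
#' the stated number of times (0 iterations is the identity).
#'
#' @param mask A `region_mask` or logical matrix.
#' @param op `"erode"` or `"dilate"`.
#' @param iterations Number of passes (>= 0).
#' @return A `region_mask` with updated provenance.
#' @export
morph <- function(mask, op = c("erode", "dilate"), iterations = 1L) {
  op <- match.arg(op)
  if (iterations < 0) abort("`iterations` must be >= 0")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  brush <- EBImage::makeBrush(3, "box")
  fun <- if (op == "erode") EBImage::erode else EBImage::dilate
  for (i in seq_len(iterations)) m <- ebi_mat(fun(m, brush))
  prov <- attr(mask, "provenance") %||% list()
  prov$ops <- c(prov$ops, rep(op, iterations))
  new_region_mask(m > 0.5, prov)
}

# 8-/4-connected component labeling of a logical matrix.
label_mask <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) abort("connectivity must be 4 or 8")
  cpp_label_components(matrix(as.logical(mask), nrow(mask), ncol(mask)),
                       as.integer(connectivity))
}

#' Connected-component particle analysis
#'
#' Labels connected foreground components (8-connected by default, so
#' diagonally touching pixels join one particle) and reports per-particle
#' area and centroid; components below `min_area` are discarded.
#'
#' @param mask A `region_mask` or logical matrix.
#' @param min_area Minimum particle area in px^2 (default 0: keep all).
#' @param connectivity 8 (default) or 4.
#' @param pixel_size_um Pixel size for the um^2 areas (default 1).
#' @return Tibble of class `particle_set`: `particle`, `area_px`,
#'   `area_um2`, `centroid_y`, `centroid_x`; the label matrix is attached as
#'   attribute `labels`.
#' @export
analyze_particles <- function(mask, min_area = 0, connectivity = 8L,
                              pixel_size_um = 1) {
  labels <- label_mask(mask, connectivity)
  ids <- seq_len(max(labels))
  if (length(ids) == 0) {
    out <- tibble(particle = integer(), area_px = integer(),
                  area_um2 = numeric(), centroid_y = numeric(),
                  centroid_x = numeric())
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    area <- tabulate(lab, nbins = max(labels))
    cy <- tapply(idx[, 1], lab, mean)
    cx <- tapply(idx[, 2], lab, mean)
    out <- tibble(particle = ids, area_px = area,
                  area_um2 = area * pixel_size_um^2,
                  centroid_y = as.numeric(cy), centroid_x = as.numeric(cx))
    out <- dplyr::filter(out, .data$area_px >= min_area)
  }
  attr(out, "labels") <- labels
  attr(out, "pixel_size_um") <- pixel_size_um
  class(out) <- c("particle_set", class(out))
  out
}

#' Area fraction of particles within a region of interest
#'
#' `percent = 100 * (sum of retained particle areas inside the ROI) /
#' (ROI area)`.
#'
#' @param particles A [analyze_particles()] result.
#' @param roi ROI as a logical matrix / `region_mask` of the same shape.
#' @return One-row tibble of class `area_fraction`: `object_area_px`,
#'   `roi_area_px`, `percent`.
#' @export
area_fraction <- function(particles, roi) {
  labels <- attr(particles, "labels")
  if (is.null(labels)) abort("`particles` must come from analyze_particles()")
  if (!all(dim(roi) == dim(labels))) abort("ROI shape must match the mask")
  roi_area <- sum(roi)
  if (roi_area == 0) abort("ROI is empty")
  inside <- labels[as.logical(roi)]
  obj <- sum(inside %in% particles$particle)
  out <- tibble(object_area_px = obj, roi_area_px = roi_area,
                percent = 100 * obj / roi_area)
  class(out) <- c("area_fraction", class(out))
  out
}

#' Percent of vessel area covered by plaque (CAA%)
#'
#' Reimplements the vessel-coverage macro. The vessel channel is
#' max-projected, background-subtracted (rolling ball), median-filtered,
#' thresholded to a mask, eroded then dilated (an opening that removes
#' speckle while restoring vessel calibre); the mask area is the total vessel
#' area. The plaque channel is max-projected and preprocessed the same way,
#' restricted to the vessel mask, and thresholded; CAA% is 100 x the
#' plaque-positive area inside the vessel mask divided by the vessel area.
#'
#' @param stack An `image_stack` with co-registered vessel and plaque
#'   channels.
#' @param vessel_channel,plaque_channel Channel names or indices (defaults
#'   `"vessel"`, `"plaque"`).
#' @param vessel_threshold,plaque_threshold Absolute intensity thresholds.
#' @param bg_radius Rolling-ball radius (default 50).
#' @param median_radius Median-filter radius for the vessel channel (default
#'   3, as in the macro); the plaque channel uses radius 2 as in the
#'   channel-level % area procedure.
#' @param erode_iter,dilate_iter Erosion/dilation passes on the vessel mask
#'   (defaults 2 and 2).
#' @return One-row tibble of class `area_fraction`: `vessel_area_px`,
#'   `vessel_area_um2`, `caa_area_px`, `percent`.
#' @export
caa_fraction <- function(stack, vessel_channel = "vessel",
                         plaque_channel = "plaque",
                         vessel_threshold, plaque_threshold,
                         bg_radius = 50L, median_radius = 3L,
                         erode_iter = 2L, dilate_iter = 2L) {
  vp <- max_project(stack, vessel_channel) |>
    subtract_background(bg_radius) |>
    median_filter(median_radius)
  vmask <- make_mask(vp, vessel_threshold) |>
    morph("erode", erode_iter) |>
    morph("dilate", dilate_iter)
  v_area <- sum(vmask)
  if (v_area == 0) abort("no vessels detected: vessel mask is empty")

  pp <- max_project(stack, plaque_channel) |>
    subtract_background(bg_radius) |>
    median_filter(2L)
  caa_area <- sum(pp >= plaque_threshold & vmask)

  out <- tibble(
    vessel_area_px = v_area,
    vessel_area_um2 = v_area * stack$pixel_size_um^2,
    caa_area_px = caa_area,
    percent = 100 * caa_area / v_area
  )
  class(out) <- c("area_fraction", class(out))
  out
}

#' Automated particle counting and density
#'
#' Background subtraction, median filtering, thresholding and particle
#' analysis on one plane; returns the particle count normalised by the
#' analysed area.
#'
#' @param plane Numeric matrix (e.g. a max projection).
#' @param threshold Absolute intensity threshold.
#' @param bg_radius Rolling-ball radius (default 50).
#' @param median_radius Median-filter radius (default 2).
#' @param min_area Minimum particle area in px^2 (default 0).
#' @param pixel_size_um Pixel size (um/px).
#' @param roi Optional ROI mask restricting the analysed area (default: full
#'   frame).
#' @return One-row tibble: `n_particles`, `area_um2`, `density_per_um2`.
#' @export
count_cells <- function(plane, threshold, bg_radius = 50L, median_radius = 2L,
                        min_area = 0, pixel_size_um = 1, roi = NULL) {
  proc <- plane |>
    subtract_background(bg_radius) |>
    median_filter(median_radius)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(plane), ncol(plane))
  proc[!roi] <- -Inf
  mask <- suppressWarnings(make_mask(proc, threshold))
  particles <- analyze_particles(mask, min_area = min_area,
                                 pixel_size_um = pixel_size_um)
  area_um2 <- sum(roi) * pixel_size_um^2
  tibble(n_particles = nrow(particles), area_um2 = area_um2,
         density_per_um2 = nrow(particles) / area_um2)
}
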