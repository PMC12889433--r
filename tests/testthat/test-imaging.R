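test_that("max projection reduces z by per-pixel maxima", {
  arr <- array(0, dim = c(1, 2, 3, 3))
  arr[1, 1, , ] <- matrix(1:9, 3, 3)
  arr[1, 2, , ] <- matrix(9:1, 3, 3)
  st <- new_image_stack(arr, "ch")
  expect_equal(max_project(st, "ch"), pmax(matrix(1:9, 3, 3), matrix(9:1, 3, 3)))

  single <- new_image_stack(array(runif(16), c(1, 1, 4, 4)), "ch")
  expect_equal(max_project(single, 1), single$intensities[1, 1, , ])
  zero <- new_image_stack(array(0, c(1, 3, 4, 4)), "ch")
  expect_true(all(max_project(zero, "ch") == 0))
  expect_error(max_project(st, "nope"), "not found")
})

test_that("background subtraction removes flat and smooth components", {
  expect_true(all(subtract_background(matrix(5, 64, 64), 10) == 0))

  # small bright blob on a flat offset survives within 5% of its peak
  plane <- matrix(10, 128, 128)
  d2 <- outer((1:128 - 64)^2, (1:128 - 64)^2, "+")
  blob <- 100 * exp(-log(2) * (d2 / 8^2)^2)
  out <- subtract_background(plane + blob, 50, smooth = FALSE)
  expect_lt(abs(max(out) - 100) / 100, 0.05)

  # smooth gradient alone leaves < 5% of its range
  grad <- outer(seq(0, 20, length.out = 96), seq(0, 10, length.out = 96), "+")
  res <- subtract_background(grad, 30, smooth = FALSE)
  expect_lt(max(res), 0.05 * diff(range(grad)))

  expect_warning(out2 <- subtract_background(matrix(1:16 / 4, 4, 4), 10),
                 "global minimum")
  expect_equal(min(out2), 0)
})

test_that("median filter handles constants, impulses and checkerboards", {
  expect_equal(median_filter(matrix(7, 10, 10), 2), matrix(7, 10, 10))

  imp <- matrix(0, 11, 11); imp[6, 6] <- 100
  expect_true(all(median_filter(imp, 2) == 0))

  cb <- outer(1:8, 1:8, function(i, j) as.numeric((i + j) %% 2 == 0))
  mf <- median_filter(cb, 1)
  # radius-1 disk = plus shape (5 px): the four neighbours share the
  # opposite parity, so each interior pixel flips
  interior <- mf[3:6, 3:6]
  expect_equal(interior, 1 - cb[3:6, 3:6])
})

test_that("make_mask thresholds inclusively and flags degenerate results", {
  plane <- matrix(c(10, 10, 200, 200), 2, 2)
  m <- make_mask(plane, 100)
  expect_identical(as.logical(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_warning(make_mask(plane, 500), "all-background")
  expect_warning(make_mask(plane, 0), "all-foreground")

  # bimodal plane: Otsu lands between the modes
  set.seed(9)
  bi <- matrix(c(rnorm(500, 10, 1), rnorm(500, 200, 1)), 100, 10)
  mo <- make_mask(bi, method = "otsu")
  expect_identical(as.logical(mo), as.logical(bi > 100))
})

test_that("binary morphology follows the 3x3 square element semantics", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  mask <- bamscape:::new_region_mask(sq)
  expect_identical(as.logical(morph(mask, "erode", 0)), as.logical(sq))

  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_false(any(morph(bamscape:::new_region_mask(line), "erode", 1)))

  opened <- morph(morph(mask, "erode", 2), "dilate", 2)
  expect_identical(as.logical(opened), as.logical(sq))
  # opening is idempotent
  opened2 <- morph(morph(opened, "erode", 2), "dilate", 2)
  expect_identical(as.logical(opened2), as.logical(opened))
})

test_that("particle analysis is 8-connected and counts match the oracle", {
  diag2 <- matrix(FALSE, 6, 6)
  diag2[2:3, 2:3] <- TRUE; diag2[4:5, 4:5] <- TRUE  # touch at one corner
  expect_equal(nrow(analyze_particles(diag2)), 1L)
  expect_equal(nrow(analyze_particles(diag2, connectivity = 4L)), 2L)

  empty <- matrix(FALSE, 5, 5)
  expect_equal(nrow(analyze_particles(empty)), 0L)

  sq <- matrix(FALSE, 100, 100); sq[11:20, 31:40] <- TRUE
  ps <- analyze_particles(sq, pixel_size_um = 0.5)
  expect_equal(ps$area_px, 100L)
  expect_equal(ps$area_um2, 25)
  expect_equal(ps$centroid_y, 15.5)

  set.seed(10)
  for (i in 1:10) {
    m <- matrix(runif(40 * 40) < 0.3, 40, 40)
    expect_equal(max(attr(analyze_particles(m), "labels")),
                 flood_fill_count(m, 8))
  }
})

test_that("area fractions and min_area filtering behave as stated", {
  sq <- matrix(FALSE, 100, 100); sq[1:10, 1:10] <- TRUE
  roi <- matrix(TRUE, 100, 100)
  af <- area_fraction(analyze_particles(sq), roi)
  expect_equal(af$percent, 1)
  expect_equal(area_fraction(analyze_particles(matrix(FALSE, 10, 10)),
                             matrix(TRUE, 10, 10))$percent, 0)
  expect_equal(area_fraction(analyze_particles(roi), roi)$percent, 100)
  expect_error(area_fraction(analyze_particles(sq), matrix(FALSE, 100, 100)),
               "empty")
  # particles below min_area do not count toward the fraction
  two <- matrix(FALSE, 30, 30); two[1:2, 1:2] <- TRUE; two[10:19, 10:19] <- TRUE
  af2 <- area_fraction(analyze_particles(two, min_area = 50), matrix(TRUE, 30, 30))
  expect_equal(af2$object_area_px, 100L)
})

test_that("caa_fraction trivial cases: no plaque, identical channels", {
  gi <- gen_image_stack(small_image_config(41, n_plaques = 0L,
                                           plaque_on_vessel_target = 0))
  A <- gi$ground_truth$amplitude
  caa0 <- caa_fraction(gi$stack, vessel_threshold = A / 2, plaque_threshold = A / 2)
  expect_lt(caa0$percent, 1)

  dup <- gi$stack
  dup$intensities[2, , , ] <- dup$intensities[1, , , ]
  caa1 <- caa_fraction(dup, vessel_threshold = A / 2, plaque_threshold = A / 2)
  expect_gt(caa1$percent, 99)

  dark <- gi$stack
  dark$intensities[1, , , ] <- 0
  suppressWarnings(
    expect_error(caa_fraction(dark, vessel_threshold = A / 2,
                              plaque_threshold = A / 2),
                 "no vessels"))
})

test_that("caa_fraction recovers a 20% generator coverage within 3 points", {
  gi <- gen_image_stack(small_image_config(42))
  gt <- gi$ground_truth
  caa <- caa_fraction(gi$stack, vessel_threshold = gt$amplitude / 2,
                      plaque_threshold = gt$amplitude / 2)
  expect_lt(abs(caa$percent - gt$coverage_pct), 3)
})

test_that("CAA% is monotone in in-mask plaque and blind to out-of-mask plaque", {
  gi <- gen_image_stack(small_image_config(43))
  gt <- gi$ground_truth
  A <- gt$amplitude
  base <- caa_fraction(gi$stack, vessel_threshold = A / 2, plaque_threshold = A / 2)

  # paint extra plaque strictly inside the vessel mask
  more <- gi$stack
  vm_idx <- which(gt$vessel_mask & !gt$plaque_mask)[1:50]
  for (z in seq_len(dim(more$intensities)[2])) {
    pl <- more$intensities[2, z, , ]
    pl[vm_idx] <- A * 2
    more$intensities[2, z, , ] <- pl
  }
  caa_more <- caa_fraction(more, vessel_threshold = A / 2, plaque_threshold = A / 2)
  expect_gte(caa_more$percent, base$percent)

  # plaque far outside the (dilated) vessel mask leaves CAA% unchanged
  outside <- gi$stack
  far <- which(!EBImage::dilate(gt$vessel_mask + 0, EBImage::makeBrush(21, "disc")) &
                 !gt$plaque_mask)[1:50]
  for (z in seq_len(dim(outside$intensities)[2])) {
    pl <- outside$intensities[2, z, , ]
    pl[far] <- A * 2
    outside$intensities[2, z, , ] <- pl
  }
  caa_out <- caa_fraction(outside, vessel_threshold = A / 2, plaque_threshold = A / 2)
  expect_equal(caa_out$percent, base$percent, tolerance = 0.02)
})

test_that("count_cells recovers disjoint blob counts and density scaling", {
  cfg <- small_image_config(44, n_vessels = 0L, n_plaques = 25L,
                            plaque_on_vessel_target = 0)
  gi <- gen_image_stack(cfg)
  gt <- gi$ground_truth
  plane <- max_project(gi$stack, "plaque")
  res <- count_cells(plane, threshold = gt$amplitude / 2, min_area = 4)
  expect_equal(res$n_particles, gt$n_particles)

  empty <- count_cells(matrix(0, 64, 64), threshold = 10)
  expect_equal(empty$n_particles, 0L)
  expect_equal(empty$density_per_um2, 0)

  # doubling the analysed area with the same blobs halves the density
  half_roi <- matrix(FALSE, nrow(plane), ncol(plane))
  half_roi[, seq_len(ncol(plane) / 2)] <- TRUE
  full <- count_cells(plane, threshold = gt$amplitude / 2, min_area = 4)
  sub <- count_cells(plane, threshold = gt$amplitude / 2, min_area = 4,
                     roi = half_roi)
  expect_equal(full$area_um2, 2 * sub$area_um2)
})

test_that("intensity operations commute with a positive rescaling", {
  gi <- gen_image_stack(small_image_config(45))
  A <- gi$ground_truth$amplitude
  caa <- caa_fraction(gi$stack, vessel_threshold = A / 2, plaque_threshold = A / 2)
  scaled <- gi$stack
  scaled$intensities <- scaled$intensities * 3.5
  caa_s <- caa_fraction(scaled, vessel_threshold = 3.5 * A / 2,
                        plaque_threshold = 3.5 * A / 2)
  expect_equal(caa_s$percent, caa$percent, tolerance = 1e-12)
})
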