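#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic cohort: patient numbers, baseline
#' cell-type composition, the AD-dependent BAM2 depletion, the Braak-linked
#' multiplicative decline, the log-normal reaction-penalty model with
#' condition/cell-type shifts, and the geometry and noise of the generated
#' fluorescence stacks. Identical configuration plus seed yields bit-identical
#' datasets.
#'
#' @param seed Integer seed; every generator derives its own sub-stream from
#'   it deterministically.
#' @param n_patients_per_condition Patients per arm (healthy / AD).
#' @param cells_per_patient_range Inclusive integer interval from which each
#'   patient's cell count is drawn uniformly.
#' @param base_proportions Named fractions for `microglia`, `BAM1`, `BAM2`,
#'   `DC`; must sum to 1 (tolerance 1e-9). The BAM2 default of 5% reflects
#'   BAMs making up roughly 4-6% of the brain immune landscape.
#' @param bam2_ad_depletion_fold Positive fold by which the BAM2 proportion is
#'   divided in AD patients before renormalisation (1 = no effect).
#' @param braak_fold_per_step Positive multiplicative BAM2 reduction per +1
#'   Braak stage (log-linear coupling; 2 = halving per stage, the default).
#' @param patient_sd_log SD of log-normal donor-level variability applied to
#'   each patient's BAM2 proportion (0 = none).
#' @param n_reactions Number of reactions; must equal `sum(subsystem_sizes)`.
#' @param subsystem_sizes Integer vector of reactions per subsystem.
#' @param penalty_location,penalty_scale Location and scale of the log-normal
#'   penalty model (`penalty = exp(Normal(location + shift, scale))`).
#' @param shift_map Data frame with columns `subsystem`, `cell_type`, `shift`:
#'   signed log-penalty shifts applied only to AD cells of the given cell type
#'   in the given subsystem. `NULL` means no shifts.
#' @param image_shape Integer `(z, y, x)` dimensions of generated stacks.
#' @param n_vessels,vessel_width_px Number and width (px) of random-walk
#'   vessel tubes in the vessel channel.
#' @param n_plaques,plaque_radius_px Number and half-maximum radius (px) of
#'   Gaussian plaque blobs in the plaque channel.
#' @param plaque_on_vessel_target Target fraction (0-1) of the noiseless
#'   vessel-mask area covered by plaque; realised coverage is within one
#'   percentage point of this target or generation errors.
#' @param snr Peak-signal-to-noise ratio; sets the photon budget (peak
#'   amplitude `A` solves `A / sqrt(A + sigma_read^2) = snr` with read noise
#'   `sigma_read = 2`).
#' @param pixel_size_um Physical pixel size in micrometres.
#'
#' @return An object of class `synthetic_config` (a validated named list).
#' @examples
#' cfg <- synthetic_config(seed = 1, n_patients_per_condition = 10)
#' cfg$base_proportions
#' @export
synthetic_config <- function(seed = 1L,
                             n_patients_per_condition = 40L,
                             cells_per_patient_range = c(1000L, 3000L),
                             base_proportions = c(microglia = 0.85, BAM1 = 0.06,
                                                  BAM2 = 0.05, DC = 0.04),
                             bam2_ad_depletion_fold = 2,
                             braak_fold_per_step = 2,
                             patient_sd_log = 0.4,
                             n_reactions = 90L,
                             subsystem_sizes = rep(10L, 9L),
                             penalty_location = 0,
                             penalty_scale = 1,
                             shift_map = NULL,
                             image_shape = c(z = 8L, y = 256L, x = 256L),
                             n_vessels = 4L,
                             vessel_width_px = 15L,
                             n_plaques = 40L,
                             plaque_radius_px = 8L,
                             plaque_on_vessel_target = 0.2,
                             snr = 5,
                             pixel_size_um = 1) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients_per_condition = as.integer(n_patients_per_condition),
    cells_per_patient_range = as.integer(cells_per_patient_range),
    base_proportions = base_proportions,
    bam2_ad_depletion_fold = bam2_ad_depletion_fold,
    braak_fold_per_step = braak_fold_per_step,
    patient_sd_log = patient_sd_log,
    n_reactions = as.integer(n_reactions),
    subsystem_sizes = as.integer(subsystem_sizes),
    penalty_location = penalty_location,
    penalty_scale = penalty_scale,
    shift_map = shift_map,
    image_shape = as.integer(image_shape),
    n_vessels = as.integer(n_vessels),
    vessel_width_px = as.integer(vessel_width_px),
    n_plaques = as.integer(n_plaques),
    plaque_radius_px = as.integer(plaque_radius_px),
    plaque_on_vessel_target = plaque_on_vessel_target,
    snr = snr,
    pixel_size_um = pixel_size_um
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (abs(sum(cfg$base_proportions) - 1) > 1e-9) {
    abort("`base_proportions` must sum to 1 (tolerance 1e-9)")
  }
  if (is.null(names(cfg$base_proportions)) || any(names(cfg$base_proportions) == "")) {
    abort("`base_proportions` must be a named vector of cell types")
  }
  if (any(cfg$base_proportions < 0)) abort("`base_proportions` must be non-negative")
  if (cfg$bam2_ad_depletion_fold <= 0) abort("`bam2_ad_depletion_fold` must be > 0")
  if (cfg$braak_fold_per_step <= 0) abort("`braak_fold_per_step` must be > 0")
  if (cfg$patient_sd_log < 0) abort("`patient_sd_log` must be >= 0")
  if (cfg$n_patients_per_condition < 1) abort("need at least one patient per condition")
  if (length(cfg$cells_per_patient_range) != 2L ||
      cfg$cells_per_patient_range[1] > cfg$cells_per_patient_range[2] ||
      cfg$cells_per_patient_range[1] < 1L) {
    abort("`cells_per_patient_range` must be an increasing positive integer interval")
  }
  if (any(cfg$subsystem_sizes < 1L)) abort("`subsystem_sizes` must all be >= 1")
  if (sum(cfg$subsystem_sizes) != cfg$n_reactions) {
    abort("`n_reactions` must equal sum(subsystem_sizes)")
  }
  if (cfg$penalty_scale < 0) abort("`penalty_scale` must be non-negative")
  if (!is.null(cfg$shift_map)) {
    if (!is.data.frame(cfg$shift_map) ||
        !all(c("subsystem", "cell_type", "shift") %in% names(cfg$shift_map))) {
      abort("`shift_map` must be a data frame with columns subsystem, cell_type, shift")
    }
  }
  if (length(cfg$image_shape) != 3L || any(cfg$image_shape < 1L)) {
    abort("`image_shape` must be positive (z, y, x)")
  }
  if (cfg$plaque_on_vessel_target < 0 || cfg$plaque_on_vessel_target > 1) {
    abort("`plaque_on_vessel_target` must lie in [0, 1]")
  }
  if (cfg$snr <= 0) abort("`snr` must be > 0")
  if (cfg$pixel_size_um <= 0) abort("`pixel_size_um` must be > 0")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  seed:", x$seed, " patients/arm:", x$n_patients_per_condition, "\n")
  cat("  cells/patient:", paste(x$cells_per_patient_range, collapse = "-"), "\n")
  cat("  base proportions:",
      paste(sprintf("%s=%.3f", names(x$base_proportions), x$base_proportions),
            collapse = " "), "\n")
  cat("  BAM2 AD depletion fold:", x$bam2_ad_depletion_fold,
      " Braak fold/step:", x$braak_fold_per_step, "\n")
  cat("  reactions:", x$n_reactions, "in", length(x$subsystem_sizes),
      "subsystems\n")
  cat("  image (z,y,x):", paste(x$image_shape, collapse = "x"),
      " target coverage:", x$plaque_on_vessel_target, " snr:", x$snr, "\n")
  invisible(x)
}

# Peak signal amplitude implied by the snr under the Poisson + read-noise
# model: A / sqrt(A + sigma_read^2) = snr.
image_amplitude <- function(snr, sigma_read = 2) {
  (snr^2 + snr * sqrt(snr^2 + 4 * sigma_read^2)) / 2
}
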