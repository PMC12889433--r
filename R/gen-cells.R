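#' Patient frame for a synthetic cohort
#'
#' Deterministically assigns patient identifiers and a balanced
#' healthy/AD split.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with `patient_id`, `condition`.
#' @export
gen_patients <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients_per_condition
  tibble(
    patient_id = sprintf("P%03d", seq_len(2L * n)),
    condition = rep(c("healthy", "AD"), each = n)
  )
}

#' Synthetic clinical covariates
#'
#' Draws the covariates used by [clinical_model()]: sex (Bernoulli 0.5),
#' Braak stage 0-6 with more mass at high stages in AD, post-mortem interval
#' (gamma, mean ~8 h), CERAD rating 1-4 (AD-skewed), years of education
#' (normal, mean 16), and APOE E2/E4 allele counts (binomial; the E4 allele
#' is more frequent in the AD arm). The Braak stage drawn here multiplies
#' each patient's BAM2 proportion by `braak_fold_per_step^-braak` when the
#' returned table is passed to [gen_cell_table()], i.e. the coupling acts
#' before cell sampling.
#'
#' @param config A [synthetic_config()].
#' @param patients Tibble with `patient_id` and `condition`, e.g. from
#'   [gen_patients()].
#' @return A tibble with one row per patient: `patient_id`, `condition`,
#'   `sex` (0/1), `braak`, `pmi`, `cerad`, `education`, `apoe_e2`, `apoe_e4`.
#' @export
gen_clinical <- function(config, patients) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(patients) == 0) abort("`patients` is empty")
  check_condition(patients$condition)
  withr::with_seed(derive_seed(config$seed, "clinical"), {
    n <- nrow(patients)
    ad <- patients$condition == "AD"
    braak_w_healthy <- c(3, 3, 2, 2, 1, 1, 1)
    braak_w_ad <- rev(braak_w_healthy)
    braak <- integer(n)
    braak[!ad] <- sample(0:6, sum(!ad), replace = TRUE, prob = braak_w_healthy)
    braak[ad] <- sample(0:6, sum(ad), replace = TRUE, prob = braak_w_ad)
    cerad <- integer(n)
    cerad[!ad] <- sample(1:4, sum(!ad), replace = TRUE, prob = c(.5, .3, .15, .05))
    cerad[ad] <- sample(1:4, sum(ad), replace = TRUE, prob = c(.05, .15, .3, .5))
    tibble(
      patient_id = patients$patient_id,
      condition = patients$condition,
      sex = rbinom(n, 1L, 0.5),
      braak = braak,
      pmi = rgamma(n, shape = 4, rate = 0.5),
      cerad = cerad,
      education = pmin(pmax(round(rnorm(n, 16, 3)), 6), 25),
      apoe_e2 = rbinom(n, 2L, 0.07),
      apoe_e4 = rbinom(n, 2L, ifelse(ad, 0.35, 0.15))
    )
  })
}

#' Synthetic per-cell table with recorded ground truth
#'
#' Samples cell-type labels per patient from condition-adjusted multinomial
#' proportions. In AD patients the BAM2 proportion is divided by
#' `bam2_ad_depletion_fold`; when a clinical table is supplied the BAM2
#' proportion is additionally multiplied by `braak_fold_per_step^-braak`;
#' donor-level log-normal noise (`patient_sd_log`) is applied on top.
#' Proportions are renormalised after adjustment.
#'
#' @param config A [synthetic_config()].
#' @param clinical Optional clinical table from [gen_clinical()]; supplies the
#'   patient frame and activates the Braak coupling. When `NULL`, patients
#'   come from [gen_patients()] and only the condition effect applies.
#' @return A list with `cells` (tibble: `cell_id`, `patient_id`, `condition`,
#'   `cluster`) and `ground_truth` (tibble of per-patient true sampling
#'   proportions and realised fractions per cell type).
#' @examples
#' cfg <- synthetic_config(seed = 1, n_patients_per_condition = 4,
#'                         cells_per_patient_range = c(100L, 200L))
#' dat <- gen_cell_table(cfg)
#' dplyr::count(dat$cells, condition, cluster)
#' @export
gen_cell_table <- function(config, clinical = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  patients <- if (is.null(clinical)) {
    gen_patients(config)
  } else {
    dplyr::distinct(clinical, .data$patient_id, .data$condition)
  }
  check_condition(patients$condition)
  base <- config$base_proportions
  if (!"BAM2" %in% names(base)) abort("`base_proportions` must contain 'BAM2'")
  types <- names(base)

  withr::with_seed(derive_seed(config$seed, "cells"), {
    per_patient <- purrr::pmap(patients, function(patient_id, condition) {
      mult <- 1
      if (condition == "AD") mult <- mult / config$bam2_ad_depletion_fold
      if (!is.null(clinical)) {
        braak <- clinical$braak[match(patient_id, clinical$patient_id)]
        mult <- mult / config$braak_fold_per_step^braak
      }
      if (config$patient_sd_log > 0) {
        mult <- mult * exp(rnorm(1, 0, config$patient_sd_log))
      }
      p <- base
      p["BAM2"] <- p["BAM2"] * mult
      if (sum(p) <= 0) abort("cell-type proportions renormalise to zero")
      p <- p / sum(p)
      lo <- config$cells_per_patient_range[1]
      hi <- config$cells_per_patient_range[2]
      n <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      counts <- drop(rmultinom(1L, n, p))
      list(patient_id = patient_id, condition = condition,
           true_proportion = p, n_cells = n, counts = counts)
    })
    cells <- purrr::map_dfr(per_patient, function(pp) {
      tibble(
        cell_id = sprintf("%s_c%05d", pp$patient_id, seq_len(pp$n_cells)),
        patient_id = pp$patient_id,
        condition = pp$condition,
        cluster = rep(types, pp$counts)
      )
    })
    ground_truth <- purrr::map_dfr(per_patient, function(pp) {
      tibble(
        patient_id = pp$patient_id,
        condition = pp$condition,
        cell_type = types,
        true_proportion = unname(pp$true_proportion),
        n_cells = pp$n_cells,
        realized_fraction = unname(pp$counts) / pp$n_cells
      )
    })
  })
  list(cells = cells, ground_truth = ground_truth)
}
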