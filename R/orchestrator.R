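#' Demo run configuration
#'
#' A small, fully synthetic end-to-end scenario: an AD-dependent BAM2
#' depletion with Braak coupling, one metabolically shifted subsystem in
#' BAM2-AD cells, and one image stack with 20% plaque-on-vessel coverage.
#'
#' @param seed Integer seed stamped into every stage.
#' @return A run-configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = synthetic_config(
      seed = as.integer(seed),
      n_patients_per_condition = 20L,
      # enough cells that the depleted BAM2-AD stratum still yields metacells
      cells_per_patient_range = c(1500L, 2500L),
      n_reactions = 40L,
      subsystem_sizes = rep(10L, 4L),
      shift_map = tibble(subsystem = "SS01", cell_type = "BAM2", shift = 0.5),
      image_shape = c(4L, 160L, 160L),
      n_vessels = 2L,
      n_plaques = 15L,
      plaque_on_vessel_target = 0.2
    ),
    max_cells_per_stratum = 400L,
    pseudobulk_size = 10L,
    stages = c("generate", "composition", "metabolic", "imaging")
  )
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order: data generation,
#' composition statistics (cluster enrichment, patient filtering, BAM2:BAM1
#' score, clinical models), metabolic post-processing (pseudobulk, flux,
#' effect sizes, subsystem enrichment, transition distance) and image
#' quantification (CAA%). Every artifact carries the seed and a hash of the
#' configuration; a rerun with the same configuration is byte-identical.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are retained.
#'
#' @param config Run configuration (see [demo_config()]). Optional elements
#'   `inputs$cells` / `inputs$clinical` name CSV files to analyse instead of
#'   generating them; referenced files must exist before anything runs.
#' @param out_dir Output directory for per-stage tables and the JSON results
#'   bundle; `NULL` (default) keeps everything in memory.
#' @return The results bundle (a nested list), invisibly when `out_dir` is
#'   set.
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_config(seed = 1))
#' res$composition$enrichment
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- load_run_config(config)
  }
  if (is.null(config$seed) || is.null(config$synthetic)) {
    abort("config error: `seed` and `synthetic` are required", class = "bamscape_config_error")
  }
  scfg <- config$synthetic
  if (!inherits(scfg, "synthetic_config")) {
    scfg <- do.call(synthetic_config, scfg)
  }
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) {
      abort(sprintf("config error: input file '%s' does not exist", p),
            class = "bamscape_config_error")
    }
  }
  stages <- config$stages %||% c("generate", "composition", "metabolic", "imaging")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  bundle <- list(seed = config$seed, config_hash = rlang::hash(config),
                 stages = stages)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "bamscape_stage_error")
    })
  }
  emit <- function(x, file) {
    if (!is.null(out_dir)) readr::write_csv(x, file.path(out_dir, file))
  }

  ## ---- generate ---------------------------------------------------------
  dat <- run_stage("generate", {
    if (!is.null(config$inputs$cells)) {
      cells <- read_table_csv(config$inputs$cells)
      clinical <- read_table_csv(config$inputs$clinical)
      list(cells = cells, clinical = clinical, ground_truth = NULL)
    } else {
      pats <- gen_patients(scfg)
      clinical <- gen_clinical(scfg, pats)
      ct <- gen_cell_table(scfg, clinical)
      list(cells = ct$cells, clinical = clinical, ground_truth = ct$ground_truth)
    }
  })
  emit(dat$cells, "cells.csv")
  emit(dat$clinical, "clinical.csv")
  bundle$generate <- list(n_cells = nrow(dat$cells),
                          n_patients = nrow(dat$clinical))

  ## ---- composition ------------------------------------------------------
  if ("composition" %in% stages) {
    comp <- run_stage("composition", {
      cells <- filter_patients(dat$cells, c("BAM1", "BAM2", "microglia"))
      enr <- cluster_enrichment(cells, "AD")
      per_pat <- cells |>
        dplyr::group_by(.data$patient_id, .data$condition) |>
        dplyr::summarise(
          n_total = dplyr::n(),
          n_bam2 = sum(.data$cluster == "BAM2"),
          n_bam1 = sum(.data$cluster == "BAM1"),
          .groups = "drop"
        ) |>
        dplyr::mutate(
          bam2_fraction = .data$n_bam2 / .data$n_total,
          log_bam2_fraction = log((.data$n_bam2 + 0.5) / (.data$n_total + 0.5)),
          e_score = bam_ratio_score(.data$n_bam2, .data$n_bam1, .data$n_total)
        )
      fit_frac <- clinical_model(
        dplyr::select(per_pat, "patient_id", value = "log_bam2_fraction"),
        dat$clinical)
      fit_score <- clinical_model(
        dplyr::select(per_pat, "patient_id", value = "e_score"),
        dat$clinical)
      list(enrichment = enr, per_patient = per_pat,
           model_fraction = tidy(fit_frac), model_score = tidy(fit_score))
    })
    emit(comp$enrichment, "enrichment.csv")
    emit(comp$per_patient, "per_patient.csv")
    emit(comp$model_fraction, "model_fraction.csv")
    emit(comp$model_score, "model_score.csv")
    bundle$composition <- list(
      enrichment = comp$enrichment,
      braak_slope = comp$model_fraction$estimate[comp$model_fraction$term == "braak"],
      braak_p = comp$model_fraction$p.value[comp$model_fraction$term == "braak"]
    )
  } else comp <- NULL

  ## ---- metabolic --------------------------------------------------------
  if ("metabolic" %in% stages) {
    met <- run_stage("metabolic", {
      cap <- config$max_cells_per_stratum %||% 400L
      cells <- dat$cells |>
        dplyr::filter(.data$cluster %in% c("BAM2", "microglia")) |>
        dplyr::group_by(.data$cluster, .data$condition) |>
        dplyr::slice_head(n = cap) |>
        dplyr::ungroup()
      labels <- tibble(sample_id = cells$cell_id, cell_type = cells$cluster,
                       condition = cells$condition)
      pen <- gen_penalty_matrix(scfg, labels)
      pb <- pseudobulk(pen$penalties$values,
                       labels[, c("cell_type", "condition")],
                       group_size = config$pseudobulk_size %||% 10L,
                       seed = derive_seed(config$seed, "pseudobulk"))
      flux <- penalty_to_flux(pb$values)
      eff <- purrr::map(c(BAM2 = "BAM2", microglia = "microglia"), function(ct) {
        ga <- pb$metacells$sample_id[pb$metacells$cell_type == ct &
                                       pb$metacells$condition == "AD"]
        gb <- pb$metacells$sample_id[pb$metacells$cell_type == ct &
                                       pb$metacells$condition == "healthy"]
        reaction_effects(flux, ga, gb)
      })
      ss <- purrr::map(eff, subsystem_summarize,
                       subsystem_map = pen$penalties$reactions)
      td <- transition_distance(flux$values, pb$metacells$condition,
                                pb$metacells$cell_type)
      list(effects = eff, subsystems = ss, distance = td,
           shift_truth = pen$ground_truth)
    })
    emit(met$subsystems$BAM2, "subsystems_bam2.csv")
    emit(met$subsystems$microglia, "subsystems_microglia.csv")
    emit(met$distance$summary, "transition_distance.csv")
    bundle$metabolic <- list(
      subsystems_bam2 = met$subsystems$BAM2,
      subsystems_microglia = met$subsystems$microglia,
      distance_summary = met$distance$summary,
      distance_comparisons = met$distance$comparisons
    )
  } else met <- NULL

  ## ---- imaging ----------------------------------------------------------
  if ("imaging" %in% stages) {
    img <- run_stage("imaging", {
      gi <- gen_image_stack(scfg)
      thr <- gi$ground_truth$amplitude / 2
      caa <- caa_fraction(gi$stack, vessel_threshold = thr,
                          plaque_threshold = thr)
      list(caa = caa, truth = gi$ground_truth)
    })
    emit(img$caa, "caa.csv")
    bundle$imaging <- list(
      caa_percent = img$caa$percent,
      true_coverage_pct = img$truth$coverage_pct,
      vessel_area_px = img$caa$vessel_area_px,
      true_vessel_area_px = img$truth$vessel_area_px
    )
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}

#' Load a run configuration from YAML or JSON
#'
#' The file mirrors the [demo_config()] structure: a `seed`, a `synthetic`
#' block of [synthetic_config()] arguments (lists become vectors; a
#' `shift_map` block becomes a data frame), optional `stages`,
#' `max_cells_per_stratum`, `pseudobulk_size` and `inputs`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A run-configuration list for [run_pipeline()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config error: file '%s' does not exist", path),
          class = "bamscape_config_error")
  }
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$synthetic)) {
    s <- cfg$synthetic
    if (!is.null(s$base_proportions)) {
      s$base_proportions <- unlist(s$base_proportions)
    }
    for (f in c("cells_per_patient_range", "image_shape", "subsystem_sizes")) {
      if (!is.null(s[[f]])) s[[f]] <- as.integer(unlist(s[[f]]))
    }
    if (!is.null(s$shift_map)) {
      s$shift_map <- as_tibble(as.data.frame(lapply(s$shift_map, unlist)))
    }
    cfg$synthetic <- s
  }
  cfg
}
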