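#' Linear model of macrophage frequency against clinical covariates
#'
#' Ordinary least squares of a per-patient response (BAM fraction or the
#' exponential BAM2:BAM1 score) on the fixed covariate set: sex, Braak score,
#' post-mortem interval, CERAD score, educational attainment, and APOE E2 and
#' E4 allele counts. CERAD and Braak enter as numeric ordinals; no
#' interactions are fitted. The coefficient table is suitable for a forest
#' plot (see [autoplot.bam_clinical_model()]).
#'
#' @param response Per-patient response: a data frame with `patient_id` and a
#'   single value column, or a numeric vector named by patient id.
#' @param covariates Clinical table with `patient_id`, `sex`, `braak`, `pmi`,
#'   `cerad`, `education`, `apoe_e2`, `apoe_e4` (e.g. from [gen_clinical()]).
#' @return An object of class `bam_clinical_model`; use [tidy()] for the
#'   per-term estimates, standard errors, p-values and confidence intervals,
#'   and [glance()] for fit diagnostics.
#' @examples
#' cfg <- synthetic_config(seed = 1, n_patients_per_condition = 30)
#' pats <- gen_patients(cfg)
#' clin <- gen_clinical(cfg, pats)
#' resp <- tibble::tibble(patient_id = clin$patient_id,
#'                        value = rnorm(nrow(clin)))
#' fit <- clinical_model(resp, clin)
#' tidy(fit)
#' @export
clinical_model <- function(response, covariates) {
  covar_names <- c("sex", "braak", "pmi", "cerad", "education",
                   "apoe_e2", "apoe_e4")
  if (!all(c("patient_id", covar_names) %in% names(covariates))) {
    abort(sprintf("`covariates` needs columns: patient_id, %s",
                  paste(covar_names, collapse = ", ")))
  }
  if (is.numeric(response) && !is.null(names(response))) {
    response <- tibble(patient_id = names(response), value = unname(response))
  }
  if (!is.data.frame(response) || !"patient_id" %in% names(response)) {
    abort("`response` must be a data frame with `patient_id` and one value column, or a named numeric vector")
  }
  value_col <- setdiff(names(response), "patient_id")
  if (length(value_col) != 1) abort("`response` must have exactly one value column")
  response_name <- value_col

  dat <- dplyr::inner_join(
    dplyr::select(response, "patient_id", value = dplyr::all_of(value_col)),
    dplyr::select(covariates, "patient_id", dplyr::all_of(covar_names)),
    by = "patient_id"
  )
  dat <- dat[complete.cases(dat), ]
  if (!all(is.finite(dat$value))) abort("responses must be finite")
  p <- length(covar_names)
  if (nrow(dat) < p + 2) {
    abort(sprintf("need at least %d patients after filtering, got %d",
                  p + 2, nrow(dat)))
  }
  fml <- stats::as.formula(paste("value ~", paste(covar_names, collapse = " + ")))
  fit <- lm(fml, data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("rank-deficient design; collinear terms: %s",
                  paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  structure(list(fit = fit, data = dat, response_name = response_name,
                 covariates = covar_names),
            class = "bam_clinical_model")
}

#' @rdname clinical_model
#' @param x,object A `bam_clinical_model`.
#' @param ... Unused.
#' @export
tidy.bam_clinical_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  ci <- confint(x$fit)
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
}

#' @rdname clinical_model
#' @export
glance.bam_clinical_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = nrow(x$data),
    df.residual = x$fit$df.residual,
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma
  )
}

#' @export
print.bam_clinical_model <- function(x, ...) {
  cat("<bam_clinical_model> response:", x$response_name,
      " n =", nrow(x$data), "\n")
  print(tidy(x))
  invisible(x)
}

#' Forest plot of clinical-model coefficients
#'
#' @param object A `bam_clinical_model`.
#' @param ... Unused.
#' @return A ggplot object: point estimates with 95% confidence intervals per
#'   covariate, intercept omitted.
#' @export
autoplot.bam_clinical_model <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL,
                  title = paste("Predictors of", object$response_name)) +
    ggplot2::theme_minimal()
}
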