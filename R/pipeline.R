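# End-to-end orchestration of the selection pipeline.

#' Run the full panel-selection pipeline
#'
#' Delta-beta prefilter -> stability selection -> random-forest
#' importances -> importance-threshold sweep with cross-validated
#' LogLoss -> one-standard-error minimal panel -> final forest fit ->
#' correlated-site discovery. Every stage failure is reported with the
#' stage name and a remediation hint. The result is a pure function of
#' `(x, delta_beta, config, r_threshold)`.
#'
#' @param x The training [beta_matrix()].
#' @param delta_beta Prefilter threshold (default 0.2).
#' @param config A [selection_config()].
#' @param r_threshold Pearson threshold for correlated-site discovery
#'   (default 0.85).
#' @param positive_class Class reported as positive; defaults to the last
#'   factor level of the labels.
#' @return A `panel_model` with `curve`, `correlated_clusters`,
#'   `candidate_frequency` (stability-selection frequencies) and
#'   `survivors` (delta-beta survivors) attached.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(heterogeneous_cohort_spec(seed = 7))
#' cfg <- selection_config(P = 15, rlr_iterations = 300, seed = 7)
#' model <- run_select(cohort$matrix, delta_beta = 0.2, config = cfg)
#' model
#' }
#' @export
run_select <- function(x, delta_beta = 0.2, config = selection_config(),
                       r_threshold = 0.85, positive_class = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  survivors <- delta_beta_filter(x, delta_beta)
  if (!length(survivors)) {
    stop("stage delta_beta_filter: no sites survive the prefilter at ",
         "delta_beta = ", delta_beta, "; lower the threshold", call. = FALSE)
  }
  xf <- subset_beta(x, sites = survivors)
  stab <- stability_select(xf, config)
  if (!length(stab$selected)) {
    stop("stage stability_select: empty candidate set (max frequency ",
         format(max(stab$frequency), digits = 3), "); lower ",
         "rlr_frequency_threshold or rlr_regularization", call. = FALSE)
  }
  imp <- rf_importances(xf, stab$selected, config)
  if (max(imp) <= 0) {
    stop("stage rf_importances: every importance is zero; the candidates ",
         "carry no class signal", call. = FALSE)
  }
  curve <- threshold_sweep(xf, imp, config, positive_class = positive_class)
  chosen <- one_se_select(curve, config$P)
  model <- fit_panel(x, chosen$site_ids, config,
                     positive_class = positive_class)
  model$curve <- curve
  model$selected_point <- chosen
  model$correlated_clusters <- find_correlated_sites(x, model$panel_sites,
                                                     r_threshold)
  model$candidate_frequency <- stab$frequency
  model$survivors <- survivors
  model
}

#' Evaluate a panel model on a labeled cohort
#'
#' @param model A `panel_model`.
#' @param x A labeled [beta_matrix()] containing the panel sites.
#' @param n_boot Bootstrap resamples for the AUC interval.
#' @param seed Seed for the bootstrap.
#' @return List with `logloss`, `precision`, `recall`, `f1`,
#'   `precision_macro`, `recall_macro`, `auc`, `auc_ci`, and the
#'   probability matrix `prob`.
#' @export
evaluate_model <- function(model, x, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(model, "panel_model"), inherits(x, "beta_matrix"))
  prob <- predict(model, x)
  truth <- factor(as.character(x$labels),
                  levels = levels(model$train_labels))
  met <- classification_metrics(prob, truth, model$positive_class,
                                n_boot = n_boot, seed = seed)
  list(
    logloss = logloss(prob, truth),
    precision = met$precision, recall = met$recall, f1 = met$f1,
    precision_macro = met$precision_macro, recall_macro = met$recall_macro,
    auc = met$auc, auc_ci = met$auc_ci,
    prob = prob
  )
}
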