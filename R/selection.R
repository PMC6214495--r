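# The core panel-selection pipeline: stability selection with
# L1-penalised logistic regression, random-forest importance estimation,
# the importance-threshold sweep scored by cross-validated LogLoss, and
# the one-standard-error minimal-panel rule.

#' Selection pipeline configuration
#'
#' Bundles and validates every tunable of the selection pipeline. Defaults
#' follow the published protocol: 1500 randomised-regression iterations, a
#' 500-tree forest for importance estimation, 1000-tree forests for the
#' cross-validated sweep, and 10-fold CV.
#'
#' @param P Upper limit on panel size (sites), >= 1.
#' @param rlr_iterations Rounds of randomised L1 logistic regression.
#' @param rlr_subsample_fraction Fraction of samples drawn (stratified,
#'   without replacement) per round, in `(0, 1)`.
#' @param rlr_regularization L1 penalty as a fraction of each round's
#'   `lambda_max` (the smallest penalty that zeroes every coefficient),
#'   in `(0, 1)`.
#' @param rlr_frequency_threshold Minimum selection frequency for a site
#'   to become a candidate, in `(0, 1]`.
#' @param importance_trees Trees in the importance-estimation forest.
#' @param sweep_trees Trees in each sweep/final forest.
#' @param cv_folds Stratified cross-validation folds; must not exceed the
#'   smallest class size.
#' @param seed Master seed; all stage seeds are derived from it, making
#'   the whole pipeline a pure function of (data, config).
#' @return A validated list of class `selection_config`.
#' @export
selection_config <- function(P = 15L,
                             rlr_iterations = 1500L,
                             rlr_subsample_fraction = 0.5,
                             rlr_regularization = 0.1,
                             rlr_frequency_threshold = 0.25,
                             importance_trees = 500L,
                             sweep_trees = 1000L,
                             cv_folds = 10L,
                             seed = 1L) {
  stopifnot(P >= 1, rlr_iterations >= 1,
            rlr_subsample_fraction > 0, rlr_subsample_fraction < 1,
            rlr_regularization > 0, rlr_regularization < 1,
            rlr_frequency_threshold > 0, rlr_frequency_threshold <= 1,
            importance_trees >= 1, sweep_trees >= 1, cv_folds >= 2)
  structure(list(
    P = as.integer(P),
    rlr_iterations = as.integer(rlr_iterations),
    rlr_subsample_fraction = rlr_subsample_fraction,
    rlr_regularization = rlr_regularization,
    rlr_frequency_threshold = rlr_frequency_threshold,
    importance_trees = as.integer(importance_trees),
    sweep_trees = as.integer(sweep_trees),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  ), class = c("selection_config", "list"))
}

# stage seeds derived from the master seed, by fixed position
stage_seeds <- function(config) {
  s <- derive_seeds(config$seed, 6L)
  names(s) <- c("rlr", "importance", "sweep_folds", "sweep_fits",
                "final_fit", "spare")
  s
}

#' Stability selection by randomised L1 logistic regression
#'
#' Repeatedly draws a stratified sample subset (default 50%), fits an
#' L1-penalised logistic (binomial; multinomial for more than two classes)
#' model at a fixed fraction of that round's `lambda_max`, and records
#' which sites receive non-zero coefficients. A site's selection frequency
#' is the share of rounds in which it was active; sites at or above
#' `rlr_frequency_threshold` become candidates. Random subsampling lets
#' highly correlated sites take turns carrying the signal, so members of a
#' correlated block each accumulate frequency rather than one absorbing
#' the credit.
#'
#' @param x A [beta_matrix()], normally already restricted to
#'   delta-beta-filter survivors.
#' @param config A [selection_config()].
#' @return List with `frequency` (named vector over all sites, in input
#'   site order) and `selected` (character vector of candidate sites; may
#'   be empty, which is reported via a message).
#' @export
stability_select <- function(x, config = selection_config()) {
  stopifnot(inherits(x, "beta_matrix"))
  check_classes(x, min_classes = 2L, min_n = 2L)
  labels <- droplevels(x$labels)
  feats <- t(x$values) # samples x sites
  n_sites <- ncol(feats)
  seeds <- stage_seeds(config)
  family <- if (nlevels(labels) == 2L) "binomial" else "multinomial"

  counts <- numeric(n_sites)
  names(counts) <- colnames(feats)
  if (n_sites == 1L) {
    # degenerate but legal: a single site is trivially always selected
    counts[] <- config$rlr_iterations
  } else {
    with_seed(seeds[["rlr"]], {
      for (it in seq_len(config$rlr_iterations)) {
        idx <- NULL
        for (try in 1:10) {
          cand <- stratified_subsample(labels, config$rlr_subsample_fraction)
          if (nlevels(droplevels(labels[cand])) == nlevels(labels)) {
            idx <- cand
            break
          }
        }
        if (is.null(idx)) {
          stop("could not draw a subsample containing every class after ",
               "10 attempts", call. = FALSE)
        }
        xi <- feats[idx, , drop = FALSE]
        yi <- droplevels(labels[idx])
        fit <- glmnet::glmnet(xi, yi, family = family, alpha = 1,
                              nlambda = 30L, lambda.min.ratio = 0.01,
                              standardize = TRUE)
        s <- max(fit$lambda) * config$rlr_regularization
        cf <- glmnet::coef.glmnet(fit, s = s)
        nz <- if (family == "binomial") {
          as.vector(cf[-1L, 1L] != 0)
        } else {
          Reduce(`|`, lapply(cf, function(m) as.vector(m[-1L, 1L] != 0)))
        }
        counts <- counts + nz
      }
    })
  }
  freq <- counts / config$rlr_iterations
  selected <- names(freq)[freq >= config$rlr_frequency_threshold]
  if (!length(selected)) {
    message("stability selection produced an empty candidate set ",
            "(max frequency ", format(max(freq), digits = 3),
            " below threshold ", config$rlr_frequency_threshold, ")")
  }
  list(frequency = freq, selected = selected)
}

#' Random-forest impurity importances for candidate sites
#'
#' Fits a single forest (default 500 trees) on the candidate sites with
#' sample weights inversely proportional to class frequency, and returns
#' Gini impurity importances normalised to sum to one.
#'
#' @param x A [beta_matrix()].
#' @param candidate_sites Non-empty character vector of site ids.
#' @param config A [selection_config()].
#' @return Named numeric vector of importances (>= 0, summing to 1).
#' @export
rf_importances <- function(x, candidate_sites, config = selection_config()) {
  stopifnot(inherits(x, "beta_matrix"))
  if (!length(candidate_sites)) {
    stop("`candidate_sites` is empty", call. = FALSE)
  }
  missing <- setdiff(candidate_sites, rownames(x$values))
  if (length(missing)) {
    stop("candidate sites absent from matrix: ", toString(missing),
         call. = FALSE)
  }
  if (length(candidate_sites) == 1L) {
    return(stats::setNames(1.0, candidate_sites))
  }
  labels <- droplevels(x$labels)
  seeds <- stage_seeds(config)
  fit <- ranger::ranger(
    x = t(x$values[candidate_sites, , drop = FALSE]), y = labels,
    num.trees = config$importance_trees,
    importance = "impurity",
    case.weights = inverse_class_weights(labels),
    seed = seeds[["importance"]],
    num.threads = 1L
  )
  imp <- fit$variable.importance[candidate_sites]
  imp[imp < 0] <- 0
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' Importance-threshold sweep with cross-validated LogLoss
#'
#' Enumerates every distinct importance value as a threshold; for each,
#' the sites at or above the threshold form a subset on which a forest
#' (default 1000 trees) is scored by stratified `cv_folds`-fold
#' cross-validation. Each curve point records the per-fold LogLoss mean
#' and standard error (SD/sqrt(folds)) plus pooled precision and recall
#' from out-of-fold argmax assignments. Sites with tied importances enter
#' and leave together. The same fold assignment is reused across points so
#' subsets are compared on identical splits.
#'
#' @param x A [beta_matrix()].
#' @param importances Named importance vector, e.g. from
#'   [rf_importances()]; at least one value must be positive.
#' @param config A [selection_config()].
#' @param positive_class Class used for pooled precision/recall on binary
#'   tasks; defaults to the last factor level. Macro averages are used for
#'   more than two classes.
#' @return A `selection_curve`: list with `points` (data.frame of
#'   `threshold`, `n_sites`, `logloss_mean`, `logloss_se`, `precision`,
#'   `recall`, ordered by increasing threshold / strictly decreasing
#'   `n_sites`) and `site_sets` (list of site-id vectors per point).
#' @export
threshold_sweep <- function(x, importances, config = selection_config(),
                            positive_class = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  if (is.null(names(importances)) || !length(importances)) {
    stop("`importances` must be a non-empty named vector", call. = FALSE)
  }
  if (max(importances) <= 0) {
    stop("no candidate has positive importance", call. = FALSE)
  }
  labels <- droplevels(x$labels)
  check_classes(x, min_classes = 2L, min_n = config$cv_folds)
  if (is.null(positive_class)) positive_class <- levels(labels)[nlevels(labels)]
  seeds <- stage_seeds(config)
  folds <- make_stratified_folds(labels, config$cv_folds,
                                 seeds[["sweep_folds"]])
  thresholds <- sort(unique(unname(importances)))
  fit_seeds <- derive_seeds(seeds[["sweep_fits"]],
                            length(thresholds) * config$cv_folds)
  site_sets <- vector("list", length(thresholds))
  rows <- vector("list", length(thresholds))
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[ti]
    sites <- names(importances)[importances >= thr]
    site_sets[[ti]] <- sites
    feats <- t(x$values[sites, , drop = FALSE])
    fold_ll <- numeric(config$cv_folds)
    oof <- matrix(NA_real_, nrow = length(labels), ncol = nlevels(labels),
                  dimnames = list(names(labels), levels(labels)))
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fit <- ranger::ranger(
        x = feats[tr, , drop = FALSE], y = labels[tr],
        num.trees = config$sweep_trees, probability = TRUE,
        case.weights = inverse_class_weights(labels[tr]),
        seed = fit_seeds[(ti - 1L) * config$cv_folds + f],
        num.threads = 1L
      )
      p <- stats::predict(fit, data = feats[!tr, , drop = FALSE],
                          num.threads = 1L)$predictions
      colnames(p) <- colnames(fit$predictions) %||% levels(labels)
      p <- p[, levels(labels), drop = FALSE]
      oof[!tr, ] <- p
      fold_ll[f] <- logloss(p, labels[!tr])
    }
    met <- classification_metrics(oof, labels, positive_class, n_boot = 0L)
    rows[[ti]] <- data.frame(
      threshold = thr,
      n_sites = length(sites),
      logloss_mean = mean(fold_ll),
      logloss_se = stats::sd(fold_ll) / sqrt(config$cv_folds),
      precision = if (nlevels(labels) == 2L) met$precision else met$precision_macro,
      recall = if (nlevels(labels) == 2L) met$recall else met$recall_macro
    )
  }
  points <- do.call(rbind, rows)
  rownames(points) <- NULL
  structure(list(points = points, site_sets = site_sets),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("selection_curve with", nrow(x$points), "points\n")
  print(x$points, digits = 4)
  invisible(x)
}

#' One-standard-error minimal-panel rule
#'
#' Among curve points with `n_sites` between 1 and `P`, locates the
#' LogLoss minimum `m` and returns the point with the smallest `n_sites`
#' whose LogLoss mean lies strictly below `logloss_mean(m) +
#' logloss_se(m)`; ties on `n_sites` are broken toward lower LogLoss.
#' When the minimum's standard error is exactly zero no point (not even
#' `m`) satisfies the strict inequality, and the minimum itself is
#' returned.
#'
#' @param curve A `selection_curve` from [threshold_sweep()].
#' @param P Upper panel-size limit.
#' @return List with the chosen point's `threshold`, `n_sites`,
#'   `logloss_mean`, `logloss_se`, `precision`, `recall`, `site_ids`, and
#'   `index` (row in the curve).
#' @export
one_se_select <- function(curve, P) {
  stopifnot(inherits(curve, "selection_curve"), P >= 1)
  pts <- curve$points
  eligible <- which(pts$n_sites >= 1L & pts$n_sites <= P)
  if (!length(eligible)) {
    stop("no curve point has between 1 and P = ", P, " sites; increase P ",
         "or loosen the candidate threshold", call. = FALSE)
  }
  m <- eligible[which.min(pts$logloss_mean[eligible])]
  bound <- pts$logloss_mean[m] + pts$logloss_se[m]
  qual <- eligible[pts$logloss_mean[eligible] < bound]
  pick <- if (!length(qual)) m else {
    smallest <- qual[pts$n_sites[qual] == min(pts$n_sites[qual])]
    smallest[which.min(pts$logloss_mean[smallest])]
  }
  c(as.list(pts[pick, , drop = FALSE]),
    list(site_ids = curve$site_sets[[pick]], index = pick))
}

#' Fit the final panel forest
#'
#' Refits a probability forest on all training samples restricted to the
#' selected panel, recording every seed and configuration value needed to
#' reproduce it exactly.
#'
#' @param x The training [beta_matrix()].
#' @param panel_sites Non-empty character vector, length <= `config$P`.
#' @param config A [selection_config()].
#' @param positive_class Class reported as "positive" in downstream
#'   metrics; defaults to the last factor level of the labels.
#' @return A `panel_model`: list with `panel_sites`, `forest` (ranger
#'   fit), `train_values` (panel x samples), `train_labels`,
#'   `positive_class`, `config`, `seeds`, and placeholders for
#'   `correlated_clusters` and `curve` filled by [run_select()].
#' @export
fit_panel <- function(x, panel_sites, config = selection_config(),
                      positive_class = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  if (!length(panel_sites)) stop("`panel_sites` is empty", call. = FALSE)
  if (length(panel_sites) > config$P) {
    stop("panel has ", length(panel_sites), " sites, exceeding P = ",
         config$P, call. = FALSE)
  }
  missing <- setdiff(panel_sites, rownames(x$values))
  if (length(missing)) {
    stop("panel sites absent from matrix: ", toString(missing), call. = FALSE)
  }
  labels <- droplevels(x$labels)
  if (is.null(positive_class)) positive_class <- levels(labels)[nlevels(labels)]
  seeds <- stage_seeds(config)
  feats <- t(x$values[panel_sites, , drop = FALSE])
  forest <- ranger::ranger(
    x = feats, y = labels,
    num.trees = config$sweep_trees, probability = TRUE,
    case.weights = inverse_class_weights(labels),
    seed = seeds[["final_fit"]],
    num.threads = 1L
  )
  structure(list(
    panel_sites = panel_sites,
    forest = forest,
    train_values = x$values[panel_sites, , drop = FALSE],
    train_labels = labels,
    positive_class = positive_class,
    config = unclass(config),
    seeds = as.list(seeds),
    correlated_clusters = NULL,
    curve = NULL
  ), class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("panel_model:", length(x$panel_sites), "sites\n")
  cat("  sites:", toString(x$panel_sites), "\n")
  cat("  classes:", toString(levels(x$train_labels)),
      sprintf("(positive: %s)", x$positive_class), "\n")
  cat(sprintf("  forest: %d trees, seed %d\n",
              x$config$sweep_trees, x$seeds[["final_fit"]]))
  if (!is.null(x$correlated_clusters)) {
    n_cor <- sum(vapply(x$correlated_clusters, nrow, integer(1L)))
    cat("  correlated sites recorded:", n_cor, "\n")
  }
  invisible(x)
}

#' Predict class probabilities for new samples
#'
#' @param object A `panel_model`.
#' @param newdata A [beta_matrix()] (labels ignored for prediction) or a
#'   samples x sites numeric matrix containing the panel sites.
#' @param ... Unused.
#' @return Samples x classes probability matrix.
#' @export
predict.panel_model <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "beta_matrix")) {
    missing <- setdiff(object$panel_sites, rownames(newdata$values))
    if (length(missing)) {
      stop("panel sites absent from newdata: ", toString(missing),
           call. = FALSE)
    }
    t(newdata$values[object$panel_sites, , drop = FALSE])
  } else {
    newdata[, object$panel_sites, drop = FALSE]
  }
  p <- stats::predict(object$forest, data = feats,
                      num.threads = 1L)$predictions
  colnames(p) <- colnames(object$forest$predictions) %||%
    levels(object$train_labels)
  rownames(p) <- rownames(feats)
  p[, levels(object$train_labels), drop = FALSE]
}
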