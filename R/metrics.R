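# Classification metrics: cross-entropy loss, precision/recall/F1, rank
# AUC with stratified bootstrap CI, and LogLoss-driven outlier flagging.

# internal: validate a probability matrix against a truth factor and
# return the matrix with columns ordered as levels(truth)
check_predictions <- function(prob, truth, tol = 1e-9) {
  truth <- as.factor(truth)
  if (!is.matrix(prob)) {
    stop("`prob` must be a samples x classes probability matrix", call. = FALSE)
  }
  if (nrow(prob) == 0L) stop("empty prediction set", call. = FALSE)
  if (nrow(prob) != length(truth)) {
    stop("prob has ", nrow(prob), " rows but truth has ", length(truth),
         " samples", call. = FALSE)
  }
  if (is.null(colnames(prob)) || !all(levels(truth) %in% colnames(prob))) {
    stop("prob needs one named column per class: ",
         toString(levels(truth)), call. = FALSE)
  }
  prob <- prob[, levels(truth), drop = FALSE]
  if (any(prob < -tol) || any(prob > 1 + tol)) {
    stop("probabilities outside [0,1]", call. = FALSE)
  }
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > tol)) {
    stop("probability rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  prob
}

#' Multiclass cross-entropy loss (LogLoss)
#'
#' `-(1/N) * sum_i log p_i(true class of i)`, with probabilities clipped to
#' `[eps, 1 - eps]` before the logarithm so a single confident mistake
#' yields a large but finite penalty.
#'
#' @param prob Samples x classes probability matrix with class-named
#'   columns; rows sum to 1.
#' @param truth Factor (or vector) of true class labels, one per row.
#' @param eps Clipping constant, default `1e-15`.
#' @return Non-negative scalar.
#' @examples
#' p <- cbind(N = c(0.9, 0.2), T = c(0.1, 0.8))
#' logloss(p, c("N", "T"))  # -(log(0.9) + log(0.8)) / 2
#' @export
logloss <- function(prob, truth, eps = 1e-15) {
  truth <- as.factor(truth)
  prob <- check_predictions(prob, truth)
  p_true <- prob[cbind(seq_len(nrow(prob)), as.integer(truth))]
  p_true <- pmin(pmax(p_true, eps), 1 - eps)
  -mean(log(p_true))
}

#' Confusion-matrix metrics plus rank AUC with bootstrap CI
#'
#' Classes are assigned by the argmax rule. Positive-class precision,
#' recall and F1 are reported alongside macro averages; AUC (binary tasks
#' only) is the Mann-Whitney rank statistic on the positive-class
#' probability, with a stratified percentile bootstrap confidence
#' interval.
#'
#' @inheritParams logloss
#' @param positive_class The class treated as "positive" (e.g. tumor).
#' @param n_boot Bootstrap resamples for the AUC interval (default 2000);
#'   `0` skips the interval.
#' @param conf Confidence level, default 0.95.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `precision`, `recall`, `f1` (positive class),
#'   `precision_macro`, `recall_macro`, `auc`, `auc_ci` (length-2 vector or
#'   `NULL`), and the confusion `table`.
#' @export
classification_metrics <- function(prob, truth, positive_class,
                                   n_boot = 2000L, conf = 0.95, seed = 1L) {
  truth <- as.factor(truth)
  prob <- check_predictions(prob, truth)
  if (!positive_class %in% levels(truth)) {
    stop("positive_class '", positive_class, "' is not a class level",
         call. = FALSE)
  }
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = levels(truth))
  cm <- table(truth = truth, predicted = pred)
  per_class <- vapply(levels(truth), function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    c(prec, rec)
  }, numeric(2L))
  prec <- per_class[1L, positive_class]
  rec <- per_class[2L, positive_class]
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  out <- list(
    precision = unname(prec), recall = unname(rec), f1 = unname(f1),
    precision_macro = mean(per_class[1L, ], na.rm = TRUE),
    recall_macro = mean(per_class[2L, ], na.rm = TRUE),
    auc = NA_real_, auc_ci = NULL, table = cm
  )
  if (nlevels(truth) == 2L) {
    if (nlevels(droplevels(truth)) < 2L) {
      stop("AUC undefined: a single class is present", call. = FALSE)
    }
    scores <- prob[, positive_class]
    is_pos <- truth == positive_class
    out$auc <- auc_rank(scores, is_pos)
    if (n_boot > 0L) {
      pos_idx <- which(is_pos)
      neg_idx <- which(!is_pos)
      aucs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
        i <- c(sample(pos_idx, length(pos_idx), replace = TRUE),
               sample(neg_idx, length(neg_idx), replace = TRUE))
        auc_rank(scores[i], is_pos[i])
      }, numeric(1L)))
      alpha <- (1 - conf) / 2
      out$auc_ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha)))
    }
  }
  out
}

#' Flag potential outliers / mislabeled samples
#'
#' Samples that sit firmly in the "wrong" region of panel space — i.e.
#' whose predicted probability of a class other than their recorded label
#' exceeds `prob_threshold` — are flagged. When the scored matrix is the
#' model's own training cohort, in-bag forest predictions would simply
#' memorise the labels, so probabilities come from the out-of-bag votes of
#' a forest refit on the supplied matrix under the model's configuration
#' and seed.
#'
#' @param model A `panel_model`.
#' @param x A labeled [beta_matrix()] containing the panel sites.
#' @param prob_threshold Flag when the wrong-class probability strictly
#'   exceeds this value, in `(0, 1]`. Default 0.5.
#' @return `data.frame` with `sample_id`, `labelled_class`,
#'   `suspected_class`, `wrong_class_probability`, sorted by descending
#'   probability; zero rows when nothing is flagged.
#' @export
detect_outliers <- function(model, x, prob_threshold = 0.5) {
  stopifnot(inherits(model, "panel_model"), inherits(x, "beta_matrix"))
  if (prob_threshold <= 0 || prob_threshold > 1) {
    stop("`prob_threshold` must lie in (0, 1]", call. = FALSE)
  }
  feats <- t(x$values[model$panel_sites, , drop = FALSE])
  labels <- droplevels(x$labels)
  fit <- ranger::ranger(
    x = feats, y = labels,
    num.trees = model$config$sweep_trees,
    probability = TRUE,
    case.weights = inverse_class_weights(labels),
    seed = model$seeds[["final_fit"]],
    num.threads = 1L
  )
  oob <- fit$predictions
  rownames(oob) <- rownames(feats)
  true_idx <- match(as.character(labels), colnames(oob))
  wrong <- oob
  wrong[cbind(seq_len(nrow(oob)), true_idx)] <- -Inf
  worst <- max.col(wrong, ties.method = "first")
  wrong_p <- oob[cbind(seq_len(nrow(oob)), worst)]
  keep <- which(wrong_p > prob_threshold)
  out <- data.frame(
    sample_id = rownames(oob)[keep],
    labelled_class = as.character(labels)[keep],
    suspected_class = colnames(oob)[worst[keep]],
    wrong_class_probability = wrong_p[keep],
    stringsAsFactors = FALSE
  )
  out[order(-out$wrong_class_probability), , drop = FALSE]
}
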