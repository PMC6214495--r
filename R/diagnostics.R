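# Post-hoc diagnostics: correlated-site interchangeability, Kuncheva
# selection stability under bootstrap resampling, noise-injection
# robustness, and k-means heterogeneity clustering.

#' Find non-panel sites highly correlated with each panel site
#'
#' For every panel site, returns the non-panel sites whose Pearson
#' correlation across all samples strictly exceeds `r_threshold`
#' (default 0.85). The threshold applies to the signed coefficient, so a
#' perfectly anti-correlated mirror site is not reported. Zero-variance
#' sites, for which the coefficient is undefined, are excluded with a
#' message.
#'
#' @param x A [beta_matrix()].
#' @param panel_sites Character vector of panel site ids, all present in
#'   `x`.
#' @param r_threshold Signed Pearson threshold (strict), default 0.85.
#' @return Named list (one element per panel site) of `data.frame`s with
#'   columns `site_id` and `r`, sorted by descending `r`.
#' @export
find_correlated_sites <- function(x, panel_sites, r_threshold = 0.85) {
  stopifnot(inherits(x, "beta_matrix"))
  missing <- setdiff(panel_sites, rownames(x$values))
  if (length(missing)) {
    stop("panel sites absent from matrix: ", toString(missing), call. = FALSE)
  }
  others <- setdiff(rownames(x$values), panel_sites)
  out <- stats::setNames(
    replicate(length(panel_sites),
              data.frame(site_id = character(0), r = numeric(0),
                         stringsAsFactors = FALSE),
              simplify = FALSE),
    panel_sites)
  if (!length(others)) return(out)
  sds <- apply(x$values, 1L, stats::sd)
  flat <- names(sds)[sds == 0]
  if (length(flat)) {
    message(length(flat), " zero-variance site(s) excluded from ",
            "correlation analysis: ", toString(utils::head(flat, 5L)))
    others <- setdiff(others, flat)
  }
  usable_panel <- setdiff(panel_sites, flat)
  if (!length(others) || !length(usable_panel)) return(out)
  cc <- stats::cor(t(x$values[usable_panel, , drop = FALSE]),
                   t(x$values[others, , drop = FALSE]))
  for (ps in usable_panel) {
    r <- cc[ps, ]
    hit <- which(r > r_threshold)
    if (length(hit)) {
      df <- data.frame(site_id = others[hit], r = unname(r[hit]),
                       stringsAsFactors = FALSE)
      out[[ps]] <- df[order(-df$r), , drop = FALSE]
    }
  }
  out
}

#' Kuncheva index of feature-selection stability
#'
#' Chance-corrected average pairwise agreement between selected subsets
#' out of a universe of `N_total` features. For equal subset sizes `s`
#' each pair contributes `(r*N - s^2) / (s*(N - s))`, where r is the
#' pair's overlap count; the index is 1 iff all subsets are
#' identical, and negative agreement below chance is possible.
#'
#' @param subsets List (length >= 2) of character vectors of selected
#'   feature ids.
#' @param N_total Size of the feature universe after prefiltering.
#' @param mode `"strict"` requires all subsets to share one size (the
#'   published formula); `"generalized"` scores unequal sizes with the
#'   pair term `(r*N - s_i*s_j) / sqrt(s_i*(N-s_i) * s_j*(N-s_j))`, which
#'   reduces to the strict form when sizes agree; `"auto"` (default) picks
#'   strict when sizes are equal.
#' @return Scalar index, at most 1.
#' @export
kuncheva_index <- function(subsets, N_total,
                           mode = c("auto", "strict", "generalized")) {
  mode <- match.arg(mode)
  k <- length(subsets)
  if (k < 2L) stop("need at least two subsets", call. = FALSE)
  subsets <- lapply(subsets, unique)
  sizes <- lengths(subsets)
  if (any(sizes == 0L) || any(sizes >= N_total)) {
    stop("subset sizes must satisfy 0 < s < N_total; got sizes ",
         toString(sizes), " with N_total = ", N_total, call. = FALSE)
  }
  if (mode == "auto") {
    mode <- if (length(unique(sizes)) == 1L) "strict" else "generalized"
  }
  if (mode == "strict" && length(unique(sizes)) != 1L) {
    stop("strict mode requires equal subset sizes; got ", toString(sizes),
         call. = FALSE)
  }
  total <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      r <- length(intersect(subsets[[i]], subsets[[j]]))
      si <- sizes[i]
      sj <- sizes[j]
      total <- total + if (mode == "strict") {
        (r * N_total - si^2) / (si * (N_total - si))
      } else {
        (r * N_total - si * sj) /
          sqrt(si * (N_total - si) * sj * (N_total - sj))
      }
    }
  }
  2 * total / (k * (k - 1))
}

#' Bootstrap stability experiment for the whole selection pipeline
#'
#' Reruns the full pipeline ([run_select()]) on repeated stratified
#' subsamples (default 100 draws of 90% of samples, without replacement)
#' and summarises how consistent the selected panels are with the
#' [kuncheva_index()]. Each panel is optionally augmented with its
#' correlated sites (as discovered on that subsample), since correlated
#' block members are interchangeable carriers of the same signal. The
#' feature universe `N_total` is the delta-beta survivor count of the full
#' matrix.
#'
#' @param x The full training [beta_matrix()].
#' @param delta_beta Prefilter threshold passed to [run_select()].
#' @param config A [selection_config()]; its `seed` is replaced per
#'   bootstrap by seeds derived from `seed`.
#' @param n_boot Number of bootstrap pipeline runs, default 100.
#' @param sample_fraction Stratified fraction drawn per run, default 0.9.
#' @param augment_with_correlated Augment each panel with its correlated
#'   sites (default `TRUE`).
#' @param r_threshold Correlation threshold for augmentation.
#' @param seed Master seed for the experiment.
#' @return List of class `stability_result`: `subsets` (the per-run,
#'   possibly augmented site sets), `panel_sites` (raw panels),
#'   `N_total`, `kuncheva`, and `n_failed` (runs that errored, excluded
#'   with a warning).
#' @export
stability_experiment <- function(x, delta_beta = 0.2,
                                 config = selection_config(),
                                 n_boot = 100L, sample_fraction = 0.9,
                                 augment_with_correlated = TRUE,
                                 r_threshold = 0.85, seed = 1L) {
  stopifnot(inherits(x, "beta_matrix"), n_boot >= 2L,
            sample_fraction > 0, sample_fraction < 1)
  survivors_full <- delta_beta_filter(x, delta_beta)
  N_total <- length(survivors_full)
  if (N_total < 2L) {
    stop("fewer than two sites survive the delta-beta prefilter on the ",
         "full data; the stability universe is degenerate", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 2L * n_boot)
  subsets <- list()
  panels <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b],
                     stratified_subsample(x$labels, sample_fraction))
    xb <- subset_beta(x, samples = colnames(x$values)[idx])
    cfg_b <- config
    cfg_b$seed <- seeds[n_boot + b]
    res <- tryCatch(
      run_select(xb, delta_beta = delta_beta, config = cfg_b,
                 r_threshold = r_threshold),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    panel <- res$panel_sites
    aug <- panel
    if (augment_with_correlated) {
      aug <- union(panel,
                   unlist(lapply(res$correlated_clusters,
                                 function(df) df$site_id)))
    }
    panels[[length(panels) + 1L]] <- panel
    subsets[[length(subsets) + 1L]] <- aug
  }
  if (n_failed > 0L) {
    warning(n_failed, " of ", n_boot, " bootstrap pipeline runs failed and ",
            "were excluded", call. = FALSE)
  }
  if (length(subsets) < 2L) {
    stop("fewer than two successful bootstrap runs; stability undefined",
         call. = FALSE)
  }
  structure(list(
    subsets = subsets,
    panel_sites = panels,
    N_total = N_total,
    kuncheva = kuncheva_index(subsets, N_total),
    n_failed = n_failed
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: %d runs (%d failed), N_total = %d\n",
              length(x$subsets) + x$n_failed, x$n_failed, x$N_total))
  cat(sprintf("Kuncheva index: %.4f\n", x$kuncheva))
  invisible(x)
}

#' Interchange permutation test for correlated panel sites
#'
#' Assesses whether panel sites can be swapped for their highly correlated
#' neighbours without losing diagnostic performance. Each permutation
#' independently replaces every panel site with a uniform random member of
#' `{itself} + its correlated cluster`, refits the final forest on the
#' training matrix with the substituted columns (reusing the baseline
#' seed), and scores AUC on the test matrix.
#'
#' @param train,test Labeled [beta_matrix()] objects; `train` is the
#'   cohort the model was fitted on.
#' @param model A `panel_model` with `correlated_clusters` populated
#'   (e.g. by [run_select()]).
#' @param n_perm Number of permutations, >= 1 (published protocol:
#'   10000).
#' @param seed Seed for the replacement draws.
#' @return List with `aucs` (length `n_perm`), `mean_auc`, `ci`
#'   (percentile 95% interval), and `baseline_auc` of the unsubstituted
#'   panel.
#' @export
interchange_test <- function(train, test, model, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(train, "beta_matrix"), inherits(test, "beta_matrix"),
            inherits(model, "panel_model"))
  if (n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  if (is.null(model$correlated_clusters)) {
    stop("model has no correlated_clusters; run find_correlated_sites() ",
         "or run_select() first", call. = FALSE)
  }
  labels_tr <- droplevels(train$labels)
  labels_te <- droplevels(test$labels)
  if (nlevels(labels_te) != 2L) {
    stop("interchange AUC is defined for binary tasks", call. = FALSE)
  }
  pos <- model$positive_class
  panel <- model$panel_sites
  pools <- lapply(panel, function(ps) {
    cl <- model$correlated_clusters[[ps]]
    c(ps, if (!is.null(cl)) cl$site_id)
  })
  score_panel <- function(sites) {
    feats_tr <- t(train$values[sites, , drop = FALSE])
    feats_te <- t(test$values[sites, , drop = FALSE])
    nm <- make.unique(sites)
    colnames(feats_tr) <- nm
    colnames(feats_te) <- nm
    fit <- ranger::ranger(
      x = feats_tr, y = labels_tr,
      num.trees = model$config$sweep_trees, probability = TRUE,
      case.weights = inverse_class_weights(labels_tr),
      seed = model$seeds[["final_fit"]],
      num.threads = 1L
    )
    p <- stats::predict(fit, data = feats_te, num.threads = 1L)$predictions
    colnames(p) <- colnames(fit$predictions) %||% levels(labels_tr)
    auc_rank(p[, pos], labels_te == pos)
  }
  baseline <- score_panel(panel)
  draws <- with_seed(seed, {
    matrix(vapply(seq_len(n_perm), function(i) {
      vapply(pools, function(pl) pl[sample.int(length(pl), 1L)],
             character(1L))
    }, character(length(panel))), nrow = length(panel))
  })
  aucs <- vapply(seq_len(n_perm), function(i) {
    sites <- draws[, i]
    if (identical(sites, panel)) baseline else score_panel(sites)
  }, numeric(1L))
  list(
    aucs = aucs,
    mean_auc = mean(aucs),
    ci = unname(stats::quantile(aucs, c(0.025, 0.975))),
    baseline_auc = baseline
  )
}

#' Noise-injection robustness sweep
#'
#' Adds independent uniform noise in `(-delta, +delta)` to every beta
#' value of the panel sites in the test matrix (model fixed), clips back
#' to `[0,1]`, and scores AUC; repeated `iterations_per_delta` times per
#' noise level. At `delta = 0` every iteration reproduces the noise-free
#' baseline exactly.
#'
#' @param model A `panel_model` (binary task).
#' @param test A labeled [beta_matrix()] containing the panel sites.
#' @param deltas Increasing vector of noise half-widths in `[0, 1]`.
#' @param iterations_per_delta Monte-Carlo iterations per level
#'   (published protocol: 1000).
#' @param seed Seed for the noise draws.
#' @return List with `baseline_auc` and `results`, a `data.frame` of
#'   `delta`, `mean_auc`, `sd_auc`.
#' @export
noise_robustness <- function(model, test, deltas = seq(0, 1, by = 0.1),
                             iterations_per_delta = 1000L, seed = 1L) {
  stopifnot(inherits(model, "panel_model"), inherits(test, "beta_matrix"),
            iterations_per_delta >= 1L)
  if (is.unsorted(deltas) || any(deltas < 0) || any(deltas > 1)) {
    stop("`deltas` must be ascending values in [0, 1]", call. = FALSE)
  }
  labels <- droplevels(test$labels)
  if (nlevels(labels) != 2L) {
    stop("noise-robustness AUC is defined for binary tasks", call. = FALSE)
  }
  pos <- model$positive_class
  feats <- t(test$values[model$panel_sites, , drop = FALSE])
  score <- function(f) {
    p <- stats::predict(model$forest, data = f, num.threads = 1L)$predictions
    colnames(p) <- colnames(model$forest$predictions) %||% levels(labels)
    auc_rank(p[, pos], labels == pos)
  }
  baseline <- score(feats)
  rows <- with_seed(seed, {
    lapply(deltas, function(d) {
      aucs <- vapply(seq_len(iterations_per_delta), function(i) {
        noise <- if (d == 0) 0 else stats::runif(length(feats), -d, d)
        noisy <- pmin(pmax(feats + noise, 0), 1)
        score(noisy)
      }, numeric(1L))
      data.frame(delta = d, mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
    })
  })
  list(baseline_auc = baseline, results = do.call(rbind, rows))
}

#' K-means heterogeneity clustering on panel sites
#'
#' Clusters samples (optionally restricted to one class, e.g. tumors) by
#' their beta profile over the panel sites, exposing methylation subtypes
#' that share a pattern across the panel.
#'
#' @param x A [beta_matrix()].
#' @param panel_sites Sites defining the profile.
#' @param k Number of clusters, >= 2 and at most the number of (filtered)
#'   samples.
#' @param class_filter Optional class label; only samples of that class
#'   are clustered.
#' @param nstart Random restarts, default 10.
#' @param seed Seed for the restarts.
#' @return List with `assignments` (named integer vector) and `centers`
#'   (k x sites matrix).
#' @export
cluster_samples <- function(x, panel_sites, k, class_filter = NULL,
                            nstart = 10L, seed = 1L) {
  stopifnot(inherits(x, "beta_matrix"))
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  keep <- if (is.null(class_filter)) colnames(x$values) else {
    if (!class_filter %in% levels(x$labels)) {
      stop("class_filter '", class_filter, "' is not a class level",
           call. = FALSE)
    }
    names(x$labels)[x$labels == class_filter]
  }
  if (length(keep) < k) {
    stop("k = ", k, " exceeds the ", length(keep),
         " samples available after filtering", call. = FALSE)
  }
  feats <- t(x$values[panel_sites, keep, drop = FALSE])
  if (nrow(unique(feats)) < k) {
    stop("degenerate input: only ", nrow(unique(feats)),
         " distinct sample profiles for k = ", k, " clusters", call. = FALSE)
  }
  km <- with_seed(seed, stats::kmeans(feats, centers = k, nstart = nstart))
  list(assignments = stats::setNames(km$cluster, keep), centers = km$centers)
}
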