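test_that("correlated-site discovery honours the signed strict threshold", {
  withr::with_seed(91, {
    n <- 200
    base <- stats::runif(n, 0.2, 0.8)
    vals <- rbind(
      cg0000001 = base,
      cg0000002 = base,                         # exact duplicate, r = 1
      cg0000003 = 1 - base,                     # mirror, r = -1
      cg0000004 = stats::runif(n, 0.2, 0.8),    # independent
      cg0000005 = rep(0.5, n)                   # zero variance
    )
    colnames(vals) <- paste0("s", seq_len(n))
    bm <- beta_matrix(vals, stats::setNames(rep(c("N", "T"), each = n / 2),
                                            colnames(vals)))
    expect_message(
      cl <- find_correlated_sites(bm, "cg0000001"),
      "zero-variance")
    expect_equal(cl$cg0000001$site_id, "cg0000002")
    expect_equal(cl$cg0000001$r, 1, tolerance = 1e-12)

    # reported r equals the direct covariance-formula computation
    x <- vals["cg0000001", ]; y <- vals["cg0000002", ]
    r_direct <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cl$cg0000001$r, r_direct, tolerance = 1e-12)
  })
})

test_that("independent noise sites are never reported as correlated", {
  withr::with_seed(92, {
    n <- 200
    vals <- matrix(stats::runif(30 * n, 0.2, 0.8), nrow = 30,
                   dimnames = list(sprintf("cg%07d", 1:30),
                                   paste0("s", seq_len(n))))
    bm <- beta_matrix(vals, stats::setNames(rep(c("N", "T"), each = n / 2),
                                            colnames(vals)))
    cl <- find_correlated_sites(bm, rownames(vals)[1:5])
    expect_true(all(vapply(cl, nrow, integer(1)) == 0L))
  })
})

test_that("Kuncheva index reproduces its worked values and guards degeneracy", {
  expect_equal(kuncheva_index(list(c("a", "b"), c("a", "b"), c("a", "b")),
                              N_total = 10), 1, tolerance = 1e-12)
  expect_equal(kuncheva_index(list(c("a", "b"), c("c", "d")), N_total = 10),
               -0.25, tolerance = 1e-12)
  expect_equal(kuncheva_index(list(c("a", "b", "c"), c("a", "b", "d")),
                              N_total = 100), 191 / 291, tolerance = 1e-12)

  expect_error(kuncheva_index(list(c("a")), 10), "at least two")
  expect_error(kuncheva_index(list(character(0), c("a")), 10), "0 < s")
  expect_error(kuncheva_index(list(c("a", "b"), c("a", "b")), 2), "0 < s")
  expect_error(kuncheva_index(list(c("a", "b"), c("a")), 10, mode = "strict"),
               "equal subset sizes")
  # the unequal-size generalisation matches its pairwise oracle
  withr::with_seed(93, {
    universe <- sprintf("f%03d", 1:40)
    fams <- replicate(6, sample(universe, sample(2:10, 1)), simplify = FALSE)
    expect_equal(kuncheva_index(fams, 40), kuncheva_oracle(fams, 40),
                 tolerance = 1e-12)
  })
})

test_that("interchange with degenerate clusters reproduces the baseline exactly", {
  coh <- generate_cohort(separable_spec(seed = 94))
  test <- generate_cohort(separable_spec(seed = 95))
  panel <- coh$truth$informative$site_id[1:2]
  model <- fit_panel(coh$matrix, panel, selection_config(P = 5, seed = 6))

  # empty clusters: every permutation is the baseline panel
  model$correlated_clusters <- stats::setNames(
    replicate(2, data.frame(site_id = character(0), r = numeric(0)),
              simplify = FALSE), panel)
  res <- interchange_test(coh$matrix, test$matrix, model, n_perm = 25, seed = 1)
  expect_true(all(res$aucs == res$baseline_auc))
  expect_equal(res$ci, rep(res$baseline_auc, 2))

  # clusters of exact duplicate columns: identical feature values, so
  # every refit and AUC is bit-identical to the baseline
  dup_vals <- coh$matrix$values[panel, , drop = FALSE]
  rownames(dup_vals) <- paste0(panel, "dup")
  train2 <- beta_matrix(rbind(coh$matrix$values, dup_vals), coh$matrix$labels)
  dup_test <- test$matrix$values[panel, , drop = FALSE]
  rownames(dup_test) <- paste0(panel, "dup")
  test2 <- beta_matrix(rbind(test$matrix$values, dup_test), test$matrix$labels)
  model2 <- fit_panel(train2, panel, selection_config(P = 5, seed = 6))
  model2$correlated_clusters <- find_correlated_sites(train2, panel)
  for (ps in panel) {
    expect_true(paste0(ps, "dup") %in% model2$correlated_clusters[[ps]]$site_id)
  }
  res2 <- interchange_test(train2, test2, model2, n_perm = 40, seed = 2)
  expect_true(all(res2$aucs == res2$baseline_auc))

  expect_error(interchange_test(coh$matrix, test$matrix, model, n_perm = 0),
               "n_perm")
})

test_that("zero noise is bit-identical to plain evaluation", {
  coh <- generate_cohort(separable_spec(seed = 96))
  test <- generate_cohort(separable_spec(seed = 97))
  model <- fit_panel(coh$matrix, coh$truth$informative$site_id,
                     selection_config(P = 5, seed = 8))
  nr <- noise_robustness(model, test$matrix, deltas = 0,
                         iterations_per_delta = 10, seed = 3)
  expect_identical(nr$results$mean_auc, nr$baseline_auc)
  expect_identical(nr$results$sd_auc, 0)
  ev <- evaluate_model(model, test$matrix, n_boot = 0)
  expect_identical(nr$baseline_auc, ev$auc)
})

test_that("bootstrap stability of a dominant marker family is perfect", {
  coh <- generate_cohort(stable_family_spec(seed = 98))
  cfg <- selection_config(P = 5, rlr_iterations = 60L, cv_folds = 5L,
                          sweep_trees = 300L, seed = 10)
  res <- stability_experiment(coh$matrix, delta_beta = 0.2, config = cfg,
                              n_boot = 6L, sample_fraction = 0.9, seed = 12)
  family <- c("cg5000001", coh$truth$blocks$cg5000001)
  # each run selects some family member; augmentation completes the family
  expect_true(all(vapply(res$subsets, setequal, logical(1), family)))
  expect_equal(res$kuncheva, 1, tolerance = 1e-12)
  expect_equal(res$kuncheva, kuncheva_oracle(res$subsets, res$N_total),
               tolerance = 1e-12)
  expect_equal(res$n_failed, 0L)
})

test_that("k-means on panel sites recovers planted subtypes", {
  withr::with_seed(99, {
    # two tumor subtypes with disjoint marker profiles over two sites
    n <- 40
    sub <- rep(1:2, each = n / 2)
    vals <- rbind(
      cg0000001 = ifelse(sub == 1, 0.85, 0.15) + stats::rnorm(n, 0, 0.02),
      cg0000002 = ifelse(sub == 2, 0.85, 0.15) + stats::rnorm(n, 0, 0.02)
    )
    vals <- pmin(pmax(vals, 0), 1)
    colnames(vals) <- paste0("t", seq_len(n))
    labs <- stats::setNames(c(rep("T", n - 2), "N", "N"), colnames(vals))
    bm <- beta_matrix(vals, labs)

    cl <- cluster_samples(bm, rownames(vals), k = 2, class_filter = "T",
                          seed = 5)
    truth <- sub[seq_len(n - 2)]
    agree <- mean(cl$assignments == truth)
    expect_true(agree %in% c(0, 1)) # exact recovery up to label swap

    expect_error(cluster_samples(bm, rownames(vals), k = 1), "at least 2")
    expect_error(cluster_samples(bm, rownames(vals), k = 50), "exceeds")

    flat <- beta_matrix(matrix(0.5, 2, 6,
                               dimnames = list(c("cg0000001", "cg0000002"),
                                               paste0("s", 1:6))),
                        stats::setNames(rep(c("N", "T"), 3), paste0("s", 1:6)))
    expect_error(cluster_samples(flat, c("cg0000001", "cg0000002"), k = 2),
                 "degenerate")
  })
})
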