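test_that("stability selection scores planted signal high and pure noise low", {
  # one perfectly separating site among 199 noise sites, 50 samples
  spec <- synthetic_spec(
    n_samples_per_class = c(N = 25L, T = 25L),
    n_noise_sites = 199L,
    informative = list(list(delta = 0.8, base_mean = 0.1, sd = 0.02)),
    seed = 41
  )
  bm <- generate_cohort(spec)$matrix
  cfg <- selection_config(rlr_iterations = 200L, seed = 7)
  res <- stability_select(bm, cfg)
  expect_gte(res$frequency[["cg5000001"]], 0.9)
  expect_true("cg5000001" %in% res$selected)

  # pure noise: no site approaches the planted site's near-certain
  # frequency, and an empty candidate set is legal and reported
  noise <- synthetic_spec(n_samples_per_class = c(N = 25L, T = 25L),
                          n_noise_sites = 60L, seed = 42)
  bm0 <- generate_cohort(noise)$matrix
  cfg0 <- selection_config(rlr_iterations = 200L,
                           rlr_frequency_threshold = 0.95, seed = 7)
  msg <- capture_messages(res0 <- stability_select(bm0, cfg0))
  expect_lt(max(res0$frequency), 0.95)
  expect_length(res0$selected, 0L)
  expect_match(paste(msg, collapse = " "), "empty candidate set")
})

test_that("duplicated informative columns share selection credit", {
  spec <- synthetic_spec(
    n_samples_per_class = c(N = 25L, T = 25L),
    n_noise_sites = 60L,
    informative = list(list(delta = 0.6, base_mean = 0.15, sd = 0.05)),
    correlation_blocks = list(list(source = 1L, n_copies = 1L,
                                   jitter_sd = 0.005)),
    seed = 43
  )
  bm <- generate_cohort(spec)$matrix
  res <- stability_select(bm, selection_config(rlr_iterations = 200L, seed = 9))
  # random subsampling lets each near-duplicate carry the signal in some
  # rounds, so both accumulate non-zero frequency
  expect_gt(res$frequency[["cg5000001"]], 0)
  expect_gt(res$frequency[["cg5000001_cor1"]], 0)
})

test_that("forest importances are normalised, deterministic, and rank planted signal first", {
  coh <- generate_cohort(synthetic_spec(
    n_samples_per_class = c(N = 25L, T = 25L),
    n_noise_sites = 20L,
    informative = list(list(delta = 0.6, base_mean = 0.15, sd = 0.04)),
    seed = 44
  ))
  bm <- coh$matrix
  cfg <- selection_config(seed = 11)
  cands <- rownames(bm$values)
  imp <- rf_importances(bm, cands, cfg)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "cg5000001")
  expect_identical(imp, rf_importances(bm, cands, cfg)) # same seed, same result

  expect_equal(rf_importances(bm, "cg5000001", cfg),
               c(cg5000001 = 1.0))
  expect_error(rf_importances(bm, character(0), cfg), "empty")
  expect_error(rf_importances(bm, "cg9999999", cfg), "absent")
})

test_that("threshold sweep enumerates distinct importances with tied sites moving together", {
  coh <- generate_cohort(separable_spec(seed = 45, n_noise = 10L))
  bm <- coh$matrix
  cfg <- selection_config(cv_folds = 5L, sweep_trees = 300L, seed = 13)

  sites <- rownames(bm$values)[1:5]
  imp_distinct <- stats::setNames(c(0.4, 0.25, 0.2, 0.1, 0.05), sites)
  curve <- threshold_sweep(bm, imp_distinct, cfg)
  expect_equal(curve$points$n_sites, 5:1)
  expect_true(all(diff(curve$points$threshold) > 0))
  expect_equal(curve$site_sets[[5]], sites[1])

  imp_tied <- stats::setNames(c(0.4, 0.3, 0.3, 0.2, 0.1), sites)
  curve_t <- threshold_sweep(bm, imp_tied, cfg)
  # the tied pair moves as a group: sizes jump 3 -> 1, size 2 unreachable
  expect_equal(curve_t$points$n_sites, c(5L, 4L, 3L, 1L))
  expect_true(all(c(sites[2], sites[3]) %in% curve_t$site_sets[[3]]))

  # separable planted signal drives the best subset's CV LogLoss near zero
  strong <- coh$truth$informative$site_id
  imp_real <- rf_importances(subset_beta(bm, sites = delta_beta_filter(bm, 0.2)),
                             strong, cfg)
  curve_r <- threshold_sweep(bm, imp_real, cfg)
  expect_lt(min(curve_r$points$logloss_mean), 0.05)
  expect_true(all(curve_r$points$logloss_se >= 0))
})

test_that("one-SE rule picks the smallest panel within one standard error", {
  mk_curve <- function(n_sites, mean, se) {
    structure(list(
      points = data.frame(threshold = seq_along(n_sites),
                          n_sites = n_sites, logloss_mean = mean,
                          logloss_se = se, precision = 1, recall = 1),
      site_sets = lapply(n_sites, function(k) sprintf("cg%07d", seq_len(k)))
    ), class = "selection_curve")
  }
  # worked example: min at 5 sites (0.28 +/- 0.05); the 3-site point
  # (0.30 < 0.33) qualifies, the 1-site point (0.90) does not
  curve <- mk_curve(c(1L, 3L, 5L, 9L),
                    c(0.90, 0.30, 0.28, 0.29),
                    c(0.05, 0.04, 0.05, 0.03))
  pick <- one_se_select(curve, P = 10)
  expect_equal(pick$n_sites, 3L)
  expect_equal(pick$site_ids, sprintf("cg%07d", 1:3))

  # strictly decreasing loss with gaps beyond one SE: the minimum wins
  curve2 <- mk_curve(c(1L, 3L, 5L), c(0.9, 0.5, 0.1), c(0.05, 0.05, 0.05))
  expect_equal(one_se_select(curve2, P = 10)$n_sites, 5L)

  # size limit excludes every point -> actionable error
  curve3 <- mk_curve(c(5L, 9L), c(0.4, 0.3), c(0.05, 0.05))
  expect_error(one_se_select(curve3, P = 3), "increase P")
  # P restricts the local-minimum search window
  expect_equal(one_se_select(curve2, P = 3)$n_sites, 3L)
})

test_that("one-SE choice matches a brute-force scan on random curves", {
  withr::with_seed(77, {
    for (i in 1:200) {
      curve <- random_curve(sample(2:12, 1))
      P <- sample(1:50, 1)
      if (!any(curve$points$n_sites <= P)) next
      expect_equal(one_se_select(curve, P)$n_sites,
                   one_se_oracle_size(curve, P))
    }
  })
})

test_that("final panel fit is reproducible and accurate on separable data", {
  coh <- generate_cohort(separable_spec(seed = 46))
  bm <- coh$matrix
  cfg <- selection_config(P = 5, seed = 17)
  site <- coh$truth$informative$site_id[1]

  model <- fit_panel(bm, site, cfg)
  prob <- predict(model, bm)
  truth_p <- prob[cbind(seq_len(ncol(bm$values)),
                        as.integer(bm$labels))]
  expect_true(all(truth_p >= 0.9)) # one perfect site classifies training cohort

  # identical refit produces byte-identical model files
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_panel_model(fit_panel(bm, site, cfg), f1)
  save_panel_model(fit_panel(bm, site, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(fit_panel(bm, "cg9999999", cfg), "absent")
  expect_error(fit_panel(bm, coh$truth$informative$site_id[1:4],
                         selection_config(P = 2)), "exceeding P")
})

test_that("the whole pipeline is a pure function of data, config and seed", {
  coh <- generate_cohort(separable_spec(seed = 47, n_noise = 40L))
  cfg <- selection_config(P = 5, rlr_iterations = 80L, cv_folds = 5L,
                          sweep_trees = 300L, seed = 19)
  m1 <- run_select(coh$matrix, 0.2, cfg)
  m2 <- run_select(coh$matrix, 0.2, cfg)
  expect_identical(m1$panel_sites, m2$panel_sites)
  expect_identical(m1$curve$points, m2$curve$points)
  expect_identical(predict(m1, coh$matrix), predict(m2, coh$matrix))
  expect_true(length(m1$panel_sites) <= cfg$P)
  expect_true(all(m1$panel_sites %in% m1$survivors))

  expect_error(run_select(coh$matrix, 0.99, cfg), "delta_beta_filter")
})
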