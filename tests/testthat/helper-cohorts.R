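# Reusable fixtures (built in code) and independent oracles.

tiny_beta <- function() {
  vals <- matrix(c(0.10, 0.12, 0.35, 0.33,
                   0.50, 0.52, 0.48, 0.51,
                   0.80, 0.82, 0.20, 0.22),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("cg0000001", "cg0000002", "cg0000003"),
                                 c("s1", "s2", "s3", "s4")))
  beta_matrix(vals, c(s1 = "N", s2 = "N", s3 = "T", s4 = "T"))
}

# cleanly separable cohort: a few strong whole-class markers plus noise
separable_spec <- function(seed, n = c(N = 30L, T = 30L), mislabeled = 0L,
                           n_strong = 4L, n_noise = 60L) {
  synthetic_spec(
    n_samples_per_class = n,
    n_noise_sites = n_noise,
    informative = lapply(seq_len(n_strong), function(i) {
      list(delta = 0.7, base_mean = 0.12, sd = 0.03)
    }),
    mislabeled = mislabeled,
    seed = seed
  )
}

# one dominant marker family (source + 3 near-duplicate copies) plus three
# weaker independent survivors: every pipeline run picks one family member
# and correlation augmentation completes the family, so augmented panels
# are identical across bootstrap runs
stable_family_spec <- function(seed, n = c(N = 40L, T = 40L)) {
  synthetic_spec(
    n_samples_per_class = n,
    n_noise_sites = 100L,
    informative = c(
      list(list(delta = 0.7, base_mean = 0.10, sd = 0.03)),
      lapply(1:3, function(i) list(delta = 0.28, base_mean = 0.30, sd = 0.13))
    ),
    correlation_blocks = list(list(source = 1L, n_copies = 3L,
                                   jitter_sd = 0.01)),
    seed = seed
  )
}

planted_universe <- function(truth) {
  c(truth$informative$site_id, unlist(truth$blocks, use.names = FALSE))
}

private_family <- function(truth) {
  priv <- truth$informative$site_id[truth$informative$subtypes == "1"]
  c(priv, unlist(truth$blocks[intersect(names(truth$blocks), priv)],
                 use.names = FALSE))
}

# random selection curve with strictly decreasing subset sizes
random_curve <- function(n_points) {
  n_sites <- sort(sample(50L, n_points))
  structure(list(
    points = data.frame(
      threshold = seq_len(n_points) / n_points,
      n_sites = n_sites,
      logloss_mean = stats::runif(n_points, 0, 1.5),
      logloss_se = stats::runif(n_points, 0, 0.3),
      precision = stats::runif(n_points),
      recall = stats::runif(n_points)
    ),
    site_sets = lapply(n_sites, function(k) sprintf("cg%07d", seq_len(k)))
  ), class = "selection_curve")
}

# brute-force scan for the one-standard-error rule: enumerate every
# point within the size limit, find the loss minimum, keep all points
# strictly inside min + se, and take the smallest (ties -> lower loss)
one_se_oracle_size <- function(curve, P) {
  pts <- curve$points
  elig <- pts[pts$n_sites >= 1 & pts$n_sites <= P, , drop = FALSE]
  m <- elig[which.min(elig$logloss_mean), , drop = FALSE]
  qual <- elig[elig$logloss_mean < m$logloss_mean + m$logloss_se, ,
               drop = FALSE]
  if (!nrow(qual)) return(m$n_sites)
  qual <- qual[order(qual$n_sites, qual$logloss_mean), , drop = FALSE]
  qual$n_sites[1L]
}

# direct pairwise recomputation of the stability index (unequal-size form,
# identical to the published formula for equal sizes)
kuncheva_oracle <- function(subsets, N) {
  k <- length(subsets)
  total <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      si <- length(subsets[[i]])
      sj <- length(subsets[[j]])
      r <- sum(subsets[[i]] %in% subsets[[j]])
      total <- total + (r * N - si * sj) /
        sqrt(si * (N - si) * sj * (N - sj))
    }
  }
  2 * total / (k * (k - 1))
}
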