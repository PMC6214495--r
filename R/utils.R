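# Internal helpers: seeding, stratification, class weights.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so package functions never
#' perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a fixed number of child seeds from one master seed
#'
#' All stage-level randomness flows through seeds produced here, so a run
#' is a pure function of (data, config, master seed).
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Stratified fold assignment for cross-validation
#'
#' Shuffles within each class, then deals fold ids round-robin so every
#' fold contains every class whenever k does not exceed the smallest
#' class size.
#' @noRd
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  n_min <- min(table(labels))
  if (k > n_min) {
    stop("cv_folds (", k, ") exceeds the smallest class size (", n_min,
         "); stratified folds cannot be constructed", call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  for (f in seq_len(k)) {
    if (nlevels(droplevels(labels[folds != f])) < nlevels(labels)) {
      stop("internal error: fold ", f, " training split lost a class",
           call. = FALSE)
    }
  }
  folds
}

#' Stratified subsample indices (without replacement)
#' @noRd
stratified_subsample <- function(labels, fraction) {
  labels <- as.factor(labels)
  idx <- integer(0)
  for (cl in levels(labels)) {
    pool <- which(labels == cl)
    take <- max(1L, round(fraction * length(pool)))
    idx <- c(idx, sample(pool, take))
  }
  sort(idx)
}

#' Per-sample weights inversely proportional to class frequency
#' @noRd
inverse_class_weights <- function(labels) {
  labels <- as.factor(labels)
  tab <- table(labels)
  w <- length(labels) / (nlevels(labels) * as.numeric(tab[labels]))
  as.numeric(w)
}

#' Mann-Whitney rank AUC for a binary task
#'
#' Midranks handle ties; equals the probability that a random positive
#' scores above a random negative.
#' @noRd
auc_rank <- function(scores, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need both classes present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
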