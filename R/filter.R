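#' Beta value from methylated/unmethylated probe intensities
#'
#' The standard Illumina summary of per-probe methylation:
#' `M / (M + U + offset)`, with the offset (default 100) regularising
#' low-intensity probes. Bounded in `[0, 1)` whenever `offset > 0`.
#'
#' @param methylated,unmethylated Non-negative intensity vectors (recycled).
#' @param offset Non-negative regularising constant, default 100.
#' @return Numeric vector of beta values.
#' @examples
#' compute_beta(900, 0)       # 0.9
#' compute_beta(4950, 4950)   # 0.495
#' @export
compute_beta <- function(methylated, unmethylated, offset = 100) {
  if (any(methylated < 0) || any(unmethylated < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (any(offset < 0)) stop("offset must be non-negative", call. = FALSE)
  denom <- methylated + unmethylated + offset
  if (any(denom == 0)) {
    stop("M + U + offset is zero; beta undefined", call. = FALSE)
  }
  methylated / denom
}

#' Differential-mean (delta-beta) prefilter
#'
#' Keeps a site iff at least one pair of classes differs in mean beta by
#' strictly more than `delta_beta`. With C classes all C(C-1)/2 pairs are
#' scanned; boundary equality removes the site. Input site order is
#' preserved in the output.
#'
#' @param x A [beta_matrix()] with at least two non-empty classes.
#' @param delta_beta Minimum between-class mean difference, in `(0, 1)`.
#'   Default 0.2.
#' @return Character vector of surviving site ids, in input order.
#' @export
delta_beta_filter <- function(x, delta_beta = 0.2) {
  stopifnot(inherits(x, "beta_matrix"))
  if (!is.numeric(delta_beta) || length(delta_beta) != 1L ||
      delta_beta <= 0 || delta_beta >= 1) {
    stop("`delta_beta` must be a single value in (0, 1)", call. = FALSE)
  }
  check_classes(x, min_classes = 2L, min_n = 1L)
  labels <- droplevels(x$labels)
  # per-class mean beta of every site: sites x classes
  class_means <- vapply(levels(labels), function(cl) {
    rowMeans(x$values[, labels == cl, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (is.null(dim(class_means))) {
    class_means <- matrix(class_means, nrow = 1L,
                          dimnames = list(rownames(x$values), levels(labels)))
  }
  max_gap <- apply(class_means, 1L, function(m) max(m) - min(m))
  rownames(x$values)[max_gap > delta_beta]
}
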