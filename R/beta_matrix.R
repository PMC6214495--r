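#' Construct a validated beta-value matrix
#'
#' The central container of the package: a sites x samples matrix of
#' methylation beta values (fractions in `[0,1]`) together with one class
#' label per sample (e.g. tumor / non-tumor). All pipeline stages consume
#' and produce this object.
#'
#' @param values Numeric matrix, sites as rows and samples as columns,
#'   with unique non-empty `rownames` (CpG ids such as `"cg02361803"`) and
#'   `colnames` (sample ids). Every entry must be finite and in `[0,1]`.
#' @param labels Class labels, one per sample: either a vector in column
#'   order or a named vector keyed by sample id. Coerced to factor.
#'
#' @return An object of class `beta_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (named factor, one level per class).
#'
#' @examples
#' vals <- matrix(runif(12), 3, 4,
#'                dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' bm <- beta_matrix(vals, c("T", "T", "N", "N"))
#' bm
#' @export
beta_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  site_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(site_ids) || is.null(sample_ids) ||
      any(!nzchar(site_ids)) || any(!nzchar(sample_ids))) {
    stop("`values` needs non-empty rownames (site ids) and colnames (sample ids)",
         call. = FALSE)
  }
  dup_site <- site_ids[duplicated(site_ids)]
  dup_sample <- sample_ids[duplicated(sample_ids)]
  if (length(dup_site) || length(dup_sample)) {
    stop("duplicate ids: ",
         paste(c(if (length(dup_site)) paste0("sites [", toString(unique(dup_site)), "]"),
                 if (length(dup_sample)) paste0("samples [", toString(unique(dup_sample)), "]")),
               collapse = "; "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    show <- utils::head(bad, 5L)
    msg <- apply(show, 1L, function(ij) {
      sprintf("site %s / sample %s = %s",
              site_ids[ij[1L]], sample_ids[ij[2L]],
              format(values[ij[1L], ij[2L]]))
    })
    stop("beta values must be finite and within [0,1]; offending cells: ",
         paste(msg, collapse = "; "),
         if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L),
         call. = FALSE)
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      stop("labels missing for samples: ", toString(missing), call. = FALSE)
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != ncol(values)) {
    stop("need one label per sample (", ncol(values), "), got ",
         length(labels), call. = FALSE)
  }
  labels <- factor(as.character(labels))
  names(labels) <- sample_ids
  if (anyNA(labels)) {
    stop("labels contain NA for samples: ",
         toString(sample_ids[is.na(labels)]), call. = FALSE)
  }
  structure(list(values = values, labels = labels), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("beta_matrix: %d sites x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Restrict a beta matrix to a subset of sites and/or samples
#'
#' @param x A [beta_matrix()].
#' @param sites,samples Character ids (or indices) to keep; `NULL` keeps all.
#' @return A `beta_matrix` with the requested subset, label levels dropped
#'   to the classes still present.
#' @export
subset_beta <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "beta_matrix"))
  v <- x$values
  if (!is.null(sites)) {
    if (is.character(sites)) {
      missing <- setdiff(sites, rownames(v))
      if (length(missing)) {
        stop("sites absent from matrix: ", toString(missing), call. = FALSE)
      }
    }
    v <- v[sites, , drop = FALSE]
  }
  lab <- x$labels
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, colnames(v))
      if (length(missing)) {
        stop("samples absent from matrix: ", toString(missing), call. = FALSE)
      }
    }
    v <- v[, samples, drop = FALSE]
    lab <- droplevels(lab[colnames(v)])
  }
  beta_matrix(v, lab)
}

# internal: require at least `min_classes` classes, each with >= min_n samples
check_classes <- function(x, min_classes = 2L, min_n = 1L) {
  tab <- table(droplevels(x$labels))
  if (length(tab) < min_classes) {
    stop("need at least ", min_classes, " classes, found ", length(tab),
         call. = FALSE)
  }
  if (any(tab < min_n)) {
    stop("classes with fewer than ", min_n, " samples: ",
         toString(names(tab)[tab < min_n]), call. = FALSE)
  }
  invisible(TRUE)
}
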