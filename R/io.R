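# Boundary I/O: delimited beta matrices, sample sheets, site annotation,
# and JSON model serialization. All validation happens here, with cell
# coordinates in every error, so downstream stages can assume clean input.

MODEL_SCHEMA_VERSION <- "methpanel-model/1"

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from a delimited file
#'
#' Reads a TSV/CSV table (GEO-series-matrix style: one id column/row plus a
#' numeric body) into a validated [beta_matrix()]. Orientation may be given
#' explicitly or auto-detected.
#'
#' @param path File path; `.csv` implies comma separation, anything else tab.
#' @param labels Named vector of class labels keyed by sample id (e.g. from
#'   [read_labels()]). Required — a `beta_matrix` always carries labels —
#'   and used by `dialect = "auto"` to resolve orientation.
#' @param dialect `"sites"` (sites as rows, the Illumina/GEO default),
#'   `"samples"` (samples as rows; the table is transposed), or `"auto"`:
#'   the side whose ids match `names(labels)` is taken to be the samples;
#'   if that is ambiguous, ids matching the `cg<digits>` probe pattern
#'   decide; as a last resort sites-as-rows is assumed with a message.
#' @param sep Field separator; default guessed from the extension.
#'
#' @return A [beta_matrix()].
#'
#' @details Duplicate ids, non-numeric cells, `NA`/`NaN`, and values outside
#'   `[0,1]` are rejected with the offending site/sample coordinates.
#'   Missing values are never imputed: imputation would silently change
#'   which sites are selected downstream.
#' @export
read_beta_matrix <- function(path, labels,
                             dialect = c("auto", "sites", "samples"),
                             sep = guess_sep(path)) {
  dialect <- match.arg(dialect)
  if (is.null(names(labels))) {
    stop("`labels` must be named by sample id", call. = FALSE)
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  m <- as.matrix(raw)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    coord <- if (nrow(bad)) {
      sprintf(" (e.g. row %s / column %s = %s)", rownames(raw)[bad[1, 1]],
              colnames(raw)[bad[1, 2]], m[bad[1, 1], bad[1, 2]])
    } else ""
    stop("non-numeric cells in ", path, coord, call. = FALSE)
  }
  sample_names <- names(labels)
  orient_sites <- switch(
    dialect,
    sites = TRUE,
    samples = FALSE,
    auto = {
      in_cols <- mean(colnames(m) %in% sample_names)
      in_rows <- mean(rownames(m) %in% sample_names)
      if (in_cols > in_rows) TRUE
      else if (in_rows > in_cols) FALSE
      else {
        cg_rows <- mean(grepl("^cg\\d+$", rownames(m)))
        cg_cols <- mean(grepl("^cg\\d+$", colnames(m)))
        if (cg_cols > cg_rows) FALSE else {
          if (cg_rows == cg_cols) {
            message("orientation ambiguous; assuming sites as rows")
          }
          TRUE
        }
      }
    }
  )
  if (!orient_sites) m <- t(m)
  na_cells <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na_cells)) {
    show <- utils::head(na_cells, 5L)
    stop("missing values are not allowed (no imputation rule); cells: ",
         paste(sprintf("site %s / sample %s", rownames(m)[show[, 1]],
                       colnames(m)[show[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  beta_matrix(m, labels)
}

#' Write a beta matrix to a delimited file
#'
#' Sites as rows, a leading `site_id` column, samples as columns.
#' @param x A [beta_matrix()].
#' @param path Output path; `.csv` implies comma separation.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, sep = guess_sep(path)) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(site_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample class labels from a sample sheet
#'
#' @param path Delimited file with a header; one row per sample.
#' @param sample_column,label_column Column names (or indices) holding
#'   sample ids and class labels.
#' @param sample_ids Optional character vector (e.g. `colnames` of a beta
#'   matrix) that must be fully covered; extra rows in the sheet are
#'   dropped with a warning, missing samples are an error listing them.
#' @param sep Field separator; guessed from the extension by default.
#' @return Named factor of class labels. At least two classes are required.
#' @export
read_labels <- function(path, sample_column = 1L, label_column = 2L,
                        sample_ids = NULL, sep = guess_sep(path)) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[sample_column]])
  labs <- as.character(df[[label_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         toString(unique(ids[duplicated(ids)])), call. = FALSE)
  }
  names(labs) <- ids
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    if (length(missing)) {
      stop("labels file does not cover samples: ", toString(missing),
           call. = FALSE)
    }
    extra <- setdiff(ids, sample_ids)
    if (length(extra)) {
      warning(length(extra), " labelled sample(s) absent from the matrix ",
              "were ignored: ", toString(utils::head(extra, 5L)),
              call. = FALSE)
      labs <- labs[sample_ids]
    }
  }
  labs <- factor(labs)
  if (nlevels(labs) < 2L) {
    stop("labels define a single class ('", levels(labs),
         "'); classification is undefined", call. = FALSE)
  }
  labs
}

#' Read CpG site annotation in Illumina-manifest column style
#'
#' Expects columns `IlmnID`, `Chr`, `Position`, and optionally gene name /
#' region group columns, as in HM450 manifest extracts.
#'
#' @param path CSV/TSV path.
#' @param sep Field separator; guessed from the extension.
#' @return `data.frame` with columns `site_id`, `chromosome`, `position`
#'   (1-based integer), `gene_name`, `region_group`.
#' @export
read_site_annotation <- function(path, sep = guess_sep(path)) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  pick <- function(cands, default = NULL) {
    hit <- intersect(cands, names(df))
    if (length(hit)) df[[hit[1L]]] else default
  }
  out <- data.frame(
    site_id = as.character(pick(c("IlmnID", "site_id", "probe_id"))),
    chromosome = as.character(pick(c("Chr", "chromosome", "CHR"))),
    position = as.integer(pick(c("Position", "position", "MAPINFO"))),
    gene_name = as.character(pick(c("Gene name", "gene_name", "UCSC_RefGene_Name"),
                                  default = "")),
    region_group = as.character(pick(c("Group", "region_group", "UCSC_RefGene_Group"),
                                     default = "")),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$site_id)) {
    stop("duplicate site ids in annotation: ",
         toString(unique(out$site_id[duplicated(out$site_id)])), call. = FALSE)
  }
  bad <- which(!is.na(out$position) & out$position < 1L)
  if (length(bad)) {
    stop("positions must be 1-based (>= 1); offending sites: ",
         toString(out$site_id[bad]), call. = FALSE)
  }
  out
}

#' Serialize a fitted panel model to JSON
#'
#' Writes a single JSON document containing the panel, the selection curve,
#' correlated-site clusters, all seeds and configuration, and the training
#' beta values restricted to the panel sites. The random forest itself is
#' not dumped: [load_panel_model()] refits it deterministically from the
#' stored training data and seed, so predictions are bit-reproducible
#' across sessions.
#'
#' @param model A `panel_model` from [fit_panel()] or [run_select()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    panel_sites = model$panel_sites,
    positive_class = model$positive_class,
    config = model$config,
    seeds = model$seeds,
    train = list(
      site_ids = rownames(model$train_values),
      sample_ids = colnames(model$train_values),
      values = unname(model$train_values),
      labels = as.character(model$train_labels),
      class_levels = levels(model$train_labels)
    ),
    correlated_clusters = model$correlated_clusters,
    curve = if (!is.null(model$curve)) {
      list(points = model$curve$points, site_sets = model$curve$site_sets)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a panel model saved by [save_panel_model()]
#'
#' @param path `.json` path.
#' @return A `panel_model` whose forest has been refit from the stored
#'   training data under the stored seed; predictions match the saved
#'   model exactly.
#' @export
load_panel_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    stop("unsupported model schema version '", doc$schema_version %||% "<missing>",
         "'; this build reads '", MODEL_SCHEMA_VERSION, "'", call. = FALSE)
  }
  vals <- doc$train$values
  if (!is.matrix(vals)) vals <- do.call(rbind, lapply(vals, unlist))
  dimnames(vals) <- list(doc$train$site_ids, doc$train$sample_ids)
  labels <- factor(doc$train$labels, levels = doc$train$class_levels)
  names(labels) <- doc$train$sample_ids
  train <- beta_matrix(vals, labels)
  config <- do.call(selection_config, doc$config)
  model <- fit_panel(train, doc$panel_sites, config,
                     positive_class = doc$positive_class)
  if (!is.null(doc$correlated_clusters) && length(doc$correlated_clusters)) {
    model$correlated_clusters <- lapply(doc$correlated_clusters, function(cl) {
      data.frame(site_id = as.character(cl$site_id), r = as.numeric(cl$r),
                 stringsAsFactors = FALSE)
    })
  }
  if (!is.null(doc$curve)) {
    model$curve <- structure(
      list(points = as.data.frame(doc$curve$points),
           site_sets = lapply(doc$curve$site_sets, as.character)),
      class = "selection_curve")
  }
  model
}
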