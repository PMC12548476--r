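#' Labeled acoustic-feature table
#'
#' The basic data container of the package: a numeric feature matrix with one
#' row per participant, a binary class label per row (0 = cognitively
#' unimpaired, CU; 1 = cognitively impaired, CI), unique sample identifiers,
#' and an optional per-row site tag recording which virtual institution a row
#' belongs to.
#'
#' @param features numeric matrix, one row per sample. Column names are kept
#'   if present, otherwise `f001...fNNN` are assigned.
#' @param labels integer/numeric vector of 0 (CU) and 1 (CI), one per row.
#' @param sample_ids character vector of unique identifiers, one per row.
#'   Defaults to `s000001...`.
#' @param site optional character vector (or single string, recycled) tagging
#'   each row with an institution.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `features`, `labels`, `sample_ids`, `site`.
#' @export
feature_table <- function(features, labels, sample_ids = NULL, site = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != number of rows (", n, ")")
  }
  if (anyNA(features)) stop("features contain missing values")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (CU) or 1 (CI) with no missing values")
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%06d", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length != number of rows")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (!is.null(site)) {
    site <- as.character(site)
    if (length(site) == 1L) site <- rep(site, n)
    if (length(site) != n) stop("site length != number of rows")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  structure(
    list(features = features, labels = labels,
         sample_ids = sample_ids, site = site),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features | CU: %d  CI: %d\n",
    nrow(x$features), ncol(x$features),
    sum(x$labels == 0L), sum(x$labels == 1L)
  ))
  if (!is.null(x$site)) {
    cat("sites:", paste(sprintf("%s=%d", names(table(x$site)), table(x$site)),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a feature table
#' @param table a `feature_table`
#' @return integer row count
#' @export
n_samples <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  nrow(table$features)
}

#' Subset a feature table by row index
#'
#' @param table a `feature_table`
#' @param idx integer or logical row index
#' @return a `feature_table` containing the selected rows
#' @export
ft_subset <- function(table, idx) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(
    features = table$features[idx, , drop = FALSE],
    labels = table$labels[idx],
    sample_ids = table$sample_ids[idx],
    site = if (is.null(table$site)) NULL else table$site[idx]
  )
}

#' Class composition summary
#'
#' Counts and percentages per class, mirroring how cohort composition tables
#' report prevalence (percentages rounded to one decimal).
#'
#' @param table a `feature_table`
#' @return data.frame with columns `class`, `count`, `percent`
#' @export
cohort_composition <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  n <- n_samples(table)
  counts <- c(CU = sum(table$labels == 0L), CI = sum(table$labels == 1L))
  data.frame(
    class = names(counts),
    count = as.integer(counts),
    percent = round(100 * as.integer(counts) / n, 1),
    row.names = NULL
  )
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(
    sample_id = x$sample_ids,
    site = if (is.null(x$site)) NA_character_ else x$site,
    label = ifelse(x$labels == 1L, "CI", "CU"),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(x$features))
}

#' Write a feature table to CSV
#'
#' Layout: header row with columns `sample_id`, `site`, `label`, then one
#' column per feature. Labels are written as the strings `CU`/`CI`; UTF-8
#' encoding with `.` as the decimal separator.
#'
#' @param table a `feature_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the layout produced by [write_feature_table()]: a header with
#' `sample_id`, `label`, and at least one feature column; an optional `site`
#' column. Label strings are mapped CU -> 0, CI -> 1. Malformed input
#' (missing columns, non-numeric feature cells, unknown label strings) is
#' rejected with the offending row/column named in the message.
#'
#' @param path CSV file path
#' @return a `feature_table`
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty feature table file: ", path)
  required <- c("sample_id", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  meta_cols <- intersect(c("sample_id", "site", "label"), names(df))
  feat_cols <- setdiff(names(df), meta_cols)
  if (length(feat_cols) == 0L) stop("no feature columns found in ", path)

  bad_label <- which(!df$label %in% c("CU", "CI"))
  if (length(bad_label) > 0L) {
    stop("unknown label '", df$label[bad_label[1]], "' at row ",
         bad_label[1], " (expected CU or CI)")
  }
  feats <- df[feat_cols]
  for (col in feat_cols) {
    v <- feats[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L) {
        stop("non-numeric feature value '", v[bad[1]], "' at row ", bad[1],
             ", column ", col)
      }
      feats[[col]] <- vn
    }
    if (anyNA(feats[[col]])) {
      stop("missing feature value at row ", which(is.na(feats[[col]]))[1],
           ", column ", col)
    }
  }
  site <- NULL
  if ("site" %in% names(df) && !all(is.na(df$site) | df$site == "")) {
    site <- as.character(df$site)
  }
  feature_table(
    features = as.matrix(feats),
    labels = ifelse(df$label == "CI", 1L, 0L),
    sample_ids = df$sample_id,
    site = site
  )
}
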