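#' Construct a cohort matrix
#'
#' A cohort matrix holds one row per subject and one column per catalog
#' feature, with binary findings coded 0/1 and continuous features as real
#' numbers. It carries the catalog rows describing its columns and, once
#' \code{\link{minmax_normalize}} has been applied, the per-feature
#' normalization record needed to map new subjects onto the same scale.
#'
#' @param values numeric matrix, subjects x features; column names must be
#'   catalog keys and row names subject identifiers
#' @param catalog catalog rows (see \code{\link{feature_catalog}}) matching
#'   the columns of \code{values}, in order
#' @param normalization \code{NULL}, or a data frame with columns \code{key},
#'   \code{x_min}, \code{x_max} for the continuous features
#' @return an object of class \code{cohort_matrix}
#' @export
cohort_matrix <- function(values, catalog, normalization = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) > 0L &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("subject identifiers must be unique row names")
  if (!identical(colnames(values), catalog$key))
    stop("column names must equal the catalog keys, in catalog order")
  if (anyNA(values))
    stop("cohort matrix must not contain missing values")
  bin <- catalog$value_type == "binary"
  if (any(bin) && !all(values[, bin, drop = FALSE] %in% c(0, 1)))
    stop("binary features must hold only 0 or 1")
  structure(list(values = values, catalog = catalog,
                 normalization = normalization),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$normalization)) "raw" else "normalized"))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$values)

subject_ids <- function(cohort) rownames(cohort$values)

#' Load a cohort table from delimited text
#'
#' Reads a CSV/TSV file whose first column is the subject identifier and whose
#' remaining header names are catalog keys. Binary cells may be encoded
#' (case-insensitively) as \code{Y}/\code{yes}/\code{1} or
#' \code{N}/\code{no}/\code{0}; anything else is a load error naming the
#' offending row and column. Continuous cells must parse as real numbers.
#'
#' @param path file path; \code{.tsv}/\code{.txt} are read tab-separated,
#'   anything else comma-separated
#' @param catalog the catalog (or catalog subset) the table must cover
#' @param impute_missing if \code{TRUE}, empty/NA cells are imputed (binary
#'   to 0, continuous to the cohort median) with a message; the default is to
#'   reject them
#' @return a raw (unnormalized) \code{\link{cohort_matrix}}
#' @export
load_cohort <- function(path, catalog, impute_missing = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("table needs a subject-ID column plus feature columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicate subject identifiers in ", path)
  feats <- raw[, -1L, drop = FALSE]

  unknown <- setdiff(colnames(feats), catalog$key)
  if (length(unknown))
    stop("schema error: unknown feature column(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(catalog$key, colnames(feats))
  if (length(missing))
    stop("schema error: missing feature column(s): ",
         paste(missing, collapse = ", "))
  feats <- feats[, catalog$key, drop = FALSE]

  values <- matrix(NA_real_, nrow(feats), ncol(feats),
                   dimnames = list(ids, catalog$key))
  for (j in seq_len(ncol(feats))) {
    key <- catalog$key[j]
    cell <- feats[[j]]
    if (catalog$value_type[j] == "binary") {
      v <- decode_binary(cell)
      bad <- which(is.na(v) & !is.na(cell))
      if (length(bad))
        stop(sprintf("load error: unparseable binary cell '%s' at row %d, column %s",
                     cell[bad[1L]], bad[1L], key))
    } else {
      v <- suppressWarnings(as.numeric(cell))
      bad <- which(is.na(v) & !is.na(cell))
      if (length(bad))
        stop(sprintf("load error: unparseable numeric cell '%s' at row %d, column %s",
                     cell[bad[1L]], bad[1L], key))
    }
    if (anyNA(v)) {
      if (!impute_missing)
        stop(sprintf("load error: missing value at row %d, column %s (set impute_missing = TRUE to impute)",
                     which(is.na(v))[1L], key))
      fill <- if (catalog$value_type[j] == "binary") 0 else
        stats::median(v, na.rm = TRUE)
      message(sprintf("imputed %d missing value(s) in %s with %s",
                      sum(is.na(v)), key, format(fill)))
      v[is.na(v)] <- fill
    }
    values[, j] <- v
  }
  cohort_matrix(values, catalog)
}

decode_binary <- function(cell) {
  x <- tolower(trimws(cell))
  v <- rep(NA_real_, length(x))
  v[x %in% c("y", "yes", "1")] <- 1
  v[x %in% c("n", "no", "0")] <- 0
  v
}

#' Write a cohort matrix (and its normalization record) to disk
#'
#' Writes the subject-by-feature table as CSV with full numeric precision so
#' that reloading reproduces identical values. If the cohort is normalized
#' and \code{normalization_path} is given, a sidecar tab-separated record
#' \code{key, x_min, x_max} is written alongside.
#'
#' @param cohort a \code{\link{cohort_matrix}}
#' @param path output CSV path
#' @param normalization_path optional sidecar path
#' @export
write_cohort <- function(cohort, path, normalization_path = NULL) {
  vals <- cohort$values
  txt <- matrix(formatC(vals, digits = 17, format = "g"), nrow(vals),
                dimnames = dimnames(vals))
  df <- data.frame(subject_id = rownames(vals), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(normalization_path)) {
    if (is.null(cohort$normalization))
      stop("cohort carries no normalization record")
    utils::write.table(cohort$normalization, normalization_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a normalization sidecar written by \code{\link{write_cohort}}
#' @param path sidecar path
#' @return data frame with columns \code{key}, \code{x_min}, \code{x_max}
#' @export
read_normalization <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric", "numeric"))
}

#' Restrict a cohort to a named feature subset
#'
#' @param cohort a \code{\link{cohort_matrix}} whose features cover the subset
#' @param subset \code{"L"}, \code{"complete"} or \code{"LE"}
#' @return the cohort restricted to the subset columns, in catalog order;
#'   subjects unchanged
#' @export
select_subset <- function(cohort, subset = c("L", "complete", "LE")) {
  subset <- match.arg(subset)
  # resolve the request against the full catalog, so that e.g. asking an
  # 8-feature cohort for the 45-feature subset is a coverage error
  target <- catalog_subset(feature_catalog(), subset)
  missing <- setdiff(target$key, colnames(cohort$values))
  if (length(missing))
    stop("schema error: cohort lacks subset feature(s): ",
         paste(missing, collapse = ", "))
  norm <- cohort$normalization
  if (!is.null(norm)) norm <- norm[norm$key %in% target$key, , drop = FALSE]
  cohort_matrix(cohort$values[, target$key, drop = FALSE], target, norm)
}

#' Min-max normalize the continuous features of a cohort
#'
#' Maps each continuous feature to \code{[0, 1]} via
#' \code{(x - x_min) / (x_max - x_min)} using the cohort-wide minimum and
#' maximum; binary features are untouched. The \code{(x_min, x_max)} pair is
#' stored on the returned cohort so new subjects can be mapped onto the same
#' scale (\code{\link{apply_normalization}}). A constant continuous feature
#' (undefined ratio) normalizes to 0 with a warning. Applying the function to
#' an already-normalized cohort is a no-op, which both makes normalization
#' idempotent and preserves the original record.
#'
#' @param cohort a raw \code{\link{cohort_matrix}}
#' @return the normalized cohort
#' @export
minmax_normalize <- function(cohort) {
  if (!is.null(cohort$normalization)) return(cohort)
  vals <- cohort$values
  cont <- cohort$catalog$key[cohort$catalog$value_type == "continuous"]
  rec <- data.frame(key = character(), x_min = numeric(), x_max = numeric())
  for (key in cont) {
    x <- vals[, key]
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning("constant continuous feature ", key, "; normalized value set to 0")
      vals[, key] <- 0
    } else {
      vals[, key] <- (x - lo) / (hi - lo)
    }
    rec <- rbind(rec, data.frame(key = key, x_min = lo, x_max = hi))
  }
  cohort_matrix(vals, cohort$catalog, rec)
}

#' Apply a stored min-max record to new subjects
#'
#' Uses the training \code{(x_min, x_max)} pairs; values outside the training
#' range are allowed and produce normalized values outside \code{[0, 1]}
#' (reported with a message). A stored constant feature maps to 0.
#'
#' @param cohort a raw \code{\link{cohort_matrix}} of new subjects
#' @param normalization a record as stored by \code{\link{minmax_normalize}}
#' @return the cohort on the training scale
#' @export
apply_normalization <- function(cohort, normalization) {
  if (is.null(normalization))
    stop("no stored normalization record")
  vals <- cohort$values
  cont <- cohort$catalog$key[cohort$catalog$value_type == "continuous"]
  missing <- setdiff(cont, normalization$key)
  if (length(missing))
    stop("normalization record lacks feature(s): ",
         paste(missing, collapse = ", "))
  for (key in cont) {
    i <- match(key, normalization$key)
    lo <- normalization$x_min[i]; hi <- normalization$x_max[i]
    v <- if (hi == lo) rep(0, nrow(vals)) else (vals[, key] - lo) / (hi - lo)
    out <- v < 0 | v > 1
    if (any(out))
      message(sprintf("%d value(s) of %s fall outside the training range",
                      sum(out), key))
    vals[, key] <- v
  }
  cohort_matrix(vals, cohort$catalog,
                normalization[normalization$key %in% cont, , drop = FALSE])
}
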