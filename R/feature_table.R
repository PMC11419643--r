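#' @keywords internal
"_PACKAGE"

# Kaggle stroke-prediction CSV dialect ---------------------------------------

#' Cohort schema in the Kaggle stroke-prediction dialect
#'
#' The cohort CSV dialect has the exact, case-sensitive header
#' `id,gender,age,hypertension,heart_disease,ever_married,work_type,`
#' `Residence_type,avg_glucose_level,bmi,smoking_status,stroke`.
#' The dataset carries 11 input attributes besides the `stroke` target;
#' of these, `id` is a record identifier and is excluded from modelling,
#' leaving 10 modelling predictors.
#'
#' @return a list with components `columns` (all 12 column names in order),
#'   `input_attributes` (the 11 non-target columns), `predictors` (the 10
#'   modelling predictors), `categorical` (categorical predictor names),
#'   `target` (`"stroke"`) and `identifier` (`"id"`).
#' @examples
#' length(cohort_schema()$input_attributes)  # 11
#' @export
cohort_schema <- function() {
  columns <- c("id", "gender", "age", "hypertension", "heart_disease",
               "ever_married", "work_type", "Residence_type",
               "avg_glucose_level", "bmi", "smoking_status", "stroke")
  list(columns = columns,
       input_attributes = setdiff(columns, "stroke"),
       predictors = setdiff(columns, c("id", "stroke")),
       categorical = c("gender", "ever_married", "work_type",
                       "Residence_type", "smoking_status"),
       target = "stroke",
       identifier = "id")
}

# Feature table container -----------------------------------------------------

#' Construct a feature table
#'
#' The in-memory cohort container: a numeric matrix of predictor values with a
#' parallel logical missingness mask, a codebook mapping categorical levels to
#' deterministic integer codes, optional 0/1 stroke labels and record ids.
#' Masked cells are ignored by every downstream statistic.
#'
#' @param values numeric matrix, records x attributes.
#' @param missing_mask logical matrix, same shape as `values`; `TRUE` marks a
#'   missing cell.
#' @param attribute_names character vector of unique attribute names.
#' @param codebook named list; for each categorical attribute, the character
#'   vector of levels in alphabetical order (the integer code of a level is
#'   its position).
#' @param labels optional integer vector of 0/1 stroke labels.
#' @param record_ids optional integer vector of record identifiers.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, missing_mask = NULL, attribute_names = NULL,
                          codebook = list(), labels = NULL,
                          record_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(attribute_names)) attribute_names <- colnames(values)
  if (is.null(attribute_names))
    stop_arg("attribute_names required when values has no column names")
  if (anyDuplicated(attribute_names))
    stop_arg("attribute names must be unique")
  colnames(values) <- attribute_names
  if (is.null(missing_mask))
    missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop_arg("values and missing_mask must have identical shape")
  dimnames(missing_mask) <- dimnames(values)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop_arg("labels length must equal the number of records")
    if (!all(labels %in% c(0L, 1L)))
      stop_arg("labels must contain only 0/1")
  }
  if (is.null(record_ids)) record_ids <- seq_len(nrow(values))
  obj <- structure(list(values = values,
                        missing_mask = missing_mask,
                        attribute_names = attribute_names,
                        codebook = codebook,
                        labels = labels,
                        record_ids = as.integer(record_ids)),
                   class = "feature_table")
  validate_feature_table(obj)
  obj
}

#' Validate a feature table
#'
#' Checks the container invariants: matching shapes, unique attribute names,
#' 0/1 labels, and a codebook that round-trips every level.
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly; signals an error on violation.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (!identical(dim(x$values), dim(x$missing_mask)))
    stop_arg("values/missing_mask shape mismatch")
  if (anyDuplicated(x$attribute_names))
    stop_arg("attribute names must be unique")
  if (!is.null(x$labels) && !all(x$labels %in% c(0L, 1L)))
    stop_arg("labels must be 0/1")
  for (attr in names(x$codebook)) {
    lv <- x$codebook[[attr]]
    if (!identical(decode_level(x, attr, encode_level(x, attr, lv)), lv))
      stop_arg("codebook does not round-trip for attribute '%s'", attr)
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d records x %d attributes\n",
              nrow(x$values), ncol(x$values)))
  cat("  attributes:", paste(x$attribute_names, collapse = ", "), "\n")
  nm <- sum(x$missing_mask)
  cat(sprintf("  missing cells: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(x$missing_mask))))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d/%d positive\n", sum(x$labels),
                length(x$labels)))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @param ... unused.
#' @export
dim.feature_table <- function(x) dim(x$values)

encode_level <- function(table, attr, level) {
  lv <- table$codebook[[attr]]
  if (is.null(lv)) stop_arg("attribute '%s' has no codebook entry", attr)
  match(level, lv)
}

decode_level <- function(table, attr, code) {
  lv <- table$codebook[[attr]]
  if (is.null(lv)) stop_arg("attribute '%s' has no codebook entry", attr)
  lv[code]
}

# masked-aware column means over observed cells
observed_col_means <- function(table) {
  v <- table$values
  v[table$missing_mask] <- NA_real_
  colMeans(v, na.rm = TRUE)
}

#' Convert a feature table to a Kaggle-dialect data frame
#'
#' Categorical codes are decoded back to their string levels; masked cells
#' become `NA`.
#'
#' @param x a `feature_table`.
#' @param row.names,optional,... passed for S3 compatibility, unused.
#' @return a `data.frame` with the 12 dialect columns.
#' @export
as.data.frame.feature_table <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  sc <- cohort_schema()
  v <- x$values
  v[x$missing_mask] <- NA_real_
  out <- list(id = x$record_ids)
  for (attr in sc$predictors) {
    col <- v[, attr]
    if (attr %in% names(x$codebook)) {
      out[[attr]] <- ifelse(is.na(col), NA_character_,
                            decode_level(x, attr, as.integer(col)))
    } else {
      out[[attr]] <- col
    }
  }
  out$stroke <- if (is.null(x$labels)) NA_integer_ else x$labels
  as.data.frame(out, stringsAsFactors = FALSE)
}
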