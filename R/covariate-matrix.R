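#' Patients-by-covariates matrix with column provenance
#'
#' A thin container around a numeric matrix whose columns carry a provenance
#' prefix: `"struct:"` for covariates from the structured record and
#' `"text:"` for covariates derived from clinical notes. Rows align with
#' `patient_ids`.
#'
#' @param values numeric matrix, patients in rows.
#' @param patient_ids character vector, one id per row.
#' @param column_names character vector of prefixed column names.
#' @return An object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, patient_ids, column_names = colnames(values)) {
  values <- as.matrix(values)
  assert_that(nrow(values) == length(patient_ids),
              "rows of values must align with patient_ids")
  assert_that(ncol(values) == length(column_names),
              "column_names must name every column")
  assert_that(!anyDuplicated(column_names),
              "duplicate column names are not allowed")
  assert_that(all(is.finite(values)), "all covariate values must be finite")
  assert_that(all(grepl("^(struct|text):", column_names)),
              "column names must carry a 'struct:' or 'text:' provenance prefix")
  dimnames(values) <- list(patient_ids, column_names)
  structure(list(patient_ids = as.character(patient_ids),
                 column_names = column_names,
                 values = values),
            class = "covariate_matrix")
}

#' @export
print.covariate_matrix <- function(x, ...) {
  ns <- sum(startsWith(x$column_names, "struct:"))
  nt <- sum(startsWith(x$column_names, "text:"))
  cat(sprintf("<covariate_matrix> %d patients x %d covariates (%d struct, %d text)\n",
              nrow(x$values), ncol(x$values), ns, nt))
  invisible(x)
}

#' @export
dim.covariate_matrix <- function(x) dim(x$values)

#' @export
as.matrix.covariate_matrix <- function(x, ...) x$values

#' Concatenate structured and text covariate blocks
#'
#' Binds two blocks column-wise after checking that the rows describe the
#' same patients in the same order.
#'
#' @param a,b `covariate_matrix` objects with identical `patient_ids`.
#' @return A `covariate_matrix`.
#' @export
concat_covariates <- function(a, b) {
  assert_that(identical(a$patient_ids, b$patient_ids),
              "patient ids must match between blocks")
  covariate_matrix(cbind(a$values, b$values), a$patient_ids,
                   c(a$column_names, b$column_names))
}

#' Subset a covariate matrix by column name
#' @param x a `covariate_matrix`.
#' @param columns character vector of column names to keep.
#' @return A `covariate_matrix` with the selected columns.
#' @export
select_columns <- function(x, columns) {
  missing <- setdiff(columns, x$column_names)
  assert_that(length(missing) == 0,
              paste("unknown covariate columns:", paste(missing, collapse = ", ")))
  covariate_matrix(x$values[, columns, drop = FALSE], x$patient_ids, columns)
}

#' Write a covariate matrix as TSV with a JSON provenance sidecar
#'
#' @param x a `covariate_matrix`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_covariate_matrix <- function(x, path) {
  df <- data.frame(patient_id = x$patient_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(columns = x$column_names,
               provenance = sub(":.*$", "", x$column_names))
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
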