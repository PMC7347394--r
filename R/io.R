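# Cohort CSV I/O and model-spec files.
#
# CSV dialect: UTF-8, comma separated, header row, one row per patient,
# booleans as 0/1, enum tokens lowercase, "." decimal, empty cell for NA.

ENUM_COLUMNS <- c("maternal_steroids", "sex", "resuscitation", "outcome")
REQUIRED_COLUMNS <- c("id", "sex", "gestational_age", "birth_weight")

#' Read a patient cohort from CSV
#'
#' Reads and validates a patient-level cohort. Enum tokens are
#' case-insensitive; unknown columns are accepted, preserved and logged;
#' invariant violations are reported with row numbers and field names.
#'
#' @param path Path to a CSV file.
#' @param validate Run [validate_cohort()] on the result (default `TRUE`).
#' @return A typed patient-level data frame.
#' @export
read_cohort <- function(path, validate = TRUE) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(REQUIRED_COLUMNS, names(x))
  if (length(miss))
    stop("schema error: required column(s) missing: ",
         paste(miss, collapse = ", "))
  for (col in intersect(ENUM_COLUMNS, names(x)))
    x[[col]] <- tolower(trimws(as.character(x[[col]])))
  x$id <- as.character(x$id)
  unknown <- setdiff(names(x), c(COHORT_COLUMNS, "p_true", "days_of_life",
                                 "model_id", "z", "p_death", "p_survival",
                                 "category"))
  if (length(unknown))
    message("unknown column(s) preserved: ", paste(unknown, collapse = ", "))
  if (validate) validate_cohort(x)
  x
}

#' Write a patient cohort to CSV
#'
#' @param cohort Patient-level data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a model specification as JSON
#'
#' Model files mirror the published constants file, so derived and
#' published models share one format and one scoring path.
#'
#' @param model A `vlbw_model`.
#' @param path File path.
#' @return `read_model_spec()` returns a `vlbw_model`.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "vlbw_model"))
  terms <- model$terms
  terms$level[is.na(terms$level)] <- ""
  obj <- list(model_id = model$model_id, label = model$label,
              intercept = model$intercept, intercept_se = model$intercept_se,
              stratum = model$stratum, terms = terms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  terms <- obj$terms
  terms$level[terms$level == ""] <- NA_character_
  stratum <- obj$stratum
  if (!is.null(stratum) && is.null(stratum$max_day)) stratum$max_day <- Inf
  model_spec(obj$model_id, obj$intercept, obj$intercept_se %||% NA_real_,
             terms, stratum = stratum, label = obj$label %||% obj$model_id)
}
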