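# Field-record table I/O, validation and response construction.

.CORE_COLUMNS <- c("field_id", "observer", "x", "y", "edge_area",
                   "center_area", "edge_infested", "center_infested")

#' Validate a field-record table
#'
#' Checks the header schema, stratum areas and proportions, observer levels,
#' covariate presence, missing values and binary/ordinal level validity.
#'
#' @param fields Field-record data frame.
#' @param registry Covariate registry the table must conform to.
#' @return Invisibly `TRUE`; signals a classed validation error otherwise.
#' @export
validate_fields <- function(fields, registry = covariate_registry()) {
  if (!is.data.frame(fields) || nrow(fields) == 0L)
    stop_weevil("weevil_validation_error", "fields must be a non-empty data frame")
  missing_core <- setdiff(.CORE_COLUMNS, names(fields))
  if (length(missing_core))
    stop_weevil("weevil_validation_error", "missing core column(s): %s",
                paste(missing_core, collapse = ", "))
  missing_cov <- setdiff(names(registry), names(fields))
  if (length(missing_cov))
    stop_weevil("weevil_validation_error", "missing covariate column(s): %s",
                paste(missing_cov, collapse = ", "))
  use <- c(.CORE_COLUMNS, names(registry))
  nas <- vapply(fields[use], function(col) any(is.na(col)), logical(1))
  if (any(nas)) {
    col <- use[which(nas)[1]]
    id <- fields$field_id[which(is.na(fields[[col]]))[1]]
    stop_weevil("weevil_validation_error",
                "missing value in column '%s' (first at field_id %s); missing data are rejected, not imputed",
                col, as.character(id))
  }
  if (any(fields$edge_area < 0) || any(fields$center_area < 0))
    stop_weevil("weevil_validation_error", "stratum areas must be nonnegative")
  if (any(fields$edge_area + fields$center_area <= 0))
    stop_weevil("weevil_validation_error",
                "edge_area + center_area must be positive for every field")
  for (col in c("edge_infested", "center_infested")) {
    if (any(fields[[col]] < 0 | fields[[col]] > 1))
      stop_weevil("weevil_validation_error",
                  "%s must be a proportion in [0, 1]", col)
  }
  bad_obs <- setdiff(unique(fields$observer), OBSERVER_LEVELS)
  if (length(bad_obs))
    stop_weevil("weevil_validation_error",
                "unknown observer level(s): %s", paste(bad_obs, collapse = ", "))
  for (s in registry) {
    v <- fields[[s$name]]
    if (s$kind == "binary" && length(setdiff(unique(v), s$levels)))
      stop_weevil("weevil_validation_error",
                  "binary covariate '%s' has level(s) outside {%s}",
                  s$name, paste(s$levels, collapse = ", "))
    if (s$kind == "ordinal" && length(setdiff(unique(v), s$levels)))
      stop_weevil("weevil_validation_error",
                  "ordinal covariate '%s' has level(s) outside its range", s$name)
    if (s$kind %in% c("continuous", "count") && !is.numeric(v))
      stop_weevil("weevil_validation_error",
                  "covariate '%s' must be numeric", s$name)
  }
  invisible(TRUE)
}

#' Area-weighted square-root infestation response
#'
#' The response is the field-level infested proportion — edge and center
#' stratum proportions weight-averaged by their areas — square-root
#' transformed. The transform is applied after area-weighting.
#'
#' @param fields Field-record data frame (or any data frame with
#'   `edge_area`, `center_area`, `edge_infested`, `center_infested`).
#' @return Numeric vector in \[0, 1\] (sqrt-proportion scale).
#' @export
compute_response <- function(fields) {
  needed <- c("edge_area", "center_area", "edge_infested", "center_infested")
  miss <- setdiff(needed, names(fields))
  if (length(miss))
    stop_weevil("weevil_validation_error", "missing column(s): %s",
                paste(miss, collapse = ", "))
  a_e <- fields$edge_area
  a_c <- fields$center_area
  if (any(a_e < 0) || any(a_c < 0) || any(a_e + a_c <= 0))
    stop_weevil("weevil_validation_error",
                "areas must be nonnegative with edge_area + center_area > 0")
  if (any(fields$edge_infested < 0 | fields$edge_infested > 1) ||
      any(fields$center_infested < 0 | fields$center_infested > 1))
    stop_weevil("weevil_validation_error",
                "stratum proportions must lie in [0, 1]")
  p <- (fields$edge_infested * a_e + fields$center_infested * a_c) / (a_e + a_c)
  sqrt(pmin(1, pmax(0, p)))
}

#' Write / read a field-record table
#'
#' Plain comma-separated text with a header row, one record per field.
#' `write_fields()` also writes the truth record (when attached) as a JSON
#' sidecar `<path>.truth.json`.
#'
#' @param fields Field-record data frame.
#' @param path Output CSV path.
#' @param truth Optional [truth_record()]; defaults to the table's
#'   `"truth"` attribute.
#' @return `write_fields()`: the path, invisibly. `read_fields()`: the
#'   validated data frame (with truth attached if a sidecar exists).
#' @export
write_fields <- function(fields, path, truth = attr(fields, "truth")) {
  utils::write.csv(as.data.frame(fields), path, row.names = FALSE)
  if (!is.null(truth)) write_truth(truth, paste0(path, ".truth.json"))
  invisible(path)
}

#' @rdname write_fields
#' @param registry Registry used for validation on read.
#' @export
read_fields <- function(path, registry = covariate_registry()) {
  fields <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fields(fields, registry)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) attr(fields, "truth") <- read_truth(sidecar)
  fields
}

#' Write / read a truth record as JSON
#'
#' @param truth A [truth_record()].
#' @param path File path.
#' @return `write_truth()`: the path, invisibly; `read_truth()`: a
#'   [truth_record()].
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(betas = as.list(truth$betas), intercept = truth$intercept,
         sigma = truth$sigma,
         observer_effects = as.list(truth$observer_effects)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth_record(betas = unlist(x$betas), intercept = x$intercept,
               sigma = x$sigma, observer_effects = unlist(x$observer_effects))
}
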