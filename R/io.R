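# Behavioural-data CSV readers and writers, plus the column-schema
# validation shared with the fitting module. Files are plain RFC-4180 CSV
# with a header row and 1-based integer category codes.

#' Behavioural data schema
#'
#' Declares which columns of a behavioural table hold the observation
#' modalities, the action factors and the subject identifier, together
#' with the category bounds used for validation.
#'
#' @param observation_cols Character vector of observation column names,
#'   in modality order.
#' @param action_cols Character vector of action column names, in factor
#'   order.
#' @param subject_col Subject identifier column name.
#' @param num_obs,num_controls Optional integer vectors of category counts
#'   used to range-check codes on read.
#' @return A list of class `aif_data_schema`.
#' @export
data_schema <- function(observation_cols = c("Location", "Reward", "Cue"),
                        action_cols = c("Action_Location", "Action_Reward"),
                        subject_col = "SubjectID",
                        num_obs = NULL, num_controls = NULL) {
  structure(list(observation_cols = observation_cols,
                 action_cols = action_cols, subject_col = subject_col,
                 num_obs = num_obs, num_controls = num_controls),
            class = "aif_data_schema")
}

validate_behavioural <- function(df, schema) {
  need <- c(schema$observation_cols, schema$action_cols, schema$subject_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("behavioural table lacks declared columns: ",
         paste(missing_cols, collapse = ", "))
  check_codes <- function(cols, bounds, what) {
    for (j in seq_along(cols)) {
      v <- df[[cols[j]]]
      if (any(v != round(v)) || any(v < 1))
        stop(sprintf("column '%s' must contain positive integer codes",
                     cols[j]))
      if (!is.null(bounds) && any(v > bounds[j])) {
        row <- which(v > bounds[j])[1]
        stop(sprintf("out-of-range %s code %d in column '%s' at row %d (max %d)",
                     what, v[row], cols[j], row, bounds[j]))
      }
    }
  }
  check_codes(schema$observation_cols, schema$num_obs, "observation")
  check_codes(schema$action_cols, schema$num_controls, "action")
  invisible(df)
}

#' Read a behavioural dataset from CSV
#'
#' Header-driven: columns are mapped through the schema, codes are
#' validated (1-based, within the declared category bounds when given).
#'
#' @param path CSV file path.
#' @param schema A [data_schema()].
#' @return A data frame with the file's columns.
#' @export
read_behavioural_csv <- function(path, schema = data_schema()) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_behavioural(df, schema)
}

#' Write a behavioural dataset to CSV
#'
#' @param df Behavioural data frame.
#' @param path Output path.
#' @param schema A [data_schema()]; validated before writing so that
#'   round trips are lossless.
#' @return The path, invisibly.
#' @export
write_behavioural_csv <- function(df, path, schema = data_schema()) {
  validate_behavioural(df, schema)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
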