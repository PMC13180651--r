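#' Read and write person-year tables
#'
#' Plain-CSV interface for the person-year record schema (see
#' [classify_dataset()]). Logical flag columns may be encoded as
#' `TRUE`/`FALSE` or 0/1.
#'
#' @param path CSV file path.
#' @return A person-year data frame (schema-validated on read).
#' @export
read_person_years <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("disability_pension", "old_age_pension", "died_in_year",
                "censored_in_year"))
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  validate_person_years(d, strict = TRUE)
  d
}

#' @rdname read_person_years
#' @param data Person-year data frame.
#' @export
write_person_years <- function(data, path) {
  validate_person_years(data, strict = TRUE)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
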