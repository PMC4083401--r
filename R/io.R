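# TSV readers/writers for the pipeline's table formats. All tables are
# plain tab-separated text with a header line; writing is deterministic
# (fixed quoting, no row names) so identical inputs give identical bytes.

#' Read a tab-separated table
#'
#' @param path file path.
#' @return data frame with character columns left as-is.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) {
    abort_coscore(paste("file not found:", path), "data_error")
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table deterministically
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read an expression table (samples x features)
#'
#' Expects a TSV whose first column is the sample id and whose remaining
#' columns are features on the log2 scale.
#' @param path file path.
#' @return data frame with first column `sample_id`.
#' @export
read_expression_table <- function(path) {
  x <- read_tsv_table(path)
  if (ncol(x) < 2L) {
    abort_coscore("expression table needs a sample id column plus >= 1 feature",
                  "data_error")
  }
  names(x)[1] <- "sample_id"
  x
}

#' Read a standardized clinical table
#'
#' @param path TSV with columns `sample_id`, `endpoint`, `time`, `event`
#'   (and optionally `stage`, `cohort`, `pub_year`).
#' @return data frame.
#' @export
read_clinical_table <- function(path) {
  x <- read_tsv_table(path)
  need <- c("sample_id", "endpoint", "time", "event")
  if (!all(need %in% names(x))) {
    abort_coscore(paste("clinical table must have columns:",
                        paste(need, collapse = ", ")), "data_error")
  }
  x
}
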