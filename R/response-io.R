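#' Validate a response matrix against item metadata
#'
#' A response matrix holds one row per enrolled patient and one column per
#' questionnaire item; cells are integer Likert responses or \code{NA} for a
#' missing response.
#'
#' @param x integer matrix with patient ids as row names and item ids as
#'   column names; \code{NA} marks a missing response.
#' @param metadata an [item_metadata()] table. The matrix columns must be
#'   exactly the metadata's item set, and every non-missing cell must lie in
#'   the item's declared response range.
#' @return \code{x}, invisibly, after validation.
#' @export
validate_responses <- function(x, metadata) {
  if (!is.matrix(x)) stop("responses must be a matrix")
  if (is.null(colnames(x))) stop("response matrix must have item ids as colnames")
  if (is.null(rownames(x))) stop("response matrix must have patient ids as rownames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate patient ids in response matrix")
  unknown <- setdiff(colnames(x), metadata$item_id)
  missing <- setdiff(metadata$item_id, colnames(x))
  if (length(unknown) || length(missing))
    stop("response columns do not match the questionnaire item set",
         if (length(unknown)) paste0("; unknown: ",
                                     paste(unknown, collapse = ", ")),
         if (length(missing)) paste0("; absent: ",
                                     paste(missing, collapse = ", ")))
  idx <- match(colnames(x), metadata$item_id)
  lo <- metadata$response_min[idx]
  hi <- metadata$response_max[idx]
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    bad <- which(!is.na(v) & (v < lo[j] | v > hi[j] | v != round(v)))
    if (length(bad))
      stop("out-of-range response for item ", colnames(x)[j],
           ", patient ", rownames(x)[bad[1]], ": ", v[bad[1]],
           " (allowed ", lo[j], "..", hi[j], ")")
  }
  invisible(x)
}

#' Read a response matrix from CSV
#'
#' The file has a \code{patient_id} column followed by one column per item;
#' empty cells are missing responses. Missing responses are never encoded as
#' sentinel numbers.
#'
#' @param path path to the CSV file.
#' @param metadata an [item_metadata()] table used for validation; when
#'   \code{NULL}, a 1--4 range is assumed for all columns found.
#' @return An integer matrix (patients x items) with \code{NA} for missing.
#' @export
read_responses <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        colClasses = "character")
  if (!"patient_id" %in% names(df))
    stop("malformed responses CSV (no patient_id column): ", path)
  ids <- df$patient_id
  df <- df[setdiff(names(df), "patient_id")]
  x <- matrix(NA_integer_, nrow = length(ids), ncol = ncol(df),
              dimnames = list(ids, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("cannot parse cell at row ", bad[1], ", column '", names(df)[j],
           "' of ", path, ": '", v[bad[1]], "'")
    x[, j] <- as.integer(num)
  }
  if (is.null(metadata))
    metadata <- item_metadata(colnames(x))
  validate_responses(x, metadata)
  x
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]: missing responses become empty cells, so a
#' round trip reproduces the values and missingness pattern exactly.
#'
#' @param x response matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_responses <- function(x, path) {
  df <- data.frame(patient_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
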