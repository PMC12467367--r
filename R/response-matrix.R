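#' Construct a person-by-item response matrix
#'
#' Ratings are integer categories, `NA` for missing. Validation checks every
#' non-missing rating against the item's category range and requires at least
#' one non-missing rating per person and per item.
#'
#' @param x a matrix or data frame of integer ratings with one column per
#'   item (column names = item ids) and one row per person (row names =
#'   person ids; generated as `P001...` when absent).
#' @param spec a [scale_spec()]; columns must match its items exactly
#'   (order is taken from the spec).
#' @return An integer matrix of class `response_matrix` with person row
#'   names and item column names.
#' @export
response_matrix <- function(x, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop_rk("x must be a matrix or data frame",
                             "raschkey_validation_error")
  ids <- spec$items$item_id
  if (is.null(colnames(x))) {
    if (ncol(x) != length(ids))
      stop_rk("unnamed response matrix must have one column per item",
              "raschkey_validation_error")
    colnames(x) <- ids
  }
  missing_items <- setdiff(ids, colnames(x))
  unknown <- setdiff(colnames(x), ids)
  if (length(unknown))
    stop_rk(sprintf("unknown item columns: %s", paste(unknown, collapse = ", ")),
            "raschkey_validation_error")
  if (length(missing_items))
    stop_rk(sprintf("missing item columns: %s",
                    paste(missing_items, collapse = ", ")),
            "raschkey_validation_error")
  x <- x[, ids, drop = FALSE]
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop_rk(sprintf("duplicate person ids: %s",
                    paste(unique(rownames(x)[duplicated(rownames(x))]),
                          collapse = ", ")),
            "raschkey_validation_error")
  storage.mode(x) <- "integer"
  m <- item_categories(spec)
  for (j in seq_along(ids)) {
    v <- x[, j]
    bad <- which(!is.na(v) & (v < 0L | v > m[[j]] - 1L))
    if (length(bad))
      stop_rk(sprintf(
        "rating out of range for item '%s' (allowed 0..%d): person '%s' has %d",
        ids[j], m[[j]] - 1L, rownames(x)[bad[1]], v[bad[1]]),
        "raschkey_validation_error")
  }
  if (any(rowSums(!is.na(x)) == 0L))
    stop_rk("every person needs at least one non-missing rating",
            "raschkey_validation_error")
  if (any(colSums(!is.na(x)) == 0L))
    stop_rk("every item needs at least one non-missing rating",
            "raschkey_validation_error")
  structure(x, class = c("response_matrix", class(x)))
}

#' Read / write response matrices as CSV
#'
#' The first column holds person ids; remaining columns are items. Blank
#' cells and `NA` are read as missing.
#'
#' @param path file path.
#' @param spec a [scale_spec()] used for validation.
#' @param responses a [response_matrix()].
#' @return `read_responses` returns a [response_matrix()];
#'   `write_responses` returns `path` invisibly.
#' @export
read_responses <- function(path, spec) {
  if (!file.exists(path))
    stop_rk(sprintf("file not found: %s", path), "raschkey_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = c("NA", ""))
  if (ncol(df) < 2L)
    stop_rk(sprintf("%s: expected a person-id column plus item columns", path),
            "raschkey_io_error")
  pid <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop_rk(sprintf("%s: row %d, column '%s': non-numeric rating '%s'",
                      path, bad[1] + 1L, colnames(mat)[j], v[bad[1]]),
              "raschkey_io_error")
  }
  storage.mode(mat) <- "numeric"
  rownames(mat) <- pid
  tryCatch(response_matrix(mat, spec),
           raschkey_validation_error = function(e)
             stop_rk(sprintf("%s: %s", path, conditionMessage(e)),
                     "raschkey_io_error"))
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  m <- unclass(responses)
  rownames(m) <- NULL
  df <- data.frame(person_id = rownames(responses), as.data.frame(m),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
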