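#' Read and write 8-bit sRGB PNG images
#'
#' Images are held in memory as integer arrays (`H x W x 3`, values
#' 0-255); on disk they are standard 8-bit RGB PNGs.
#'
#' @param img integer array `H x W x 3` with values in 0-255.
#' @param path file path.
#' @return `read_png()` returns an integer array; `write_png()` the path,
#'   invisibly.
#' @export
write_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3,
            min(img) >= 0, max(img) <= 255)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3]
  array(as.integer(round(a * 255)), dim(a))
}

# response-table schema shared by the readers/writers and the aggregator
response_schema <- c("observer_id", "environment", "task",
                     "illumination_condition", "object", "difficulty",
                     "m", "chosen_index", "correct")

#' Read and write trial response tables (CSV)
#'
#' Column schema: `observer_id, environment, task, illumination_condition,
#' object, difficulty, m, chosen_index, correct`. Reading validates the
#' schema and basic value constraints and reports offending rows.
#'
#' @param records data frame of trial records.
#' @param path CSV file path.
#' @return `read_response_table()` returns the validated data frame.
#' @export
write_response_table <- function(records, path) {
  missing_cols <- setdiff(response_schema, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[response_schema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(response_schema, names(tab))
  if (length(missing_cols))
    stop("malformed response table, missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!tab$m %in% c(3, 4) | tab$chosen_index < 1 |
                 tab$chosen_index > tab$m | is.na(tab$correct))
  if (length(bad))
    stop("malformed response rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  tab$correct <- as.logical(tab$correct)
  tab
}

#' Write a feature table (one row per image, named feature columns)
#'
#' @param features numeric matrix with column names (feature names) and
#'   row names (image identifiers).
#' @param path CSV path.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  df <- data.frame(image = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# manifest of artifact files: path + md5 (reproducibility contract)
build_manifest <- function(paths) {
  data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
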