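#' Read per-subject connectivity matrices
#'
#' Reads one square numeric matrix file per subject (whitespace- or
#' comma-delimited, auto-detected) and vectorizes each into one row of a
#' [connectivity_table()]. Matrices must share a common dimension; asymmetric
#' entries are symmetrized by averaging and the diagonal is ignored.
#'
#' @param paths character vector of matrix file paths, one per subject.
#' @param subject_ids subject labels matching `paths`; defaults to file
#'   names without extension.
#' @return A `connectivity_table` with one row per file.
#' @export
read_connectivity_matrices <- function(paths, subject_ids = NULL) {
  if (length(paths) == 0L) stop("no files given")
  if (is.null(subject_ids))
    subject_ids <- sub("\\.[^.]*$", "", basename(paths))
  mats <- lapply(paths, read_matrix_file)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("matrix dimension mismatch across subjects: ",
         paste(unique(dims), collapse = ", "))
  rows <- vapply(mats, vectorize_connectivity,
                 numeric(dims[1] * (dims[1] - 1) / 2))
  connectivity_table(t(rows), subject_ids, n_regions = dims[1])
}

read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  if (nrow(mat) != ncol(mat))
    stop("not a square matrix: ", path)
  if (anyNA(mat)) stop("NaN or missing values in ", path)
  if (any(mat[row(mat) != col(mat)] < 0)) stop("negative values in ", path)
  mat
}

#' Write per-subject connectivity matrices
#'
#' Writes each row of a table back out as a square symmetric matrix file
#' (tab-delimited, zero diagonal), one file per subject, named
#' `<subject_id>.tsv`. Reading the files back reproduces the table.
#'
#' @param table a `connectivity_table`.
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the vector of written file paths.
#' @export
write_connectivity_matrices <- function(table, out_dir) {
  stopifnot(inherits(table, "connectivity_table"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, paste0(table$subject_ids, ".tsv"))
  for (k in seq_along(paths)) {
    m <- devectorize_connectivity(table$values[k, ], table$n_regions)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = NA),
                       paths[k], sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read a subject metadata table
#'
#' Reads a delimited text table (comma or tab, auto-detected) with a header
#' row. Columns `subject_id` and `site` are required; `sex` is recognized if
#' present; every other column is kept as a covariate. Empty cells become
#' `NA`.
#'
#' @param path file path.
#' @return A data frame with one row per subject; character columns
#'   `subject_id`, `site`, `sex` (NA when absent from the file) followed by
#'   covariate columns.
#' @export
read_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("subject_id", "site")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    if (!"sex" %in% names(df)) df$sex <- character(0)
    return(df)
  }
  df$subject_id <- as.character(df$subject_id)
  df$site <- as.character(df$site)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids in metadata")
  if (anyNA(df$site))
    stop("site must be non-missing for every subject")
  if (!"sex" %in% names(df)) df$sex <- NA_character_ else
    df$sex <- as.character(df$sex)
  covar <- setdiff(names(df), c("subject_id", "site", "sex"))
  df[, c("subject_id", "site", "sex", covar), drop = FALSE]
}

#' Write a subject metadata table
#'
#' @param meta data frame as returned by [read_metadata()].
#' @param path output file path (comma-delimited).
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read/write a stacked subjects-by-connections table
#'
#' The stacked format stores the whole cohort as one tab-delimited
#' subjects-by-connections matrix (subject ids in the first column) plus a
#' JSON sidecar `<path>.json` carrying `n_regions` and the region-pair index,
#' so a table survives a round trip without per-subject matrix files.
#'
#' @param table a `connectivity_table`.
#' @param path path of the `.tsv` table; the sidecar is written next to it.
#' @return `write_connectivity_table()` invisibly returns `path`;
#'   `read_connectivity_table()` returns a `connectivity_table`.
#' @export
write_connectivity_table <- function(table, path) {
  stopifnot(inherits(table, "connectivity_table"))
  df <- data.frame(subject_id = table$subject_ids,
                   table$values, check.names = FALSE)
  names(df)[-1] <- paste0("c", table$pair_index[, 1], "_", table$pair_index[, 2])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_regions = table$n_regions,
         pair_index = unname(as.data.frame(table$pair_index))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity_table
#' @export
read_connectivity_table <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  connectivity_table(as.matrix(df[, -1, drop = FALSE]),
                     df$subject_id, n_regions = sidecar$n_regions)
}

#' Align metadata rows to a connectivity table
#'
#' Joins metadata by `subject_id`, preserving the table's row order.
#'
#' @param table a `connectivity_table`.
#' @param meta metadata data frame.
#' @return The metadata rows reordered to match `table$subject_ids`.
#' @export
align_metadata <- function(table, meta) {
  idx <- match(table$subject_ids, meta$subject_id)
  if (anyNA(idx))
    stop("metadata missing for subject(s): ",
         paste(utils::head(table$subject_ids[is.na(idx)], 5), collapse = ", "))
  out <- meta[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
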