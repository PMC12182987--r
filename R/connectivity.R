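#' Connectivity tables
#'
#' A `connectivity_table` holds non-negative structural connectivity values
#' for a cohort as a subjects-by-connections matrix, together with the map
#' from column to brain-region pair. Columns enumerate the strict upper
#' triangle of the underlying symmetric R-by-R connectivity matrix in
#' row-major order, with 0-based region indices `(i, j)`, `i < j`, so an
#' 85-region parcellation yields `85 * 84 / 2 = 3570` connections.
#'
#' @param values numeric matrix, rows = subjects, columns = connections;
#'   all entries must be finite and non-negative.
#' @param subject_ids character vector of unique subject labels, one per row.
#' @param n_regions number of brain regions R; the table must have exactly
#'   `R (R - 1) / 2` columns.
#'
#' @return An object of class `connectivity_table`: a list with elements
#'   `values`, `subject_ids`, `pair_index` (two-column integer matrix of
#'   0-based region pairs) and `n_regions`.
#' @examples
#' m <- matrix(runif(2 * 3), 2, 3)
#' tab <- connectivity_table(m, c("s1", "s2"), n_regions = 3)
#' tab$pair_index
#' @export
connectivity_table <- function(values, subject_ids = NULL, n_regions) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  n_regions <- as.integer(n_regions)
  n_conn <- (n_regions * (n_regions - 1L)) %/% 2L
  if (ncol(values) != n_conn)
    stop("expected ", n_conn, " connections for ", n_regions,
         " regions, got ", ncol(values), " columns")
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length does not match number of rows")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids")
  if (anyNA(values) || any(!is.finite(values)))
    stop("connectivity values must be finite and non-missing")
  if (any(values < 0))
    stop("connectivity values must be non-negative")
  dimnames(values) <- list(subject_ids, NULL)
  structure(
    list(values = values, subject_ids = subject_ids,
         pair_index = pair_index(n_regions), n_regions = n_regions),
    class = "connectivity_table"
  )
}

#' Region-pair index of the vectorized upper triangle
#'
#' @param n_regions number of regions R.
#' @return Integer matrix with `R (R - 1) / 2` rows and columns `i`, `j`,
#'   giving the 0-based region pair of each connection, in row-major order
#'   over the strict upper triangle (the column order used by
#'   [connectivity_table()]).
#' @export
pair_index <- function(n_regions) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) stop("need at least 2 regions")
  i <- rep.int(seq_len(n_regions - 1L) - 1L, times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L) - 1L,
                     function(a) seq.int(a + 1L, n_regions - 1L)))
  cbind(i = i, j = as.integer(j))
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat("connectivity_table:", nrow(x$values), "subjects x",
      ncol(x$values), "connections (", x$n_regions, "regions )\n")
  cat("  zero fraction:", signif(mean(x$values == 0), 3), "\n")
  invisible(x)
}

#' @export
dim.connectivity_table <- function(x) dim(x$values)

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle of a square matrix in row-major order
#' (the inverse of [devectorize_connectivity()]). Asymmetric input is
#' symmetrized by averaging the `(i, j)` and `(j, i)` entries; the diagonal
#' is ignored.
#'
#' @param mat square numeric matrix.
#' @return Numeric vector of length `R (R - 1) / 2`.
#' @export
vectorize_connectivity <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  sym <- (mat + t(mat)) / 2
  # t() because upper.tri extracts column-major; we store row-major pairs
  t(sym)[lower.tri(sym)]
}

#' Rebuild a symmetric matrix from a connection vector
#'
#' @param v numeric vector of length `R (R - 1) / 2`.
#' @param n_regions number of regions R.
#' @return Symmetric `R`-by-`R` matrix with zero diagonal.
#' @export
devectorize_connectivity <- function(v, n_regions) {
  n_regions <- as.integer(n_regions)
  if (length(v) != (n_regions * (n_regions - 1L)) %/% 2L)
    stop("length of v does not match n_regions")
  out <- matrix(0, n_regions, n_regions)
  out[lower.tri(out)] <- v        # fills column-major = row-major upper triangle
  out <- t(out)
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

n_regions_for <- function(n_conn) {
  r <- (1 + sqrt(1 + 8 * n_conn)) / 2
  if (r != round(r)) stop("column count ", n_conn, " is not R(R-1)/2 for integer R")
  as.integer(r)
}

#' Replace the value matrix of a connectivity table
#'
#' Internal-style helper used by transforms that preserve table shape.
#' @param table a `connectivity_table`.
#' @param values replacement matrix of identical dimensions.
#' @return A `connectivity_table` with the new values.
#' @keywords internal
with_values <- function(table, values) {
  stopifnot(inherits(table, "connectivity_table"),
            all(dim(values) == dim(table$values)))
  connectivity_table(values, table$subject_ids, table$n_regions)
}
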