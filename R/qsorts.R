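#' Q-sort response matrix
#'
#' Container for the raw responses of a Q study: an n-statements by
#' m-respondents integer matrix in which each column is one complete Q-sort.
#' Every column must be a permutation of the grid values (the forced
#' distribution), which also guarantees that no column has zero variance.
#'
#' @param data integer matrix, statements in rows, Q-sorts in columns.
#' @param grid a \code{q_grid}; each column of \code{data} must use exactly its
#'   multiset of values.
#' @param statement_ids,qsort_ids optional row/column labels; defaults are
#'   \code{s1..sn} and \code{q1..qm}.
#' @param allow_duplicate_ids internal; bootstrap resamples legitimately repeat
#'   Q-sort ids.
#' @return An object of class \code{q_sorts}: list with \code{data},
#'   \code{grid}, \code{statement_ids}, \code{qsort_ids}, \code{n}, \code{m}.
#' @export
qsort_matrix <- function(data, grid, statement_ids = NULL, qsort_ids = NULL,
                         allow_duplicate_ids = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)) || any(data != round(data)))
    stop("Q-sort data must be a finite integer matrix")
  storage.mode(data) <- "integer"
  n <- nrow(data); m <- ncol(data)
  if (n < 3L) stop("need at least 3 statements, got ", n)
  if (m < 2L) stop("need at least 2 Q-sorts, got ", m)
  if (!inherits(grid, "q_grid")) stop("grid must be a q_grid")
  if (grid$n != n)
    stop("grid has ", grid$n, " values but data has ", n, " statements")
  if (is.null(statement_ids)) statement_ids <- rownames(data)
  if (is.null(statement_ids)) statement_ids <- paste0("s", seq_len(n))
  if (is.null(qsort_ids)) qsort_ids <- colnames(data)
  if (is.null(qsort_ids)) qsort_ids <- paste0("q", seq_len(m))
  statement_ids <- as.character(statement_ids); qsort_ids <- as.character(qsort_ids)
  if (length(statement_ids) != n || length(qsort_ids) != m)
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(statement_ids))
    stop("duplicate statement ids: ",
         paste(unique(statement_ids[duplicated(statement_ids)]), collapse = ", "))
  if (!allow_duplicate_ids && anyDuplicated(qsort_ids))
    stop("duplicate Q-sort ids: ",
         paste(unique(qsort_ids[duplicated(qsort_ids)]), collapse = ", "))
  bad <- vapply(seq_len(m), function(j) {
    !identical(sort(unname(data[, j])), grid$values)
  }, logical(1))
  if (any(bad))
    stop("columns violate the forced distribution: ",
         paste(qsort_ids[bad], collapse = ", "))
  dimnames(data) <- list(statement_ids, qsort_ids)
  structure(list(data = data, grid = grid,
                 statement_ids = statement_ids, qsort_ids = qsort_ids,
                 n = n, m = m),
            class = "q_sorts")
}

#' @export
print.q_sorts <- function(x, ...) {
  cat("Q-sort matrix:", x$n, "statements x", x$m, "Q-sorts\n")
  cat("  grid columns:", min(x$grid$values), "to", max(x$grid$values), "\n")
  cat("  Q-sorts:", paste(utils::head(x$qsort_ids, 8), collapse = " "),
      if (x$m > 8) "..." else "", "\n")
  invisible(x)
}

# subset/duplicate columns per bootstrap indices; keeps original ids (repeated)
resample_qsorts <- function(q, idx) {
  if (any(idx < 1L | idx > q$m)) stop("resample index out of range")
  qsort_matrix(q$data[, idx, drop = FALSE], q$grid,
               statement_ids = q$statement_ids,
               qsort_ids = q$qsort_ids[idx],
               allow_duplicate_ids = TRUE)
}
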