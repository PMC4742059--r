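#' Forced-distribution grid
#'
#' A Q grid is the fixed multiset of column values into which every respondent
#' must sort the statements, e.g. \code{(-2,-1,-1,0,0,0,1,1,2)} for a 9-statement
#' study. Its length equals the number of statements and its population standard
#' deviation \eqn{s} enters the standard error of factor z-scores,
#' \eqn{SE_f = s\sqrt{1 - r_f}}.
#'
#' @param values integer vector, the complete array of grid values (one per
#'   statement); stored sorted non-decreasing.
#' @return An object of class \code{q_grid} with elements \code{values} (sorted
#'   integer vector), \code{n} (number of statements) and \code{sd} (population
#'   standard deviation of the values).
#' @examples
#' grid_spec(c(-2, -1, -1, 0, 0, 0, 1, 1, 2))
#' @export
grid_spec <- function(values) {
  if (length(values) < 2L)
    stop("a grid needs at least 2 values")
  if (any(!is.finite(values)) || any(values != round(values)))
    stop("grid values must be finite integers")
  values <- as.integer(sort(values))
  n <- length(values)
  s <- sqrt(sum((values - mean(values))^2) / n)  # population SD: the grid IS the distribution
  if (s <= 0)
    stop("grid values are constant; the grid standard deviation must be positive")
  structure(list(values = values, n = n, sd = s), class = "q_grid")
}

#' Build a grid from per-column counts
#'
#' @param min_val,max_val integer range of grid columns.
#' @param counts number of statements per column, from \code{min_val} to
#'   \code{max_val}.
#' @return A \code{q_grid}.
#' @examples
#' grid_from_counts(-2, 2, c(1, 2, 3, 2, 1))
#' @export
grid_from_counts <- function(min_val, max_val, counts) {
  cols <- seq.int(min_val, max_val)
  if (length(counts) != length(cols))
    stop("need one count per column: ", length(cols), " columns, ",
         length(counts), " counts given")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  grid_spec(rep(cols, times = counts))
}

#' Construct a standard grid shape
#'
#' Builds a symmetric forced distribution over the columns \code{min_val} to
#' \code{max_val}. \code{"flat"} puts the same number of statements in every
#' column; \code{"quasi-normal"} builds a symmetric, unimodal shape (fewest
#' statements at the extremes), the conventional Q layout.
#'
#' The quasi-normal fill starts from one statement per column and repeatedly
#' adds one statement to the widest centred window that still fits the
#' remaining total, which keeps the counts symmetric and unimodal for any
#' feasible \code{n}.
#'
#' @param n number of statements.
#' @param min_val,max_val column value range.
#' @param shape \code{"quasi-normal"} (default) or \code{"flat"}.
#' @return A \code{q_grid}.
#' @examples
#' make_grid(9, -2, 2)                  # counts 1,2,3,2,1
#' make_grid(5, -2, 2, shape = "flat")
#' @export
make_grid <- function(n, min_val, max_val, shape = c("quasi-normal", "flat")) {
  shape <- match.arg(shape)
  ncol_ <- max_val - min_val + 1L
  if (ncol_ < 2L) stop("grid needs at least two columns")
  if (ncol_ > n) stop("more columns (", ncol_, ") than statements (", n, ")")
  if (shape == "flat") {
    if (n %% ncol_ != 0L)
      stop("flat shape infeasible: ", n, " statements over ", ncol_, " columns")
    return(grid_from_counts(min_val, max_val, rep(n %/% ncol_, ncol_)))
  }
  # symmetric counts over an even number of columns always sum to an even total
  if (ncol_ %% 2L == 0L && n %% 2L != 0L)
    stop("quasi-normal shape infeasible: symmetric counts over ", ncol_,
         " columns cannot sum to odd ", n)
  counts <- rep(1L, ncol_)
  remaining <- n - ncol_
  # centred windows of growing width (1,3,5,... or 2,4,... for even ncol_)
  mid <- (ncol_ + 1) / 2
  widths <- if (ncol_ %% 2L == 1L) seq(1L, ncol_, by = 2L) else seq(2L, ncol_, by = 2L)
  while (remaining > 0L) {
    w <- max(widths[widths <= remaining])
    idx <- seq.int(ceiling(mid - (w - 1) / 2), length.out = w)
    counts[idx] <- counts[idx] + 1L
    remaining <- remaining - w
  }
  grid_from_counts(min_val, max_val, counts)
}

#' @export
print.q_grid <- function(x, ...) {
  counts <- table(x$values)
  cat("Q grid:", x$n, "statements over columns",
      min(x$values), "to", max(x$values), "\n")
  cat("  counts:", paste(as.integer(counts), collapse = " "), "\n")
  cat("  sd (population):", format(x$sd, digits = 6), "\n")
  invisible(x)
}

grid_counts <- function(grid) as.integer(table(factor(grid$values, levels = sort(unique(grid$values)))))
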