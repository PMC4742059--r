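#' Interpretation tables from bootstrap results
#'
#' Pure function of an existing result object (no recomputation): builds (a)
#' the salience/stability classification of statement-factor cells, (b) the
#' statements that were distinguishing for a factor in the standard analysis
#' but lose distinctiveness under the statement-specific bootstrap test, and
#' (c) the ambiguous Q-sorts, those flagged in a middling fraction of the
#' repetitions (by default between 20\% and 80\%).
#'
#' @param res a \code{q_bootstrap}.
#' @param ambiguity_band flag-frequency interval (open) that marks a Q-sort
#'   as an ambiguous representative; default \code{c(0.2, 0.8)}.
#' @return list of data frames: \code{classification}, \code{lost_distinctiveness},
#'   \code{ambiguous_qsorts}, \code{unstable_statements}; class
#'   \code{q_report} with a printed rendering.
#' @export
render_interpretation_tables <- function(res, ambiguity_band = c(0.2, 0.8)) {
  stopifnot(inherits(res, "q_bootstrap"))
  std <- res$standard; boot <- res$boot
  cls <- res$classification
  classification <- data.frame(
    statement = rep(rownames(cls), ncol(cls)),
    factor = rep(colnames(cls), each = nrow(cls)),
    class = as.vector(cls), stringsAsFactors = FALSE)

  lost <- data.frame(statement = character(), factor = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(std$distinguishing) && !is.null(res$distinguishing)) {
    was <- std$distinguishing$distinguishing_for
    still <- res$distinguishing$statement_specific$distinguishing_for
    idx <- which(was & !still, arr.ind = TRUE)
    lost <- data.frame(statement = rownames(was)[idx[, 1]],
                       factor = colnames(was)[idx[, 2]],
                       stringsAsFactors = FALSE)
  }

  ff <- boot$flag_freq
  amb_idx <- which(ff > ambiguity_band[1] & ff < ambiguity_band[2],
                   arr.ind = TRUE)
  ambiguous <- data.frame(qsort = rownames(ff)[amb_idx[, 1]],
                          factor = colnames(ff)[amb_idx[, 2]],
                          flag_freq = ff[amb_idx],
                          stringsAsFactors = FALSE)
  ambiguous <- ambiguous[order(ambiguous$qsort, ambiguous$factor), ,
                         drop = FALSE]

  # floor the cut at numerical noise so zero-variability runs list nothing
  st_cut <- max(attr(cls, "stability_cut"), 1e-8)
  un_idx <- which(boot$zscore_se > st_cut, arr.ind = TRUE)
  unstable <- data.frame(statement = rownames(boot$zscore_se)[un_idx[, 1]],
                         factor = colnames(boot$zscore_se)[un_idx[, 2]],
                         z_se = boot$zscore_se[un_idx],
                         stringsAsFactors = FALSE)
  unstable <- unstable[order(-unstable$z_se), , drop = FALSE]

  structure(list(classification = classification,
                 lost_distinctiveness = lost,
                 ambiguous_qsorts = ambiguous,
                 unstable_statements = unstable,
                 ambiguity_band = ambiguity_band,
                 stability_cut = st_cut),
            class = "q_report")
}

#' @export
print.q_report <- function(x, digits = 3, ...) {
  cat("Interpretation summary\n")
  cat("======================\n\n")
  tab <- table(x$classification$class)
  cat("Statement classes (salience/stability):\n")
  for (nm in names(tab)) cat(sprintf("  %-35s %d\n", nm, tab[[nm]]))
  cat("\nDistinguishing statements that are not distinctive any more:\n")
  if (nrow(x$lost_distinctiveness) == 0) cat("  (none)\n")
  else for (r in seq_len(nrow(x$lost_distinctiveness)))
    cat("  ", x$lost_distinctiveness$statement[r], "on",
        x$lost_distinctiveness$factor[r], "\n")
  cat("\nAmbiguous Q-sorts (flag frequency in (",
      x$ambiguity_band[1], ", ", x$ambiguity_band[2], ")):\n", sep = "")
  if (nrow(x$ambiguous_qsorts) == 0) cat("  (none)\n")
  else for (r in seq_len(nrow(x$ambiguous_qsorts)))
    cat(sprintf("  %s on %s (%.2f)\n", x$ambiguous_qsorts$qsort[r],
                x$ambiguous_qsorts$factor[r], x$ambiguous_qsorts$flag_freq[r]))
  cat("\nUnstable statements (z-score SE above ",
      format(x$stability_cut, digits = digits), "):\n", sep = "")
  if (nrow(x$unstable_statements) == 0) cat("  (none)\n")
  else {
    top <- utils::head(x$unstable_statements, 10)
    for (r in seq_len(nrow(top)))
      cat(sprintf("  %s on %s (SE %.3f)\n", top$statement[r],
                  top$factor[r], top$z_se[r]))
    if (nrow(x$unstable_statements) > 10)
      cat("  ... and", nrow(x$unstable_statements) - 10, "more\n")
  }
  invisible(x)
}
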