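#' Read Q-sorts from CSV
#'
#' Expects a rectangular CSV with statements in rows: the first column holds
#' the statement id (or text), the remaining columns one Q-sort each with
#' integer cells. Column validity against the forced distribution is checked
#' by the \code{\link{qsort_matrix}} constructor, which names offending
#' Q-sorts.
#'
#' @param path CSV file.
#' @param grid a \code{q_grid} the columns must conform to.
#' @return a \code{q_sorts}.
#' @export
read_qsort_csv <- function(path, grid) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expected an id column plus at least 2 Q-sort columns")
  ids <- as.character(df[[1]])
  dat <- df[, -1, drop = FALSE]
  for (j in seq_along(dat)) {
    v <- dat[[j]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != round(v)))
      stop("non-integer cells in Q-sort column '", names(dat)[j], "'")
  }
  qsort_matrix(as.matrix(dat), grid, statement_ids = ids,
               qsort_ids = names(dat))
}

#' Write Q-sorts to CSV
#'
#' Inverse of \code{\link{read_qsort_csv}}; a write-read round trip is the
#' identity.
#'
#' @param q a \code{q_sorts}.
#' @param path output CSV file.
#' @export
write_qsort_csv <- function(q, path) {
  df <- data.frame(statement = q$statement_ids, q$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a grid specification from JSON or YAML
#'
#' Accepts either an explicit value array (\code{{"values": [-2,-1,...]}}) or
#' a range plus per-column counts
#' (\code{{"min": -2, "max": 2, "counts": [1,2,3,2,1]}}).
#'
#' @param path a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return a \code{q_grid}.
#' @export
read_grid <- function(path) {
  spec <- read_structured(path)
  grid_from_spec(spec)
}

grid_from_spec <- function(spec) {
  if (inherits(spec, "q_grid")) return(spec)
  if (!is.null(spec$values)) return(grid_spec(unlist(spec$values)))
  if (!is.null(spec$min) && !is.null(spec$max) && !is.null(spec$counts))
    return(grid_from_counts(spec$min, spec$max, unlist(spec$counts)))
  stop("grid specification needs either 'values' or 'min'/'max'/'counts'")
}

#' Write a grid specification to JSON
#'
#' @param grid a \code{q_grid}.
#' @param path output JSON file.
#' @export
write_grid <- function(grid, path) {
  jsonlite::write_json(list(values = grid$values), path, auto_unbox = FALSE)
  invisible(path)
}

read_structured <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop("unsupported config format '.", ext, "' (use JSON or YAML)")
}

config_known_keys <- c("k", "extraction", "rotation", "flagging",
                       "manual_flags", "nsteps", "seed", "flag_const",
                       "sig_levels", "salience_cut", "stability_cut",
                       "grid", "align", "freq_denominator", "abs_flagging",
                       "reliability_coef", "output_dir", "ambiguity_band")

#' Load a run configuration from JSON or YAML
#'
#' Fills defaults (extraction \code{"pca"}, rotation \code{"varimax"},
#' flagging \code{"auto"}, \code{nsteps} 2000), validates \code{k} and the
#' grid, warns when \code{nsteps} is below the 50-repetition minimum for SE
#' estimation or the 1000-repetition minimum for CIs, and rejects unknown
#' keys.
#'
#' @param path a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return list of class \code{q_config}, including a parsed \code{grid}.
#' @export
load_config <- function(path) {
  raw <- read_structured(path)
  unknown <- setdiff(names(raw), config_known_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$grid)) stop("configuration is missing the grid")
  cfg <- utils::modifyList(
    list(extraction = "pca", rotation = "varimax", flagging = "auto",
         nsteps = 2000, seed = NULL, flag_const = 1.96,
         sig_levels = c(1.96, 2.58), salience_cut = 1.0,
         stability_cut = NULL, align = TRUE, abs_flagging = FALSE,
         freq_denominator = "present", reliability_coef = 0.8,
         ambiguity_band = c(0.2, 0.8), output_dir = "."),
    raw, keep.null = TRUE)
  if (is.null(cfg$k) || cfg$k < 1 || cfg$k != round(cfg$k))
    stop("configuration needs a positive integer k")
  if (!identical(cfg$extraction, "pca"))
    stop("only PCA extraction is supported")
  cfg$grid <- grid_from_spec(cfg$grid)
  if (cfg$nsteps < 50)
    warning("nsteps = ", cfg$nsteps,
            " is below 50, the minimum for SE estimation (200 are satisfactory)")
  else if (cfg$nsteps < 1000)
    warning("nsteps = ", cfg$nsteps,
            " is below 1000, the minimum to estimate confidence intervals")
  structure(cfg, class = "q_config")
}

fmt6 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.6f", x) else x
}

write_table6 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt6), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Statement-level results table
#'
#' One row per statement x factor: standard and bootstrap z-scores, bootstrap
#' SE and bias, standard and bootstrap factor scores, distinguishing codes
#' under both the standard SED criterion and the statement-specific bootstrap
#' criterion, and the salience/stability class.
#'
#' @param res a \code{q_bootstrap}.
#' @return data frame in long format.
#' @export
statement_table <- function(res) {
  std <- res$standard; boot <- res$boot
  k <- std$k
  rows <- expand.grid(statement = std$statement_ids,
                      factor = colnames(std$zscores),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(rows$statement, std$statement_ids)
  j <- match(rows$factor, colnames(std$zscores))
  cell <- cbind(i, j)
  dist_std <- if (!is.null(std$distinguishing))
    ifelse(std$distinguishing$distinguishing_for[cell], "distinguishing",
           ifelse(std$distinguishing$consensus[i], "consensus", "-"))
  else rep(NA_character_, nrow(rows))
  dist_boot <- if (!is.null(res$distinguishing))
    ifelse(res$distinguishing$statement_specific$distinguishing_for[cell],
           "distinguishing",
           ifelse(res$distinguishing$statement_specific$consensus[i],
                  "consensus", "-"))
  else rep(NA_character_, nrow(rows))
  data.frame(
    statement = rows$statement, factor = rows$factor,
    z_standard = std$zscores[cell],
    z_boot = boot$zscore_mean[cell],
    z_se = boot$zscore_se[cell],
    z_bias = boot$zscore_bias[cell],
    fscore_standard = std$factor_scores[cell],
    fscore_boot = boot$factor_scores_boot[cell],
    dist_standard = dist_std, dist_boot = dist_boot,
    class = res$classification[cell],
    stringsAsFactors = FALSE)
}

#' Q-sort-level results table
#'
#' One row per Q-sort x factor: standard loading, bootstrap loading mean and
#' SE, whether the Q-sort was flagged in the standard analysis, and its
#' flagging frequency over the bootstrap.
#'
#' @param res a \code{q_bootstrap}.
#' @return data frame in long format.
#' @export
qsort_table <- function(res) {
  std <- res$standard; boot <- res$boot
  rows <- expand.grid(qsort = std$qsort_ids,
                      factor = colnames(std$loadings),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell <- cbind(match(rows$qsort, std$qsort_ids),
                match(rows$factor, colnames(std$loadings)))
  data.frame(
    qsort = rows$qsort, factor = rows$factor,
    loading_standard = std$loadings[cell],
    loading_boot = boot$loading_mean[cell],
    loading_se = boot$loading_se[cell],
    flagged_standard = std$flags[cell],
    flag_freq = boot$flag_freq[cell],
    stringsAsFactors = FALSE)
}

#' Factor summary table
#'
#' Per factor: defining Q-sorts, composite reliability, SE of z-scores,
#' eigenvalue, explained variance, and the correlation between standard and
#' bootstrap z-score columns.
#'
#' @param res a \code{q_bootstrap}.
#' @return data frame.
#' @export
factor_table <- function(res) {
  ch <- res$standard$characteristics
  ch$z_correlation_boot <- res$boot$zscore_correlation[ch$factor]
  ch
}

#' Long-format export of z-scores for plotting
#'
#' One row per statement x factor with standard z, bootstrap z and SE,
#' ordered by the statement's cumulative SE across all factors (most stable
#' statements last), the ordering used to rank statements by stability.
#'
#' @param res a \code{q_bootstrap}.
#' @return data frame ordered by decreasing cumulative SE.
#' @export
export_zscore_long <- function(res) {
  tab <- statement_table(res)[, c("statement", "factor", "z_standard",
                                  "z_boot", "z_se")]
  cum <- tapply(tab$z_se, tab$statement, sum)
  tab$cumulative_se <- as.numeric(cum[tab$statement])
  tab[order(-tab$cumulative_se, tab$statement, tab$factor), ]
}

#' Write all result tables to a directory
#'
#' Writes \code{statements.csv}, \code{qsorts_summary.csv},
#' \code{factors_summary.csv}, \code{zscores_long.csv} and
#' \code{runlog.json}. Output is deterministic: fixed column order, floats
#' with 6 decimals, identifiers preserved verbatim and never re-sorted.
#'
#' @param res a \code{q_bootstrap}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "q_bootstrap"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("statements.csv", "qsorts_summary.csv",
                            "factors_summary.csv", "zscores_long.csv",
                            "runlog.json"))
  write_table6(statement_table(res), paths[1])
  write_table6(qsort_table(res), paths[2])
  write_table6(factor_table(res), paths[3])
  write_table6(export_zscore_long(res), paths[4])
  cfg <- res$config
  log <- c(res$log, list(
    version = as.character(utils::packageVersion("qboots")),
    rotation = cfg$rotation, flagging = cfg$flagging,
    flag_const = cfg$flag_const,
    freq_denominator = cfg$freq_denominator, align = cfg$align,
    k = res$standard$k))
  jsonlite::write_json(log, paths[5], auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(paths)
}
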