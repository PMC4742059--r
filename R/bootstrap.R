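# degenerate-resample conditions are signalled with a dedicated class so the
# bootstrap loop can redraw without masking programming errors
stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("qboots_degenerate", "error")))
}

#' Bootstrap configuration
#'
#' Settings for the Q bootstrap. The number of repetitions defaults to 2000;
#' fewer than 50 repetitions are insufficient even for standard errors (200
#' are satisfactory) and at least 1000 are needed for confidence intervals,
#' so warnings are emitted below those marks. Extraction, rotation and
#' flagging are fixed across all repetitions.
#'
#' @param nsteps number of bootstrap repetitions (default 2000).
#' @param seed integer seed for the resampling stream.
#' @param rotation,flagging,manual_flags,flag_const,abs_flagging,reliability_coef,sig_levels
#'   analysis options, as in \code{\link{run_standard_analysis}}.
#' @param align apply the reorder-reflect alignment correction (default TRUE;
#'   disabling it exists to demonstrate the variability inflation it prevents).
#' @param freq_denominator denominator of the flagging frequency:
#'   \code{"present"} counts only repetitions in which the Q-sort appears
#'   (default), \code{"all"} counts all repetitions.
#' @param max_redraw_factor degenerate repetitions are redrawn, up to
#'   \code{max_redraw_factor * nsteps} total draws.
#' @return list of class \code{q_boot_config}.
#' @export
bootstrap_config <- function(nsteps = 2000, seed = NULL,
                             rotation = c("varimax", "none"),
                             flagging = c("auto", "manual", "all"),
                             manual_flags = NULL,
                             flag_const = 1.96, abs_flagging = FALSE,
                             reliability_coef = 0.8,
                             sig_levels = c(1.96, 2.58),
                             align = TRUE,
                             freq_denominator = c("present", "all"),
                             max_redraw_factor = 10) {
  if (nsteps < 1) stop("nsteps must be at least 1")
  if (nsteps < 50)
    warning("nsteps = ", nsteps, " is below 50, the minimum for SE estimation ",
            "(200 are satisfactory)")
  else if (nsteps < 1000)
    warning("nsteps = ", nsteps, " is below 1000, the minimum to estimate ",
            "confidence intervals")
  structure(list(nsteps = as.integer(nsteps), seed = seed,
                 rotation = match.arg(rotation),
                 flagging = match.arg(flagging),
                 manual_flags = manual_flags,
                 flag_const = flag_const, abs_flagging = abs_flagging,
                 reliability_coef = reliability_coef,
                 sig_levels = sig_levels, align = isTRUE(align),
                 freq_denominator = match.arg(freq_denominator),
                 max_redraw_factor = max_redraw_factor),
            class = "q_boot_config")
}

#' Draw one bootstrap resample of Q-sort indices
#'
#' m i.i.d. uniform draws on 1..m with replacement: some Q-sorts may repeat,
#' others may be absent. Uses the current RNG state.
#'
#' @param m number of Q-sorts in the original sample.
#' @return integer vector of length m.
#' @export
draw_resample <- function(m) {
  if (m < 1) stop("m must be positive")
  sample.int(m, m, replace = TRUE)
}

#' Adapt the target loading matrix to a resample
#'
#' Because Q resamples respondents (the rows of the loading matrix), the
#' resampled loadings are row-incomparable with the full-sample target. The
#' adapted target repeats/drops target rows following the resample indices so
#' that row r of the adapted target and row r of the resampled loadings refer
#' to the same Q-sort.
#'
#' @param target m x k full-sample loading matrix.
#' @param idx resample indices (values in 1..m).
#' @return loading matrix with \code{length(idx)} rows.
#' @export
build_adapted_target <- function(target, idx) {
  target <- as.matrix(target)
  if (any(idx < 1L | idx > nrow(target)))
    stop("resample index out of range 1..", nrow(target))
  target[idx, , drop = FALSE]
}

#' Correct factor reordering and reflection against a target
#'
#' The alignment correction of the Q bootstrap. A k x k correlation matrix
#' between target and bootstrapped factor columns is computed; bootstrapped
#' factors are reordered so that each target position receives the boot
#' factor with the highest absolute correlation (greedy by descending
#' absolute correlation, each boot factor assigned once), and then reflected
#' (multiplied by -1) wherever the correlation of the matched pair is
#' negative.
#'
#' @param adapted_target loading matrix row-matched to the resample (see
#'   \code{\link{build_adapted_target}}).
#' @param boot resampled loading matrix of the same shape.
#' @return list: \code{corrected} loading matrix, \code{permutation} (entry t
#'   is the boot column moved to target position t), \code{signs} (+1/-1 per
#'   position), \code{reordered}, \code{reflected} logicals.
#' @export
align_factors <- function(adapted_target, boot) {
  T_ <- as.matrix(adapted_target); B <- as.matrix(boot)
  if (!all(dim(T_) == dim(B))) stop("target and boot loadings must have the same shape")
  k <- ncol(B)
  C <- suppressWarnings(stats::cor(T_, B))
  if (any(!is.finite(C))) {
    # constant loading columns (e.g. a resample made of copies of one Q-sort)
    # have undefined correlation; cosine similarity still identifies order and
    # reflection because loadings are anchored at zero
    cosine <- crossprod(T_, B) /
      outer(sqrt(colSums(T_^2)), sqrt(colSums(B^2)))
    C[!is.finite(C)] <- cosine[!is.finite(C)]
    if (any(!is.finite(C)))
      stop_degenerate("zero loading column: factor alignment undefined")
  }
  # greedy one-to-one assignment by descending |correlation|; ties (|cor|
  # rounded to 12 decimals) prefer positive correlation, then the diagonal,
  # then lowest indices -- all-|cor|-one ties occur when a clean resample has
  # only k distinct response patterns, and there the positive pairing is the
  # unreflected one
  cells <- expand.grid(t = seq_len(k), b = seq_len(k))
  cc <- C[cbind(cells$t, cells$b)]
  cells <- cells[order(-round(abs(cc), 12), cc < 0,
                       cells$t != cells$b, cells$t, cells$b), ]
  perm <- integer(k); used <- logical(k); filled <- logical(k)
  for (r in seq_len(nrow(cells))) {
    t <- cells$t[r]; b <- cells$b[r]
    if (!filled[t] && !used[b]) { perm[t] <- b; used[b] <- TRUE; filled[t] <- TRUE }
  }
  d <- C[cbind(seq_len(k), perm)]          # correlations of the matched pairs
  signs <- ifelse(d < 0, -1, 1)
  corrected <- sweep(B[, perm, drop = FALSE], 2, signs, `*`)
  dimnames(corrected) <- list(rownames(B), colnames(T_))
  list(corrected = corrected, permutation = perm, signs = signs,
       reordered = any(perm != seq_len(k)), reflected = any(signs < 0))
}

#' One bootstrap repetition
#'
#' Resamples the Q-sorts per \code{idx}, runs extraction and rotation with
#' the configured (fixed) methods, aligns the resampled loadings against the
#' adapted target, flags (automatically, or the fixed manual set mapped
#' through the resample indices), and computes statement z-scores and factor
#' scores. Degenerate resamples (rank below k, a factor without definers, a
#' zero-variance composite) raise a condition of class
#' \code{qboots_degenerate} which \code{\link{run_bootstrap}} handles by
#' redrawing.
#'
#' @param q the original \code{q_sorts}.
#' @param idx resample indices from \code{\link{draw_resample}}.
#' @param config a \code{q_boot_config}.
#' @param target full-sample (rotated) loading matrix.
#' @return a repetition record: list with \code{idx}, aligned
#'   \code{loadings}, \code{permutation}, \code{signs}, \code{reordered},
#'   \code{reflected}, \code{flags}, \code{zscores}, \code{factor_scores}.
#' @export
bootstrap_step <- function(q, idx, config, target) {
  k <- ncol(target)
  rq <- resample_qsorts(q, idx)
  corr <- correlate_qsorts(rq)
  ext <- tryCatch(extract_factors_pca(corr, k), error = function(e) {
    if (grepl("positive eigenvalues", conditionMessage(e)))
      stop_degenerate(conditionMessage(e)) else stop(e)
  })
  L <- if (config$rotation == "varimax") rotate_varimax(ext$loadings) else ext$loadings
  if (config$align) {
    al <- align_factors(build_adapted_target(target, idx), L)
  } else {
    al <- list(corrected = L, permutation = seq_len(k),
               signs = rep(1, k), reordered = FALSE, reflected = FALSE)
  }
  L <- al$corrected
  flags <- switch(config$flagging,
    auto = flag_qsorts_auto(L, q$n, const = config$flag_const,
                            absolute = config$abs_flagging),
    manual = {
      mf <- as.matrix(config$manual_flags)[idx, , drop = FALSE]
      dimnames(mf) <- dimnames(L)
      mf
    },
    all = matrix(TRUE, length(idx), k, dimnames = dimnames(L))
  )
  use_all <- config$flagging == "all"
  if (!use_all && any(colSums(flags) == 0))
    stop_degenerate("factor without flagged Q-sorts in this resample")
  zsc <- tryCatch(
    compute_statement_zscores(rq, L, flags, use_all = use_all),
    error = function(e) stop_degenerate(conditionMessage(e)))
  list(idx = idx, loadings = L,
       permutation = al$permutation, signs = al$signs,
       reordered = al$reordered, reflected = al$reflected,
       flags = flags, zscores = zsc,
       factor_scores = zscores_to_factor_scores(zsc, q$grid))
}

#' Aggregate bootstrap repetitions
#'
#' Per statement and factor: the mean and standard deviation (the bootstrap
#' SE, n-1 denominator) of the z-scores over repetitions, the bias (standard
#' value minus bootstrap mean), and bootstrap factor scores obtained by
#' forcing the mean z-scores back onto the grid. Per Q-sort and factor: mean
#' and SE of the aligned loadings over the repetitions in which the Q-sort
#' appears (multiple appearances within one repetition are averaged to one
#' value first), and the flagging frequency. Per factor: the Pearson
#' correlation between standard and bootstrap z-score columns.
#'
#' @param reps list of repetition records from \code{\link{bootstrap_step}}.
#' @param standard the \code{q_analysis} of the full sample.
#' @param grid the \code{q_grid}.
#' @param freq_denominator \code{"present"} (repetitions containing the
#'   Q-sort; default) or \code{"all"}.
#' @return object of class \code{q_boot_results}.
#' @export
aggregate_bootstrap <- function(reps, standard, grid,
                                freq_denominator = c("present", "all")) {
  freq_denominator <- match.arg(freq_denominator)
  if (length(reps) == 0L) stop("no non-degenerate repetitions to aggregate")
  nrep <- length(reps)
  n <- nrow(standard$zscores); k <- ncol(standard$zscores)
  m <- length(standard$qsort_ids)
  zarr <- vapply(reps, `[[`, matrix(0, n, k), "zscores")   # n x k x nrep
  zmean <- apply(zarr, c(1, 2), mean)
  zse <- if (nrep > 1) apply(zarr, c(1, 2), stats::sd) else matrix(NA_real_, n, k)
  dimnames(zmean) <- dimnames(zse) <- dimnames(standard$zscores)
  loading_mean <- loading_se <- flag_freq <-
    matrix(NA_real_, m, k, dimnames = dimnames(standard$loadings))
  present_count <- integer(m)
  for (o in seq_len(m)) {
    lo <- matrix(NA_real_, 0, k); flagged <- 0L
    for (r in reps) {
      pos <- which(r$idx == o)
      if (length(pos) == 0L) next
      lo <- rbind(lo, colMeans(r$loadings[pos, , drop = FALSE]))
      flagged <- flagged + apply(r$flags[pos, , drop = FALSE], 2, any)
    }
    present_count[o] <- nrow(lo)
    if (nrow(lo) > 0L) {
      loading_mean[o, ] <- colMeans(lo)
      if (nrow(lo) > 1L) loading_se[o, ] <- apply(lo, 2, stats::sd)
      denom <- if (freq_denominator == "present") nrow(lo) else nrep
      flag_freq[o, ] <- flagged / denom
    }
  }
  zcor <- vapply(seq_len(k), function(j)
    stats::cor(standard$zscores[, j], zmean[, j]), numeric(1))
  names(zcor) <- colnames(standard$zscores)
  structure(list(
    nsteps = nrep,
    zscore_mean = zmean, zscore_se = zse,
    zscore_bias = standard$zscores - zmean,
    factor_scores_boot = zscores_to_factor_scores(zmean, grid),
    loading_mean = loading_mean, loading_se = loading_se,
    flag_freq = flag_freq, present_count = present_count,
    zscore_correlation = zcor,
    reordered_count = sum(vapply(reps, `[[`, logical(1), "reordered")),
    reflected_count = sum(vapply(reps, `[[`, logical(1), "reflected")),
    freq_denominator = freq_denominator
  ), class = "q_boot_results")
}

#' Distinguishing statements from bootstrap variability
#'
#' Statement-specific inference: statement s distinguishes factors i and j at
#' p < .05 when the absolute difference of its bootstrap mean z-scores
#' exceeds 1.96 times \eqn{\sqrt{SE_i(s)^2 + SE_j(s)^2}} (2.58 for p < .01),
#' with the statement's own bootstrap SEs replacing the factor-level SED of
#' the standard analysis. When the standard SED is supplied, the standard
#' criteria are additionally re-applied to the bootstrap mean z-scores.
#'
#' @param boot a \code{q_boot_results}.
#' @param sed_standard optional k x k SED matrix of the standard analysis.
#' @param levels multipliers for the .05/.01 levels.
#' @return list: \code{statement_specific} (codes array,
#'   \code{distinguishing_for}, \code{consensus}) and, when
#'   \code{sed_standard} is given, \code{standard_criteria} (same structure,
#'   standard SED thresholds on bootstrap means).
#' @export
bootstrap_distinguishing <- function(boot, sed_standard = NULL,
                                     levels = c(1.96, 2.58)) {
  z <- boot$zscore_mean; se <- boot$zscore_se
  n <- nrow(z); k <- ncol(z)
  if (k < 2L) stop("need at least 2 factors")
  codes <- array("ns", dim = c(n, k, k),
                 dimnames = list(rownames(z), colnames(z), colnames(z)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    d <- abs(z[, i] - z[, j])
    sed_s <- sqrt(se[, i]^2 + se[, j]^2)
    codes[, i, j][d > levels[1] * sed_s] <- "p<.05"
    codes[, i, j][d > levels[2] * sed_s] <- "p<.01"
  }
  dist_for <- matrix(TRUE, n, k, dimnames = dimnames(z))
  for (f in seq_len(k)) for (o in setdiff(seq_len(k), f))
    dist_for[, f] <- dist_for[, f] & (codes[, f, o] != "ns")
  out <- list(statement_specific = list(
    codes = codes, distinguishing_for = dist_for,
    consensus = rowSums(dist_for) == 0))
  if (!is.null(sed_standard))
    out$standard_criteria <-
      identify_distinguishing_consensus(z, sed_standard, levels)
  out
}

#' Classify statements by salience and stability
#'
#' Two-by-two classification of statement-factor cells for interpretation:
#' salience is the magnitude of the bootstrap mean z-score, stability the
#' (inverse of the) bootstrap z-score SE. Cells that are salient and stable
#' carry the highest interpretative power and are very reliable; salient but
#' unstable cells are meaningful but their relative position is fuzzy; stable
#' but non-salient cells are reliable but not particularly meaningful; the
#' rest have the lowest interpretative power.
#'
#' @param boot a \code{q_boot_results}.
#' @param salience_cut threshold on \code{|zscore_mean|} (default 1.0).
#' @param stability_cut threshold on \code{zscore_se}; default is the median
#'   SE over all cells.
#' @return n x k character matrix with values
#'   \code{"high-salience/high-stability"},
#'   \code{"high-salience/low-stability"},
#'   \code{"low-salience/high-stability"},
#'   \code{"low-salience/low-stability"}; the cuts used are attached as
#'   attributes.
#' @export
classify_statements <- function(boot, salience_cut = 1.0,
                                stability_cut = NULL) {
  if (is.null(stability_cut))
    stability_cut <- stats::median(boot$zscore_se, na.rm = TRUE)
  salient <- abs(boot$zscore_mean) >= salience_cut
  stable <- boot$zscore_se <= stability_cut
  out <- matrix(paste0(ifelse(salient, "high", "low"), "-salience/",
                       ifelse(stable, "high", "low"), "-stability"),
                nrow(salient), ncol(salient), dimnames = dimnames(salient))
  attr(out, "salience_cut") <- salience_cut
  attr(out, "stability_cut") <- stability_cut
  out
}

#' Bootstrap a Q study
#'
#' Runs the standard analysis on the full sample to obtain the target loading
#' matrix, then draws \code{nsteps} resamples of the Q-sorts with
#' replacement, analyses each with the same fixed extraction, rotation and
#' flagging, corrects each repetition's factor order and signs against the
#' adapted target, and aggregates z-scores, loadings, biases and flagging
#' frequencies. Degenerate resamples are counted and replaced by fresh draws
#' (up to \code{max_redraw_factor * nsteps} total draws).
#'
#' @param q a \code{q_sorts}.
#' @param k number of factors.
#' @param config a \code{q_boot_config} (see \code{\link{bootstrap_config}}).
#' @return object of class \code{q_bootstrap}: list with \code{standard} (the
#'   \code{q_analysis}), \code{boot} (the \code{q_boot_results}),
#'   \code{distinguishing} (bootstrap distinguishing/consensus tests),
#'   \code{classification} (salience/stability classes), \code{config} and
#'   \code{log} (seed, draws, reorder/reflect/skip counts).
#' @export
run_bootstrap <- function(q, k, config = bootstrap_config()) {
  stopifnot(inherits(q, "q_sorts"), inherits(config, "q_boot_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  standard <- run_standard_analysis(
    q, k, rotation = config$rotation, flagging = config$flagging,
    manual_flags = config$manual_flags, flag_const = config$flag_const,
    abs_flagging = config$abs_flagging,
    reliability_coef = config$reliability_coef,
    sig_levels = config$sig_levels)
  target <- standard$loadings
  reps <- vector("list", config$nsteps)
  ok <- 0L; draws <- 0L; skipped <- 0L
  max_draws <- config$max_redraw_factor * config$nsteps
  while (ok < config$nsteps && draws < max_draws) {
    idx <- draw_resample(q$m)
    draws <- draws + 1L
    rec <- tryCatch(bootstrap_step(q, idx, config, target),
                    qboots_degenerate = function(e) NULL)
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    ok <- ok + 1L
    reps[[ok]] <- rec
  }
  if (ok < config$nsteps)
    warning("only ", ok, " of ", config$nsteps,
            " repetitions completed within the redraw cap")
  reps <- reps[seq_len(ok)]
  boot <- aggregate_bootstrap(reps, standard, q$grid,
                              freq_denominator = config$freq_denominator)
  dist <- if (k >= 2)
    bootstrap_distinguishing(boot, sed_standard = standard$sed,
                             levels = config$sig_levels) else NULL
  structure(list(
    standard = standard, boot = boot,
    distinguishing = dist,
    classification = classify_statements(boot),
    config = config,
    log = list(nsteps = config$nsteps, achieved = ok, seed = config$seed,
               draws = draws, skipped = skipped,
               reordered = boot$reordered_count,
               reflected = boot$reflected_count)
  ), class = "q_bootstrap")
}

#' @export
print.q_boot_results <- function(x, digits = 3, ...) {
  cat("Q bootstrap results over", x$nsteps, "repetitions\n")
  cat("  z-score SE range:",
      paste(format(range(x$zscore_se, na.rm = TRUE), digits = digits),
            collapse = " .. "), "\n")
  cat("  standard-vs-bootstrap z correlations:",
      paste(format(x$zscore_correlation, digits = digits), collapse = " "), "\n")
  cat("  repetitions reordered:", x$reordered_count,
      " reflected:", x$reflected_count, "\n")
  invisible(x)
}

#' @export
print.q_bootstrap <- function(x, digits = 3, ...) {
  cat("Bootstrapped Q analysis (", x$log$achieved, " repetitions, seed ",
      if (is.null(x$log$seed)) "unset" else x$log$seed, ")\n\n", sep = "")
  print(x$standard, digits = digits)
  cat("\n")
  print(x$boot, digits = digits)
  cat("  skipped degenerate resamples:", x$log$skipped, "\n")
  invisible(x)
}
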