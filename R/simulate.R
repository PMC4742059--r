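#' Latent archetype set for simulation
#'
#' Draws k archetypal statement profiles (standard-normal n-vectors),
#' rejection-sampled until all pairwise Pearson correlations are below
#' \code{cor_cap} so the perspectives are separable, and assigns respondents
#' to archetypes. Each respondent's latent vector is their archetype profile
#' plus independent Gaussian noise of standard deviation \code{noise_sd}.
#'
#' @param k number of archetypes (latent perspectives).
#' @param n number of statements.
#' @param m number of respondents; assigned to archetypes as evenly as
#'   possible, in blocks.
#' @param noise_sd respondent noise standard deviation, either a scalar or
#'   one value per respondent. The default 0.5 is moderate relative to the
#'   unit-scale profiles: individual rankings are visibly perturbed but the
#'   group structure stays recoverable.
#' @param cor_cap maximum allowed absolute pairwise profile correlation
#'   (default 0.3).
#' @param max_tries rejection-sampling cap.
#' @return object of class \code{q_archetypes}: list with \code{profiles}
#'   (n x k), \code{assignment} (length m), \code{noise_sd} (length m),
#'   \code{k}, \code{n}, \code{m}.
#' @export
make_archetypes <- function(k, n, m, noise_sd = 0.5, cor_cap = 0.3,
                            max_tries = 1000) {
  if (k < 1 || n < 3 || m < k) stop("need k >= 1, n >= 3, m >= k")
  for (i in seq_len(max_tries)) {
    profiles <- matrix(stats::rnorm(n * k), n, k,
                       dimnames = list(paste0("s", seq_len(n)),
                                       paste0("a", seq_len(k))))
    if (k == 1 || max(abs(stats::cor(profiles)[upper.tri(diag(k))])) < cor_cap)
      break
    if (i == max_tries)
      stop("could not draw ", k, " profiles with pairwise |cor| < ", cor_cap,
           " in ", max_tries, " tries")
  }
  assignment <- sort(rep_len(seq_len(k), m))
  noise_sd <- rep_len(noise_sd, m)
  structure(list(profiles = profiles, assignment = assignment,
                 noise_sd = noise_sd, k = k, n = n, m = m),
            class = "q_archetypes")
}

# deterministic latent-to-grid forcing: rank order, ties by index ascending
force_to_grid <- function(latent, grid) {
  vals <- sort(grid$values, decreasing = TRUE)
  out <- integer(length(latent))
  out[order(-latent)] <- vals
  out
}

#' Simulate forced-distribution Q-sorts from archetypes
#'
#' Each respondent's latent statement values (archetype profile plus noise)
#' are rank-forced onto the grid, exactly as factor z-scores are forced to
#' factor scores, so every generated column satisfies the forced-distribution
#' invariant by construction.
#'
#' @param arch a \code{q_archetypes}.
#' @param grid a \code{q_grid} with \code{arch$n} values.
#' @param seed optional integer seed; same seed, same dataset.
#' @return list: \code{qsorts} (a \code{q_sorts}), \code{truth} (the
#'   \code{q_archetypes} plus the seed used).
#' @export
simulate_qsorts <- function(arch, grid, seed = NULL) {
  stopifnot(inherits(arch, "q_archetypes"), inherits(grid, "q_grid"))
  if (grid$n != arch$n)
    stop("grid has ", grid$n, " values but archetypes have ", arch$n, " statements")
  if (!is.null(seed)) set.seed(seed)
  data <- matrix(NA_integer_, arch$n, arch$m)
  for (i in seq_len(arch$m)) {
    latent <- arch$profiles[, arch$assignment[i]] +
      stats::rnorm(arch$n, 0, arch$noise_sd[i])
    data[, i] <- force_to_grid(latent, grid)
  }
  q <- qsort_matrix(data, grid,
                    statement_ids = rownames(arch$profiles),
                    qsort_ids = paste0("r", seq_len(arch$m)))
  list(qsorts = q, truth = c(unclass(arch), list(seed = seed)))
}

#' Parameter recovery against simulation ground truth
#'
#' Matches estimated factors to archetypes greedily by maximal absolute
#' correlation between factor z-score profiles and archetype profiles
#' (one-to-one), then reports per-factor Pearson and Spearman correlations of
#' z-scores against the latent profiles, the Spearman correlation of the
#' recovered factor scores against the archetype profile forced onto the same
#' grid (\code{score_spearman}; both sides share the grid's tie structure, so
#' exact ranking recovery gives exactly 1), and the respondent assignment
#' accuracy: the fraction of respondents flagged on the factor matched to
#' their true archetype.
#'
#' @param results a \code{q_analysis} (or the \code{$standard} element of a
#'   \code{q_bootstrap}).
#' @param truth the \code{truth} element returned by
#'   \code{\link{simulate_qsorts}}.
#' @param grid the \code{q_grid} used for the simulated study; needed for
#'   \code{score_spearman} (defaults to the grid stored in the analysis).
#' @return list: \code{matching} (archetype index per factor), \code{pearson},
#'   \code{spearman}, \code{score_spearman} (length-k, signed),
#'   \code{assignment_accuracy}.
#' @export
recovery_metrics <- function(results, truth, grid = NULL) {
  if (inherits(results, "q_bootstrap")) results <- results$standard
  if (is.null(grid)) grid <- results$grid
  z <- results$zscores
  k <- ncol(z)
  if (k != truth$k)
    stop("analysis has ", k, " factors but truth has ", truth$k, " archetypes")
  C <- stats::cor(z, truth$profiles)
  match_arch <- integer(k); used <- logical(truth$k)
  cells <- expand.grid(f = seq_len(k), a = seq_len(truth$k))
  cells <- cells[order(-abs(C)[cbind(cells$f, cells$a)], cells$f, cells$a), ]
  for (r in seq_len(nrow(cells))) {
    f <- cells$f[r]; a <- cells$a[r]
    if (match_arch[f] == 0L && !used[a]) { match_arch[f] <- a; used[a] <- TRUE }
  }
  pearson <- vapply(seq_len(k), function(f)
    C[f, match_arch[f]], numeric(1))
  spearman <- vapply(seq_len(k), function(f)
    stats::cor(z[, f], truth$profiles[, match_arch[f]], method = "spearman"),
    numeric(1))
  score_spearman <- vapply(seq_len(k), function(f) {
    target <- force_to_grid(sign(pearson[f]) * truth$profiles[, match_arch[f]],
                            grid)
    stats::cor(results$factor_scores[, f], target, method = "spearman")
  }, numeric(1))
  # respondent accuracy: flagged factor must map to the true archetype
  flags <- results$flags
  flagged_factor <- apply(flags, 1, function(fl)
    if (any(fl)) which(fl)[1] else NA_integer_)
  correct <- !is.na(flagged_factor) &
    match_arch[replace(flagged_factor, is.na(flagged_factor), 1L)] == truth$assignment
  correct[is.na(flagged_factor)] <- FALSE
  list(matching = match_arch, pearson = pearson, spearman = spearman,
       score_spearman = score_spearman,
       assignment_accuracy = mean(correct))
}

#' Calibration of bootstrap standard errors against true sampling spread
#'
#' Monte-Carlo oracle for the bootstrap SE: regenerates \code{nrepl}
#' independent datasets from the same archetype set, runs the standard
#' analysis on each (aligning factors to a reference run so cells are
#' comparable), and takes the across-replicate standard deviation of each
#' statement z-score as the true spread. Reports the mean absolute error
#' between one dataset's bootstrap SEs and those true SDs.
#'
#' @param arch a \code{q_archetypes}.
#' @param grid a \code{q_grid}.
#' @param k factors to extract.
#' @param nrepl number of regenerated datasets (default 100).
#' @param nsteps bootstrap repetitions for the single bootstrapped dataset.
#' @param seed integer seed.
#' @return list: \code{mae} (mean absolute SE error), \code{boot_se},
#'   \code{true_sd} (both n x k).
#' @export
se_calibration <- function(arch, grid, k, nrepl = 100, nsteps = 200, seed = 1) {
  set.seed(seed)
  ref_sim <- simulate_qsorts(arch, grid)
  ref <- run_standard_analysis(ref_sim$qsorts, k)
  zrep <- array(NA_real_, c(arch$n, k, nrepl))
  for (r in seq_len(nrepl)) {
    sim <- simulate_qsorts(arch, grid)
    res <- run_standard_analysis(sim$qsorts, k)
    al <- align_factors(ref$loadings, res$loadings)
    zrep[, , r] <- sweep(res$zscores[, al$permutation, drop = FALSE],
                         2, al$signs, `*`)
  }
  true_sd <- apply(zrep, c(1, 2), stats::sd)
  cfg <- suppressWarnings(bootstrap_config(nsteps = nsteps, seed = seed + 1))
  bt <- run_bootstrap(ref_sim$qsorts, k, cfg)
  list(mae = mean(abs(bt$boot$zscore_se - true_sd)),
       boot_se = bt$boot$zscore_se, true_sd = true_sd)
}
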