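#' Correlate Q-sorts
#'
#' In Q methodology the respondents, not the variables, are correlated: the
#' result is the m x m Pearson correlation matrix between Q-sort columns, the
#' starting point for factor extraction.
#'
#' @param q a \code{q_sorts} object.
#' @return m x m symmetric correlation matrix with unit diagonal.
#' @export
correlate_qsorts <- function(q) {
  stopifnot(inherits(q, "q_sorts"))
  sds <- apply(q$data, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance Q-sort column(s): ",
         paste(q$qsort_ids[sds == 0], collapse = ", "))
  stats::cor(q$data)
}

# orient each column so its largest-magnitude entry is positive (first max on ties)
orient_columns <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Extract unrotated principal-component factors
#'
#' Eigendecomposition of the Q-sort correlation matrix; column j of the
#' loading matrix is the j-th eigenvector scaled by the square root of its
#' eigenvalue, so that loadings are correlations of Q-sorts with components.
#' Each column is sign-oriented so that its largest-magnitude loading is
#' positive, which makes the extraction deterministic.
#'
#' @param corr m x m symmetric correlation matrix.
#' @param k number of factors to retain (at most the number of positive
#'   eigenvalues).
#' @return list with \code{loadings} (m x k), \code{eigenvalues} (all m, in
#'   descending order).
#' @export
extract_factors_pca <- function(corr, k) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("corr must be a symmetric square matrix")
  m <- nrow(corr)
  if (k < 1L || k > m) stop("k must be between 1 and ", m)
  e <- eigen(corr, symmetric = TRUE)
  npos <- sum(e$values > 1e-8)
  if (k > npos)
    stop("k = ", k, " exceeds the number of positive eigenvalues (", npos,
         "); the resample has too few distinct Q-sorts")
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  L <- orient_columns(L)
  dimnames(L) <- list(rownames(corr), paste0("f", seq_len(k)))
  list(loadings = L, eigenvalues = e$values)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximising the varimax criterion with Kaiser row
#' normalization (each row scaled to unit communality during rotation),
#' delegated to \code{\link[stats]{varimax}} with convergence tolerance
#' \code{eps} on the relative change of the criterion. After rotation the
#' factors are reordered by decreasing explained variance and sign-oriented as
#' in extraction. Row communalities are preserved by construction and checked.
#'
#' @param loadings m x k loading matrix; returned unchanged when k = 1.
#' @param eps convergence tolerance (default 1e-5).
#' @return rotated m x k loading matrix; attribute \code{"rotmat"} holds the
#'   orthogonal matrix R with \code{loadings \%*\% R} equal to the result.
#' @export
rotate_varimax <- function(loadings, eps = 1e-5) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2L) {
    attr(L, "rotmat") <- diag(1)
    return(L)
  }
  # multi-start: the identity start is a stationary point for some exactly
  # symmetric configurations, so also start from fixed orthogonal rotations
  # (deterministic, no RNG use) and keep the best criterion value
  best <- NULL; best_crit <- -Inf
  for (S in varimax_starts(k)) {
    vr <- stats::varimax(L %*% S, normalize = TRUE, eps = eps)
    Rs <- S %*% vr$rotmat
    crit <- varimax_criterion(L %*% Rs)
    if (crit > best_crit) { best_crit <- crit; best <- Rs }
  }
  R <- best
  Z <- L %*% R
  # deterministic presentation: order by explained variance, largest loading positive
  ord <- order(colSums(Z^2), decreasing = TRUE)
  Z <- Z[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(Z[, j]))
    if (Z[i, j] < 0) { Z[, j] <- -Z[, j]; R[, j] <- -R[, j] }
  }
  if (max(abs(rowSums(Z^2) - rowSums(L^2))) > 1e-6)
    stop("varimax failed to preserve communalities at tolerance 1e-6 (eps = ",
         eps, ")")
  dimnames(Z) <- list(rownames(L), paste0("f", seq_len(k)))
  attr(Z, "rotmat") <- R
  Z
}

# fixed orthogonal start rotations for multi-start varimax: identity plus the
# Q factors of deterministic dense matrices (no RNG involved)
varimax_starts <- function(k) {
  starts <- list(diag(k))
  for (t in 1:3) {
    M <- matrix(sin(seq_len(k * k) * t + t), k, k) + diag(k)
    Q <- qr.Q(qr(M))
    starts[[t + 1L]] <- Q
  }
  starts
}

# raw varimax criterion (Kaiser-normalized rows), used by tests as an oracle
# and exported for transparency
#' Varimax simplicity criterion
#'
#' Sum over factors of the variance of squared (Kaiser-normalized) loadings;
#' the quantity varimax rotation maximises.
#'
#' @param loadings m x k loading matrix.
#' @param normalize apply Kaiser row normalization first (default TRUE).
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  L <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  sq <- L^2
  sum(apply(sq, 2, function(col) mean((col - mean(col))^2)))
}

#' Automatic flagging of defining Q-sorts
#'
#' A Q-sort is flagged for a factor when (1) its loading is significantly
#' high, i.e. exceeds \code{const/sqrt(n)} where n is the number of statements
#' (1.96 for p < .05, 2.58 for p < .01), and (2) the squared loading on that
#' factor exceeds the sum of its squared loadings on all other factors.
#' Criterion 2 guarantees at most one flag per Q-sort. By default the rule is
#' signed (only positive loaders define a factor); set \code{absolute = TRUE}
#' to flag on \code{|loading|}.
#'
#' @param loadings m x k loading matrix.
#' @param nstat number of statements (determines the significance threshold).
#' @param const significance constant, default 1.96.
#' @param absolute flag on absolute loadings instead of signed ones.
#' @return m x k logical matrix of flags.
#' @export
flag_qsorts_auto <- function(loadings, nstat, const = 1.96, absolute = FALSE) {
  if (nstat < 3L) stop("need at least 3 statements")
  L <- as.matrix(loadings)
  thr <- const / sqrt(nstat)
  crit1 <- if (absolute) abs(L) > thr else L > thr
  crit2 <- L^2 > (rowSums(L^2) - L^2)
  flags <- crit1 & crit2
  dimnames(flags) <- dimnames(L)
  flags
}

#' Statement z-scores per factor
#'
#' The z-score of a statement for a factor is the standardized weighted
#' average of the values that the factor's defining (flagged) Q-sorts gave to
#' the statement. Weights follow Brown's formula \eqn{w = f / (1 - f^2)} on
#' the defining loadings f (clamped to |f| < 1); the weighted composite is
#' then standardized across statements to mean 0 and unit standard deviation.
#'
#' @param q a \code{q_sorts} object.
#' @param loadings m x k loading matrix.
#' @param flags m x k logical flag matrix; ignored when \code{use_all = TRUE}.
#' @param use_all use every Q-sort, weighted by its loading, instead of only
#'   flagged definers.
#' @return n x k matrix of z-scores.
#' @export
compute_statement_zscores <- function(q, loadings, flags, use_all = FALSE) {
  stopifnot(inherits(q, "q_sorts"))
  L <- as.matrix(loadings)
  k <- ncol(L)
  z <- matrix(NA_real_, q$n, k,
              dimnames = list(q$statement_ids, colnames(L)))
  for (j in seq_len(k)) {
    sel <- if (use_all) seq_len(q$m) else which(flags[, j])
    if (length(sel) == 0L)
      stop("factor ", j, " has no flagged Q-sorts; cannot compute z-scores")
    f <- L[sel, j]
    f <- pmax(pmin(f, 1 - 1e-6), -(1 - 1e-6))
    w <- f / (1 - f^2)
    comp <- as.vector(q$data[, sel, drop = FALSE] %*% w)
    s <- stats::sd(comp)
    if (!is.finite(s) || s == 0)
      stop("z-score composite for factor ", j, " has zero variance")
    z[, j] <- (comp - mean(comp)) / s
  }
  z
}

#' Force z-scores back onto the grid (factor scores)
#'
#' Orders the statements of each factor by descending z-score and assigns the
#' grid values in descending order, so each factor's scores are a permutation
#' of the forced distribution. Ties in z are broken by statement index
#' (ascending), making the assignment deterministic.
#'
#' @param zscores n x k matrix of statement z-scores.
#' @param grid a \code{q_grid} with n values.
#' @return n x k integer matrix of factor scores.
#' @export
zscores_to_factor_scores <- function(zscores, grid) {
  z <- as.matrix(zscores)
  if (grid$n != nrow(z))
    stop("grid has ", grid$n, " values but z-scores have ", nrow(z), " rows")
  vals <- sort(grid$values, decreasing = TRUE)
  out <- matrix(NA_integer_, nrow(z), ncol(z), dimnames = dimnames(z))
  for (j in seq_len(ncol(z))) {
    ord <- order(-z[, j])      # stable: ties keep ascending statement index
    out[ord, j] <- vals
  }
  out
}

#' General factor characteristics
#'
#' For each factor: the number of defining Q-sorts p, the composite
#' reliability \eqn{r_f = 0.8 p / (1 + (p - 1) 0.8)} (0.8 being the customary
#' average reliability coefficient), the standard error of factor z-scores
#' \eqn{SE_f = s \sqrt{1 - r_f}} with s the population standard deviation of
#' the grid values, the explained variance (sum of squared loadings, reported
#' also as a percentage of m), and the factor's eigenvalue. Factors with p = 0
#' get \code{NA} reliability and SE.
#'
#' @param flags m x k logical flag matrix.
#' @param loadings m x k loading matrix (rotated).
#' @param grid a \code{q_grid}.
#' @param reliability_coef average reliability coefficient (default 0.8).
#' @param use_all if TRUE, p is the number of Q-sorts m (all sorts define).
#' @return data frame with one row per factor: \code{factor}, \code{p},
#'   \code{reliability}, \code{se_f}, \code{eigenvalue}, \code{expl_var_pct}.
#' @export
factor_characteristics <- function(flags, loadings, grid,
                                   reliability_coef = 0.8, use_all = FALSE) {
  L <- as.matrix(loadings)
  m <- nrow(L)
  p <- if (use_all) rep(m, ncol(L)) else colSums(as.matrix(flags))
  rf <- ifelse(p >= 1,
               reliability_coef * p / (1 + (p - 1) * reliability_coef),
               NA_real_)
  se <- grid$sd * sqrt(1 - rf)
  ev <- colSums(L^2)
  data.frame(factor = colnames(L) %||% paste0("f", seq_len(ncol(L))),
             p = as.integer(p), reliability = rf, se_f = se,
             eigenvalue = ev, expl_var_pct = 100 * ev / m,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard errors of differences between factors
#'
#' \eqn{SED_{ij} = \sqrt{SE_i^2 + SE_j^2}}; symmetric with zero diagonal.
#'
#' @param se numeric vector of per-factor z-score standard errors.
#' @return k x k SED matrix.
#' @export
sed_matrix <- function(se) {
  k <- length(se)
  out <- sqrt(outer(se^2, se^2, `+`))
  diag(out) <- 0
  dimnames(out) <- list(names(se), names(se))
  out
}

#' Distinguishing and consensus statements
#'
#' A statement distinguishes factor i from factor j at p < .05 when the
#' absolute difference of its z-scores exceeds 1.96 SED_ij (2.58 for p < .01).
#' It is distinguishing FOR a factor when it distinguishes that factor from
#' every other factor (at .05 or better), and consensus when it distinguishes
#' no factor.
#'
#' @param zscores n x k z-score matrix.
#' @param sed k x k SED matrix.
#' @param levels multipliers for the .05 and .01 levels (default 1.96, 2.58).
#' @return list: \code{codes} n x k x k character array with values
#'   \code{"ns"}, \code{"p<.05"}, \code{"p<.01"}; \code{distinguishing_for}
#'   n x k logical; \code{consensus} length-n logical.
#' @export
identify_distinguishing_consensus <- function(zscores, sed,
                                              levels = c(1.96, 2.58)) {
  z <- as.matrix(zscores)
  k <- ncol(z)
  if (k < 2L) stop("need at least 2 factors")
  n <- nrow(z)
  codes <- array("ns", dim = c(n, k, k),
                 dimnames = list(rownames(z), colnames(z), colnames(z)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    d <- abs(z[, i] - z[, j])
    codes[, i, j][d > levels[1] * sed[i, j]] <- "p<.05"
    codes[, i, j][d > levels[2] * sed[i, j]] <- "p<.01"
  }
  dist_for <- matrix(TRUE, n, k, dimnames = dimnames(z))
  for (f in seq_len(k)) {
    others <- setdiff(seq_len(k), f)
    for (o in others)
      dist_for[, f] <- dist_for[, f] & (codes[, f, o] != "ns")
  }
  list(codes = codes, distinguishing_for = dist_for,
       consensus = rowSums(dist_for) == 0)
}

#' Run the standard Q analysis
#'
#' Composes the full standard pipeline: correlation of Q-sorts, PCA
#' extraction, varimax rotation, flagging, statement z-scores and factor
#' scores, factor characteristics (reliability, SE, SED), factor z-score
#' correlations, and distinguishing/consensus classification.
#'
#' @param q a \code{q_sorts} object.
#' @param k number of factors to extract.
#' @param rotation \code{"varimax"} (default) or \code{"none"}.
#' @param flagging \code{"auto"} (significance + majority criteria),
#'   \code{"manual"} (supply \code{manual_flags}), or \code{"all"} (every
#'   Q-sort weighted by its loading).
#' @param manual_flags m x k logical matrix, required for manual flagging.
#' @param flag_const significance constant for automatic flagging (1.96).
#' @param abs_flagging flag on absolute loadings (default FALSE: signed).
#' @param reliability_coef average reliability coefficient (0.8).
#' @param sig_levels multipliers for the .05/.01 distinguishing thresholds.
#' @return object of class \code{q_analysis}.
#' @export
run_standard_analysis <- function(q, k,
                                  rotation = c("varimax", "none"),
                                  flagging = c("auto", "manual", "all"),
                                  manual_flags = NULL,
                                  flag_const = 1.96,
                                  abs_flagging = FALSE,
                                  reliability_coef = 0.8,
                                  sig_levels = c(1.96, 2.58)) {
  stopifnot(inherits(q, "q_sorts"))
  rotation <- match.arg(rotation)
  flagging <- match.arg(flagging)
  if (k > q$m) stop("cannot extract k = ", k, " factors from m = ", q$m, " Q-sorts")
  corr <- correlate_qsorts(q)
  ext <- extract_factors_pca(corr, k)
  loadings <- if (rotation == "varimax") rotate_varimax(ext$loadings) else ext$loadings
  flags <- switch(flagging,
    auto = flag_qsorts_auto(loadings, q$n, const = flag_const,
                            absolute = abs_flagging),
    manual = {
      if (is.null(manual_flags))
        stop("manual flagging requires an m x k logical manual_flags matrix")
      mf <- as.matrix(manual_flags)
      if (!all(dim(mf) == dim(loadings)))
        stop("manual_flags must be ", q$m, " x ", k)
      storage.mode(mf) <- "logical"
      dimnames(mf) <- dimnames(loadings)
      mf
    },
    all = matrix(TRUE, q$m, k, dimnames = dimnames(loadings))
  )
  use_all <- flagging == "all"
  zsc <- compute_statement_zscores(q, loadings, flags, use_all = use_all)
  fsc <- zscores_to_factor_scores(zsc, q$grid)
  chars <- factor_characteristics(flags, loadings, q$grid,
                                  reliability_coef = reliability_coef,
                                  use_all = use_all)
  sed <- sed_matrix(stats::setNames(chars$se_f, chars$factor))
  dist <- if (k >= 2) identify_distinguishing_consensus(zsc, sed, sig_levels) else NULL
  structure(list(
    k = k, grid = q$grid,
    statement_ids = q$statement_ids, qsort_ids = q$qsort_ids,
    options = list(rotation = rotation, flagging = flagging,
                   flag_const = flag_const, abs_flagging = abs_flagging,
                   reliability_coef = reliability_coef,
                   sig_levels = sig_levels),
    corr = corr, eigenvalues = ext$eigenvalues,
    unrotated = ext$loadings, loadings = loadings,
    flags = flags, zscores = zsc, factor_scores = fsc,
    characteristics = chars, sed = sed,
    zscore_correlations = stats::cor(zsc),
    distinguishing = dist
  ), class = "q_analysis")
}

#' @export
print.q_analysis <- function(x, digits = 3, ...) {
  cat("Standard Q analysis:", length(x$statement_ids), "statements,",
      length(x$qsort_ids), "Q-sorts,", x$k, "factors (",
      x$options$rotation, "rotation,", x$options$flagging, "flagging)\n\n")
  cat("Factor characteristics:\n")
  print(x$characteristics, digits = digits, row.names = FALSE)
  cat("\nFlagged Q-sorts per factor:",
      paste(colSums(x$flags), collapse = " "), "\n")
  if (!is.null(x$distinguishing))
    cat("Consensus statements:", sum(x$distinguishing$consensus), "of",
        length(x$statement_ids), "\n")
  invisible(x)
}
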