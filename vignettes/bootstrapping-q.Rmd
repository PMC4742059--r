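---
title: "Bootstrapped Q methodology: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapped Q methodology: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qboots)
```

## The problem

Q methodology identifies typologies of perspectives from ranked-statement
data. Each of m respondents sorts n statements into a fixed quasi-normal
grid (the *forced distribution*), producing a Q-sort: an integer vector
whose value multiset is exactly the grid's. The analysis correlates
*respondents* rather than variables, reduces the m×m correlation matrix to
a few factors — archetypal Q-sorts — and reconstructs each factor's
statement ranking.

The standard analysis reports a single standard error per factor, derived
from nothing but the number of defining respondents and the grid shape. It
attaches no variability measure to individual statements (on which
interpretation rests) or to factor loadings (which tie respondents to
perspectives). `qboots` adds a non-parametric bootstrap of the Q-sorts that
yields statement-specific z-score standard errors and bias estimates,
loading standard errors, and per-respondent flagging frequencies.

## The standard pipeline

`run_standard_analysis()` composes:

1. **Correlation** of Q-sort columns (Pearson).
2. **Extraction** by principal components: column j of the loading matrix is
   the j-th eigenvector of the correlation matrix scaled by the square root
   of its eigenvalue, so loadings are respondent–factor correlations in
   [−1, 1]. Each column is oriented so its largest-magnitude loading is
   positive, which fixes the sign indeterminacy of eigenvectors.
3. **Varimax rotation** with Kaiser row normalization (k = 1 passes
   through). Communalities are preserved and checked to 1e−6; the rotation
   matrix is orthogonal by construction.
4. **Flagging** of defining Q-sorts: loading above the significance
   threshold `const/sqrt(n)` (1.96 by default, p < .05) *and* squared
   loading strictly greater than the sum of squared loadings on all other
   factors. The majority criterion guarantees at most one flag per
   respondent.
5. **Statement z-scores**: each factor's score vector is the weighted
   average of its definers' raw values, weights `w = f/(1 − f²)` on the
   defining loadings, standardized across statements to mean 0 and unit
   (sample) standard deviation.
6. **Factor scores**: statements ordered by z-score are matched to the grid
   values in descending order, so each factor's integer scores are a
   permutation of the grid.
7. **Factor characteristics and tests**: composite reliability
   `r_f = 0.8p / (1 + (p − 1)·0.8)` with p the number of definers, factor
   z-score standard error `SE_f = s·sqrt(1 − r_f)` with s the population
   standard deviation of the grid values, `SED_ij = sqrt(SE_i² + SE_j²)`,
   and the distinguishing/consensus classification: a statement
   distinguishes factors i and j at p < .05 when |z_i − z_j| > 1.96·SED_ij
   (2.58 for p < .01); it is distinguishing *for* a factor when it
   distinguishes it from every other factor, and consensus when it
   distinguishes none.

## The bootstrap and the alignment problem

`run_bootstrap()` first runs the standard analysis to obtain the *target*
loading matrix, then draws resamples of the m Q-sorts with replacement and
re-runs extraction, rotation, flagging and scoring on each with the same
fixed options. Naively aggregating these repetitions inflates variability:
factor extraction is indifferent to column order (factors explaining
similar variance swap places) and to sign (a factor and its mirror image
fit equally well). The correction compares each repetition to the target:

- Because Q resamples the *rows* of the loading matrix, the target is first
  row-adapted to the resample (`build_adapted_target()`), repeating and
  dropping target rows so row r of both matrices refers to the same
  respondent.
- `align_factors()` computes the k×k correlation matrix between target and
  bootstrapped factor columns, reorders the bootstrapped factors so each
  target position receives the factor with the highest absolute
  correlation, and reflects (negates) any factor whose matched correlation
  is negative.

Aggregation then reports, per statement and factor, the mean and standard
deviation (the bootstrap SE, n−1 denominator) of z-scores, the bias
(standard value minus bootstrap mean), and bootstrap factor scores obtained
by forcing the mean z-scores back onto the grid; per respondent and factor,
the loading mean, loading SE and flagging frequency; and per factor the
correlation between standard and bootstrap z-score columns.

## Tunable parameters

- `nsteps` (default 2000): bootstrap repetitions. Below 50 even SEs are
  unreliable (200 are satisfactory); CIs need at least 1000. The
  constructor warns below those marks.
- `flag_const` (default 1.96): flagging significance constant; 2.58 gives
  the stricter p < .01 rule. The signed rule (only positive loaders define
  a factor) is the default because Q factors are interpreted from their
  positive definers; `abs_flagging = TRUE` switches to absolute loadings.
- `reliability_coef` (default 0.8): the customary average reliability
  coefficient entering `r_f`.
- `freq_denominator`: flagging frequency counts flagged repetitions over
  repetitions *in which the respondent appears* (default) or over all
  repetitions.
- `salience_cut` (1.0, in z units) and `stability_cut` (median bootstrap
  SE) for the two-by-two salience/stability classification; the ambiguity
  band for respondents defaults to flagging frequencies in (0.2, 0.8).

## Numerical choices

- **Varimax** is delegated to `stats::varimax` (Kaiser normalization on,
  tolerance 1e−5 on the criterion plateau). Because exactly symmetric
  loading configurations — which noise-free simulated data produce — are
  stationary saddles of the criterion where the algorithm stalls at its
  start, the rotation is run from the identity plus three fixed orthogonal
  starts (no RNG involved) and the solution with the highest criterion is
  kept. Factors are then reordered by explained variance and sign-oriented.
- **Alignment tie-breaks**: the greedy reorder assignment ranks candidate
  pairings by absolute correlation rounded to 12 decimals, preferring
  positive correlation, then the diagonal, then lowest indices. The
  positive-first rule matters when a clean resample contains only k
  distinct response patterns: every target–boot column correlation is then
  exactly ±1, and the positive pairing is the unreflected one.
- **Constant loading columns** (e.g. a resample made of copies of a single
  Q-sort) have undefined Pearson correlation with any target column; the
  alignment falls back to cosine similarity, which still identifies order
  and reflection because loadings are anchored at zero. Only when that too
  is undefined is the repetition skipped.
- **Degenerate repetitions** — resamples with fewer distinct Q-sorts than
  factors, or leaving some factor without definers — are skipped, counted,
  and replaced by fresh draws, capped at 10·`nsteps` total draws.
  Zero-filling them would bias SEs downward.
- **Ties** when forcing z-scores onto the grid are broken by statement
  index (stable sort), and the synthetic generator uses the identical rule,
  so exact recovery is well-defined.
- **Standardization** of z-score composites uses the sample SD; factor
  scores are invariant to this choice. Loadings with |f| ≥ 1 are clamped to
  1 − 1e−6 before Brown weighting.
- The population SD (divide by n) is used for the grid's s in `SE_f`: the
  grid is the complete response distribution, not a sample from one.
- One seeded RNG drives the whole run; skips and logging consume no random
  numbers, so enabling diagnostics never changes the resample stream.

## The synthetic-data generator

`make_archetypes()` draws k standard-normal statement profiles, rejection
sampled until all pairwise correlations are below 0.3 (separable
perspectives), assigns respondents to archetypes in blocks, and
`simulate_qsorts()` adds Gaussian respondent noise (default SD 0.5,
moderate against unit-scale profiles) before rank-forcing each latent
vector onto the grid. Generated data therefore satisfy the
forced-distribution invariant by construction, and the ground truth
(profiles, assignments, noise) is returned for recovery checks.

What this emulates: a population whose views cluster around a few latent
perspectives with independent idiosyncratic deviation. What it does not:
response styles (e.g. extreme-column avoidance), correlated errors between
similar statements, respondents blending several perspectives, or
non-forced sorting. Tests passing on these data show the *algorithms*
recover known structure under the stated noise model; they do not certify
behaviour on real data with those unmodelled features.

`recovery_metrics()` matches factors to archetypes greedily by absolute
z–profile correlation and reports Pearson/Spearman profile correlations, a
rank correlation on the grid-forced scale (`score_spearman`, which is
exactly 1 on noise-free data because both sides share the grid's tie
structure), and respondent assignment accuracy via flags.
`se_calibration()` is the Monte-Carlo oracle for the bootstrap SE: it
regenerates datasets from the same truth and compares the across-replicate
SD of z-scores with one dataset's bootstrap SEs.

## Problem sizes used in the test-suite checks

The suite exercises exhaustive alignment recovery for k ≤ 5 (all
permutations × sign patterns of a 12-row target), noise-free conservation
with 12 respondents and 100 repetitions, varimax against a 0.1°-step angle
search on two-factor problems, and parameter recovery with 45 respondents,
3 archetypes, 33 statements and 200 repetitions — sizes chosen so each
property is demonstrated on a realistic scale while the whole suite runs in
a couple of minutes.

## Known limitations

- Extraction is PCA only; centroid extraction, judgemental rotation and
  interactive flag editing are out of scope. Manual flagging is supported
  under the bootstrap only as a fixed flag set mapped through the resample
  indices.
- The alignment correction assumes the full-sample solution is a sensible
  reference; if the standard analysis itself is unstable (e.g. k chosen too
  large), corrected repetitions inherit that instability.
- Bootstrap intervals beyond SE-based ones (percentile, BCa) are not
  provided, and k is fixed across repetitions.
- With very small m, many resamples are degenerate; the redraw cap then
  limits the achieved number of repetitions (reported in the run log).
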