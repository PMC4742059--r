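# qboots — bootstrapped Q-methodology analysis

Q methodology identifies typologies of human perspectives: each of *m*
respondents ranks *n* statements into a fixed quasi-normal grid (a *Q-sort*),
the respondents — not the variables — are correlated, and the correlation
matrix is reduced to a few *factors*, archetypal Q-sorts that summarise
groups with similar views. Interpretation rests on each factor's statement
*z-scores* (standardized weighted averages over the factor's defining,
*flagged*, Q-sorts) and integer *factor scores* (z-scores forced back onto
the grid), plus the *distinguishing/consensus* classification: statement
z-score differences between factors i and j are tested against
`SED_ij = sqrt(SE_i^2 + SE_j^2)` at 1.96 (p&nbsp;<&nbsp;.05) and 2.58
(p&nbsp;<&nbsp;.01), where `SE_f = s*sqrt(1 - r_f)`,
`r_f = 0.8p/(1 + (p-1)*0.8)`, *p* is the number of defining Q-sorts and *s*
the grid's population SD.

These standard variability measures are one number per factor. `qboots` adds
a non-parametric bootstrap of the Q-sorts: resamples with replacement are
re-analysed with fixed extraction (PCA), rotation (varimax) and flagging,
and each repetition is corrected for the *alignment problem* — the arbitrary
reordering and sign reflection of factors across resamples that would
otherwise inflate variability — by reordering and reflecting factors against
the full-sample target loading matrix (row-adapted to each resample). The
result is what the standard analysis cannot give:

- statement-specific z-score standard errors and bias estimates,
- loading standard errors per respondent,
- flagging frequencies (how consistently each respondent defines a factor),
- statement-specific distinguishing tests and a salience × stability
  classification of statements for interpretation.

## Worked example

```r
library(qboots)

grid <- make_grid(20, -3, 3)                       # 20 statements, columns -3..3
set.seed(10)
arch <- make_archetypes(2, 20, 12, noise_sd = 0.5) # 2 latent perspectives, 12 respondents
sim  <- simulate_qsorts(arch, grid)

res <- run_bootstrap(sim$qsorts, 2, bootstrap_config(nsteps = 500, seed = 11))
print(res)
```

```
Bootstrapped Q analysis (500 repetitions, seed 11)

Standard Q analysis: 20 statements, 12 Q-sorts, 2 factors ( varimax rotation, auto flagging)

Factor characteristics:
 factor p reliability  se_f eigenvalue expl_var_pct
     f1 6        0.96 0.363       4.79         39.9
     f2 6        0.96 0.363       4.54         37.9

Flagged Q-sorts per factor: 6 6
Consensus statements: 9 of 20

Q bootstrap results over 500 repetitions
  z-score SE range: 0.0436 .. 0.5612
  standard-vs-bootstrap z correlations: 0.999 0.999
  repetitions reordered: 219  reflected: 0
  skipped degenerate resamples: 1
```

Each factor is defined by 6 respondents (`p`), giving composite reliability
0.96 and a factor-level `SE_f` of 0.363 grid units. The bootstrap refines
this single number into per-statement SEs ranging from 0.04 (very stable
positions) to 0.56 (ambiguous ones); 219 of 500 repetitions needed factor
reordering, which untreated would have contaminated those SEs. Per-statement
detail:

```r
head(statement_table(res)[, c("statement", "factor", "z_standard", "z_boot",
                              "z_se", "fscore_standard", "fscore_boot")], 4)
```

```
  statement factor z_standard     z_boot      z_se fscore_standard fscore_boot
1        s1     f1 -0.1740724 -0.1999309 0.3213228               0           0
2        s2     f1 -0.3572155 -0.4085351 0.2610749              -1          -1
3        s3     f1 -1.7004916 -1.6447336 0.1381286              -3          -3
4        s4     f1 -0.6315318 -0.5498424 0.2141660              -2          -1
```

Statement `s3` is salient (z ≈ −1.7) and stable (SE 0.14): high
interpretative power. `s4` moves one grid column under the bootstrap — its
position should be read with care. Recovery against the simulation's ground
truth (`recovery_metrics(res, sim$truth)`) gives factor–archetype
correlations 0.968 and 0.965 with every respondent assigned to the correct
perspective.

`render_interpretation_tables(res)` prints the salience/stability classes,
the statements that lose distinctiveness under the bootstrap, and the
ambiguously flagged respondents; `write_results(res, "out/")` writes the
statement, Q-sort and factor tables plus a run log. A command-line wrapper
with `run`, `boot`, `simulate` and `report` subcommands is installed at
`inst/cli/qboots`.

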