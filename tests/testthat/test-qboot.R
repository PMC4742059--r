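test_that("resampling is reproducible and uniform with replacement", {
  set.seed(61); a <- draw_resample(4)
  set.seed(61); b <- draw_resample(4)
  expect_identical(a, b)
  expect_identical({set.seed(62); draw_resample(1)}, 1L)
  set.seed(63)
  draws <- replicate(10000, draw_resample(4))
  freq <- table(factor(draws, levels = 1:4)) / length(draws)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("the adapted target row-matches the resample", {
  set.seed(64)
  target <- matrix(rnorm(12), 4, 3)
  expect_identical(build_adapted_target(target, 1:4), target)
  adapted <- build_adapted_target(target, c(1, 1, 1, 4))
  expect_identical(adapted, target[c(1, 1, 1, 4), ])
  idx <- c(3, 2, 2, 4)
  out <- build_adapted_target(target, idx)
  for (r in seq_along(idx))
    expect_identical(out[r, ], target[idx[r], ])
  expect_error(build_adapted_target(target, c(1, 2, 5, 3)), "out of range")
})

test_that("alignment correction inverts column permutations and reflections", {
  set.seed(65)
  target <- matrix(rnorm(30), 10, 3)
  al0 <- align_factors(target, target)
  expect_equal(al0$permutation, 1:3)
  expect_equal(al0$signs, rep(1, 3))
  expect_false(al0$reordered || al0$reflected)

  boot <- target[, c(2, 1, 3)]
  boot[, 3] <- -boot[, 3]
  al <- align_factors(target, boot)
  expect_equal(al$permutation, c(2, 1, 3))
  expect_equal(al$signs, c(1, 1, -1))
  expect_true(al$reordered && al$reflected)
  expect_equal(unname(al$corrected), unname(target))

  noisy <- target + matrix(rnorm(30, sd = 0.01), 10, 3)
  aln <- align_factors(target, noisy)
  expect_equal(aln$permutation, 1:3)
  expect_equal(aln$signs, rep(1, 3))
})

test_that("an identity resample reproduces the standard analysis", {
  g <- fig_grid()
  sim <- archetype_qsorts(2, 9, 8, noise_sd = 0.3, grid = g, seed = 66)
  std <- run_standard_analysis(sim$qsorts, 2)
  cfg <- quiet_config(nsteps = 1, seed = 1)
  rec <- bootstrap_step(sim$qsorts, seq_len(8), cfg, std$loadings)
  expect_equal(rec$zscores, std$zscores, tolerance = 1e-10)
  expect_equal(rec$permutation, 1:2)
  expect_equal(rec$factor_scores, std$factor_scores)
})

test_that("an all-duplicates resample with one factor yields that sort's profile", {
  g <- fig_grid()
  q <- random_qsorts(g, 5, seed = 67)
  std <- run_standard_analysis(q, 1)
  cfg <- quiet_config(nsteps = 1, seed = 1)
  # duplicate a sort that shares the target factor's orientation
  j <- which(std$loadings[, 1] > 0)[1]
  rec <- bootstrap_step(q, rep(j, 5), cfg, std$loadings)
  expect_equal(unname(rec$zscores[, 1]), as.vector(scale(q$data[, j])))
})

test_that("resamples of noise-free archetype data keep the archetype rankings", {
  g <- make_grid(12, -2, 2)
  sim <- archetype_qsorts(2, 12, 10, noise_sd = 0, grid = g, seed = 68)
  std <- run_standard_analysis(sim$qsorts, 2)
  cfg <- quiet_config(nsteps = 1, seed = 1)
  set.seed(69)
  for (i in 1:10) {
    idx <- draw_resample(10)
    rec <- tryCatch(bootstrap_step(sim$qsorts, idx, cfg, std$loadings),
                    qboots_degenerate = function(e) NULL)
    if (is.null(rec)) next
    expect_equal(rec$factor_scores, std$factor_scores)
  }
})

test_that("aggregation computes means, sample-SD SEs, bias and frequencies", {
  g <- fig_grid()
  sim <- archetype_qsorts(2, 9, 6, noise_sd = 0.3, grid = g, seed = 70)
  std <- run_standard_analysis(sim$qsorts, 2)
  cfg <- quiet_config(nsteps = 1, seed = 1)
  rec <- bootstrap_step(sim$qsorts, seq_len(6), cfg, std$loadings)

  # identical repetitions conserve: zero SE, zero bias, frequencies in {0,1}
  agg <- aggregate_bootstrap(list(rec, rec, rec), std, g)
  expect_equal(max(agg$zscore_se), 0)
  expect_equal(max(abs(agg$zscore_bias)), 0, tolerance = 1e-12)
  expect_true(all(agg$flag_freq %in% c(0, 1)))
  expect_equal(agg$factor_scores_boot, std$factor_scores)

  # two repetitions with z = 1 and 2 in a cell: mean 1.5, sample SD 0.70711
  rec2 <- rec
  rec2$zscores[1, 1] <- rec$zscores[1, 1] + 1
  agg2 <- aggregate_bootstrap(list(rec, rec2), std, g)
  expect_equal(agg2$zscore_mean[1, 1], rec$zscores[1, 1] + 0.5)
  expect_equal(agg2$zscore_se[1, 1], 0.70711, tolerance = 1e-5)
  expect_equal(agg2$zscore_bias[1, 1],
               std$zscores[1, 1] - agg2$zscore_mean[1, 1])

  # flag frequency does not depend on repetition order
  reps <- list(rec, rec2, rec, rec2, rec)
  expect_equal(aggregate_bootstrap(reps, std, g)$flag_freq,
               aggregate_bootstrap(rev(reps), std, g)$flag_freq)

  # a never-sampled Q-sort gets undefined loading statistics
  # (both archetype groups stay represented; Q-sort 5 is left out)
  rec_sub <- bootstrap_step(sim$qsorts, c(1L, 2L, 3L, 4L, 6L, 6L), cfg,
                            std$loadings)
  agg_sub <- aggregate_bootstrap(list(rec_sub), std, g)
  expect_true(all(is.na(agg_sub$loading_mean[5, ])))
  expect_equal(agg_sub$present_count[5], 0L)
})

test_that("statement-specific tests use per-statement bootstrap SEs", {
  boot <- structure(list(
    zscore_mean = cbind(f1 = c(0.5, 1, 0), f2 = c(0, 1, 0)),
    zscore_se = cbind(f1 = c(0.3, 0, 0.1), f2 = c(0.3, 0, 0.1))
  ), class = "q_boot_results")
  d <- bootstrap_distinguishing(boot)
  # 0.5 < 1.96 * sqrt(0.09 + 0.09) = 0.8316
  expect_equal(d$statement_specific$codes[1, 1, 2], "ns")
  # zero SE and nonzero difference: distinguishing at both levels
  boot$zscore_mean[1, 2] <- -0.5
  boot$zscore_se[1, ] <- 0
  d2 <- bootstrap_distinguishing(boot)
  expect_equal(d2$statement_specific$codes[1, 1, 2], "p<.01")
  # equal z columns: all consensus
  expect_equal(d$statement_specific$codes[2, 1, 2], "ns")
  expect_true(all(d$statement_specific$consensus[2:3]))
})

test_that("salience/stability classes partition all statement-factor cells", {
  set.seed(71)
  boot <- structure(list(
    zscore_mean = matrix(rnorm(20), 10, 2),
    zscore_se = matrix(runif(20, 0, 0.5), 10, 2)
  ), class = "q_boot_results")
  cls <- classify_statements(boot,
                             salience_cut = median(abs(boot$zscore_mean)),
                             stability_cut = median(boot$zscore_se))
  expect_equal(sum(table(cls)), 20)
  expect_true(all(cls %in% c("high-salience/high-stability",
                             "high-salience/low-stability",
                             "low-salience/high-stability",
                             "low-salience/low-stability")))
  b2 <- boot
  b2$zscore_mean[1, 1] <- 2; b2$zscore_se[1, 1] <- 0
  expect_equal(classify_statements(b2)[1, 1], "high-salience/high-stability")
  b2$zscore_mean[2, 1] <- 0; b2$zscore_se[2, 1] <- 10
  expect_equal(classify_statements(b2)[2, 1], "low-salience/low-stability")
})

test_that("bootstrap z means track standard z on well-separated data", {
  g <- make_grid(12, -2, 2)
  sim <- archetype_qsorts(2, 12, 12, noise_sd = 0.3, grid = g, seed = 72)
  bt <- run_bootstrap(sim$qsorts, 2, quiet_config(nsteps = 120, seed = 73))
  expect_true(all(bt$boot$zscore_correlation > 0.99))
  expect_true(all(bt$boot$zscore_se >= 0))
  expect_true(all(bt$boot$flag_freq >= 0 & bt$boot$flag_freq <= 1, na.rm = TRUE))
})

test_that("disabling the alignment correction inflates loading SEs (sign swap)", {
  # two opposed blocks around one bipolar factor: orientation is ambiguous
  g <- make_grid(12, -2, 2)
  set.seed(74)
  profile <- rnorm(12)
  data <- sapply(1:8, function(i) {
    s <- if (i <= 4) 1 else -1
    qboots:::force_to_grid(s * profile + rnorm(12, sd = 0.2), g)
  })
  q <- qsort_matrix(data, g)
  on_ <- run_bootstrap(q, 1, quiet_config(nsteps = 100, seed = 75, align = TRUE))
  off <- run_bootstrap(q, 1, quiet_config(nsteps = 100, seed = 75, align = FALSE))
  expect_gt(mean(off$boot$loading_se, na.rm = TRUE),
            mean(on_$boot$loading_se, na.rm = TRUE))
  expect_equal(off$log$reflected, 0)   # correction was never applied
  expect_gt(on_$log$reflected, 10)     # reflections detected and corrected
})

test_that("corrected loading distributions are unimodal in the sign-swap scenario", {
  g <- make_grid(12, -2, 2)
  set.seed(76)
  profile <- rnorm(12)
  data <- sapply(1:8, function(i) {
    s <- if (i <= 4) 1 else -1
    qboots:::force_to_grid(s * profile + rnorm(12, sd = 0.2), g)
  })
  q <- qsort_matrix(data, g)
  std <- run_standard_analysis(q, 1)
  collect <- function(align) {
    cfg <- quiet_config(nsteps = 80, seed = 77, align = align)
    set.seed(77)
    vals <- vector("list", 8)
    for (i in 1:80) {
      idx <- draw_resample(8)
      rec <- tryCatch(bootstrap_step(q, idx, cfg, std$loadings),
                      qboots_degenerate = function(e) NULL)
      if (is.null(rec)) next
      for (o in 1:8) {
        pos <- which(idx == o)
        if (length(pos)) vals[[o]] <- c(vals[[o]], mean(rec$loadings[pos, 1]))
      }
    }
    vals
  }
  von <- collect(TRUE); voff <- collect(FALSE)
  sign_purity <- function(v) max(mean(v > 0), mean(v < 0))
  # corrected: each Q-sort's loadings keep one sign; uncorrected: mixed (bimodal)
  expect_true(all(vapply(von, sign_purity, numeric(1)) > 0.95))
  expect_true(any(vapply(voff, sign_purity, numeric(1)) < 0.8))
})

test_that("a fixed manual flag set is mapped through the resample indices", {
  g <- fig_grid()
  sim <- archetype_qsorts(2, 9, 8, noise_sd = 0.3, grid = g, seed = 78)
  manual <- run_standard_analysis(sim$qsorts, 2)$flags
  cfg <- quiet_config(nsteps = 1, seed = 1, flagging = "manual",
                      manual_flags = manual)
  std <- run_standard_analysis(sim$qsorts, 2, flagging = "manual",
                               manual_flags = manual)
  idx <- c(1L, 1L, 2L, 4L, 5L, 6L, 7L, 8L)
  rec <- bootstrap_step(sim$qsorts, idx, cfg, std$loadings)
  expect_equal(unname(rec$flags), unname(manual[idx, ]))
})

test_that("run_bootstrap logs seeds, skips and corrections and is reproducible", {
  g <- fig_grid()
  sim <- archetype_qsorts(2, 9, 8, noise_sd = 0.4, grid = g, seed = 79)
  b1 <- run_bootstrap(sim$qsorts, 2, quiet_config(nsteps = 60, seed = 80))
  b2 <- run_bootstrap(sim$qsorts, 2, quiet_config(nsteps = 60, seed = 80))
  expect_equal(b1$boot$zscore_mean, b2$boot$zscore_mean)
  expect_equal(b1$boot$flag_freq, b2$boot$flag_freq)
  expect_equal(b1$log$draws, b2$log$draws)
  expect_gte(b1$log$draws, b1$log$achieved)
})
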