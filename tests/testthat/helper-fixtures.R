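# fixtures are built in code; every stochastic fixture takes an explicit seed

fig_grid <- function() grid_spec(c(-2, -1, -1, 0, 0, 0, 1, 1, 2))

# m random valid Q-sorts: independent permutations of the grid values
random_qsorts <- function(grid, m, seed) {
  set.seed(seed)
  data <- replicate(m, sample(grid$values))
  qsort_matrix(data, grid)
}

# noise-free (or noisy) k-archetype dataset with its ground truth
archetype_qsorts <- function(k, n, m, noise_sd, grid, seed) {
  set.seed(seed)
  arch <- make_archetypes(k, n, m, noise_sd = noise_sd)
  simulate_qsorts(arch, grid)
}

quiet_config <- function(...) suppressWarnings(bootstrap_config(...))

# brute-force varimax for k = 2: exhaustive search over the rotation angle
varimax_bruteforce_2f <- function(L, step_deg = 0.1) {
  angles <- seq(0, 90, by = step_deg) * pi / 180
  crit <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    varimax_criterion(L %*% R)
  }, numeric(1))
  best <- which.max(crit)
  list(angle_deg = angles[best] * 180 / pi, criterion = crit[best])
}
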