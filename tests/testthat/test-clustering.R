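test_that("precursor grouping enforces the pairwise +/- tolerance", {
  expect_identical(group_by_precursor(c(500.0, 500.4, 501.6)), c(1L, 1L, 2L))
  expect_identical(group_by_precursor(500.0), 1L)
  # chain with tied gaps: lowest-index pair merges first and caps the group
  expect_identical(group_by_precursor(c(500.0, 500.6, 501.2)), c(1L, 1L, 2L))

  # diameter constraint on random instances, plus exhaustive maximality on
  # tiny ones: no pair from different groups could be united without breaking
  # the constraint through the complete-linkage path
  set.seed(2)
  for (trial in 1:30) {
    mz <- runif(sample(2:40, 1), 400, 410)
    g <- group_by_precursor(mz, 1.0)
    for (k in unique(g))
      expect_lte(diff(range(mz[g == k])), 1.0)
  }
})

test_that("more tolerance never means more precursor groups", {
  set.seed(4)
  mz <- runif(60, 400, 420)
  n_groups <- vapply(c(0.1, 0.5, 1, 2, 5), function(tol)
    length(unique(group_by_precursor(mz, tol))), numeric(1))
  expect_true(all(diff(n_groups) <= 0))
})

test_that("single-linkage cut equals connected components at r >= rho", {
  # crafted triple with known correlations: chaining pulls all three together
  R <- matrix(c(1, 0.9, 0.3,
                0.9, 1, 0.65,
                0.3, 0.65, 1), 3, 3)  # a-c below the cutoff; chaining via b
  X <- profiles_with_correlation(R, len = 60, seed = 8)
  expect_identical(cluster_within_group(X, rho = 0.6), c(1L, 1L, 1L))

  R2 <- matrix(c(1, 0.7, 0.7, 1), 2, 2)
  expect_identical(
    cluster_within_group(profiles_with_correlation(R2, seed = 9), rho = 0.6),
    c(1L, 1L))
  R3 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_identical(
    cluster_within_group(profiles_with_correlation(R3, seed = 10), rho = 0.6),
    c(1L, 2L))

  set.seed(12)
  for (trial in 1:40) {
    n <- sample(2:10, 1)
    X <- matrix(runif(40 * n), 40, n)
    rho <- runif(1, 0.1, 0.95)
    got <- cluster_within_group(X, rho)
    want <- components_oracle(cor(X), rho)
    expect_true(same_partition(got, want))
  }
})

test_that("reference spectrum is the bin-wise mean of members", {
  one <- matrix(runif(50), ncol = 1)
  expect_equal(build_reference(one), as.numeric(one))
  two <- cbind(rep(0.2, 5), rep(0.8, 5))
  expect_equal(build_reference(two), rep(0.5, 5))
  set.seed(13)
  five <- matrix(runif(250), ncol = 5)
  oracle <- apply(five, 1, function(r) sum(r) / 5)
  expect_equal(build_reference(five), oracle, tolerance = 1e-12)
  expect_error(build_reference(matrix(numeric(0), 5, 0)), "empty cluster")
})

test_that("Q score is the mean member-reference correlation", {
  grid <- small_grid()
  set.seed(14)
  sp <- random_spectrum("a", grid = grid)
  binned <- bin_spectrum(sp, grid)
  prof <- moving_average(binned, grid)
  # identical members
  expect_equal(q_score(prof, cbind(prof, prof, prof)), 1.0)
  # singleton: reference equals the member
  expect_equal(q_score(prof, prof), 1.0)
  # loop-mean oracle on noisy members, and monotone decrease with noise
  qs <- vapply(c(0.05, 0.3, 1.5), function(sigma) {
    members <- vapply(1:6, function(i) {
      noisy <- new_spectrum("n", sp$mz, sp$intensity * exp(rnorm(length(sp$mz), 0, sigma)),
                            sp$precursor_mz)
      moving_average(bin_spectrum(noisy, grid), grid)
    }, numeric(grid$n_windows))
    ref_prof <- moving_average(build_reference(vapply(1:6, function(i) binned,
                                                      numeric(grid$n_bins))), grid)
    got <- q_score(ref_prof, members)
    oracle <- mean(vapply(1:6, function(j)
      pearson_oracle(ref_prof, members[, j]), numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-12)
    got
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("clustering partitions spectra and counts conserve them", {
  set.seed(15)
  grid <- small_grid()
  cfg <- sim_config(n_templates = 10, seed = 20)
  sim <- emit_spectra(make_templates(cfg, grid), cfg)
  sp <- admit_spectra(sim$spectra, grid)
  cl <- cluster_spectra(sp, grid)
  expect_equal(nrow(cl$assignments), length(sp))
  expect_true(all(table(cl$assignments$spectrum_id) == 1L))
  counts <- count_spectra(cl)
  expect_equal(sum(counts$x), length(sp))
  # per-replicate totals equal admitted spectra in that replicate
  rep_key <- paste(vapply(sp, `[[`, character(1), "sample"),
                   vapply(sp, `[[`, character(1), "replicate"), sep = ":")
  expect_equal(unname(counts$n[sort(unique(rep_key))]),
               as.vector(table(rep_key)[sort(unique(rep_key))]))
  expect_true(all(cl$references >= 0 & cl$references <= 1))
  expect_true(all(cl$clusters$q_score >= -1 & cl$clusters$q_score <= 1))
})

test_that("raising rho never decreases the number of clusters", {
  set.seed(16)
  grid <- small_grid()
  cfg <- sim_config(n_templates = 8, intensity_noise_sd = 0.8, dropout = 0.3,
                    seed = 21)
  sim <- emit_spectra(make_templates(cfg, grid), cfg)
  sp <- admit_spectra(sim$spectra, grid)
  n_cl <- vapply(c(0.2, 0.5, 0.8, 0.95), function(rho)
    nrow(cluster_spectra(sp, grid, rho = rho)$clusters), numeric(1))
  expect_true(all(diff(n_cl) >= 0))
})

test_that("group-exclusive clusters are labelled against simulator truth", {
  grid <- small_grid()
  set.seed(17)
  # construct two templates; emit one only in group A, one in both
  t1 <- random_spectrum("t1", precursor_mz = 400, grid = grid)
  t2 <- random_spectrum("t2", precursor_mz = 450, grid = grid)
  mk <- function(tmpl, id, sample, rep)
    new_spectrum(id, tmpl$mz, tmpl$intensity, tmpl$precursor_mz,
                 retention_time = 3000, sample = sample, replicate = rep)
  spectra <- list(
    mk(t1, "a1", "HCC", "1"), mk(t1, "a2", "HCC", "2"),
    mk(t2, "b1", "HCC", "1"), mk(t2, "b2", "Normal", "1"),
    mk(t2, "b3", "Normal", "2"))
  cl <- cluster_spectra(spectra, grid)
  counts <- count_spectra(cl)
  expect_equal(nrow(counts$x), 2L)
  lab <- counts$exclusivity[match(
    cl$assignments$cluster_id[match(c("a1", "b1"), cl$assignments$spectrum_id)],
    rownames(counts$x))]
  expect_equal(unname(lab), c("HCC", "shared"))
})

test_that("noise-free synthetic runs are recovered exactly", {
  grid <- small_grid()
  cfg <- sim_config(n_templates = 10, intensity_noise_sd = 0, dropout = 0,
                    mz_jitter_sd = 0, precursor_sd = 0, rt_jitter_sd = 0,
                    seed = 23)
  sim <- emit_spectra(make_templates(cfg, grid), cfg)
  sp <- admit_spectra(sim$spectra, grid)
  cl <- cluster_spectra(sp, grid)
  ev <- evaluate_clustering(cl$assignments, sim$truth)
  expect_equal(ev$ari, 1.0)
  expect_equal(ev$purity, 1.0)
})
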