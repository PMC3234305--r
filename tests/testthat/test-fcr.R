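test_that("cluster CV is percent sample-sd over mean", {
  expect_equal(cluster_cv(c(3000, 3000, 3000)), 0)
  expect_equal(cluster_cv(c(100, 300)), 100 * sd(c(100, 300)) / 200)
  expect_equal(cluster_cv(c(100, 300)), 70.71068, tolerance = 1e-6)
  expect_true(is.na(cluster_cv(1500)))
  expect_error(cluster_cv(c(-10, 5)), "non-positive mean")
})

test_that("a replicated elution profile like spectral set S366006 passes delta = 4.4", {
  rt <- c(6096.18, 6144.00, 6197.20, 6248.89, 6278.55, 6341.52, 6441.91,
          6149.98, 6154.65)
  cv <- cluster_cv(rt)
  expect_equal(cv, 100 * sd(rt) / mean(rt), tolerance = 1e-12)
  expect_lt(cv, 4.4)
})

test_that("identical retention times force FCR = 1", {
  rts <- list(a = rep(3000, 3), b = rep(3000, 2), c = rep(3000, 3))
  expect_equal(compute_fcr(rts, delta = 1, P = 10, seed = 1), 1.0)
  expect_equal(compute_fcr(rts, delta = 0.5, exhaustive = TRUE), 1.0)
})

test_that("exhaustive FCR matches the full-enumeration oracle", {
  rts <- list(a = c(1000, 1040), b = c(2600, 2540), c = c(4000, 4100))
  for (delta in c(2, 3, 6)) {
    got <- compute_fcr(rts, delta, exhaustive = TRUE)
    expect_equal(got, fcr_enum_oracle(rts, delta), tolerance = 1e-12)
  }
})

test_that("sampled FCR converges to the exhaustive value", {
  rts <- list(a = c(1000, 1040, 980), b = c(2600, 2540), c = c(4000, 4100, 3950))
  exact <- compute_fcr(rts, 3, exhaustive = TRUE)
  sampled <- compute_fcr(rts, 3, P = 4000, seed = 5)
  expect_lt(abs(sampled - exact), 0.05)
  # determinism under a fixed seed
  expect_identical(sampled, compute_fcr(rts, 3, P = 4000, seed = 5))
  expect_false(identical(sampled, compute_fcr(rts, 3, P = 4000, seed = 6)))
})

test_that("FCR is invariant to cluster relabeling and within-cluster order", {
  rts <- list(a = c(1000, 1040, 980), b = c(2600, 2540), c = c(4000, 4100))
  f1 <- compute_fcr(rts, 4, exhaustive = TRUE)
  shuffled <- list(z = rev(rts$c), y = rts$a[c(2, 3, 1)], x = rts$b)
  f2 <- compute_fcr(shuffled[c("y", "x", "z")], 4, exhaustive = TRUE)
  expect_equal(f1, f2)
})

test_that("degenerate scans: singletons give NA, huge delta gives 1", {
  expect_warning(f <- compute_fcr(list(a = 1, b = 2), 5, P = 5, seed = 1),
                 "no eligible cluster")
  expect_true(is.na(f))
  scan <- suppressWarnings(scan_delta(list(a = 1, b = 2), 1:3, P = 5, seed = 1))
  expect_true(all(is.na(scan$fcr)))

  rts <- list(a = c(1000, 1100), b = c(5000, 5600))
  expect_equal(compute_fcr(rts, delta = 1e6, P = 20, seed = 2), 1.0)
})

test_that("threshold scan rises with delta on separated elution profiles", {
  # clusters tight enough that every observed CV clears the smallest
  # threshold: the denominator is then constant and the scan must rise
  set.seed(31)
  rts <- lapply(1:25, function(i) rnorm(sample(2:5, 1), i * 200 + 1000, 2))
  names(rts) <- paste0("c", 1:25)
  scan <- scan_delta(rts, delta_grid = c(0.5, 1, 2, 4.4, 10, 50), P = 60,
                     seed = 7)
  expect_true(all(!is.na(scan$fcr)))
  expect_true(all(diff(scan$fcr) >= 0))
  expect_lt(scan$fcr[scan$delta == 4.4], 0.5)
  expect_equal(attr(scan, "C"), 25L)
})

test_that("choose_threshold picks nearest-from-below with ties to smaller", {
  scan <- data.frame(delta = c(1, 2, 3, 4), fcr = c(0.01, 0.04, 0.04, 0.12))
  expect_equal(choose_threshold(scan, target = 0.05), 2)
  scan2 <- data.frame(delta = 1:3, fcr = c(0.2, 0.3, 0.4))
  expect_equal(choose_threshold(scan2, target = 0.05), 1)
})

test_that("reclustering scan over rho mirrors the decreasing-FCR pattern", {
  # templates deliberately share precursors (groups of 3 within 0.6 Da), so
  # a loose correlation cutoff merges unrelated elution profiles and the FCR
  # rises towards 1, while the truth-recovering cutoff keeps it low
  grid <- small_grid()
  cfg <- sim_config(n_templates = 24, base_rate = 3, precursor_sd = 0.05,
                    seed = 33)
  tmpl <- make_templates(cfg, grid)
  for (t in seq_along(tmpl))
    tmpl[[t]]$precursor_mz <- 400 + 25 * ((t - 1) %/% 3) + 0.3 * ((t - 1) %% 3)
  sim <- emit_spectra(tmpl, cfg)
  sp <- admit_spectra(sim$spectra, grid)
  scan <- scan_rho(sp, grid, rho_grid = c(0, 0.6), delta = 30, P = 40,
                   seed = 9)
  expect_gt(scan$fcr[scan$rho == 0], scan$fcr[scan$rho == 0.6])
  expect_gt(scan$n_clusters[scan$rho == 0.6], scan$n_clusters[scan$rho == 0])
  # identical rerun under the same seed
  scan2 <- scan_rho(sp, grid, rho_grid = c(0, 0.6), delta = 30, P = 40,
                    seed = 9)
  expect_identical(scan$fcr, scan2$fcr)
})
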