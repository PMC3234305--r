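test_that("beta-binomial pmf: uniform case, binomial limit, normalization", {
  # alpha = beta = 1 (pi = 0.5, phi = 1/3) makes every count equally likely
  for (n in c(4, 9, 25))
    expect_equal(exp(betabinom_logpmf(0:n, n, 0.5, 1/3)), rep(1 / (n + 1), n + 1))

  # tiny phi agrees with the binomial pmf (relative, at typical counts)
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:100, 1); pi <- runif(1, 0.05, 0.95)
    x <- rbinom(1, n, pi)
    expect_equal(exp(betabinom_logpmf(x, n, pi, 1e-8)),
                 dbinom(x, n, pi), tolerance = 1e-6)
  }

  # sums to one
  for (i in 1:10) {
    n <- sample(3:60, 1); pi <- runif(1, 0.05, 0.95); phi <- runif(1, 0, 0.7)
    expect_equal(sum(exp(betabinom_logpmf(0:n, n, pi, phi))), 1,
                 tolerance = 1e-10)
  }

  expect_error(betabinom_logpmf(5, 3, 0.5, 0.1))
  expect_error(betabinom_logpmf(1, 3, 1.2, 0.1))
  expect_error(betabinom_logpmf(1, 3, 0.5, 1))
})

test_that("pmf agrees with quadrature of the marginal integral", {
  set.seed(43)
  for (i in 1:15) {
    n <- sample(5:150, 1)
    pi <- runif(1, 0.05, 0.95); phi <- runif(1, 0.02, 0.6)
    a <- pi * (1 - phi) / phi; b <- (1 - pi) * (1 - phi) / phi
    x <- rbinom(1, n, rbeta(1, a, b))  # a typical draw from the model
    q <- integrate(function(u) dbinom(x, n, qbeta(u, a, b)), 0, 1,
                   rel.tol = 1e-11)$value
    expect_equal(exp(betabinom_logpmf(x, n, pi, phi)), q, tolerance = 1e-8)
  }
})

test_that("fitting recovers the proportion and flags degenerate inputs", {
  n <- rep(5000, 6)
  x <- rep(1500, 6)  # identical proportions, no overdispersion
  f <- fit_betabinom(x, n, matrix(1, 6, 1))
  expect_true(f$converged)
  expect_equal(unique(f$pi), 0.3, tolerance = 1e-3)
  expect_true(f$boundary_phi)

  f0 <- fit_betabinom(rep(0L, 6), n, matrix(1, 6, 1))
  expect_true(f0$degenerate)
  expect_lt(max(f0$pi), 1e-4)
})

test_that("moment identities hold on beta-binomial simulation", {
  cfg <- sim_config(n_clusters = 3000, dep_fraction = 0, pi = 0.05, phi = 0.1,
                    total_counts = 500, seed = 44)
  x <- emit_counts(cfg)$counts$x
  expect_equal(mean(x), 500 * 0.05, tolerance = 0.02)
  expect_equal(var(as.vector(x)), 500 * 0.05 * 0.95 * (1 + 499 * 0.1),
               tolerance = 0.05)
})

test_that("LRT is null at equal proportions and invariant to label swap", {
  n <- rep(4000, 6)
  group <- rep(c("g1", "g2"), each = 3)
  x <- rep(40L, 6)
  r <- lrt_test(x, n, group)
  expect_lt(r$statistic, 1e-4)
  expect_gt(r$p, 0.99)

  set.seed(45)
  x2 <- c(12L, 19L, 15L, 41L, 30L, 38L)
  r1 <- lrt_test(x2, n, group)
  r2 <- lrt_test(x2, n, rev(group))
  expect_equal(r1$p, r2$p, tolerance = 1e-4)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-4)
  expect_false(r1$direction == r2$direction)
})

test_that("with no overdispersion the statistic reduces to the binomial LRT", {
  # counts close to binomial with no real group effect: BOTH fits drive phi to
  # the boundary (a genuine group difference would be absorbed as
  # overdispersion by the null fit, so equality with the binomial LRT is only
  # expected when phi vanishes under both models)
  n <- rep(2000, 6)
  x <- c(20L, 22L, 18L, 21L, 19L, 23L)
  group <- rep(c("a", "b"), each = 3)
  r <- lrt_test(x, n, group, ref = "chisq")
  expect_true(r$fit_alt$boundary_phi)
  expect_true(r$fit_null$boundary_phi)
  # closed-form binomial LRT: pooled vs per-group proportions
  ll <- function(x, n, p) sum(dbinom(x, n, p, log = TRUE))
  p_all <- sum(x) / sum(n)
  p_a <- sum(x[1:3]) / sum(n[1:3]); p_b <- sum(x[4:6]) / sum(n[4:6])
  stat_binom <- 2 * (ll(x[1:3], n[1:3], p_a) + ll(x[4:6], n[4:6], p_b) -
                       ll(x, n, p_all))
  expect_equal(r$statistic, stat_binom, tolerance = 1e-3)
})

test_that("BH adjustment equals the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(46)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone and >= p
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("run_dep tests only shared clusters and returns an empty frame cleanly", {
  counts <- structure(list(
    x = matrix(c(3L, 0L, 0L, 4L), 2, 2,
               dimnames = list(c("S1", "S2"), c("A:1", "B:1"))),
    n = c(3L, 4L), group = c("A", "B"),
    exclusivity = c("A", "B")), class = "qfish_counts")
  res <- run_dep(counts)
  expect_s3_class(res, "qfish_dep")
  expect_equal(nrow(res), 0L)
})

test_that("direction labels follow the simulated effect", {
  cfg <- sim_config(n_clusters = 60, dep_fraction = 0.5, odds_ratio = 8,
                    phi = 0.002, seed = 47)
  ec <- emit_counts(cfg)
  res <- run_dep(ec$counts, alpha = 0.05)
  sig <- res[res$significant, ]
  expect_gt(nrow(sig), 0)
  is_true_dep <- sig$cluster_id %in% ec$truth$cluster_id[ec$truth$is_dep]
  # FDR control leaves room for occasional false calls; the bulk must be true
  expect_gte(mean(is_true_dep), 0.8)
  # effects are simulated as lower odds in the second group
  expect_true(all(sig$direction[is_true_dep] == "down"))
})
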