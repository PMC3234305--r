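# Beta-binomial model for differential spectral counts between two groups.
#
# Per cluster, the count x_j in replicate j out of the replicate total n_j is
# binomial with a beta-distributed proportion; marginally x is beta-binomial
# with mean proportion pi = h(X b) (h the inverse link) and overdispersion
# phi = 1/(alpha + beta + 1), so E x = n pi and
# Var x = n pi (1 - pi) [1 + (n - 1) phi]. The group effect is the b
# coefficient on the group indicator; its significance is assessed with a
# likelihood ratio test against the intercept-only fit.

#' Beta-binomial log probability mass
#'
#' `log P(x | n, pi, phi)` in the mean/overdispersion parameterization
#' `alpha = pi (1 - phi) / phi`, `beta = (1 - pi)(1 - phi) / phi`, computed
#' through log-beta functions. `phi = 0` (and tiny `phi`) is handled as the
#' binomial limit.
#'
#' @param x Counts, `0 <= x <= n` (vectorized).
#' @param n Totals.
#' @param pi Mean proportion in (0, 1).
#' @param phi Overdispersion in `[0, 1)`.
#' @return Log probability (vectorized over `x`, `n`, `pi`).
#' @export
betabinom_logpmf <- function(x, n, pi, phi) {
  stopifnot(all(x >= 0), all(x <= n), all(pi > 0), all(pi < 1),
            all(phi >= 0), all(phi < 1))
  if (all(phi < 1e-12))
    return(stats::dbinom(x, n, pi, log = TRUE))
  a <- pi * (1 - phi) / phi
  b <- (1 - pi) * (1 - phi) / phi
  lchoose(n, x) + lbeta(a + x, n + b - x) - lbeta(a, b)
}

# inverse links
inv_link <- function(eta, link) {
  switch(link,
         logit = stats::plogis(eta),
         cloglog = -expm1(-exp(eta)),
         stop("unknown link: ", link))
}
link_fun <- function(p, link) {
  switch(link,
         logit = stats::qlogis(p),
         cloglog = log(-log1p(-p)),
         stop("unknown link: ", link))
}

# negative marginal log-likelihood over theta = (b, logit(phi))
bb_negll <- function(theta, x, n, X, link) {
  k <- ncol(X)
  pi <- inv_link(drop(X %*% theta[seq_len(k)]), link)
  phi <- stats::plogis(theta[k + 1L])
  pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
  ll <- betabinom_logpmf(x, n, pi, phi)
  if (any(!is.finite(ll))) return(1e10)
  -sum(ll)
}

#' Fit the beta-binomial model to one cluster
#'
#' Maximizes the marginal beta-binomial log-likelihood over the link-scale
#' coefficients `b` and a single shared overdispersion `phi`, by bounded
#' quasi-Newton (`nlminb`) on `(b, logit(phi))` with a deterministic
#' multi-start: the pooled-proportion moment estimate with a moment estimate
#' of `phi`, and the same coefficients with `phi = 0.01`. A fit driven to the
#' `phi` boundary is reported as a binomial fit (`phi = 0`, flagged).
#'
#' @param x Integer counts per replicate.
#' @param n Totals per replicate.
#' @param design Design matrix with an intercept column and optionally a
#'   group-indicator column.
#' @param link `"logit"` (default) or `"cloglog"`.
#' @return List of class `qfish_bbfit`: `b`, `phi`, `pi` (fitted proportions
#'   per replicate), `loglik`, `converged`, `boundary_phi`, `degenerate`
#'   (all-zero or saturated counts: the proportion is pinned at a boundary),
#'   `link`.
#' @export
fit_betabinom <- function(x, n, design, link = c("logit", "cloglog")) {
  link <- match.arg(link)
  stopifnot(length(x) == length(n), nrow(design) == length(x))
  k <- ncol(design)
  p_pool <- min(max(sum(x) / sum(n), 1e-6), 1 - 1e-6)

  # moment estimate of phi from the variance inflation of x/n
  p_j <- x / n
  vif <- if (length(x) > 1L && p_pool > 0 && stats::var(p_j) > 0) {
    v_obs <- stats::var(p_j)
    v_bin <- mean(p_pool * (1 - p_pool) / n)
    max((v_obs - v_bin) / (p_pool * (1 - p_pool)), 1e-4)
  } else 1e-4
  phi_mom <- min(vif, 0.9)

  b0 <- numeric(k)
  b0[1L] <- link_fun(p_pool, link)
  starts <- list(c(b0, stats::qlogis(phi_mom)),
                 c(b0, stats::qlogis(0.01)))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, bb_negll, x = x, n = n, X = design, link = link,
                    control = list(rel.tol = 1e-10, iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10) {
    return(structure(list(b = rep(NA_real_, k), phi = NA_real_,
                          pi = rep(NA_real_, length(x)), loglik = NA_real_,
                          converged = FALSE, boundary_phi = FALSE,
                          degenerate = all(x == 0) || all(x == n),
                          link = link),
                     class = "qfish_bbfit"))
  }
  b <- best$par[seq_len(k)]
  phi <- stats::plogis(best$par[k + 1L])
  boundary <- phi < 1e-6
  if (boundary) phi <- 0
  structure(list(b = b, phi = phi,
                 pi = inv_link(drop(design %*% b), link),
                 loglik = -best$objective,
                 converged = best$convergence == 0 || boundary,
                 boundary_phi = boundary,
                 degenerate = all(x == 0) || all(x == n),
                 link = link),
            class = "qfish_bbfit")
}

#' Likelihood ratio test for a group effect
#'
#' Fits the beta-binomial model with and without the group indicator and
#' tests the group coefficient with the likelihood ratio statistic (twice the
#' log-likelihood difference, floored at 0).
#'
#' With only a few replicates per group the classical chi-squared reference
#' for the statistic is badly anticonservative, because the overdispersion is
#' a nuisance parameter estimated from the same handful of observations (the
#' same reason a z-test misbehaves where a t-test is needed). The default
#' reference therefore maps the statistic through the signed-root
#' transformation `t^2 = (N - 2) (exp(stat / N) - 1)` — exact for the Gaussian
#' analogue of the model — and refers it to a t distribution with `N - 2`
#' degrees of freedom, where `N` is the number of replicates. The asymptotic
#' chi-squared (1 df) reference is available with `ref = "chisq"`.
#'
#' @param x Counts per replicate for one cluster.
#' @param n Totals per replicate.
#' @param group Two-level factor or character vector of group labels.
#' @param link Link function, see [fit_betabinom()].
#' @param ref Reference distribution for the p-value: `"t"` (default,
#'   small-sample calibrated) or `"chisq"`. With fewer than 3 replicates in
#'   total the chi-squared reference is used regardless.
#' @return List: `statistic`, `p`, `fit_alt`, `fit_null`, `direction` (sign of
#'   the group coefficient: `"up"` means higher proportion in the second group
#'   level).
#' @export
lrt_test <- function(x, n, group, link = "logit", ref = c("t", "chisq")) {
  ref <- match.arg(ref)
  g <- factor(group)
  stopifnot(nlevels(g) == 2L)
  X_alt <- cbind(1, as.numeric(g == levels(g)[2L]))
  X_null <- X_alt[, 1L, drop = FALSE]
  alt <- fit_betabinom(x, n, X_alt, link)
  null <- fit_betabinom(x, n, X_null, link)
  if (!alt$converged || !null$converged || is.na(alt$loglik) || is.na(null$loglik))
    return(list(statistic = NA_real_, p = NA_real_, fit_alt = alt,
                fit_null = null, direction = NA_character_))
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  N <- length(x)
  p <- if (ref == "t" && N >= 3L) {
    tt <- sqrt((N - 2) * (exp(stat / N) - 1))
    2 * stats::pt(-tt, df = N - 2)
  } else {
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  list(statistic = stat, p = p,
       fit_alt = alt, fit_null = null,
       direction = if (alt$b[2L] >= 0) "up" else "down")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; `NA`s are
#' excluded from the number of tests and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Differential expression over a count table
#'
#' Runs the beta-binomial likelihood ratio test on every shared cluster
#' (present in both groups) of a count table, adjusts with
#' Benjamini-Hochberg, and declares clusters with `q <= alpha` differentially
#' expressed. Group-exclusive clusters are reported descriptively but not
#' tested. Clusters may be pre-filtered (e.g. by a retention-time CV
#' threshold certified by the FCR) via `keep`.
#'
#' @param counts A `qfish_counts` object (see [count_spectra()]), or a list
#'   with `x`, `n`, `group` and optionally `exclusivity`.
#' @param alpha FDR level (default 0.05).
#' @param link Link function, see [fit_betabinom()].
#' @param ref Reference distribution for p-values, see [lrt_test()].
#' @param keep Optional logical vector (or cluster-id character vector)
#'   selecting the clusters eligible for testing.
#' @return Data.frame of class `qfish_dep`: one row per tested cluster with
#'   fitted per-group proportions, `phi`, `statistic`, `p`, `q`, `direction`
#'   (relative to the second group level) and `significant`.
#' @export
run_dep <- function(counts, alpha = 0.05, link = "logit", ref = "t",
                    keep = NULL) {
  x <- counts$x; n <- counts$n; group <- factor(counts$group)
  stopifnot(nlevels(group) == 2L)
  ids <- rownames(x)
  eligible <- if (!is.null(counts$exclusivity))
    counts$exclusivity == "shared" else rep(TRUE, nrow(x))
  if (!is.null(keep)) {
    sel <- if (is.character(keep)) ids %in% keep else keep
    eligible <- eligible & sel
  }
  idx <- which(eligible)
  if (length(idx) == 0L) {
    out <- data.frame(cluster_id = character(0), pi_1 = numeric(0),
                      pi_2 = numeric(0), phi = numeric(0),
                      statistic = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0), significant = logical(0))
    class(out) <- c("qfish_dep", "data.frame")
    return(out)
  }
  res <- lapply(idx, function(i) lrt_test(x[i, ], n, group, link, ref = ref))
  lev <- levels(group)
  pi_g <- t(vapply(res, function(r) {
    if (anyNA(r$fit_alt$pi)) c(NA_real_, NA_real_)
    else c(mean(r$fit_alt$pi[group == lev[1L]]),
           mean(r$fit_alt$pi[group == lev[2L]]))
  }, numeric(2)))
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- bh_adjust(p)
  out <- data.frame(
    cluster_id = ids[idx],
    pi_1 = pi_g[, 1L], pi_2 = pi_g[, 2L],
    phi = vapply(res, function(r) r$fit_alt$phi, numeric(1)),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    p = p, q = q,
    direction = vapply(res, function(r)
      if (is.na(r$p)) NA_character_ else r$direction, character(1)),
    significant = !is.na(q) & q <= alpha,
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "pi_1"] <- paste0("pi_", lev[1L])
  names(out)[names(out) == "pi_2"] <- paste0("pi_", lev[2L])
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- lev
  class(out) <- c("qfish_dep", "data.frame")
  out
}
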