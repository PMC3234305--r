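# Retention-time validation of clusterings: per-cluster coefficient of
# variation and the permutation-based false clustering rate (FCR), with
# threshold scans over the CV cutoff (delta) and the correlation cutoff (rho).

#' Coefficient of variation of cluster retention times
#'
#' Replicate spectra of one peptide elute within a narrow chromatographic
#' window, so the CV (in percent, sample standard deviation over mean) of the
#' member retention times is small for a correctly assembled cluster.
#'
#' @param rt Numeric vector of retention times (seconds) of one cluster's
#'   members.
#' @return CV in percent, or `NA` for clusters of size < 2 (CV undefined;
#'   such clusters are ineligible for the FCR).
#' @export
cluster_cv <- function(rt) {
  if (length(rt) < 2L) return(NA_real_)
  m <- mean(rt)
  if (m <= 0) stop("non-positive mean retention time")
  100 * stats::sd(rt) / m
}

# Internal: extract eligible (size >= 2) clusters' RT list
eligible_rts <- function(rt_list) {
  rt_list[vapply(rt_list, length, integer(1)) >= 2L]
}

#' False clustering rate at a CV threshold
#'
#' Estimates how often clusters as tight (in retention-time CV) as the
#' observed ones would arise by chance. Retention times of all spectra in
#' eligible clusters (size >= 2) are shuffled globally and dealt back into the
#' same cluster-size template; the FCR at threshold `delta` is the mean over
#' permutations of the ratio (# permuted clusters with CV <= delta) /
#' (# observed clusters with CV <= delta). Values above 1 are possible and
#' reported unclamped with a warning.
#'
#' @param rt_list List of per-cluster retention-time vectors (e.g. from
#'   [cluster_rts()]); singletons are excluded from both numerator and
#'   denominator.
#' @param delta CV threshold in percent.
#' @param P Number of permutations (default 100); ignored when
#'   `exhaustive = TRUE`.
#' @param seed RNG seed for the permutations.
#' @param exhaustive If `TRUE`, enumerate all permutations of the pooled RTs
#'   instead of sampling (only sensible for <= 8 pooled RTs).
#' @return The FCR (a single number), or `NA` with a warning when no observed
#'   cluster falls below `delta`.
#' @export
compute_fcr <- function(rt_list, delta, P = 100, seed = 1L,
                        exhaustive = FALSE) {
  el <- eligible_rts(rt_list)
  if (length(el) == 0L) {
    warning("no eligible cluster (all singletons): FCR undefined")
    return(NA_real_)
  }
  cv_obs <- vapply(el, cluster_cv, numeric(1))
  denom <- sum(cv_obs <= delta)
  if (denom == 0L) {
    warning("no observed cluster with CV <= delta: FCR undefined")
    return(NA_real_)
  }
  sizes <- vapply(el, length, integer(1))
  pool <- unlist(el, use.names = FALSE)
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  count_pass <- function(perm) {
    sum(vapply(seq_along(sizes), function(i)
      cluster_cv(perm[starts[i]:ends[i]]) <= delta, logical(1)))
  }
  if (exhaustive) {
    perms <- permutations_of(length(pool))
    num <- vapply(seq_len(nrow(perms)), function(p)
      count_pass(pool[perms[p, ]]), numeric(1))
  } else {
    rng <- local_rng(seed)
    num <- vapply(seq_len(P), function(p)
      count_pass(sample(pool)), numeric(1))
    rng()
  }
  fcr <- mean(num / denom)
  if (fcr > 1) warning("FCR exceeds 1 (permuted clusters tighter than observed)")
  fcr
}

# all permutations of 1..n as a matrix (n! rows); recursion, n <= 8 intended
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# set seed locally, return restorer
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Scan the CV threshold
#'
#' Computes the FCR over a grid of CV thresholds; on real chromatographic
#' data the FCR grows with the threshold, and the working threshold is chosen
#' where the FCR is near a target (0.05 by convention).
#'
#' @inheritParams compute_fcr
#' @param delta_grid Numeric vector of CV thresholds (percent).
#' @return An object of class `qfish_fcr_scan`: data.frame with columns
#'   `delta` and `fcr`, plus attributes `P`, `seed`, `cv_observed` and `C`
#'   (number of eligible clusters).
#' @export
scan_delta <- function(rt_list, delta_grid = 1:10, P = 100, seed = 1L) {
  fcr <- vapply(delta_grid, function(d)
    suppressWarnings(compute_fcr(rt_list, d, P = P, seed = seed)), numeric(1))
  el <- eligible_rts(rt_list)
  structure(data.frame(delta = delta_grid, fcr = fcr),
            class = c("qfish_fcr_scan", "data.frame"),
            P = P, seed = seed,
            cv_observed = vapply(el, cluster_cv, numeric(1)),
            C = length(el))
}

#' Choose a threshold from a scan
#'
#' Returns the grid value whose FCR is closest to `target` from below; when no
#' FCR is below the target, the value with FCR closest to the target. Ties go
#' to the smaller threshold.
#'
#' @param scan A data.frame with the threshold in the first column and `fcr`.
#' @param target Target FCR (default 0.05).
#' @return The chosen threshold value.
#' @export
choose_threshold <- function(scan, target = 0.05) {
  thr <- scan[[1L]]; fcr <- scan$fcr
  ok <- !is.na(fcr)
  thr <- thr[ok]; fcr <- fcr[ok]
  if (length(thr) == 0L) return(NA_real_)
  below <- fcr <= target
  cand <- if (any(below)) which(below & fcr == max(fcr[below]))
          else which(abs(fcr - target) == min(abs(fcr - target)))
  min(thr[cand])
}

#' Scan the correlation cutoff
#'
#' Reclusters the spectra at each correlation cutoff `rho` and computes the
#' FCR at a fixed CV threshold `delta`; low cutoffs lump unrelated spectra
#' together and drive the FCR towards 1, tight cutoffs yield small FCR.
#'
#' @param spectra List of `qfish_spectrum`.
#' @param grid A [grid_config()].
#' @param rho_grid Correlation cutoffs to scan.
#' @param delta Fixed CV threshold (percent) at which the FCR is evaluated.
#' @param precursor_tol Precursor tolerance passed to [cluster_spectra()].
#' @inheritParams compute_fcr
#' @return A `qfish_fcr_scan` data.frame with columns `rho`, `fcr` and
#'   `n_clusters`.
#' @export
scan_rho <- function(spectra, grid = grid_config(),
                     rho_grid = seq(0, 1, by = 0.1), delta = 4.4,
                     precursor_tol = 1.0, P = 100, seed = 1L) {
  res <- lapply(rho_grid, function(rho) {
    cl <- cluster_spectra(spectra, grid, precursor_tol = precursor_tol,
                          rho = rho)
    c(fcr = suppressWarnings(compute_fcr(cluster_rts(cl), delta,
                                         P = P, seed = seed)),
      n_clusters = nrow(cl$clusters))
  })
  out <- data.frame(rho = rho_grid,
                    fcr = vapply(res, `[[`, numeric(1), "fcr"),
                    n_clusters = vapply(res, `[[`, numeric(1), "n_clusters"))
  structure(out, class = c("qfish_fcr_scan", "data.frame"),
            P = P, seed = seed, delta = delta)
}
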