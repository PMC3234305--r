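# Ground-truthed synthetic MS/MS data: peptide fragment templates, replicated
# noisy acquisitions, and beta-binomial count tables. Every knob the pipeline
# is sensitive to (intensity noise, peak dropout, m/z and precursor error,
# retention-time jitter, group-dependent abundance with overdispersion) is a
# parameter, so each stage can be tested against known truth.

#' Simulation configuration
#'
#' Defaults emulate a two-group (disease vs normal), three-replicate
#' label-free LC-MS/MS study at desk scale: tens of peptide templates, a few
#' acquisitions of each peptide per run (spectral counts in the low units,
#' as in typical ion-trap runs), retention times spread over a ~90 min
#' gradient with ~20 s within-peptide jitter (CV well below 1% of elution
#' time), moderate relative intensity noise and peak dropout, and a 10%
#' fraction of truly differential peptides at odds ratio 4.
#'
#' @param n_templates Number of peptide templates.
#' @param groups Two sample-group labels.
#' @param replicates Replicates per group.
#' @param base_rate Mean acquisitions (Poisson) per template, replicate run.
#' @param n_peaks_range Range of fragment-peak counts per template.
#' @param intensity_noise_sd SD of multiplicative lognormal intensity noise
#'   (log scale).
#' @param dropout Per-peak dropout probability per acquisition.
#' @param mz_jitter_sd SD of fragment m/z error (Da).
#' @param precursor_sd SD of precursor m/z error (Da).
#' @param rt_span Run retention-time span (seconds) over which template
#'   elution times are placed uniformly.
#' @param rt_jitter_sd SD of within-template retention-time jitter (seconds).
#' @param dep_fraction Fraction of templates with a true group effect.
#' @param odds_ratio Abundance odds ratio of true differential templates
#'   (first group over second).
#' @param n_clusters,total_counts,pi,phi Count-table simulation (see
#'   [emit_counts()]): clusters, per-replicate totals, baseline proportion and
#'   overdispersion.
#' @param seed Root RNG seed.
#' @return A list of class `qfish_simconfig`.
#' @export
sim_config <- function(n_templates = 30, groups = c("HCC", "Normal"),
                       replicates = 3, base_rate = 4,
                       n_peaks_range = c(20, 40),
                       intensity_noise_sd = 0.3, dropout = 0.1,
                       mz_jitter_sd = 0.02, precursor_sd = 0.2,
                       rt_span = c(1800, 7200), rt_jitter_sd = 20,
                       dep_fraction = 0.1, odds_ratio = 4,
                       n_clusters = 200, total_counts = 5000,
                       pi = 0.01, phi = 0.05,
                       seed = 1L) {
  stopifnot(length(groups) == 2L, dropout >= 0, dropout <= 1,
            intensity_noise_sd >= 0, mz_jitter_sd >= 0, precursor_sd >= 0,
            rt_jitter_sd >= 0, dep_fraction >= 0, dep_fraction <= 1,
            odds_ratio > 0, phi >= 0, phi < 1, pi > 0, pi < 1)
  structure(as.list(environment()), class = "qfish_simconfig")
}

#' Generate peptide fragment templates
#'
#' Each template is a set of fragment peaks (m/z within the grid range,
#' relative intensities in (0, 1]) with a precursor m/z and an elution time.
#' Templates are rejection-sampled until all pairwise moving-window-average
#' correlations are below 0.3, and precursor m/z values are spaced at least
#' `2 * precursor_tol` apart unless `collide = TRUE`, which places the first
#' two templates at the same precursor (for stress-testing stage 2).
#'
#' @param config A [sim_config()].
#' @param grid A [grid_config()] defining the m/z range and profiles.
#' @param precursor_tol The clustering precursor tolerance the spacing must
#'   clear (Da).
#' @param collide Request one colliding precursor pair.
#' @param max_tries Attempts per template before giving up.
#' @return List of templates: `template_id`, `mz`, `intensity`,
#'   `precursor_mz`, `elution_time`.
#' @export
make_templates <- function(config, grid = grid_config(),
                           precursor_tol = 1.0, collide = FALSE,
                           max_tries = 200L) {
  restore <- local_rng(config$seed)
  on.exit(restore())
  lo <- grid$mz_min + 5 * grid$bin_width
  hi <- grid$mz_max - grid$window_k * grid$bin_width

  # precursor ladder with guaranteed spacing
  span <- c(300, 2000)
  gap <- 2 * precursor_tol
  n <- config$n_templates
  if ((span[2] - span[1]) < n * gap)
    stop("cannot place ", n, " precursors with spacing ", gap, " Da")
  prec <- sort(span[1] + (seq_len(n) - 1) * (span[2] - span[1]) / n +
                 stats::runif(n, 0, (span[2] - span[1]) / n - gap))
  if (collide && n >= 2L) prec[2L] <- prec[1L] + precursor_tol / 2

  elution <- stats::runif(n, config$rt_span[1], config$rt_span[2])

  templates <- list()
  profiles <- NULL
  for (t in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      np <- sample(config$n_peaks_range[1]:config$n_peaks_range[2], 1L)
      mz <- sort(stats::runif(np, lo, hi))
      intensity <- stats::runif(np, 0.05, 1)
      intensity[which.max(intensity)] <- 1
      sp <- new_spectrum(sprintf("T%03d", t), mz, intensity, prec[t])
      prof <- moving_average(bin_spectrum(sp, grid), grid)
      if (is.null(profiles) ||
          all(apply(profiles, 2L, function(p)
            suppressWarnings(correlation_index(p, prof))) < 0.3)) {
        profiles <- cbind(profiles, prof)
        templates[[t]] <- list(template_id = sprintf("T%03d", t),
                               mz = mz, intensity = intensity,
                               precursor_mz = prec[t],
                               elution_time = elution[t])
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not generate template ", t,
           " with pairwise profile correlation < 0.3 in ", max_tries, " tries")
  }
  templates
}

#' Emit noisy replicated acquisitions of the templates
#'
#' For each template and replicate run, the number of acquisitions is Poisson
#' with the group's rate (`base_rate`, scaled by `sqrt(odds_ratio)` up in the
#' first group and down in the second for the true-differential templates).
#' Each acquisition multiplies intensities by lognormal noise, drops peaks
#' independently, jitters fragment and precursor m/z, and jitters the
#' retention time around the template's elution time.
#'
#' @param templates From [make_templates()].
#' @param config A [sim_config()].
#' @param seed Seed for the acquisition noise (defaults to `config$seed + 1`).
#' @return List with `spectra` (list of `qfish_spectrum`, possibly including
#'   degenerate all-dropped spectra at extreme dropout; filter with
#'   [admit_spectra()]) and `truth` (data.frame: spectrum_id, template_id,
#'   sample, replicate, is_dep).
#' @export
emit_spectra <- function(templates, config, seed = config$seed + 1L) {
  restore <- local_rng(seed)
  on.exit(restore())
  n <- length(templates)
  n_dep <- round(config$dep_fraction * n)
  # first templates carry the group effect; no effect at odds ratio 1
  is_dep <- seq_len(n) <= n_dep & config$odds_ratio != 1
  spectra <- list(); truth <- list()
  serial <- 0L
  for (t in seq_len(n)) {
    tmpl <- templates[[t]]
    for (g in seq_along(config$groups)) {
      rate <- config$base_rate *
        if (is_dep[t]) (if (g == 1L) sqrt(config$odds_ratio)
                        else 1 / sqrt(config$odds_ratio)) else 1
      for (r in seq_len(config$replicates)) {
        n_acq <- stats::rpois(1L, rate)
        for (a in seq_len(n_acq)) {
          serial <- serial + 1L
          keep <- stats::runif(length(tmpl$mz)) >= config$dropout
          id <- sprintf("syn%05d", serial)
          mz <- tmpl$mz[keep] +
            stats::rnorm(sum(keep), 0, config$mz_jitter_sd)
          intensity <- tmpl$intensity[keep] *
            exp(stats::rnorm(sum(keep), 0, config$intensity_noise_sd))
          spectra[[serial]] <- new_spectrum(
            id, mz, intensity,
            precursor_mz = tmpl$precursor_mz +
              stats::rnorm(1L, 0, config$precursor_sd),
            retention_time = max(0, tmpl$elution_time +
                                   stats::rnorm(1L, 0, config$rt_jitter_sd)),
            sample = config$groups[g],
            replicate = as.character(r))
          truth[[serial]] <- data.frame(
            spectrum_id = id, template_id = tmpl$template_id,
            sample = config$groups[g], replicate = as.character(r),
            is_dep = is_dep[t], stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(spectra = spectra, truth = do.call(rbind, truth))
}

#' Filter out degenerate spectra
#'
#' Drops spectra with no peaks or no positive in-range intensity (the pipeline
#' admits only spectra it can standardize), with a message giving the count.
#'
#' @param spectra List of `qfish_spectrum`.
#' @param grid Optional [grid_config()]; when given, spectra with no in-range
#'   peak are also dropped.
#' @return The admitted spectra, with attribute `n_dropped`.
#' @export
admit_spectra <- function(spectra, grid = NULL) {
  ok <- vapply(spectra, function(sp) {
    if (length(sp$mz) == 0L || !any(sp$intensity > 0)) return(FALSE)
    if (!is.null(grid))
      return(any(sp$mz >= grid$mz_min & sp$mz < grid$mz_max &
                   sp$intensity > 0))
    TRUE
  }, logical(1))
  if (any(!ok))
    message(sum(!ok), " degenerate spectra dropped before clustering")
  out <- spectra[ok]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Simulate a spectral-count table directly
#'
#' Samples counts from the beta-binomial model the differential test assumes:
#' per cluster a baseline proportion `pi` and overdispersion `phi`; for the
#' true-differential fraction the second group's odds are divided by
#' `odds_ratio`. Totals `n` are fixed at `total_counts` per replicate (the
#' denominators stand for all spectra in the run, of which the simulated
#' clusters are a subset).
#'
#' @param config A [sim_config()]; fields used: `n_clusters`, `groups`,
#'   `replicates`, `total_counts`, `pi`, `phi`, `dep_fraction`, `odds_ratio`,
#'   `seed`.
#' @param seed Override seed (defaults to `config$seed`).
#' @return List with `counts` (a `qfish_counts`-compatible list: `x`, `n`,
#'   `group`, `exclusivity`) and `truth` (data.frame: cluster_id, is_dep,
#'   pi per group).
#' @export
emit_counts <- function(config, seed = config$seed) {
  restore <- local_rng(seed)
  on.exit(restore())
  C <- config$n_clusters
  n_rep <- config$replicates * 2L
  group <- rep(config$groups, each = config$replicates)
  rep_names <- paste(group, rep(seq_len(config$replicates), 2L), sep = ":")
  n_dep <- round(config$dep_fraction * C)
  is_dep <- seq_len(C) <= n_dep & config$odds_ratio != 1
  odds <- config$pi / (1 - config$pi)
  pi_g1 <- rep(config$pi, C)
  pi_g2 <- ifelse(is_dep, (odds / config$odds_ratio) /
                    (1 + odds / config$odds_ratio), config$pi)
  x <- matrix(0L, C, n_rep, dimnames = list(sprintf("S%04d", seq_len(C)),
                                            rep_names))
  for (c_ in seq_len(C)) {
    for (j in seq_len(n_rep)) {
      pi_cj <- if (group[j] == config$groups[1L]) pi_g1[c_] else pi_g2[c_]
      p <- if (config$phi > 0) {
        a <- pi_cj * (1 - config$phi) / config$phi
        b <- (1 - pi_cj) * (1 - config$phi) / config$phi
        stats::rbeta(1L, a, b)
      } else pi_cj
      x[c_, j] <- stats::rbinom(1L, config$total_counts, p)
    }
  }
  counts <- structure(list(x = x, n = rep(config$total_counts, n_rep),
                           group = group,
                           exclusivity = rep("shared", C)),
                      class = "qfish_counts")
  truth <- data.frame(cluster_id = rownames(x), is_dep = is_dep,
                      pi_1 = pi_g1, pi_2 = pi_g2, stringsAsFactors = FALSE)
  names(truth)[3:4] <- paste0("pi_", config$groups)
  list(counts = counts, truth = truth)
}

#' Write a synthetic run to disk
#'
#' Materializes a simulated experiment as one MGF per replicate run, a sample
#' sheet, and a truth TSV, so the file-reading path can be exercised
#' end-to-end.
#'
#' @param sim Output of [emit_spectra()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the MGF paths, sample-sheet path and truth
#'   path.
#' @export
write_synthetic_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(vapply(sim$spectra, `[[`, character(1), "sample"),
               vapply(sim$spectra, `[[`, character(1), "replicate"),
               sep = "_")
  paths <- character(0)
  for (k in unique(key)) {
    p <- file.path(dir, paste0(k, ".mgf"))
    write_mgf(sim$spectra[key == k], p)
    paths <- c(paths, p)
  }
  ss <- data.frame(file = basename(paths),
                   sample = sub("_[^_]*$", "", basename(paths)),
                   replicate = sub("\\.mgf$", "",
                                   sub("^.*_", "", basename(paths))))
  ss$sample <- sub("\\.mgf$", "", ss$sample)
  ss_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(ss, ss_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(mgf = paths, sample_sheet = ss_path, truth = truth_path))
}
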