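# End-to-end orchestration, evaluation against ground truth, and the small
# report helpers for literature-style confusion tables.

#' Default run configuration
#'
#' Collects every pipeline parameter in one flat list that can be written
#' next to the outputs and re-read (key=value text).
#'
#' @param grid A [grid_config()].
#' @param precursor_tol,rho Clustering parameters (Da; correlation cutoff).
#' @param delta CV threshold in percent certified by the FCR scan.
#' @param delta_grid,rho_grid Scan grids.
#' @param P Permutations for the FCR.
#' @param alpha FDR level of the differential test.
#' @param link Beta-binomial link function.
#' @param seed Root seed.
#' @param scan_rho Whether [run_pipeline()] also performs the (costly)
#'   correlation-cutoff scan.
#' @return List of class `qfish_runconfig`.
#' @export
run_config <- function(grid = grid_config(), precursor_tol = 1.0, rho = 0.6,
                       delta = 4.4, delta_grid = 1:10,
                       rho_grid = seq(0, 1, by = 0.1), P = 100,
                       alpha = 0.05, link = "logit", seed = 1L,
                       scan_rho = FALSE) {
  structure(as.list(environment()), class = "qfish_runconfig")
}

write_run_config <- function(config, path) {
  flat <- c(
    mz_min = config$grid$mz_min, mz_max = config$grid$mz_max,
    bin_width = config$grid$bin_width, window_k = config$grid$window_k,
    kernel = config$grid$kernel,
    precursor_tol = config$precursor_tol, rho = config$rho,
    delta = config$delta,
    delta_grid = paste(config$delta_grid, collapse = ","),
    rho_grid = paste(config$rho_grid, collapse = ","),
    P = config$P, alpha = config$alpha, link = config$link,
    seed = config$seed, scan_rho = config$scan_rho)
  writeLines(paste0(names(flat), "=", flat), path)
  invisible(path)
}

#' Read a run configuration from a key=value file
#'
#' @param path Path to a flat `key=value` text file as written next to every
#'   run's outputs.
#' @return A `qfish_runconfig` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    paste(x[-1L], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  run_config(
    grid = grid_config(num("mz_min", 200), num("mz_max", 2000),
                       num("bin_width", 0.1), num("window_k", 30),
                       if ("kernel" %in% names(vals)) vals[["kernel"]]
                       else "gaussian"),
    precursor_tol = num("precursor_tol", 1.0), rho = num("rho", 0.6),
    delta = num("delta", 4.4),
    delta_grid = if ("delta_grid" %in% names(vals))
      as.numeric(strsplit(vals[["delta_grid"]], ",")[[1]]) else 1:10,
    rho_grid = if ("rho_grid" %in% names(vals))
      as.numeric(strsplit(vals[["rho_grid"]], ",")[[1]])
      else seq(0, 1, by = 0.1),
    P = num("P", 100), alpha = num("alpha", 0.05),
    link = if ("link" %in% names(vals)) vals[["link"]] else "logit",
    seed = as.integer(num("seed", 1)),
    scan_rho = isTRUE(as.logical(vals[["scan_rho"]])))
}

#' Run the full pipeline
#'
#' Reads spectra (or takes them in memory), clusters them, counts spectra per
#' cluster and replicate, scans the CV threshold and computes the FCR at the
#' working threshold, selects shared clusters passing the CV filter, runs the
#' beta-binomial differential test, and writes clusters, counts, FCR scan and
#' differential-expression TSVs plus the resolved configuration into
#' `out_dir`.
#'
#' @param spectra List of `qfish_spectrum`, or `NULL` to read from `mgf`.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param mgf,sample_sheet MGF paths and sample-sheet path (used when
#'   `spectra` is `NULL`).
#' @return Invisibly, a list with the clustering, counts, scans, the
#'   differential result and the output paths.
#' @export
run_pipeline <- function(spectra = NULL, out_dir, config = run_config(),
                         mgf = NULL, sample_sheet = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)

  if (is.null(spectra)) {
    ss <- if (is.character(sample_sheet)) read_sample_sheet(sample_sheet)
          else sample_sheet
    spectra <- read_mgf(mgf, ss)
    logf("read %d spectra from %d MGF file(s), %d dropped at ingest",
         length(spectra), length(mgf), attr(spectra, "n_dropped"))
  }
  n_in <- length(spectra)
  spectra <- admit_spectra(spectra, config$grid)
  logf("admitted %d/%d spectra", length(spectra), n_in)

  clusters <- cluster_spectra(spectra, config$grid,
                              precursor_tol = config$precursor_tol,
                              rho = config$rho)
  logf("clustered %d spectra into %d clusters",
       nrow(clusters$assignments), nrow(clusters$clusters))
  write_clusters_tsv(clusters, file.path(out_dir, "clusters.tsv"))

  counts <- count_spectra(clusters)
  write_counts_tsv(counts, file.path(out_dir, "counts.tsv"), clusters)
  logf("counts conserve spectra: %s",
       sum(counts$x) == nrow(clusters$assignments))

  rts <- cluster_rts(clusters)
  dscan <- scan_delta(rts, config$delta_grid, P = config$P,
                      seed = config$seed)
  utils::write.table(as.data.frame(dscan), file.path(out_dir, "fcr_delta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fcr_at_delta <- suppressWarnings(
    compute_fcr(rts, config$delta, P = config$P, seed = config$seed))
  logf("FCR at delta = %g: %s", config$delta, format(fcr_at_delta))

  rscan <- NULL
  if (isTRUE(config$scan_rho)) {
    rscan <- scan_rho(spectra, config$grid, config$rho_grid,
                      delta = config$delta,
                      precursor_tol = config$precursor_tol,
                      P = config$P, seed = config$seed)
    utils::write.table(as.data.frame(rscan), file.path(out_dir, "fcr_rho.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # clusters eligible for testing: shared between groups and, when of size
  # >= 2, passing the CV filter at the working threshold
  cv <- vapply(rts, cluster_cv, numeric(1))
  pass_cv <- is.na(cv) | cv <= config$delta
  keep <- rownames(counts$x)[pass_cv[rownames(counts$x)]]
  dep <- run_dep(counts, alpha = config$alpha, link = config$link,
                 keep = keep)
  logf("tested %d shared clusters, %d significant at q <= %g",
       nrow(dep), sum(dep$significant), config$alpha)
  utils::write.table(dep, file.path(out_dir, "dep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.txt"))

  invisible(list(clusters = clusters, counts = counts, delta_scan = dscan,
                 rho_scan = rscan, fcr_at_delta = fcr_at_delta, dep = dep,
                 out_dir = out_dir))
}

#' Compare a clustering with ground truth
#'
#' @param assigned Named vector or data.frame mapping spectrum ids to cluster
#'   ids (e.g. `clusters$assignments[, c("spectrum_id", "cluster_id")]`).
#' @param truth Data.frame with `spectrum_id` and `template_id` columns.
#' @return List: `ari` (adjusted Rand index), `purity` (fraction of spectra in
#'   the majority template of their cluster) and `n_clusters`.
#' @export
evaluate_clustering <- function(assigned, truth) {
  if (is.data.frame(assigned))
    assigned <- stats::setNames(assigned$cluster_id, assigned$spectrum_id)
  common <- intersect(names(assigned), truth$spectrum_id)
  if (length(common) == 0L)
    stop("no spectrum ids shared between clustering and truth")
  a <- assigned[common]
  t_ <- truth$template_id[match(common, truth$spectrum_id)]
  purity <- sum(vapply(split(t_, a), function(v) max(table(v)), numeric(1))) /
    length(common)
  list(ari = mclust::adjustedRandIndex(a, t_),
       purity = purity,
       n_clusters = length(unique(a)))
}

#' Accuracy of a 2x2 confusion table
#'
#' Percent agreement between a method's over/under-expression calls and a
#' literature reference: 100 times the diagonal sum over the table total,
#' rounded to two decimals for reporting.
#'
#' @param table 2x2 matrix of non-negative counts: rows = reference
#'   (over-expressed, under-expressed), columns = method call (first group,
#'   second group); the diagonal holds the agreements.
#' @return Accuracy in percent, rounded to 2 decimals.
#' @export
confusion_accuracy <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  total <- sum(table)
  if (total == 0) stop("empty confusion table")
  round(100 * sum(diag(table)) / total, 2L)
}

#' Percentage of spectra a search engine left unassigned
#'
#' Database and library search engines typically assign only a minority of
#' MS/MS spectra to peptides; this is the complementary percentage that would
#' be lost to a purely identification-based quantification.
#'
#' @param n_identified Spectra the engine assigned.
#' @param n_total Total acquired spectra.
#' @return Percent unassigned, rounded to 2 decimals.
#' @export
unassigned_percent <- function(n_identified, n_total) {
  stopifnot(n_total > 0, n_identified >= 0, n_identified <= n_total)
  round(100 * (n_total - n_identified) / n_total, 2L)
}
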