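# Two-stage clustering: precursor-mass grouping (pairwise +/- tolerance),
# single-linkage on the correlation index within each group, reference
# spectra, Q scores and per-replicate spectral counts.

#' Group spectra by precursor m/z
#'
#' Agglomerative complete-linkage clustering on absolute precursor m/z
#' differences, cut so that every group's diameter is at most
#' `precursor_tol`: any two members of a group differ by no more than the
#' tolerance. When merge distances tie, the pair containing the lowest
#' spectrum index merges first, making the grouping deterministic.
#'
#' @param precursor_mz Numeric vector of precursor m/z values (Da).
#' @param precursor_tol Maximum pairwise difference within a group (Da,
#'   default 1.0, i.e. a +/- 1 Da window).
#' @return Integer vector of group ids (1-based, in order of first member).
#' @export
group_by_precursor <- function(precursor_mz, precursor_tol = 1.0) {
  n <- length(precursor_mz)
  if (n == 0L) return(integer(0))
  # On the real line, groups under complete linkage are intervals and the
  # minimum-distance pair is always adjacent in sorted order (the span of the
  # union of two intervals only grows with their separation), so it suffices
  # to merge adjacent intervals.
  o <- order(precursor_mz)
  lo <- precursor_mz[o]; hi <- precursor_mz[o]
  members <- lapply(o, identity)         # original indices per group
  min_idx <- o                            # lowest original index per group
  repeat {
    g <- length(members)
    if (g == 1L) break
    d <- hi[-1L] - lo[-g]                 # complete-linkage gap of adjacents
    best_d <- min(d)
    if (best_d > precursor_tol) break
    tied <- which(d <= best_d + 1e-12)
    a <- tied[which.min(pmin(min_idx[tied], min_idx[tied + 1L]))]
    members[[a]] <- c(members[[a]], members[[a + 1L]])
    hi[a] <- hi[a + 1L]
    min_idx[a] <- min(min_idx[a], min_idx[a + 1L])
    members[[a + 1L]] <- NULL
    lo <- lo[-(a + 1L)]; hi <- hi[-(a + 1L)]; min_idx <- min_idx[-(a + 1L)]
  }
  ids <- integer(n)
  ord <- order(vapply(members, min, numeric(1)))
  for (k in seq_along(ord)) ids[members[[ord[k]]]] <- k
  ids
}

#' Single-linkage clustering within a precursor group
#'
#' Agglomerates spectra at distance `d = 1 - r` (with `r` the correlation
#' index of their moving-window-average profiles) and cuts the single-linkage
#' tree at height `1 - rho`. The resulting partition equals the connected
#' components of the graph with an edge wherever `r >= rho`.
#'
#' @param profiles Matrix of profiles, one spectrum per column.
#' @param rho Correlation cutoff (default 0.6).
#' @return Integer vector of cluster ids within the group.
#' @export
cluster_within_group <- function(profiles, rho = 0.6) {
  n <- ncol(profiles)
  if (n == 1L) return(1L)
  r <- suppressWarnings(stats::cor(profiles))
  r[!is.finite(r)] <- 0  # zero-variance profiles: treated as dissimilar
  d <- stats::as.dist(1 - r)
  tree <- stats::hclust(d, method = "single")
  as.integer(stats::cutree(tree, h = 1 - rho))
}

#' Reference spectrum of a cluster
#'
#' The bin-wise arithmetic mean of the members' scale-standardized binned
#' spectra; the cluster's representative peak pattern.
#'
#' @param binned Matrix of binned standardized spectra, one member per column.
#' @return Numeric vector over the grid bins.
#' @export
build_reference <- function(binned) {
  if (is.null(dim(binned))) binned <- matrix(binned, ncol = 1L)
  if (ncol(binned) == 0L) stop("empty cluster: no members to average")
  rowMeans(binned)
}

#' Q score of a cluster
#'
#' Mean correlation index between the reference spectrum's profile and each
#' member's profile; close to 1 when the reference represents the members
#' well. A singleton cluster scores 1 by the identity property.
#'
#' @param ref_profile Moving-window-average profile of the reference spectrum.
#' @param member_profiles Matrix of member profiles (one per column).
#' @return Mean correlation in `[-1, 1]`.
#' @export
q_score <- function(ref_profile, member_profiles) {
  if (is.null(dim(member_profiles)))
    member_profiles <- matrix(member_profiles, ncol = 1L)
  mean(apply(member_profiles, 2L,
             function(m) suppressWarnings(correlation_index(ref_profile, m))))
}

#' Two-stage clustering of MS/MS spectra
#'
#' Runs the full clustering: bins and smooths every spectrum, groups by
#' precursor m/z (pairwise tolerance), single-linkage clusters each group on
#' the correlation index, and computes per-cluster reference spectra, Q
#' scores and retention-time lists. All replicates of all samples are
#' clustered jointly; counting per replicate comes after
#' (see [count_spectra()]). Precursor charge is ignored unless
#' `split_by_charge = TRUE`.
#'
#' @param spectra List of `qfish_spectrum`.
#' @param grid A [grid_config()].
#' @param precursor_tol Pairwise precursor m/z tolerance in Da (default 1.0).
#' @param rho Correlation cutoff for single linkage (default 0.6).
#' @param split_by_charge If `TRUE`, spectra with known, differing precursor
#'   charges are never grouped together.
#' @return An object of class `qfish_clusters` with elements `assignments`
#'   (data.frame: spectrum_id, cluster_id, sample, replicate, retention_time,
#'   precursor_mz), `clusters` (data.frame: cluster_id, size, q_score,
#'   precursor_mz), `references` (bins x clusters matrix), `grid` and the
#'   parameters used.
#' @export
cluster_spectra <- function(spectra, grid = grid_config(), precursor_tol = 1.0,
                            rho = 0.6, split_by_charge = FALSE) {
  stopifnot(length(spectra) > 0L)
  prof <- profile_spectra(spectra, grid)
  pmz <- vapply(spectra, `[[`, numeric(1), "precursor_mz")

  charge_key <- rep("", length(spectra))
  if (split_by_charge) {
    ch <- vapply(spectra, `[[`, integer(1), "precursor_charge")
    charge_key <- ifelse(is.na(ch), "", as.character(ch))
  }

  cluster_of <- integer(length(spectra))
  next_id <- 0L
  for (ck in unique(charge_key)) {
    in_ck <- which(charge_key == ck)
    gid <- group_by_precursor(pmz[in_ck], precursor_tol)
    for (g in sort(unique(gid))) {
      idx <- in_ck[gid == g]
      sub <- cluster_within_group(prof$profiles[, idx, drop = FALSE], rho)
      cluster_of[idx] <- next_id + sub
      next_id <- next_id + max(sub)
    }
  }

  # serial "S"-prefixed ids in order of first member appearance
  first_seen <- order(vapply(split(seq_along(cluster_of), cluster_of), min,
                             numeric(1)))
  remap <- integer(next_id)
  remap[as.integer(names(split(seq_along(cluster_of), cluster_of)))[first_seen]] <-
    seq_along(first_seen)
  cluster_of <- remap[cluster_of]
  ids <- sprintf("S%04d", cluster_of)

  assignments <- data.frame(
    spectrum_id = vapply(spectra, `[[`, character(1), "spectrum_id"),
    cluster_id = ids,
    sample = vapply(spectra, `[[`, character(1), "sample"),
    replicate = vapply(spectra, `[[`, character(1), "replicate"),
    retention_time = vapply(spectra, `[[`, numeric(1), "retention_time"),
    precursor_mz = pmz,
    stringsAsFactors = FALSE
  )

  uids <- sprintf("S%04d", seq_len(max(cluster_of)))
  refs <- matrix(NA_real_, nrow = grid$n_bins, ncol = length(uids),
                 dimnames = list(NULL, uids))
  qs <- numeric(length(uids)); sz <- integer(length(uids)); pm <- numeric(length(uids))
  for (k in seq_along(uids)) {
    idx <- which(cluster_of == k)
    ref <- build_reference(prof$binned[, idx, drop = FALSE])
    refs[, k] <- ref
    qs[k] <- q_score(moving_average(ref, grid),
                     prof$profiles[, idx, drop = FALSE])
    sz[k] <- length(idx)
    pm[k] <- mean(pmz[idx])
  }

  structure(list(
    assignments = assignments,
    clusters = data.frame(cluster_id = uids, size = sz, q_score = qs,
                          precursor_mz = pm, stringsAsFactors = FALSE),
    references = refs,
    grid = grid,
    precursor_tol = precursor_tol,
    rho = rho
  ), class = "qfish_clusters")
}

#' @export
print.qfish_clusters <- function(x, ...) {
  cat(sprintf("%d spectra in %d clusters (precursor_tol = %g Da, rho = %g)\n",
              nrow(x$assignments), nrow(x$clusters), x$precursor_tol, x$rho))
  invisible(x)
}

#' Per-cluster retention times
#'
#' @param clusters A `qfish_clusters` object.
#' @return Named list of numeric RT vectors, one per cluster.
#' @export
cluster_rts <- function(clusters) {
  split(clusters$assignments$retention_time, clusters$assignments$cluster_id)
}

#' Spectral-count table
#'
#' Counts member spectra per cluster and replicate; the count matrix `x` and
#' the per-replicate totals `n` (column sums over all clusters, i.e. all
#' admitted spectra in that run) are the inputs to the beta-binomial test.
#' Each cluster is also labelled group-exclusive (members from one sample
#' group only) or shared.
#'
#' @param clusters A `qfish_clusters` object.
#' @return An object of class `qfish_counts`: list with `x` (clusters x
#'   replicates integer matrix, columns named `sample:replicate`), `n`
#'   (per-replicate totals), `group` (sample group per column), and
#'   `exclusivity` (per-cluster label: one of the group names, or "shared").
#' @export
count_spectra <- function(clusters) {
  a <- clusters$assignments
  rep_key <- paste(a$sample, a$replicate, sep = ":")
  rep_levels <- unique(rep_key[order(a$sample, a$replicate)])
  x <- table(factor(a$cluster_id, levels = clusters$clusters$cluster_id),
             factor(rep_key, levels = rep_levels))
  x <- matrix(as.integer(x), nrow = nrow(x), dimnames = dimnames(x))
  group <- sub(":.*$", "", rep_levels)
  present <- t(apply(x, 1L, function(r) tapply(r, group, sum) > 0))
  exclusivity <- apply(present, 1L, function(p)
    if (sum(p) == 1L) colnames(present)[which(p)] else "shared")
  structure(list(x = x, n = colSums(x), group = group,
                 exclusivity = exclusivity),
            class = "qfish_counts")
}

#' @export
print.qfish_counts <- function(x, ...) {
  cat(sprintf("count table: %d clusters x %d replicates (groups: %s); %d shared\n",
              nrow(x$x), ncol(x$x), paste(unique(x$group), collapse = ", "),
              sum(x$exclusivity == "shared")))
  invisible(x)
}

#' Write the count table to TSV
#'
#' @param counts A `qfish_counts` object.
#' @param clusters The matching `qfish_clusters` (for Q scores and precursor
#'   m/z), or `NULL`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, clusters = NULL) {
  tab <- data.frame(cluster_id = rownames(counts$x), counts$x,
                    exclusivity = counts$exclusivity,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    m <- match(tab$cluster_id, clusters$clusters$cluster_id)
    tab$q_score <- clusters$clusters$q_score[m]
    tab$precursor_mz <- clusters$clusters$precursor_mz[m]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
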