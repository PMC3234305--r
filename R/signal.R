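# Fixed-grid binning, scale standardization, moving-window-average profiles
# and the pairwise correlation index.

#' Grid configuration for spectrum profiles
#'
#' Defines the fixed m/z grid on which every spectrum is binned and smoothed,
#' so that all profiles share one length and are directly comparable. The
#' moving window spans `window_k` bins (3.0 Da at the defaults) and the
#' profile length is always derived as `bins - window_k + 1`.
#'
#' @param mz_min,mz_max Grid range in Da; peaks outside `[mz_min, mz_max)` are
#'   dropped. Default 200-2000 Da, a typical ion-trap fragment scan range.
#' @param bin_width Bin width in Da (default 0.1).
#' @param window_k Moving-window size in bins (default 30, i.e. 3.0 Da).
#' @param kernel Window weight kernel, `"gaussian"` (default) or `"uniform"`.
#' @return An object of class `qfish_grid`.
#' @export
grid_config <- function(mz_min = 200, mz_max = 2000, bin_width = 0.1,
                        window_k = 30, kernel = c("gaussian", "uniform")) {
  kernel <- match.arg(kernel)
  stopifnot(mz_max > mz_min, bin_width > 0, window_k >= 1)
  n_bins <- as.integer(floor((mz_max - mz_min) / bin_width + 1e-9))
  if (window_k > n_bins)
    stop("window_k (", window_k, ") exceeds the number of grid bins (", n_bins, ")")
  structure(list(mz_min = mz_min, mz_max = mz_max, bin_width = bin_width,
                 window_k = as.integer(window_k), kernel = kernel,
                 n_bins = n_bins, n_windows = n_bins - as.integer(window_k) + 1L),
            class = "qfish_grid")
}

#' @export
print.qfish_grid <- function(x, ...) {
  cat(sprintf("m/z grid [%g, %g) Da, bin %g Da (%d bins), window K = %d (%s kernel), %d profile windows\n",
              x$mz_min, x$mz_max, x$bin_width, x$n_bins, x$window_k, x$kernel,
              x$n_windows))
  invisible(x)
}

#' Scale-standardize intensities
#'
#' Divides every intensity by the spectrum maximum, so the largest peak has
#' standardized intensity 1 and spectra become comparable regardless of total
#' ion current.
#'
#' @param x Numeric vector of non-negative intensities, at least one positive.
#' @return `x / max(x)`.
#' @export
scale_standardize <- function(x) {
  if (length(x) == 0L || !any(x > 0) || any(x < 0) || anyNA(x))
    stop("degenerate spectrum: intensities must be non-negative with at least one positive value")
  x / max(x)
}

#' Bin a spectrum onto the grid
#'
#' Each peak with `mz_min <= mz < mz_max` falls in bin
#' `floor((mz - mz_min)/bin_width)` (half-open bins); intensities within a bin
#' are summed and the bin vector is then scale-standardized. Out-of-range
#' peaks are dropped and counted.
#'
#' @param spectrum A `qfish_spectrum`.
#' @param grid A [grid_config()].
#' @return Numeric vector of length `grid$n_bins` with values in `[0, 1]` and
#'   maximum exactly 1; attribute `n_out_of_range` counts dropped peaks.
#' @export
bin_spectrum <- function(spectrum, grid) {
  keep <- spectrum$mz >= grid$mz_min & spectrum$mz < grid$mz_max
  if (!any(keep & spectrum$intensity > 0))
    stop("degenerate spectrum '", spectrum$spectrum_id,
         "': no in-range peak with positive intensity")
  idx <- 1L + as.integer(floor((spectrum$mz[keep] - grid$mz_min) / grid$bin_width))
  idx <- pmin(idx, grid$n_bins)  # guard against floating-point edge at mz_max
  y <- numeric(grid$n_bins)
  agg <- rowsum(spectrum$intensity[keep], idx)
  y[as.integer(rownames(agg))] <- agg[, 1L]
  y <- scale_standardize(y)
  attr(y, "n_out_of_range") <- sum(!keep)
  y
}

#' Moving-window kernel weights
#'
#' Uniform weights are `1/K`. Gaussian weights are the standard normal
#' density evaluated at the standardized within-window bin-center m/z offsets
#' (the offsets are the same arithmetic sequence for every window position, so
#' the kernel is one fixed symmetric bell), renormalized to sum to 1.
#'
#' @param grid A [grid_config()].
#' @return Numeric vector of length `grid$window_k` summing to 1.
#' @export
window_weights <- function(grid) {
  k <- grid$window_k
  if (grid$kernel == "uniform") return(rep(1 / k, k))
  if (k == 1L) return(1)
  centers <- (seq_len(k) - 1) * grid$bin_width
  z <- (centers - mean(centers)) / stats::sd(centers)
  w <- stats::dnorm(z)
  w / sum(w)
}

#' Moving-window-average profile
#'
#' Slides a `window_k`-bin window with stride one bin along the binned
#' spectrum and takes the kernel-weighted mean in each position:
#' `m[i] = sum_j w_j y[i + j]`. Because the weights sum to 1, a vector in
#' `[0, 1]` maps into `[0, 1]`.
#'
#' @param binned Binned standardized spectrum from [bin_spectrum()], or any
#'   numeric vector of length `grid$n_bins`.
#' @param grid A [grid_config()].
#' @return Numeric profile of length `grid$n_windows`.
#' @export
moving_average <- function(binned, grid) {
  stopifnot(length(binned) == grid$n_bins)
  w <- window_weights(grid)
  k <- grid$window_k
  if (k == 1L) return(as.numeric(binned))
  out <- stats::filter(as.numeric(binned), rev(w), method = "convolution",
                       sides = 1)
  as.numeric(out[k:grid$n_bins])
}

#' Correlation index between two profiles
#'
#' Pearson correlation of two moving-window-average profiles on the same
#' grid; the similarity on which spectra are clustered. If either profile has
#' zero variance the correlation is undefined; by convention the pair is
#' treated as dissimilar (`r = 0`) with a warning, so near-empty spectra never
#' merge.
#'
#' @param p,q Numeric profiles of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
correlation_index <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    warning("zero-variance profile: correlation undefined, returning 0")
    return(0)
  }
  stats::cor(p, q)
}

# Bin + smooth a list of spectra into a profile matrix (spectra in columns)
# plus the binned matrix needed for reference spectra.
profile_spectra <- function(spectra, grid) {
  binned <- vapply(spectra, bin_spectrum, numeric(grid$n_bins), grid = grid)
  profiles <- apply(binned, 2L, moving_average, grid = grid)
  list(binned = binned, profiles = profiles)
}
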