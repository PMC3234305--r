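# Reading MS/MS peak lists (MGF) and attaching sample/replicate labels.

#' Read a sample sheet
#'
#' A sample sheet maps each LC-MS/MS run to its sample group and replicate
#' label. It is a tab-separated file with a header and columns `file` (the
#' basename of the MGF file for that run) or `title_pattern` (a regular
#' expression matched against spectrum TITLE lines), plus `sample` and
#' `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `file` and/or `title_pattern`, `sample`,
#'   `replicate`.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "replicate") %in% names(ss)))
    stop("sample sheet must have 'sample' and 'replicate' columns")
  if (!any(c("file", "title_pattern") %in% names(ss)))
    stop("sample sheet must have a 'file' or 'title_pattern' column")
  ss$sample <- as.character(ss$sample)
  ss$replicate <- as.character(ss$replicate)
  ss
}

resolve_labels <- function(file, title, sample_sheet) {
  if (!is.null(sample_sheet$file)) {
    hit <- which(sample_sheet$file == basename(file))
    if (length(hit) == 1L)
      return(sample_sheet[hit, c("sample", "replicate")])
    if (length(hit) > 1L)
      stop("sample sheet maps file '", basename(file), "' to multiple rows")
  }
  if (!is.null(sample_sheet$title_pattern) && !is.na(title) && nzchar(title)) {
    hit <- which(vapply(sample_sheet$title_pattern, grepl, logical(1), x = title))
    if (length(hit) >= 1L)
      return(sample_sheet[hit[1L], c("sample", "replicate")])
  }
  stop("spectrum (file '", basename(file), "', title '", title,
       "') matches no sample-sheet row")
}

#' Construct an MS/MS spectrum
#'
#' Builds the in-memory spectrum the pipeline operates on: a peak list with a
#' precursor m/z, retention time, and sample/replicate labels. Peaks are
#' sorted by m/z and duplicate m/z entries merged by summing intensities, so
#' the total ion current is preserved.
#'
#' @param spectrum_id Unique identifier string.
#' @param mz,intensity Fragment peak m/z values (Da) and intensities
#'   (non-negative, arbitrary ion-count units).
#' @param precursor_mz Precursor ion m/z (Da), positive.
#' @param precursor_charge Integer charge or `NA` when unknown.
#' @param retention_time Elution time in seconds.
#' @param sample,replicate Sample-group and replicate labels.
#' @return An object of class `qfish_spectrum`.
#' @export
new_spectrum <- function(spectrum_id, mz, intensity, precursor_mz,
                         precursor_charge = NA_integer_,
                         retention_time = NA_real_,
                         sample = NA_character_, replicate = NA_character_) {
  # sort and merge duplicate m/z by summing intensity, so the binned x[i]
  # is well defined downstream
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(
    spectrum_id = spectrum_id,
    mz = mz, intensity = intensity,
    precursor_mz = precursor_mz,
    precursor_charge = precursor_charge,
    retention_time = retention_time,
    sample = sample, replicate = replicate
  ), class = "qfish_spectrum")
}

#' @export
print.qfish_spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum '%s': %d peaks, precursor m/z %.4f, RT %.2f s, %s/%s\n",
              x$spectrum_id, length(x$mz), x$precursor_mz,
              x$retention_time, x$sample, x$replicate))
  invisible(x)
}

#' Read MS/MS spectra from MGF files
#'
#' Parses Mascot Generic Format peak lists (`BEGIN IONS`/`END IONS` blocks
#' with `PEPMASS`, optional `CHARGE`, `RTINSECONDS` or `RTINMINUTES`, and
#' `TITLE` headers). Peaks are sorted by m/z with duplicate m/z entries merged
#' by summing their intensities; spectra with an empty peak list or with no
#' positive intensity are dropped with a message. Sample and replicate labels
#' are resolved through the sample sheet, by file name first and by TITLE
#' regular expression as a fallback.
#'
#' @param paths Character vector of MGF file paths (one file per LC run).
#' @param sample_sheet A data.frame as returned by [read_sample_sheet()], or
#'   `NULL` to leave labels unset.
#' @return A list of spectra (class `qfish_spectrum`), with attribute
#'   `n_dropped` giving the number of degenerate blocks discarded.
#' @export
read_mgf <- function(paths, sample_sheet = NULL) {
  spectra <- list()
  dropped <- 0L
  for (path in paths) {
    lines <- readLines(path, warn = FALSE)
    begins <- grep("^BEGIN IONS\\s*$", lines)
    ends <- grep("^END IONS\\s*$", lines)
    if (length(begins) != length(ends) || any(ends < begins))
      stop("malformed MGF '", path, "': unbalanced BEGIN IONS/END IONS")
    for (b in seq_along(begins)) {
      block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
      block <- block[nzchar(trimws(block))]
      is_kv <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
      kv <- block[is_kv]
      keys <- toupper(sub("=.*$", "", kv))
      vals <- sub("^[^=]*=", "", kv)
      getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_

      pepmass <- getv("PEPMASS")
      if (is.na(pepmass))
        stop("malformed MGF block ", b, " in '", path, "': missing PEPMASS")
      precursor_mz <- as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1])
      if (!is.finite(precursor_mz) || precursor_mz <= 0)
        stop("malformed MGF block ", b, " in '", path, "': bad PEPMASS")

      rt <- NA_real_
      if (!is.na(getv("RTINSECONDS"))) rt <- as.numeric(getv("RTINSECONDS"))
      else if (!is.na(getv("RTINMINUTES"))) rt <- 60 * as.numeric(getv("RTINMINUTES"))
      if (is.na(rt) || rt < 0)
        stop("malformed MGF block ", b, " in '", path,
             "': missing or negative retention time")

      charge <- NA_integer_
      ch <- getv("CHARGE")
      if (!is.na(ch)) {
        chn <- suppressWarnings(as.integer(sub("\\+$", "", trimws(ch))))
        if (!is.na(chn)) charge <- chn
      }
      title <- getv("TITLE")

      peak_lines <- block[!is_kv]
      pk <- lapply(strsplit(trimws(peak_lines), "[ \t]+"), function(f) {
        v <- suppressWarnings(as.numeric(f[1:2]))
        if (anyNA(v)) stop("malformed MGF block ", b, " in '", path,
                           "': unparseable peak line")
        v
      })
      mz <- vapply(pk, `[`, numeric(1), 1L)
      intensity <- vapply(pk, `[`, numeric(1), 2L)
      if (any(intensity < 0))
        stop("malformed MGF block ", b, " in '", path, "': negative intensity")
      if (length(mz) == 0L || all(intensity == 0)) {
        dropped <- dropped + 1L
        next
      }

      id <- if (!is.na(title)) title else sprintf("%s#%d", basename(path), b)
      sample <- NA_character_; replicate <- NA_character_
      if (!is.null(sample_sheet)) {
        lab <- resolve_labels(path, if (is.na(title)) "" else title, sample_sheet)
        sample <- lab$sample; replicate <- lab$replicate
      }
      spectra[[length(spectra) + 1L]] <-
        new_spectrum(id, mz, intensity, precursor_mz, charge, rt,
                     sample, replicate)
    }
  }
  if (dropped > 0L)
    message(dropped, " spectra dropped (empty or all-zero peak list)")
  attr(spectra, "n_dropped") <- dropped
  spectra
}

#' Write spectra to an MGF file
#'
#' Companion writer to [read_mgf()]; used mainly to materialize synthetic
#' runs. Retention time is written as RTINSECONDS and the spectrum id as
#' TITLE.
#'
#' @param spectra List of `qfish_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      if (!is.na(sp$precursor_charge)) sprintf("CHARGE=%d+", sp$precursor_charge),
      sprintf("RTINSECONDS=%.4f", sp$retention_time),
      sprintf("%.6f %.6f", sp$mz, sp$intensity),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

#' Write cluster membership to TSV
#'
#' One row per member spectrum: cluster id, sample, replicate, retention time,
#' precursor m/z and the cluster's Q score. Round-trips losslessly through
#' [read_clusters_tsv()].
#'
#' @param clusters A clustering as returned by [cluster_spectra()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  a <- clusters$assignments
  tab <- data.frame(
    cluster_id = a$cluster_id,
    spectrum_id = a$spectrum_id,
    sample = a$sample,
    replicate = a$replicate,
    retention_time = a$retention_time,
    precursor_mz = a$precursor_mz,
    q_score = clusters$clusters$q_score[match(a$cluster_id,
                                              clusters$clusters$cluster_id)],
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster membership back from TSV
#'
#' @param path A TSV written by [write_clusters_tsv()].
#' @return A data.frame with one row per member spectrum.
#' @export
read_clusters_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(cluster_id = "character",
                                   spectrum_id = "character",
                                   sample = "character",
                                   replicate = "character"))
}
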