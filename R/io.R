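# Readers and writers for the toolkit's file formats: feature-table CSV,
# MGF / mzML spectra, transition lists, quantification and results tables,
# and the run configuration.

#' Read an MS1 feature table
#'
#' CSV with header `feature_id, mz, rt_min`, then one intensity column per
#' sample. Malformed numeric cells are reported with their file line number.
#'
#' @param path CSV path.
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt_min")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("feature table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  numeric_cols <- setdiff(names(raw), "feature_id")
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & nzchar(raw[[cc]]))
    if (length(bad)) {
      stop("non-numeric value in column '", cc, "' at line ",
           paste(bad + 1L, collapse = ", "), " of ", path)
    }
    raw[[cc]] <- v
  }
  raw
}

#' @rdname read_feature_table
#' @param features Feature table to write.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS/MS spectra from MGF
#'
#' Parses `BEGIN IONS` blocks honoring `PEPMASS` (first token) and
#' `RTINSECONDS` (converted to minutes).
#'
#' @param path MGF path.
#' @return List of spectra (`precursor_mz`, `rt` in minutes, `peaks`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("unbalanced BEGIN/END IONS blocks in ", path)
  }
  lapply(seq_along(starts), function(b) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    header <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[header], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    pep <- vals[keys == "PEPMASS"]
    rts <- vals[keys == "RTINSECONDS"]
    if (length(pep) == 0) stop("MGF block ", b, " lacks PEPMASS")
    peak_lines <- block[!header & nzchar(trimws(block))]
    peaks <- if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                                   function(x) as.numeric(x[1:2])))
      if (any(is.na(mat))) stop("unparseable peak line in MGF block ", b)
      colnames(mat) <- c("mz", "intensity")
      mat[order(mat[, 1]), , drop = FALSE]
    } else {
      matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    list(precursor_mz = as.numeric(strsplit(pep[1], "[ \t]+")[[1]][1]),
         rt = if (length(rts)) as.numeric(rts[1]) / 60 else NA_real_,
         peaks = peaks)
  })
}

#' @rdname read_mgf
#' @param spectra List of spectra to write.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.null(s$rt) && !is.na(s$rt)) {
      writeLines(sprintf("RTINSECONDS=%.4f", s$rt * 60), con)
    }
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.6f %.6f", s$peaks[, 1], s$peaks[, 2]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  ms2 <- which(hdr$msLevel == 2)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(f, i)
    colnames(pk) <- c("mz", "intensity")
    list(precursor_mz = hdr$precursorMZ[i],
         rt = hdr$retentionTime[i] / 60,
         peaks = pk[order(pk[, 1]), , drop = FALSE])
  })
}

#' Read MS/MS spectra (MGF or mzML)
#'
#' Dispatches on the file extension; mzML reading keeps MS2 scans only and
#' converts retention times to minutes.
#'
#' @param path Spectra file (.mgf, .mzML).
#' @return List of spectra.
#' @export
read_spectra <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mgf = read_mgf(path),
         mzml = read_mzml(path),
         stop("unsupported spectra format: .", ext))
}

#' Write and re-read transition lists and result tables
#'
#' Plain CSV/TSV writers with stable column and row order; m/z values keep
#' full precision (display rounding is the caller's concern).
#'
#' @param transitions Transition list from [export_transitions()].
#' @param path Output path.
#' @export
write_transitions <- function(transitions, path) {
  utils::write.csv(transitions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_transitions
#' @param x Data frame to write as TSV.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A single structured YAML file holds tolerances, filter parameters,
#' integration settings, QC cutoff and statistics options; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML path.
#' @return Configuration list (defaults filled in).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  bad <- intersect(c("ms1_tol_ppm", "ms2_tol_ppm", "rt_window", "width_ppm"),
                   names(cfg))
  for (k in bad) {
    if (cfg[[k]] <= 0) stop("configuration key ", k, " must be positive")
  }
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @export
default_config <- function() {
  list(ms1_tol_ppm = 5, ms2_tol_ppm = 10, rt_window = 0.2,
       mz_range = c(100, 1600), rt_range = c(0.5, 16),
       min_intensity = 300, min_samples = 3, group_scope = "any",
       require_isotope_partner = TRUE,
       width_ppm = 100, noise_pct = 40, smooth_points = 2,
       cv_max = 25, var_equal = TRUE, seed = 1, output_dir = ".")
}
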