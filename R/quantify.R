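# Fragment-ion chromatogram extraction, peak integration, class-specific
# fragment summation, internal-standard/weight normalization and pooled-QC
# coefficient-of-variation filtering.

#' Extract a fragment-ion chromatogram
#'
#' Sums, per time-ordered MS/MS scan, the intensities of all peaks inside a
#' ppm window around the target m/z (an extracted ion count chromatogram).
#'
#' @param spectra Time-ordered list of spectra (elements `rt` in minutes and
#'   `peaks`, a two-column mz/intensity matrix).
#' @param target_mz Target m/z.
#' @param width_ppm Full window width in ppm (peaks within +/- width/2 count).
#' @return Data frame with columns `time` (minutes) and `intensity`; zero
#'   rows for an empty series.
#' @export
extract_eicc <- function(spectra, target_mz, width_ppm = 100) {
  stopifnot(target_mz > 0, width_ppm > 0)
  if (length(spectra) == 0) {
    return(data.frame(time = numeric(0), intensity = numeric(0)))
  }
  times <- vapply(spectra, function(s) s$rt, 0.0)
  if (is.unsorted(times, strictly = TRUE)) {
    o <- order(times)
    spectra <- spectra[o]
    times <- times[o]
    if (anyDuplicated(times)) stop("spectra must have distinct scan times")
  }
  half <- target_mz * width_ppm / 2 * 1e-6
  intensity <- vapply(spectra, function(s) {
    pk <- s$peaks
    if (is.null(pk) || nrow(pk) == 0) return(0.0)
    sum(pk[abs(pk[, 1] - target_mz) <= half, 2])
  }, 0.0)
  data.frame(time = times, intensity = intensity)
}

.gaussian_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(0, half), y, rep(0, half))
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(ypad[i:(i + 2 * half)] * k)
  }
  out
}

#' Integrate the main chromatographic peak of a trace
#'
#' The trace is smoothed with a Gaussian kernel whose standard deviation is
#' `smooth_points` sample intervals. The baseline threshold is `noise_pct`
#' percent of the trace's robust background level (the median of the smoothed
#' trace, which for a chromatogram dominated by baseline estimates the
#' background); at 0 percent everything above zero integrates, and the
#' retained region shrinks monotonically as the parameter grows. The area is
#' the trapezoidal integral of the raw trace over the contiguous
#' above-threshold region containing the apex.
#'
#' @param trace Chromatogram data frame from [extract_eicc()].
#' @param noise_pct Noise percentage parameter (0-100).
#' @param smooth_points Gaussian smoothing width in sample intervals.
#' @return Peak area (0 for an empty or all-zero trace).
#' @export
integrate_peak <- function(trace, noise_pct = 40, smooth_points = 2) {
  stopifnot(noise_pct >= 0, noise_pct <= 100)
  if (nrow(trace) == 0 || all(trace$intensity == 0)) return(0.0)
  if (nrow(trace) < 2) return(0.0)
  sm <- .gaussian_smooth(trace$intensity, smooth_points)
  background <- stats::median(sm)
  threshold <- noise_pct / 100 * background
  apex <- which.max(sm)
  above <- sm > threshold
  if (!above[apex]) return(0.0)
  lo <- apex
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- apex
  while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  if (hi == lo) return(0.0)
  pracma::trapz(trace$time[lo:hi], trace$intensity[lo:hi])
}

#' Class-specific fragment summation rules
#'
#' Which product ions are integrated and summed per quantified lipid
#' category: all chain carboxylate anions for diacyl glycerophospholipids,
#' glycerolipids and cardiolipins; all fatty-acid neutral-loss products for
#' diacylglycerols; the long-chain base plus its successive dehydration ions
#' (up to three waters) for ceramides and hexosylceramides; and the single
#' dehydrated backbone ion for sterols.
#'
#' @return Data frame of category, polarity and fragment-selection rule.
#' @export
class_quant_rules <- function() {
  data.frame(
    category = c("GP", "GL", "CL", "DAG", "Cer", "HexCer", "ST"),
    polarity = c("negative", "negative", "negative", "positive", "positive",
                 "positive", "positive"),
    fragment_selector = c("all_carboxylates", "all_carboxylates",
                          "all_carboxylates", "all_fa_neutral_losses",
                          "lcb_dehydration_series", "lcb_dehydration_series",
                          "dehydrated_backbone"),
    stringsAsFactors = FALSE)
}

#' Quantify one species from its fragment chromatograms
#'
#' Integrates the extracted ion chromatogram of each fragment selected by the
#' category rule and sums the per-fragment areas (per-fragment integration
#' first, then summation).
#'
#' @param fragment_mz Numeric vector of product-ion m/z values. For
#'   `Cer`/`HexCer`, the single long-chain-base m/z (the three dehydration
#'   ions are derived internally); for `ST`, the single backbone ion.
#' @param spectra Time-ordered list of spectra for this species' transitions.
#' @param category Quantification category (see [class_quant_rules()]).
#' @param width_ppm,noise_pct,smooth_points Integration settings.
#' @param iso Isotope table (used for the water mass in dehydration series).
#' @return Summed raw peak area.
#' @export
class_quantify <- function(fragment_mz, spectra, category,
                           width_ppm = 100, noise_pct = 40, smooth_points = 2,
                           iso = isotope_table()) {
  rules <- class_quant_rules()
  if (!category %in% rules$category) {
    stop("no quantification rule for category: ", category)
  }
  selector <- rules$fragment_selector[rules$category == category]
  targets <- switch(selector,
    all_carboxylates = ,
    all_fa_neutral_losses = fragment_mz,
    lcb_dehydration_series = {
      stopifnot(length(fragment_mz) == 1)
      water <- monoisotopic_mass("H2O", iso)
      fragment_mz - water * 0:3
    },
    dehydrated_backbone = {
      stopifnot(length(fragment_mz) == 1)
      fragment_mz
    })
  sum(vapply(targets, function(mz) {
    integrate_peak(extract_eicc(spectra, mz, width_ppm), noise_pct,
                   smooth_points)
  }, 0.0))
}

#' Normalize raw areas by internal standard and sample weight
#'
#' Scales each sample's raw response to the batch-reference internal-standard
#' intensity and to the equivalent of 250 mg fresh sample weight:
#' `raw * (reference_is / is_intensity) * (250 / weight_mg)`.
#'
#' @param raw Numeric vector (or matrix with samples in columns) of raw areas.
#' @param weight_mg Sample weights in mg, positive.
#' @param is_intensity Observed internal-standard intensities, positive.
#' @param reference_is Batch reference internal-standard intensity; defaults
#'   to the batch median.
#' @param reference_weight_mg Reference fresh weight (mg).
#' @return Normalized values with the shape of `raw`.
#' @export
normalize_abundance <- function(raw, weight_mg, is_intensity,
                                reference_is = stats::median(is_intensity),
                                reference_weight_mg = 250) {
  if (any(weight_mg <= 0)) stop("sample weight must be positive")
  if (any(is_intensity <= 0)) stop("internal-standard intensity must be positive")
  scale <- (reference_is / is_intensity) * (reference_weight_mg / weight_mg)
  if (is.matrix(raw)) {
    sweep(raw, 2, scale, `*`)
  } else {
    raw * scale
  }
}

.quant_sample_cols <- function(quant) {
  setdiff(names(quant), c("lipid", "class"))
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Computes, per lipid, the percent coefficient of variation over repeated
#' pooled-QC injections and removes lipids at or above the cutoff. Lipids
#' whose pooled-QC mean is not positive have undefined CV and are removed.
#'
#' @param quant Quantification table: columns `lipid`, optionally `class`,
#'   then one column per sample.
#' @param meta Sample metadata with columns `sample` and logical `is_pbqc`.
#' @param cv_max CV cutoff in percent; lipids with CV below this are retained.
#' @return List with `quant` (filtered table), `report` (per-lipid CV and
#'   retention flag) and `median_cv` (median CV of retained lipids).
#' @export
pbqc_filter <- function(quant, meta, cv_max = 25) {
  qc <- meta$sample[as.logical(meta$is_pbqc)]
  if (length(qc) < 2) stop("at least two pooled-QC injections are required")
  missing <- setdiff(qc, names(quant))
  if (length(missing)) {
    stop("pooled-QC samples absent from the table: ",
         paste(missing, collapse = ", "))
  }
  vals <- as.matrix(quant[qc])
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  cv <- ifelse(m > 0, 100 * s / m, NA_real_)
  retained <- !is.na(cv) & cv < cv_max
  report <- data.frame(lipid = quant$lipid, cv = cv, retained = retained,
                       stringsAsFactors = FALSE)
  out <- quant[retained, , drop = FALSE]
  rownames(out) <- NULL
  list(quant = out, report = report,
       median_cv = stats::median(cv[retained]))
}
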