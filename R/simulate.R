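# Synthetic-data generation with known ground truth: MS1 feature tables with
# planted candidates, isotope partners and mass decoys; MS/MS spectra with
# predicted fragments plus contaminants; and full multi-group quantitative
# experiments with planted fold changes and per-lipid variability.
#
# Mass error is Normal in ppm (truncated so planted features stay inside the
# matching tolerance by construction), abundance noise is multiplicative
# lognormal, and the retention-time model is linear in chain descriptors with
# signs consistent with reversed-phase elution patterns (more carbons later;
# more double bonds or oxygens earlier). The model is qualitative only.

#' Simulation design
#'
#' Bundles every knob of the synthetic-data generator; a fixed seed makes all
#' outputs reproducible.
#'
#' @param candidates Candidate library to plant (default: the full default
#'   enumeration from [ox_candidates()]).
#' @param ppm_sd,ppm_max MS1 mass error: Normal(0, `ppm_sd`) truncated at
#'   `ppm_max` (ppm).
#' @param ms2_ppm_sd,ms2_ppm_max Fragment mass error in MS/MS spectra (ppm).
#' @param n_decoys Number of decoy features, each at least `decoy_min_ppm`
#'   from every candidate precursor.
#' @param decoy_min_ppm Minimum decoy mass offset (ppm).
#' @param rt_coef Linear RT model coefficients (minutes): intercept,
#'   per_carbon, per_double_bond, per_extra_oxygen; RT = intercept +
#'   per_carbon * C - per_double_bond * D - per_extra_oxygen * X.
#' @param varieties,treatments,replicates Group design; the second treatment
#'   level is the "treated" one.
#' @param n_pbqc Number of pooled-QC injections in the experiment.
#' @param lipids Lipid species for the quantitative experiment (default: the
#'   38 curated reference species).
#' @param log2_fc Planted log2 fold change (scalar, or named per lipid).
#' @param cv Per-lipid biological/technical coefficient of variation
#'   (fraction, e.g. 0.10).
#' @param n_contaminants Contaminant peaks per simulated MS/MS spectrum.
#' @param seed Integer seed.
#' @return A list of class `sim_design`.
#' @export
simulation_design <- function(candidates = NULL,
                              ppm_sd = 1.5, ppm_max = 4.5,
                              ms2_ppm_sd = 2, ms2_ppm_max = 8,
                              n_decoys = 60, decoy_min_ppm = 20,
                              rt_coef = c(intercept = 0, per_carbon = 0.25,
                                          per_double_bond = 0.55,
                                          per_extra_oxygen = 0.9),
                              varieties = paste0("variety", 1:4),
                              treatments = c("control", "salt"),
                              replicates = 5, n_pbqc = 5,
                              lipids = NULL, log2_fc = 1, cv = 0.10,
                              n_contaminants = 5, seed = 1) {
  stopifnot(rt_coef[["per_double_bond"]] > 0, rt_coef[["per_extra_oxygen"]] > 0)
  if (is.null(candidates)) candidates <- ox_candidates()
  if (is.null(lipids)) lipids <- unique(ox_reference()$species)
  structure(list(candidates = candidates, ppm_sd = ppm_sd, ppm_max = ppm_max,
                 ms2_ppm_sd = ms2_ppm_sd, ms2_ppm_max = ms2_ppm_max,
                 n_decoys = n_decoys, decoy_min_ppm = decoy_min_ppm,
                 rt_coef = rt_coef, varieties = varieties,
                 treatments = treatments, replicates = replicates,
                 n_pbqc = n_pbqc, lipids = lipids, log2_fc = log2_fc,
                 cv = cv, n_contaminants = n_contaminants,
                 seed = as.integer(seed)),
            class = "sim_design")
}

.rt_model <- function(carbons, double_bonds, extra_oxygens, rt_coef) {
  rt_coef[["intercept"]] + rt_coef[["per_carbon"]] * carbons -
    rt_coef[["per_double_bond"]] * double_bonds -
    rt_coef[["per_extra_oxygen"]] * extra_oxygens
}

.rtruncnorm <- function(n, sd, bound) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  x
}

#' Simulate an MS1 feature table with ground truth
#'
#' Plants one feature per unique candidate species at its theoretical
#' precursor m/z perturbed by the design's ppm error, with a co-eluting
#' isotopic partner one 13C spacing up, plus decoy features at least
#' `decoy_min_ppm` from every candidate. Intensities clear the default noise
#' and replicate filters in every sample.
#'
#' @param design A [simulation_design()].
#' @return List with `features` (feature table), `groups` (named vector
#'   mapping the intensity columns to two groups) and `manifest` (ground
#'   truth: feature id, role, species, true and observed m/z, planted ppm
#'   error, RT).
#' @export
simulate_features <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  cand <- design$candidates
  sp <- !duplicated(cand$species)
  species <- cand$species[sp]
  true_mz <- cand$precursor_mz[sp]
  rt <- .rt_model(cand$carbons[sp], cand$double_bonds[sp],
                  cand$extra_oxygens[sp], design$rt_coef)
  eps <- .rtruncnorm(length(species), design$ppm_sd, design$ppm_max)
  obs_mz <- true_mz * (1 + eps * 1e-6)
  spacing <- isotope_table()$isotope_spacing
  n_samples <- 2L * max(3L, design$replicates)
  samples <- sprintf("s%02d", seq_len(n_samples))
  groups <- stats::setNames(rep(c("g1", "g2"), each = n_samples / 2), samples)
  base_int <- function(n) {
    matrix(stats::rlnorm(n * n_samples, log(1e5), 0.3), nrow = n)
  }
  planted_int <- base_int(length(species))
  partner_int <- planted_int * 0.35
  decoy_mz <- numeric(design$n_decoys)
  i <- 0L
  while (i < design$n_decoys) {
    mz <- stats::runif(1, 150, 1100)
    if (all(abs(ppm_error(mz, true_mz)) > design$decoy_min_ppm)) {
      i <- i + 1L
      decoy_mz[i] <- mz
    }
  }
  decoy_rt <- stats::runif(design$n_decoys, 1, 10)
  decoy_int <- base_int(design$n_decoys)
  ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  features <- rbind(
    data.frame(feature_id = ids("P", length(species)), mz = obs_mz,
               rt_min = rt, stringsAsFactors = FALSE),
    data.frame(feature_id = ids("I", length(species)), mz = obs_mz + spacing,
               rt_min = rt, stringsAsFactors = FALSE),
    data.frame(feature_id = ids("D", design$n_decoys), mz = decoy_mz,
               rt_min = decoy_rt, stringsAsFactors = FALSE))
  ints <- rbind(planted_int, partner_int, decoy_int)
  colnames(ints) <- samples
  features <- cbind(features, as.data.frame(ints))
  manifest <- data.frame(
    feature_id = features$feature_id,
    role = rep(c("planted", "isotope_partner", "decoy"),
               c(length(species), length(species), design$n_decoys)),
    species = c(species, species, rep(NA_character_, design$n_decoys)),
    true_mz = c(true_mz, true_mz + spacing, rep(NA_real_, design$n_decoys)),
    observed_mz = features$mz,
    ppm_planted = c(eps, eps, rep(NA_real_, design$n_decoys)),
    rt_min = features$rt_min,
    stringsAsFactors = FALSE)
  rownames(features) <- rownames(manifest) <- NULL
  list(features = features, groups = groups, manifest = manifest)
}

#' Simulate one MS/MS spectrum for a candidate
#'
#' Peaks at each predicted product ion (perturbed by the MS/MS ppm error)
#' plus uniformly placed contaminant peaks.
#'
#' @param candidate One-row candidate data frame.
#' @param rt Spectrum retention time (minutes).
#' @param design A [simulation_design()] (error model and contaminant count).
#' @param precursor_mz Recorded precursor m/z (default: theoretical).
#' @param extra_products Additional product m/z values to include (e.g. the
#'   fragments of a co-isolated composition sharing the species label).
#' @param seed Optional seed for standalone reproducibility.
#' @return A spectrum: list with `precursor_mz`, `rt`, `peaks`.
#' @export
simulate_msms <- function(candidate, rt, design,
                          precursor_mz = candidate$precursor_mz,
                          extra_products = numeric(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prod_mz <- unique(c(candidate$frag1_mz, candidate$frag2_mz, extra_products))
  eps <- .rtruncnorm(length(prod_mz), design$ms2_ppm_sd, design$ms2_ppm_max)
  obs <- prod_mz * (1 + eps * 1e-6)
  int <- seq(100, 60, length.out = length(prod_mz))
  if (design$n_contaminants > 0) {
    cmz <- stats::runif(design$n_contaminants, 100,
                        max(precursor_mz - 10, 120))
    obs <- c(obs, cmz)
    int <- c(int, stats::runif(design$n_contaminants, 1, 40))
  }
  o <- order(obs)
  list(precursor_mz = precursor_mz, rt = rt,
       peaks = cbind(mz = obs[o], intensity = int[o]))
}

#' Simulate MS/MS spectra for all planted features
#'
#' One spectrum per planted feature, containing the predicted fragments of
#' every chain composition sharing the feature's species label (compositions
#' co-isolated under one precursor appear as a fragment mixture).
#'
#' @param design A [simulation_design()].
#' @param sim Output of [simulate_features()] (regenerated if omitted).
#' @return List of spectra.
#' @export
simulate_spectra <- function(design, sim = simulate_features(design)) {
  set.seed(design$seed + 1L)
  planted <- sim$manifest[sim$manifest$role == "planted", ]
  lapply(seq_len(nrow(planted)), function(i) {
    sp <- planted$species[i]
    comps <- design$candidates[design$candidates$species == sp, ]
    simulate_msms(comps[1, ], rt = planted$rt_min[i], design = design,
                  precursor_mz = planted$observed_mz[i],
                  extra_products = unique(c(comps$frag1_mz, comps$frag2_mz)))
  })
}

#' Simulate a multi-group quantitative experiment
#'
#' Lognormal abundances around planted group means implementing the designed
#' log2 fold changes (treated mean = control mean times 2^fc) at the designed
#' coefficient of variation, for every variety. Pooled-QC injections are
#' drawn around the all-sample pool mean at the same CV. Sample weights and
#' internal-standard intensities are jittered and the returned areas are
#' raw, i.e. divided by the normalization factor, so that
#' [normalize_quant()] recovers the planted design.
#'
#' @param design A [simulation_design()].
#' @return List with `raw` (raw-area quantification table), `meta` (sample
#'   metadata: sample, variety, treatment, weight_mg, is_intensity, is_pbqc)
#'   and `manifest` (per-lipid planted log2 fold change, CV and control
#'   mean).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed + 2L)
  lipids <- design$lipids
  fc <- design$log2_fc
  if (length(fc) == 1 && is.null(names(fc))) {
    fc <- stats::setNames(rep(fc, length(lipids)), lipids)
  }
  stopifnot(all(lipids %in% names(fc)))
  sdlog <- sqrt(log(1 + design$cv^2))
  base <- stats::setNames(stats::rlnorm(length(lipids), log(1e5), 0.5), lipids)
  meta <- expand.grid(rep = seq_len(design$replicates),
                      treatment = design$treatments,
                      variety = design$varieties,
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_r%d", meta$variety, meta$treatment, meta$rep)
  meta$is_pbqc <- FALSE
  qc <- data.frame(rep = seq_len(design$n_pbqc), treatment = NA,
                   variety = NA,
                   sample = sprintf("pbqc_%d", seq_len(design$n_pbqc)),
                   is_pbqc = TRUE, stringsAsFactors = FALSE)
  meta <- rbind(meta, qc)
  meta$weight_mg <- stats::runif(nrow(meta), 230, 290)
  meta$is_intensity <- stats::rlnorm(nrow(meta), log(1e4), 0.15)
  treated_level <- design$treatments[length(design$treatments)]
  expected <- sapply(seq_len(nrow(meta)), function(j) {
    if (meta$is_pbqc[j]) return(rep(NA_real_, length(lipids)))
    mu <- base
    if (identical(meta$treatment[j], treated_level)) mu <- mu * 2^fc[lipids]
    mu
  })
  pool_mean <- rowMeans(expected, na.rm = TRUE)
  values <- matrix(NA_real_, length(lipids), nrow(meta))
  for (j in seq_len(nrow(meta))) {
    mu <- if (meta$is_pbqc[j]) pool_mean else expected[, j]
    noise <- exp(stats::rnorm(length(lipids), 0, sdlog) - sdlog^2 / 2)
    values[, j] <- mu * noise
  }
  ref_is <- stats::median(meta$is_intensity)
  scale <- (ref_is / meta$is_intensity) * (250 / meta$weight_mg)
  raw <- sweep(values, 2, scale, `/`)
  colnames(raw) <- meta$sample
  ref <- ox_reference()
  cls <- ref$class[match(lipids, ref$species)]
  raw_tab <- data.frame(lipid = lipids,
                        class = ifelse(is.na(cls), "unknown", cls),
                        stringsAsFactors = FALSE)
  raw_tab <- cbind(raw_tab, as.data.frame(raw))
  manifest <- data.frame(lipid = lipids, log2_fc = unname(fc[lipids]),
                         cv = design$cv, control_mean = unname(base),
                         stringsAsFactors = FALSE)
  rownames(raw_tab) <- rownames(manifest) <- NULL
  list(raw = raw_tab, meta = meta[c("sample", "variety", "treatment",
                                    "weight_mg", "is_intensity", "is_pbqc")],
       manifest = manifest)
}

#' Normalize a raw quantification table
#'
#' Applies [normalize_abundance()] column-wise using the metadata's weights
#' and internal-standard intensities (batch median as reference).
#'
#' @param quant Raw quantification table (`lipid`, optional `class`, sample
#'   columns).
#' @param meta Sample metadata with `sample`, `weight_mg`, `is_intensity`.
#' @return The table with normalized sample columns.
#' @export
normalize_quant <- function(quant, meta) {
  samples <- intersect(.quant_sample_cols(quant), meta$sample)
  i <- match(samples, meta$sample)
  vals <- normalize_abundance(as.matrix(quant[samples]),
                              weight_mg = meta$weight_mg[i],
                              is_intensity = meta$is_intensity[i])
  quant[samples] <- as.data.frame(vals)
  quant
}
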