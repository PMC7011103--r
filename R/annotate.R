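# MS1 feature filtering, alignment, accurate-mass matching against the
# candidate library, MS/MS verification and retention-time plausibility rules.
#
# A feature table is a data frame with columns feature_id, mz, rt_min,
# optionally has_isotope_partner, followed by one intensity column per sample.
# MS/MS spectra are lists with elements precursor_mz, rt (minutes) and peaks
# (two-column matrix: mz, intensity; sorted by mz).

.intensity_cols <- function(features, groups = NULL) {
  fixed <- c("feature_id", "mz", "rt_min", "has_isotope_partner")
  cols <- setdiff(names(features), fixed)
  if (!is.null(groups)) {
    missing <- setdiff(names(groups), cols)
    if (length(missing)) {
      stop("group metadata names samples absent from the feature table: ",
           paste(missing, collapse = ", "))
    }
    cols <- names(groups)
  }
  cols
}

#' Flag features with an isotopic partner
#'
#' A feature has an isotopic partner when another co-eluting feature lies one
#' 13C-12C spacing away in m/z (either direction), the signature of a genuine
#' singly charged analyte rather than noise.
#'
#' @param features Feature table.
#' @param mz_tol Absolute m/z tolerance on the spacing (Da).
#' @param rt_tol Co-elution tolerance (minutes).
#' @param spacing 13C-12C mass difference (Da).
#' @return The feature table with a logical `has_isotope_partner` column.
#' @export
detect_isotope_partner <- function(features, mz_tol = 0.01, rt_tol = 0.2,
                                   spacing = isotope_table()$isotope_spacing) {
  n <- nrow(features)
  flag <- logical(n)
  if (n > 1) {
    for (i in seq_len(n)) {
      dmz <- abs(abs(features$mz - features$mz[i]) - spacing)
      drt <- abs(features$rt_min - features$rt_min[i])
      hit <- dmz <= mz_tol & drt <= rt_tol
      hit[i] <- FALSE
      flag[i] <- any(hit)
    }
  }
  features$has_isotope_partner <- flag
  features
}

#' Filter an MS1 feature table
#'
#' Applies the standard extraction filters: m/z and RT windows, a noise
#' threshold that must be met in a minimum number of samples of a group, and
#' the isotopic-partner requirement. Row order is preserved.
#'
#' @param features Feature table.
#' @param groups Named character vector mapping sample (intensity column)
#'   names to group labels.
#' @param mz_range,rt_range Inclusive windows for m/z and RT (minutes).
#' @param min_intensity Noise threshold; a sample counts as detecting a
#'   feature when its intensity is at least this value.
#' @param min_samples Minimum number of detecting samples required per group.
#' @param group_scope `"any"`: at least one group must reach `min_samples`
#'   detections (default); `"all"`: every group must.
#' @param require_isotope_partner Drop features without an isotopic partner
#'   (computed with [detect_isotope_partner()] if the column is absent).
#' @return The filtered feature table.
#' @export
filter_features <- function(features, groups,
                            mz_range = c(100, 1600), rt_range = c(0.5, 16),
                            min_intensity = 300, min_samples = 3,
                            group_scope = c("any", "all"),
                            require_isotope_partner = TRUE) {
  group_scope <- match.arg(group_scope)
  if (nrow(features) == 0) return(features)
  if (is.null(groups) || is.null(names(groups)) || !all(nzchar(names(groups)))) {
    stop("groups must be a named vector mapping sample columns to group labels")
  }
  cols <- .intensity_cols(features, groups)
  if (require_isotope_partner && is.null(features$has_isotope_partner)) {
    features <- detect_isotope_partner(features)
  }
  keep <- features$mz >= mz_range[1] & features$mz <= mz_range[2] &
    features$rt_min >= rt_range[1] & features$rt_min <= rt_range[2]
  detected <- as.matrix(features[cols]) >= min_intensity
  per_group <- vapply(split(cols, unname(groups[cols])), function(cc) {
    rowSums(detected[, cc, drop = FALSE]) >= min_samples
  }, logical(nrow(features)))
  if (nrow(features) == 1) per_group <- matrix(per_group, nrow = 1)
  keep <- keep & (if (group_scope == "any") apply(per_group, 1, any)
                  else apply(per_group, 1, all))
  if (require_isotope_partner) keep <- keep & features$has_isotope_partner
  out <- features[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align feature tables across batches
#'
#' Optionally applies a single-point RT shift per table so a shared anchor
#' (internal standard) lands at its reference RT, then groups features across
#' tables when their m/z values agree within an absolute tolerance and their
#' RTs within a relative tolerance. Ambiguities are resolved by nearest m/z,
#' then nearest RT. Each group becomes one consensus feature with median m/z
#' and RT and the union of per-sample intensities.
#'
#' @param tables List of feature tables (samples must not overlap).
#' @param mz_tol Absolute m/z tolerance (Da).
#' @param rt_rel_tol Relative RT tolerance (fraction; 0.05 = 5 percent).
#' @param anchor_mz,anchor_rt Optional anchor m/z and its reference RT; each
#'   table is shifted so its feature nearest `anchor_mz` (within `mz_tol`)
#'   elutes at `anchor_rt`.
#' @return Consensus feature table.
#' @export
align_features <- function(tables, mz_tol = 0.01, rt_rel_tol = 0.05,
                           anchor_mz = NULL, anchor_rt = NULL) {
  stopifnot(length(tables) >= 1)
  if (!is.null(anchor_mz)) {
    stopifnot(!is.null(anchor_rt))
    tables <- lapply(tables, function(tb) {
      d <- abs(tb$mz - anchor_mz)
      i <- which.min(d)
      if (length(i) && d[i] <= mz_tol) {
        tb$rt_min <- tb$rt_min + (anchor_rt - tb$rt_min[i])
      }
      tb
    })
  }
  pooled <- do.call(rbind, lapply(seq_along(tables), function(k) {
    tb <- tables[[k]]
    data.frame(table = k, row = seq_len(nrow(tb)), mz = tb$mz,
               rt_min = tb$rt_min)
  }))
  pooled <- pooled[order(pooled$mz, pooled$rt_min), ]
  group <- integer(nrow(pooled))
  g_mz <- numeric(0)  # running group centroids
  g_rt <- numeric(0)
  for (i in seq_len(nrow(pooled))) {
    dmz <- abs(g_mz - pooled$mz[i])
    drt <- abs(g_rt - pooled$rt_min[i])
    rel <- drt / pmax(pmin(g_rt, pooled$rt_min[i]), .Machine$double.eps)
    ok <- which(dmz <= mz_tol & rel <= rt_rel_tol)
    if (length(ok) == 0) {
      g_mz <- c(g_mz, pooled$mz[i]); g_rt <- c(g_rt, pooled$rt_min[i])
      group[i] <- length(g_mz)
    } else {
      best <- ok[order(dmz[ok], drt[ok])][1]
      group[i] <- best
      members <- which(group == best)
      g_mz[best] <- stats::median(pooled$mz[members])
      g_rt[best] <- stats::median(pooled$rt_min[members])
    }
  }
  pooled$group <- group
  all_samples <- unique(unlist(lapply(tables, .intensity_cols)))
  rows <- lapply(sort(unique(group)), function(g) {
    sub <- pooled[pooled$group == g, ]
    out <- data.frame(feature_id = sprintf("F%04d", g),
                      mz = stats::median(sub$mz),
                      rt_min = stats::median(sub$rt_min))
    ints <- stats::setNames(rep(NA_real_, length(all_samples)), all_samples)
    for (j in seq_len(nrow(sub))) {
      tb <- tables[[sub$table[j]]]
      cc <- .intensity_cols(tb)
      ints[cc] <- as.numeric(tb[sub$row[j], cc])
    }
    cbind(out, as.data.frame(as.list(ints), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mz, out$rt_min), ]
  rownames(out) <- NULL
  out
}

.spectrum_ok <- function(s) {
  is.list(s) && !is.null(s$precursor_mz) && !is.null(s$rt) &&
    !is.null(s$peaks)
}

#' Match MS1 features to library candidates and verify by MS/MS
#'
#' A feature within the MS1 ppm tolerance of a candidate precursor becomes an
#' `MS1_ONLY` match. MS/MS spectra whose precursor matches the feature (same
#' tolerance) and whose RT lies within the association window are then
#' searched for each predicted carboxylate fragment at the MS/MS tolerance; a
#' match is upgraded to `MS1_MS2` when at least one oxidized-chain fragment is
#' found. All candidate matches per feature are reported, ranked by absolute
#' ppm error, then by fragments found (more first), with ties broken by lower
#' precursor m/z then species label.
#'
#' @param features Feature table.
#' @param spectra List of MS/MS spectra (may be empty).
#' @param candidates Candidate data frame from [ox_candidates()].
#' @param ms1_tol_ppm,ms2_tol_ppm Mass tolerances in ppm.
#' @param rt_window Precursor-to-spectrum RT association window (minutes).
#' @return Match table: feature id, m/z and RT, candidate identity (species,
#'   class, chains, totals), theoretical m/z, signed ppm error, fragment
#'   bookkeeping, tier, and per-feature rank.
#' @export
match_and_verify <- function(features, spectra = list(), candidates,
                             ms1_tol_ppm = 5, ms2_tol_ppm = 10,
                             rt_window = 0.2) {
  stopifnot(ms1_tol_ppm > 0, ms2_tol_ppm > 0)
  if (length(spectra) && !all(vapply(spectra, .spectrum_ok, TRUE))) {
    stop("spectra must each have precursor_mz, rt and peaks")
  }
  rows <- list()
  for (i in seq_len(nrow(features))) {
    fmz <- features$mz[i]
    frt <- features$rt_min[i]
    ppm <- ppm_error(fmz, candidates$precursor_mz)
    hits <- which(abs(ppm) <= ms1_tol_ppm)
    if (length(hits) == 0) next
    # spectra associated with this feature
    assoc <- if (length(spectra) == 0) integer(0) else which(vapply(
      spectra, function(s) {
        abs(ppm_error(fmz, s$precursor_mz)) <= ms1_tol_ppm ||
          abs(ppm_error(s$precursor_mz, fmz)) <= ms1_tol_ppm
      }, TRUE) & vapply(spectra, function(s) abs(s$rt - frt) <= rt_window, TRUE))
    for (h in hits) {
      cand <- candidates[h, ]
      found1 <- found2 <- FALSE
      for (a in assoc) {
        pk <- spectra[[a]]$peaks
        if (nrow(pk) == 0) next
        found1 <- found1 ||
          any(abs(ppm_error(pk[, 1], cand$frag1_mz)) <= ms2_tol_ppm)
        found2 <- found2 ||
          any(abs(ppm_error(pk[, 1], cand$frag2_mz)) <= ms2_tol_ppm)
      }
      ox1 <- parse_chain_label(cand$frag1_label)$extra_oxygens > 0
      ox2 <- parse_chain_label(cand$frag2_label)$extra_oxygens > 0
      ox_found <- (ox1 && found1) || (ox2 && found2)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = features$feature_id[i], mz = fmz, rt_min = frt,
        species = cand$species, class = cand$class,
        chain1 = cand$chain1, chain2 = cand$chain2,
        carbons = cand$carbons, double_bonds = cand$double_bonds,
        extra_oxygens = cand$extra_oxygens,
        theoretical_mz = cand$precursor_mz, ppm_error = ppm[h],
        n_fragments_found = found1 + found2,
        ox_fragment_found = ox_found,
        tier = if (ox_found) "MS1_MS2" else "MS1_ONLY",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(feature_id = character(0), mz = numeric(0),
                      rt_min = numeric(0), species = character(0),
                      class = character(0), chain1 = character(0),
                      chain2 = character(0), carbons = integer(0),
                      double_bonds = integer(0), extra_oxygens = integer(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      n_fragments_found = integer(0),
                      ox_fragment_found = logical(0), tier = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  ord <- order(out$feature_id, abs(out$ppm_error), -out$n_fragments_found,
               out$theoretical_mz, out$species)
  out <- out[ord, ]
  out$rank <- stats::ave(seq_len(nrow(out)), out$feature_id,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Elution-order violations within a lipid class
#'
#' On reversed-phase columns, shorter acyl chains and higher unsaturation both
#' shift elution earlier. Taken jointly over species of the same class and
#' extra-oxygen count, this yields a partial order: species `a` must elute no
#' later than `b` whenever `a` has no more carbons and no fewer double bonds
#' (at least one strictly). The two statements are not totalized into a single
#' carbon ordering because species differing in both directions (e.g. 34:3 vs
#' 36:5) are chromatographically incomparable.
#'
#' @param df Data frame with columns species, class, extra_oxygens, carbons,
#'   double_bonds, rt_min (one row per species).
#' @return Data frame of violating ordered pairs (earlier-required species
#'   first) with their RTs; zero rows when the order is respected.
#' @export
elution_order_violations <- function(df) {
  df <- unique(df[c("species", "class", "extra_oxygens", "carbons",
                    "double_bonds", "rt_min")])
  out <- list()
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      a <- df[i, ]; b <- df[j, ]
      if (a$class != b$class || a$extra_oxygens != b$extra_oxygens) next
      comparable <- a$carbons <= b$carbons && a$double_bonds >= b$double_bonds &&
        (a$carbons < b$carbons || a$double_bonds > b$double_bonds)
      if (comparable && a$rt_min > b$rt_min) {
        out[[length(out) + 1L]] <- data.frame(
          earlier_species = a$species, later_species = b$species,
          earlier_rt = a$rt_min, later_rt = b$rt_min,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(earlier_species = character(0),
                      later_species = character(0),
                      earlier_rt = numeric(0), later_rt = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Apply retention-time plausibility rules to matches
#'
#' Rule A: an oxidized lipid must elute earlier than its non-oxidized parent
#' (checked when a parent RT is supplied; parent label is the species without
#' its oxygen suffix). Rule B: the within-class elution partial order of
#' [elution_order_violations()] must hold over the accepted set. Violations
#' are flagged, never silently dropped; matches already verified by MS/MS and
#' free of violations are upgraded to tier `MS1_MS2_RT`.
#'
#' @param matches Match table from [match_and_verify()].
#' @param parent_rts Optional named numeric vector of parent-lipid RTs
#'   (minutes) keyed by parent label, e.g. `c("PE(36:5)" = 7.9)`.
#' @return The match table with logical columns `rt_rule_a`, `rt_rule_b`
#'   (NA when not applicable) and updated `tier`.
#' @export
apply_rt_rules <- function(matches, parent_rts = NULL) {
  if (nrow(matches) == 0) {
    matches$rt_rule_a <- logical(0)
    matches$rt_rule_b <- logical(0)
    return(matches)
  }
  parent_label <- sub("-[0-9]?O$", "", matches$species)
  matches$rt_rule_a <- NA
  if (!is.null(parent_rts)) {
    known <- parent_label %in% names(parent_rts)
    matches$rt_rule_a[known] <-
      matches$rt_min[known] < unname(parent_rts[parent_label[known]])
  }
  per_species <- unique(data.frame(
    species = matches$species, class = matches$class,
    extra_oxygens = matches$extra_oxygens, carbons = matches$carbons,
    double_bonds = matches$double_bonds, rt_min = matches$rt_min,
    stringsAsFactors = FALSE))
  viol <- elution_order_violations(per_species)
  bad <- unique(c(viol$earlier_species, viol$later_species))
  matches$rt_rule_b <- !(matches$species %in% bad)
  clean <- matches$tier == "MS1_MS2" &
    (is.na(matches$rt_rule_a) | matches$rt_rule_a) & matches$rt_rule_b
  matches$tier[clean] <- "MS1_MS2_RT"
  matches
}
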