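# In-silico candidate library of oxidized diacyl membrane lipids.
#
# Candidates are built constructively: a glycerol backbone, two free fatty
# acids condensed on with loss of two waters, and a class-specific head-group
# increment. Each class carries a fixed negative-mode adduct (acetate adduct
# for PC/MGDG/DGDG, deprotonation for PE/PG/PI, deprotonation plus serine
# head loss for PS); the assignment was derived by reconciling the published
# reference masses and is configuration, not measurement.

GLYCEROL <- c(C = 3, H = 8, O = 3)
WATER <- c(H = 2, O = 1)

#' Lipid class specifications
#'
#' @param config Chemistry configuration (see [read_chem_config()]).
#' @return Data frame with one row per diacyl class: `class`, `head_increment`
#'   (formula string added to the diacylglycerol core, condensation water
#'   already netted out), `adduct` (adduct key), `adduct_label`,
#'   `adduct_delta` (formula string), `adduct_sign` and `charge`.
#' @export
lipid_classes <- function(config = chem_config()) {
  cls <- config$classes
  ad <- config$adducts
  rows <- lapply(names(cls), function(nm) {
    a <- cls[[nm]]$adduct
    if (is.null(ad[[a]])) stop("unknown adduct for class ", nm, ": ", a)
    data.frame(class = nm,
               head_increment = cls[[nm]]$head_increment,
               adduct = a,
               adduct_label = ad[[a]]$label,
               adduct_delta = ad[[a]]$delta,
               adduct_sign = as.integer(ad[[a]]$sign),
               charge = as.integer(ad[[a]]$charge),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.class_row <- function(lipid_class, classes) {
  i <- match(lipid_class, classes$class)
  if (is.na(i)) {
    stop("unknown lipid class: ", lipid_class, " (known: ",
         paste(classes$class, collapse = ", "), ")")
  }
  classes[i, ]
}

#' Neutral molecular formula of a diacyl lipid
#'
#' Glycerol + both free-acid chain formulas - 2 H2O + the class head-group
#' increment. Symmetric under swapping the two chains.
#'
#' @param lipid_class Class name (PC, PE, PG, PI, PS, MGDG, DGDG by default).
#' @param chain1,chain2 [acyl_chain()] objects.
#' @param classes Class table from [lipid_classes()].
#' @return Named numeric count vector.
#' @export
neutral_formula <- function(lipid_class, chain1, chain2,
                            classes = lipid_classes()) {
  spec <- .class_row(lipid_class, classes)
  f <- formula_combine(GLYCEROL, chain_formula(chain1))
  f <- formula_combine(f, chain_formula(chain2))
  f <- formula_combine(f, c(H = 4, O = 2), sign = -1)
  formula_combine(f, formula_parse(spec$head_increment))
}

#' Monitored precursor m/z of a diacyl lipid
#'
#' Applies the class adduct to the neutral monoisotopic mass: acetate addition
#' (+C2H3O2) for PC/MGDG/DGDG, deprotonation (-H) for PE/PG/PI, and combined
#' deprotonation plus serine head loss (-C3H6NO2) for PS. Singly charged
#' negative ions only; no electron-mass correction.
#'
#' @inheritParams neutral_formula
#' @param iso Isotope table.
#' @return Precursor m/z.
#' @examples
#' precursor_mz("PE", acyl_chain(18, 2, 1), acyl_chain(18, 3, 0))  # 752.487
#' @export
precursor_mz <- function(lipid_class, chain1, chain2,
                         classes = lipid_classes(), iso = isotope_table()) {
  spec <- .class_row(lipid_class, classes)
  neutral <- neutral_formula(lipid_class, chain1, chain2, classes)
  ion <- formula_combine(neutral, formula_parse(spec$adduct_delta),
                         sign = spec$adduct_sign)
  monoisotopic_mass(ion, iso)
}

#' Default acyl chain sets
#'
#' The three most abundant normal fatty acids and the five 18-carbon oxylipin
#' chain types considered by the targeted workflow.
#'
#' @return List of [acyl_chain()] objects.
#' @export
default_normal_fas <- function() {
  list(acyl_chain(16, 0, 0), acyl_chain(18, 2, 0), acyl_chain(18, 3, 0))
}

#' @rdname default_normal_fas
#' @export
default_ox_chains <- function() {
  list(acyl_chain(18, 2, 1), acyl_chain(18, 3, 1), acyl_chain(18, 4, 1),
       acyl_chain(18, 2, 2), acyl_chain(18, 3, 2))
}

.species_label <- function(lipid_class, chain1, chain2) {
  x <- chain1$extra_oxygens + chain2$extra_oxygens
  suffix <- if (x == 0) "" else if (x == 1) "-O" else paste0("-", x, "O")
  sprintf("%s(%d:%d)%s", lipid_class,
          chain1$carbons + chain2$carbons,
          chain1$double_bonds + chain2$double_bonds, suffix)
}

.chain_key <- function(chain) {
  sprintf("%03d:%02d:%d", chain$carbons, chain$double_bonds,
          chain$extra_oxygens)
}

.candidate_row <- function(lipid_class, chain1, chain2, classes, iso) {
  # store chains in canonical (carbons, double bonds, extra oxygens) order
  if (.chain_key(chain2) < .chain_key(chain1)) {
    tmp <- chain1; chain1 <- chain2; chain2 <- tmp
  }
  neutral <- neutral_formula(lipid_class, chain1, chain2, classes)
  data.frame(
    class = lipid_class,
    species = .species_label(lipid_class, chain1, chain2),
    chain1 = chain_label(chain1),
    chain2 = chain_label(chain2),
    carbons = chain1$carbons + chain2$carbons,
    double_bonds = chain1$double_bonds + chain2$double_bonds,
    extra_oxygens = chain1$extra_oxygens + chain2$extra_oxygens,
    formula = formula_string(neutral),
    neutral_mass = monoisotopic_mass(neutral, iso),
    adduct = .class_row(lipid_class, classes)$adduct_label,
    precursor_mz = precursor_mz(lipid_class, chain1, chain2, classes, iso),
    frag1_label = chain_label(chain1),
    frag1_mz = carboxylate_fragment_mz(chain1, iso),
    frag2_label = chain_label(chain2),
    frag2_mz = carboxylate_fragment_mz(chain2, iso),
    stringsAsFactors = FALSE)
}

#' Build a single lipid candidate
#'
#' @inheritParams neutral_formula
#' @param iso Isotope table.
#' @return One-row candidate data frame (see [ox_candidates()]).
#' @export
ox_candidate <- function(lipid_class, chain1, chain2,
                         classes = lipid_classes(), iso = isotope_table()) {
  .candidate_row(lipid_class, chain1, chain2, classes, iso)
}

#' Enumerate candidate oxidized diacyl lipids
#'
#' For every class, pairs each normal FA with each oxylipin chain and forms
#' every unordered pair of oxylipin chains (self-pairs included), so the total
#' number of extra oxygens per candidate lies in 1..4. Candidates are keyed by
#' chain composition: two compositions sharing a species label (e.g. the
#' 18:2-O/18:3 and 18:3-O/18:2 forms of PE(36:5)-O) are distinct rows.
#'
#' @param classes Class table from [lipid_classes()] or a character vector of
#'   class names to restrict to.
#' @param normal_fas,ox_chains Lists of [acyl_chain()] objects; defaults are
#'   the workflow's standard sets.
#' @param iso Isotope table.
#' @return Data frame, one row per (class, chain composition), sorted by
#'   class, total carbons, double bonds, extra oxygens, chain labels. Columns
#'   include the species label, neutral formula and mass, adduct, precursor
#'   m/z, and both predicted carboxylate fragment m/z values.
#' @export
ox_candidates <- function(classes = lipid_classes(),
                          normal_fas = default_normal_fas(),
                          ox_chains = default_ox_chains(),
                          iso = isotope_table()) {
  if (is.character(classes)) {
    classes <- lipid_classes()[lipid_classes()$class %in% classes, ]
  }
  if (length(normal_fas) == 0 || length(ox_chains) == 0) {
    stop("normal_fas and ox_chains must be non-empty")
  }
  if (any(vapply(ox_chains, function(ch) ch$extra_oxygens, 0L) == 0)) {
    stop("ox_chains must all carry at least one extra oxygen")
  }
  rows <- list()
  for (cl in classes$class) {
    for (nf in normal_fas) {
      for (ox in ox_chains) {
        rows[[length(rows) + 1L]] <- .candidate_row(cl, nf, ox, classes, iso)
      }
    }
    n_ox <- length(ox_chains)
    for (i in seq_len(n_ox)) {
      for (j in i:n_ox) {
        rows[[length(rows) + 1L]] <-
          .candidate_row(cl, ox_chains[[i]], ox_chains[[j]], classes, iso)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$extra_oxygens >= 1 & out$extra_oxygens <= 4, ]
  key <- paste(out$class, out$chain1, out$chain2)
  out <- out[!duplicated(key), ]
  ord <- order(match(out$class, classes$class), out$carbons,
               out$double_bonds, out$extra_oxygens, out$chain1, out$chain2)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Curated reference list of confirmed oxidized lipids
#'
#' The packaged transcription of the 38 oxidized diacyl glycerophospholipid
#' and galactolipid species confirmed in barley roots by the targeted
#' negative-mode workflow (one row per detected fragment pair, 46 rows in
#' total; species with two resolvable chain compositions appear twice).
#' Printed values are transcribed verbatim, including a handful of internally
#' inconsistent entries flagged in the `note` column; library and matching
#' code always uses computed masses.
#'
#' @return Data frame with row id, class, species label, inferred oxidized and
#'   normal chain compositions, detected and printed-theoretical precursor
#'   m/z, fragment m/z values, retention time (minutes) and printed precursor
#'   mass error (ppm).
#' @export
ox_reference <- function() {
  path <- system.file("extdata", "ox_lipid_reference.csv", package = "oxlipidr")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Candidate set for the curated reference species
#'
#' Rebuilds each reference chain composition with the constructive chemistry,
#' giving computed precursor and fragment m/z values for the confirmed set
#' (the targeted assay list).
#'
#' @param reference Reference table from [ox_reference()].
#' @param classes,iso See [ox_candidates()].
#' @return Candidate data frame as in [ox_candidates()], one row per reference
#'   chain composition, plus the reference `rt_min`.
#' @export
reference_candidates <- function(reference = ox_reference(),
                                 classes = lipid_classes(),
                                 iso = isotope_table()) {
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    cand <- .candidate_row(r$class, parse_chain_label(r$chain_ox),
                           parse_chain_label(r$chain_fa), classes, iso)
    cand$rt_min <- r$rt_min
    cand
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a scheduled-MRM transition list
#'
#' One row per (candidate, product ion). Retention-time windows are attached
#' from a named lookup when available, otherwise left unbounded.
#'
#' @param candidates Candidate data frame from [ox_candidates()].
#' @param rt_windows Optional named numeric vector of expected RTs (minutes)
#'   keyed by species label.
#' @param rt_half_width Half-width of the scheduling window in minutes.
#' @return Data frame with columns species, chain composition, precursor m/z,
#'   product label and m/z, RT window bounds (NA when unknown) and polarity.
#' @export
export_transitions <- function(candidates, rt_windows = NULL,
                               rt_half_width = 0.5) {
  if (nrow(candidates) == 0) stop("candidates must be non-empty")
  long <- rbind(
    data.frame(candidates[c("species", "class", "chain1", "chain2",
                            "precursor_mz")],
               product_label = candidates$frag1_label,
               product_mz = candidates$frag1_mz,
               stringsAsFactors = FALSE),
    data.frame(candidates[c("species", "class", "chain1", "chain2",
                            "precursor_mz")],
               product_label = candidates$frag2_label,
               product_mz = candidates$frag2_mz,
               stringsAsFactors = FALSE))
  ord <- order(match(long$species, candidates$species), long$chain1,
               long$chain2, long$product_mz)
  long <- long[ord, ]
  rt <- if (is.null(rt_windows)) rep(NA_real_, nrow(long)) else
    unname(rt_windows[long$species])
  long$rt_min_low <- rt - rt_half_width
  long$rt_min_high <- rt + rt_half_width
  long$polarity <- "negative"
  rownames(long) <- NULL
  long
}
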