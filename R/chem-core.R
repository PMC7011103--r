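# Elemental-formula arithmetic and monoisotopic mass computation.
#
# Formulas are named numeric vectors of non-negative integer counts keyed by
# element symbol (e.g. c(C = 3, H = 8, O = 3)). Elements with count zero are
# dropped, so equality is plain element-wise identity. All mass arithmetic in
# the package funnels through monoisotopic_mass().

.chem_env <- new.env(parent = emptyenv())

#' Load the chemistry configuration
#'
#' Reads the structured configuration holding monoisotopic atomic masses, the
#' 13C-12C isotope spacing, negative-mode adduct definitions and diacyl lipid
#' class head-group increments. The packaged defaults reproduce the published
#' reference masses of oxidized membrane lipids to 3 decimal places.
#'
#' @param path Path to a YAML configuration; defaults to the packaged file.
#' @return A list with elements `isotopes`, `adducts` and `classes`.
#' @export
read_chem_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chem_defaults.yml", package = "oxlipidr")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("chemistry configuration file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  need <- c("isotopes", "adducts", "classes")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("chemistry configuration lacks section(s): ",
         paste(missing, collapse = ", "))
  }
  cfg
}

chem_config <- function() {
  cfg <- getOption("oxlipidr.chem")
  if (!is.null(cfg)) return(cfg)
  if (is.null(.chem_env$cfg)) .chem_env$cfg <- read_chem_config()
  .chem_env$cfg
}

#' Monoisotopic isotope table
#'
#' @param config Chemistry configuration (see [read_chem_config()]).
#' @return A list with `masses`, a named vector of monoisotopic masses in Da
#'   (at least C, H, N, O, P), and `isotope_spacing`, the 13C-12C mass
#'   difference in Da.
#' @export
isotope_table <- function(config = chem_config()) {
  masses <- unlist(config$isotopes$masses)
  if (any(masses <= 0)) stop("isotope masses must be positive")
  need <- c("C", "H", "N", "O", "P")
  if (!all(need %in% names(masses))) {
    stop("isotope table must contain at least C, H, N, O, P")
  }
  list(masses = masses,
       isotope_spacing = as.numeric(config$isotopes$isotope_spacing))
}

.element_order <- function(els) {
  # Hill-like ordering: C, H first, then the rest alphabetically
  lead <- c("C", "H")
  c(intersect(lead, els), sort(setdiff(els, lead)))
}

normalize_formula <- function(f) {
  if (length(f) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop("formula counts must be named by element symbol")
  }
  f <- tapply(unname(f), names(f), sum)
  f <- f[f != 0]
  if (any(f < 0)) {
    stop("negative element count for: ",
         paste(names(f)[f < 0], collapse = ", "))
  }
  if (any(f != round(f))) stop("element counts must be integers")
  out <- as.numeric(f)
  names(out) <- names(f)
  out[.element_order(names(out))]
}

#' Parse a molecular formula string
#'
#' @param x Formula string such as `"C18H30O2"`. An empty string yields the
#'   empty formula.
#' @return Named numeric vector of element counts.
#' @examples
#' formula_parse("C3H8O3")
#' @export
formula_parse <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  if (!nzchar(x)) return(normalize_formula(numeric(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  els <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  normalize_formula(stats::setNames(cnt, els))
}

#' Format a formula as a string
#'
#' @param f Named numeric vector of element counts.
#' @return Character scalar, elements in C, H, then alphabetical order; counts
#'   of one are left implicit.
#' @export
formula_string <- function(f) {
  f <- normalize_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(f == 1, "", format(f, trim = TRUE, scientific = FALSE)),
         collapse = "")
}

#' Combine two elemental formulas
#'
#' Element-wise sum (`sign = 1`) or difference (`sign = -1`). Subtraction that
#' would drive any element negative is an error naming the element.
#'
#' @param a,b Named numeric count vectors (or formula strings).
#' @param sign `+1` to add, `-1` to subtract `b` from `a`.
#' @return Named numeric count vector with zero counts dropped.
#' @examples
#' formula_combine(formula_parse("C18H30O3"), formula_parse("H2O"), sign = -1)
#' @export
formula_combine <- function(a, b, sign = 1) {
  if (is.character(a)) a <- formula_parse(a)
  if (is.character(b)) b <- formula_parse(b)
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1")
  a <- normalize_formula(a)
  b <- normalize_formula(b)
  els <- union(names(a), names(b))
  av <- ifelse(els %in% names(a), a[els], 0)
  bv <- ifelse(els %in% names(b), b[els], 0)
  out <- av + sign * bv
  names(out) <- els
  if (any(out < 0)) {
    stop("formula arithmetic yields negative count for: ",
         paste(els[out < 0], collapse = ", "))
  }
  normalize_formula(out)
}

#' Monoisotopic mass of a formula
#'
#' Plain sum of count times atomic monoisotopic mass; no electron-mass
#' correction is applied anywhere in the package (anion m/z values are
#' neutral-formula arithmetic minus/plus the adduct delta, matching the
#' reference table conventions).
#'
#' @param f Named numeric count vector or formula string.
#' @param iso Isotope table from [isotope_table()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f, iso = isotope_table()) {
  if (is.character(f)) f <- formula_parse(f)
  f <- normalize_formula(f)
  if (length(f) == 0) return(0.0)
  unknown <- setdiff(names(f), names(iso$masses))
  if (length(unknown)) {
    stop("element(s) absent from isotope table: ",
         paste(unknown, collapse = ", "))
  }
  sum(f * iso$masses[names(f)])
}

#' Acyl chain descriptor
#'
#' Describes a fatty acyl chain by carbon count, double bonds, and extra
#' oxygens beyond the two carboxyl oxygens (0 for normal FAs; 1 or 2 for the
#' oxylipins, printed as the `-O` / `-2O` suffix). The free-acid molecular
#' formula is C(n) H(2n-2d) O(2+x).
#'
#' @param carbons Integer >= 2.
#' @param double_bonds Integer >= 0 with `2 * double_bonds <= carbons`.
#' @param extra_oxygens Integer in 0..2.
#' @return An object of class `acyl_chain`.
#' @examples
#' acyl_chain(18, 3, 1)  # the 18:3-O oxylipin
#' @export
acyl_chain <- function(carbons, double_bonds, extra_oxygens = 0) {
  stopifnot(length(carbons) == 1, length(double_bonds) == 1,
            length(extra_oxygens) == 1)
  if (carbons < 2 || carbons != round(carbons)) {
    stop("carbons must be an integer >= 2")
  }
  if (double_bonds < 0 || double_bonds != round(double_bonds) ||
      2 * double_bonds > carbons) {
    stop("double_bonds must be a non-negative integer with 2*d <= carbons")
  }
  if (!extra_oxygens %in% 0:2) stop("extra_oxygens must be 0, 1 or 2")
  structure(list(carbons = as.integer(carbons),
                 double_bonds = as.integer(double_bonds),
                 extra_oxygens = as.integer(extra_oxygens)),
            class = "acyl_chain")
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl chain ", chain_label(x), ">\n", sep = "")
  invisible(x)
}

#' Shorthand label of an acyl chain
#'
#' @param chain An [acyl_chain()].
#' @return Label such as `"16:0"`, `"18:3-O"` or `"18:2-2O"`.
#' @export
chain_label <- function(chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  suffix <- c("", "-O", "-2O")[chain$extra_oxygens + 1]
  sprintf("%d:%d%s", chain$carbons, chain$double_bonds, suffix)
}

#' Parse an acyl chain label
#'
#' Inverse of [chain_label()]; accepts `"C:D"`, `"C:D-O"`, `"C:D-2O"`.
#'
#' @param x Character scalar.
#' @return An [acyl_chain()].
#' @export
parse_chain_label <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+)(-([0-9]?)O)?$", x))[[1]]
  if (length(m) == 0) stop("cannot parse chain label: ", x)
  nx <- if (!nzchar(m[4])) 0L else if (!nzchar(m[5])) 1L else as.integer(m[5])
  acyl_chain(as.integer(m[2]), as.integer(m[3]), nx)
}

#' Free-acid formula of an acyl chain
#'
#' @param chain An [acyl_chain()].
#' @return Named numeric count vector, C(n) H(2n-2d) O(2+x).
#' @export
chain_formula <- function(chain) {
  stopifnot(inherits(chain, "acyl_chain"))
  normalize_formula(c(C = chain$carbons,
                      H = 2 * chain$carbons - 2 * chain$double_bonds,
                      O = 2 + chain$extra_oxygens))
}

#' Carboxylate-anion fragment of an acyl chain
#'
#' Collision-induced dissociation of negatively charged diacyl lipids releases
#' each chain as its deprotonated free acid. Chains carrying two extra oxygens
#' lose a further water in-source, so their fragment collapses onto the anion
#' one double-bond equivalent up (e.g. 18:3-2O is detected as the 18:4-O
#' anion, 18:2-2O as the 18:3-O anion).
#'
#' @param chain An [acyl_chain()].
#' @return For `carboxylate_fragment_formula`, the anion formula; for
#'   `carboxylate_fragment_mz`, its m/z (no electron-mass correction).
#' @examples
#' carboxylate_fragment_mz(acyl_chain(18, 3, 1))  # 293.2117
#' @export
carboxylate_fragment_formula <- function(chain) {
  f <- formula_combine(chain_formula(chain), c(H = 1), sign = -1)
  if (chain$extra_oxygens == 2) {
    f <- formula_combine(f, formula_parse("H2O"), sign = -1)
  }
  f
}

#' @rdname carboxylate_fragment_formula
#' @param iso Isotope table.
#' @export
carboxylate_fragment_mz <- function(chain, iso = isotope_table()) {
  monoisotopic_mass(carboxylate_fragment_formula(chain), iso)
}

#' Relative mass error in parts per million
#'
#' Signed as (observed - theoretical) / theoretical * 1e6, so a positive value
#' means the observed m/z is high.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return ppm error, vectorized.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Round half away from zero
#'
#' Display rounding used for 3-decimal m/z tables; matching always uses
#' unrounded values, so rounding can never affect identification.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
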