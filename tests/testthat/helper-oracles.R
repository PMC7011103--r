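# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: per-atom mass summation instead of count*mass,
# a definitional step-up FDR instead of stats::p.adjust, and a vectorized
# pairwise elution-order check instead of the annotator's loop.

# brute-force monoisotopic mass: expand the formula to individual atoms
oracle_mass <- function(counts, masses) {
  atoms <- unlist(lapply(names(counts), function(el) {
    rep(masses[[el]], counts[[el]])
  }))
  if (is.null(atoms)) 0.0 else sum(atoms)
}

random_formula <- function() {
  els <- sample(c("C", "H", "N", "O", "P"), sample(1:5, 1))
  stats::setNames(sample(0:40, length(els), replace = TRUE), els)
}

# definitional BH: adjusted p = min over thresholds t >= p_i of m*t/#{p <= t}
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- sort(unique(p[p >= pi]))
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), 0.0)))
  }, 0.0)
}

# all violated comparable pairs under the within-class elution partial order
oracle_rt_violations <- function(df) {
  pairs <- expand.grid(i = seq_len(nrow(df)), j = seq_len(nrow(df)))
  pairs <- pairs[pairs$i != pairs$j, ]
  a <- df[pairs$i, ]
  b <- df[pairs$j, ]
  comparable <- a$class == b$class & a$extra_oxygens == b$extra_oxygens &
    a$carbons <= b$carbons & a$double_bonds >= b$double_bonds &
    (a$carbons < b$carbons | a$double_bonds > b$double_bonds)
  viol <- comparable & a$rt_min > b$rt_min
  unique(sort(paste(a$species[viol], b$species[viol], sep = ">")))
}

# sampled Gaussian elution profile as a spectra series carrying one peak
gaussian_spectra <- function(frag_mz, amplitude, apex_min, sigma_min,
                             from = 0, to = 2, dt = 0.01) {
  times <- seq(from, to, by = dt)
  lapply(seq_along(times), function(i) {
    ints <- amplitude * exp(-(times[i] - apex_min)^2 / (2 * sigma_min^2))
    list(precursor_mz = 750, rt = times[i],
         peaks = cbind(mz = frag_mz, intensity = ints))
  })
}
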