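make_features <- function(mz, rt, intensity = 1e4, samples = paste0("s", 1:6),
                          partner = TRUE) {
  n <- length(mz)
  ints <- matrix(intensity, n, length(samples),
                 dimnames = list(NULL, samples))
  cbind(data.frame(feature_id = sprintf("F%03d", seq_len(n)), mz = mz,
                   rt_min = rt, has_isotope_partner = partner,
                   stringsAsFactors = FALSE),
        as.data.frame(ints))
}

six_groups <- stats::setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))

test_that("isotope partners are detected symmetrically and only at spacing", {
  f <- make_features(c(500, 501.0034), c(5, 5))
  f$has_isotope_partner <- NULL
  out <- detect_isotope_partner(f)
  expect_true(all(out$has_isotope_partner))
  f2 <- make_features(c(500, 500.5), c(5, 5))
  f2$has_isotope_partner <- NULL
  expect_false(any(detect_isotope_partner(f2)$has_isotope_partner))
  # co-elution required
  f3 <- make_features(c(500, 501.0034), c(5, 6))
  f3$has_isotope_partner <- NULL
  expect_false(any(detect_isotope_partner(f3)$has_isotope_partner))
})

test_that("k planted isotope pairs flag exactly 2k members", {
  set.seed(3)
  k <- 5L
  base <- c(200, 310, 420, 530, 640)
  singles <- 700 + 7 * (1:20)
  mz <- c(base, base + 1.0033548, singles)
  rt <- c(rep(5, 2 * k), runif(20, 1, 10))
  f <- make_features(mz, rt)
  f$has_isotope_partner <- NULL
  out <- detect_isotope_partner(f)
  expect_identical(sum(out$has_isotope_partner), 2L * k)
})

test_that("feature filtering applies every rule and preserves order", {
  f <- make_features(500, 5)
  expect_identical(nrow(filter_features(f[0, ], six_groups)), 0L)
  # intensity 300 in exactly 3 samples of one group, partner present: retained
  f1 <- make_features(500, 5, intensity = 0)
  f1[paste0("s", 1:3)] <- 300
  expect_identical(nrow(filter_features(f1, six_groups)), 1L)
  # same but only 2 samples: dropped
  f2 <- make_features(500, 5, intensity = 0)
  f2[paste0("s", 1:2)] <- 300
  expect_identical(nrow(filter_features(f2, six_groups)), 0L)
  # group_scope = "all" requires both groups
  expect_identical(nrow(filter_features(f1, six_groups, group_scope = "all")),
                   0L)
  expect_error(filter_features(f1, NULL), "named")
})

test_that("a planted 100-feature table passes exactly its 40 clean features", {
  set.seed(21)
  good <- make_features(mz = runif(40, 300, 1200), rt = runif(40, 2, 12))
  bad_mz <- make_features(mz = runif(15, 1700, 2000), rt = runif(15, 2, 12))
  bad_rt <- make_features(mz = runif(15, 300, 1200), rt = runif(15, 17, 20))
  bad_int <- make_features(mz = runif(15, 300, 1200), rt = runif(15, 2, 12),
                           intensity = 0)
  bad_int[paste0("s", 1:2)] <- 5000   # detected in only two samples
  bad_partner <- make_features(mz = runif(15, 300, 1200),
                               rt = runif(15, 2, 12), partner = FALSE)
  tab <- rbind(good, bad_mz, bad_rt, bad_int, bad_partner)
  tab$feature_id <- sprintf("F%03d", seq_len(nrow(tab)))
  out <- filter_features(tab, six_groups)
  expect_identical(nrow(out), 40L)
  expect_identical(out$feature_id, tab$feature_id[1:40])
})

test_that("alignment groups shifted tables and respects the m/z tolerance", {
  t1 <- make_features(c(400, 600, 800), c(2, 5, 8))[-4]
  t1 <- t1[c("feature_id", "mz", "rt_min", paste0("s", 1:3))]
  t2 <- t1
  names(t2)[4:6] <- paste0("s", 4:6)
  expect_identical(nrow(align_features(list(t1))), 3L)
  # uniform +2% RT shift with a shared anchor at 600 m/z: fully aligned
  t2$rt_min <- t1$rt_min * 1.02
  out <- align_features(list(t1, t2), anchor_mz = 600, anchor_rt = 5)
  expect_identical(nrow(out), 3L)
  expect_true(all(!is.na(out[paste0("s", 1:6)])))
  # identical tables: consensus equals input coordinates
  out2 <- align_features(list(t1, setNames(t1, c(names(t1)[1:3],
                                                 paste0("s", 4:6)))))
  expect_equal(out2$mz, t1$mz)
  expect_equal(out2$rt_min, t1$rt_min)
  # 0.02 Da apart is never grouped
  t3 <- t1
  names(t3)[4:6] <- paste0("s", 4:6)
  t3$mz <- t1$mz + 0.02
  expect_identical(nrow(align_features(list(t1, t3))), 6L)
})

test_that("a feature at a candidate's exact m/z self-matches at 0 ppm", {
  cand <- ox_candidates()
  i <- which(cand$species == "PE(36:5)-O")[1]
  f <- make_features(cand$precursor_mz[i], 6.6)
  m <- match_and_verify(f, list(), cand)
  expect_true("PE(36:5)-O" %in% m$species)
  expect_equal(min(abs(m$ppm_error)), 0, tolerance = 1e-9)
  expect_true(all(m$tier == "MS1_ONLY"))
  # far-off feature matches nothing
  f2 <- make_features(cand$precursor_mz[i] * (1 + 50e-6), 6.6)
  expect_identical(nrow(match_and_verify(f2, list(), cand)), 0L)
})

test_that("MS/MS fragment presence upgrades the tier", {
  cand <- ox_candidates()
  i <- which(cand$species == "PE(36:5)-O" & cand$chain2 == "18:3-O")
  f <- make_features(cand$precursor_mz[i], 6.6)
  spec <- list(precursor_mz = cand$precursor_mz[i], rt = 6.6,
               peaks = cbind(mz = c(279.2324, 293.2117),
                             intensity = c(80, 100)))
  m <- match_and_verify(f, list(spec), cand)
  hit <- m[m$species == "PE(36:5)-O" & m$chain2 == "18:3-O", ]
  expect_identical(hit$tier, "MS1_MS2")
  expect_identical(hit$n_fragments_found, 2L)
  # spectrum outside the RT window does not verify
  spec_far <- spec
  spec_far$rt <- 7.5
  m2 <- match_and_verify(f, list(spec_far), cand)
  expect_true(all(m2$tier == "MS1_ONLY"))
})

test_that("planted candidates match and mass decoys never do", {
  cand <- ox_candidates()
  planted <- cand[!duplicated(cand$species), ][1:20, ]
  decoy_src <- cand[!duplicated(cand$species), ][21:40, ]
  # decoys built to sit at least 20 ppm from every library precursor
  decoy_mz <- vapply(decoy_src$precursor_mz, function(mz) {
    for (off in c(30, 60, 90, 120) * 1e-6) {
      cand_mz <- mz * (1 + off)
      if (all(abs(ppm_error(cand_mz, cand$precursor_mz)) >= 20)) {
        return(cand_mz)
      }
    }
    stop("could not place decoy")
  }, 0.0)
  f <- make_features(c(planted$precursor_mz * (1 + 3e-6), decoy_mz),
                     rt = rep(5, 40))
  m <- match_and_verify(f, list(), cand)
  matched <- unique(m$feature_id)
  expect_setequal(matched, sprintf("F%03d", 1:20))
  # tolerance monotonicity: shrinking the tolerance never adds matches
  m1 <- match_and_verify(f, list(), cand, ms1_tol_ppm = 2)
  key <- function(x) paste(x$feature_id, x$species, x$chain1, x$chain2)
  expect_true(all(key(m1) %in% key(m)))
  # determinism
  expect_identical(m, match_and_verify(f, list(), cand))
})

test_that("elution rules pass consistent data and flag permuted orders", {
  cand <- ox_candidates()
  rows <- cand[cand$class == "PE" & cand$extra_oxygens == 1 &
                 !duplicated(cand$species), ]
  rt <- 0.25 * rows$carbons - 0.55 * rows$double_bonds - 0.9
  f <- make_features(rows$precursor_mz, rt)
  m <- match_and_verify(f, list(), cand)
  m <- m[m$rank == 1, ]
  out <- apply_rt_rules(m, parent_rts = stats::setNames(
    rep(99, nrow(m)), sub("-[0-9]?O$", "", m$species)))
  expect_true(all(out$rt_rule_a))
  expect_true(all(out$rt_rule_b))
  # rule A violation when the parent elutes earlier
  out2 <- apply_rt_rules(m, parent_rts = stats::setNames(
    rep(0.1, nrow(m)), sub("-[0-9]?O$", "", m$species)))
  expect_false(any(out2$rt_rule_a))
})

test_that("permuted within-class RTs are flagged exactly as the oracle says", {
  ref <- ox_reference()
  rc <- reference_candidates()
  per <- unique(data.frame(species = rc$species, class = rc$class,
                           extra_oxygens = rc$extra_oxygens,
                           carbons = rc$carbons,
                           double_bonds = rc$double_bonds,
                           rt_min = rc$rt_min, stringsAsFactors = FALSE))
  set.seed(14)
  n_detected <- 0
  for (k in 1:20) {
    perm <- per
    perm$rt_min <- sample(per$rt_min)
    got <- elution_order_violations(perm)
    got_keys <- unique(sort(paste(got$earlier_species, got$later_species,
                                  sep = ">")))
    expect_identical(got_keys, oracle_rt_violations(perm))
    if (length(got_keys)) n_detected <- n_detected + 1
  }
  expect_gt(n_detected, 15)  # random permutations almost always violate
})

test_that("replaying the curated reference recovers all 38 species by MS/MS", {
  rc <- reference_candidates()
  sp <- !duplicated(rc$species)
  f <- make_features(rc$precursor_mz[sp], rc$rt_min[sp])
  spectra <- lapply(which(sp), function(i) {
    frags <- unique(c(rc$frag1_mz[rc$species == rc$species[i]],
                      rc$frag2_mz[rc$species == rc$species[i]]))
    list(precursor_mz = rc$precursor_mz[i], rt = rc$rt_min[i],
         peaks = cbind(mz = sort(frags),
                       intensity = rep(100, length(frags))))
  })
  m <- match_and_verify(f, spectra, rc)
  recovered <- unique(m$species[m$tier == "MS1_MS2"])
  expect_setequal(recovered, unique(rc$species))
  # rule A against parents placed later than all their oxidized derivatives
  lab <- sub("-[0-9]?O$", "", rc$species[sp])
  parents <- tapply(rc$rt_min[sp], lab, max) + 1.0
  out <- apply_rt_rules(m, parent_rts = parents)
  expect_true(all(out$rt_rule_a))
})
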