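test_that("extracted ion chromatograms sum peaks inside the ppm window", {
  expect_identical(nrow(extract_eicc(list(), 293.2117)), 0L)
  spec <- function(rt, mz, int) list(precursor_mz = 750, rt = rt,
                                     peaks = cbind(mz = mz, intensity = int))
  series <- list(spec(1, 500, 10), spec(2, 293.2117, 40), spec(3, 400, 5))
  tr <- extract_eicc(series, 293.2117, width_ppm = 100)
  expect_equal(tr$intensity, c(0, 40, 0))
  # two peaks inside the window sum; a peak at 100 ppm away does not
  series2 <- list(spec(1, c(293.2117, 293.2117 * (1 + 20e-6),
                            293.2117 * (1 + 100e-6)), c(10, 20, 99)))
  expect_equal(extract_eicc(series2, 293.2117, width_ppm = 100)$intensity, 30)
})

test_that("peak integration recovers a planted Gaussian area", {
  expect_identical(integrate_peak(data.frame(time = 1:5, intensity = 0)), 0.0)
  amp <- 800
  sigma <- 0.05
  series <- gaussian_spectra(293.2117, amp, apex_min = 1, sigma_min = sigma)
  tr <- extract_eicc(series, 293.2117)
  area <- integrate_peak(tr)
  expect_equal(area, amp * sigma * sqrt(2 * pi), tolerance = 0.02)
  # linearity and time-shift invariance
  tr2 <- tr
  tr2$intensity <- 2 * tr$intensity
  expect_equal(integrate_peak(tr2), 2 * area, tolerance = 1e-9)
  tr3 <- tr
  tr3$time <- tr$time + 3
  expect_equal(integrate_peak(tr3), area, tolerance = 1e-9)
})

test_that("the noise percentage is monotone and bounded as documented", {
  set.seed(5)
  series <- gaussian_spectra(400, 500, apex_min = 1, sigma_min = 0.05)
  tr <- extract_eicc(series, 400)
  tr$intensity <- tr$intensity + runif(nrow(tr), 0, 20)  # noisy baseline
  areas <- vapply(c(0, 20, 40, 80, 100), function(np) {
    integrate_peak(tr, noise_pct = np)
  }, 0.0)
  expect_true(all(diff(areas) <= 1e-9))
  expect_gt(areas[1], 0)
})

test_that("class rules sum the documented fragment sets", {
  amp_for <- function(area, sigma = 0.05) area / (sigma * sqrt(2 * pi))
  series <- gaussian_spectra(c(293.2117, 279.2324),
                             c(amp_for(100), amp_for(50)),
                             apex_min = 1, sigma_min = 0.05)
  got <- class_quantify(c(293.2117, 279.2324), series, "GP")
  expect_equal(got, 150, tolerance = 0.03)
  # permutation invariance in fragment order
  expect_equal(class_quantify(c(279.2324, 293.2117), series, "GP"), got,
               tolerance = 1e-9)
  # sterol rule with no backbone ion present
  expect_identical(class_quantify(400.0, series, "ST"), 0.0)
  expect_error(class_quantify(400.0, series, "XXX"), "rule")
})

test_that("ceramide rule integrates the LCB plus three dehydration ions", {
  water <- monoisotopic_mass("H2O")
  lcb <- 300.2897
  targets <- lcb - water * 0:3
  amp <- 100 / (0.05 * sqrt(2 * pi))
  series <- gaussian_spectra(targets, rep(amp, 4), apex_min = 1,
                             sigma_min = 0.05)
  got <- class_quantify(lcb, series, "Cer")
  expect_equal(got, 400, tolerance = 0.03)
  # only the LCB present: a quarter of the series total
  series1 <- gaussian_spectra(lcb, amp, apex_min = 1, sigma_min = 0.05)
  expect_equal(class_quantify(lcb, series1, "Cer"), 100, tolerance = 0.03)
})

test_that("normalization scales by internal standard and weight", {
  expect_equal(normalize_abundance(100, weight_mg = 250, is_intensity = 1e4,
                                   reference_is = 1e4), 100)
  expect_equal(normalize_abundance(100, weight_mg = 125, is_intensity = 1e4,
                                   reference_is = 1e4), 200)
  # an IS drift of x2 in one sample halves that sample relative to naive
  raw <- matrix(100, 1, 3)
  out <- normalize_abundance(raw, weight_mg = rep(250, 3),
                             is_intensity = c(1e4, 2e4, 1e4),
                             reference_is = 1e4)
  expect_equal(as.numeric(out), c(100, 50, 100))
  expect_error(normalize_abundance(1, 0, 1), "weight")
  expect_error(normalize_abundance(1, 250, 0), "internal-standard")
})

test_that("pooled-QC CV filter removes variable lipids and reports medians", {
  quant <- data.frame(lipid = c("a", "b", "c"), class = "ox-PE",
                      q1 = c(100, 100, 0), q2 = c(100, 150, 0),
                      s1 = c(5, 5, 5), stringsAsFactors = FALSE)
  meta <- data.frame(sample = c("q1", "q2", "s1"),
                     is_pbqc = c(TRUE, TRUE, FALSE))
  out <- pbqc_filter(quant, meta)
  expect_identical(out$quant$lipid, "a")          # CV 0 retained
  expect_equal(out$report$cv[2], 100 * sd(c(100, 150)) / 125,
               tolerance = 1e-9)                  # ~28.3%, removed
  expect_false(out$report$retained[2])
  expect_true(is.na(out$report$cv[3]))            # zero mean: undefined CV
  expect_identical(out$median_cv, 0)
  expect_error(pbqc_filter(quant, meta[3, ]), "two pooled-QC")
})

test_that("CV is invariant under global rescaling of a lipid's QC values", {
  quant <- data.frame(lipid = "a", q1 = 80, q2 = 120, q3 = 100)
  meta <- data.frame(sample = c("q1", "q2", "q3"), is_pbqc = TRUE)
  cv1 <- pbqc_filter(quant, meta)$report$cv
  quant2 <- quant
  quant2[paste0("q", 1:3)] <- quant[paste0("q", 1:3)] * 1000
  expect_equal(pbqc_filter(quant2, meta)$report$cv, cv1, tolerance = 1e-12)
})
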