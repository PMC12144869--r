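test_that("a lone aldehyde Lorentzian is picked and typed", {
  syn <- synth_nmr(data.frame(ppm = 9.95, integral = 1), linewidth_hz = 2,
                   noise_sd = 1e-4, seed = 3)
  pk <- pick_peaks(syn$spectrum, snr_threshold = 10)
  expect_equal(nrow(pk), 1)
  expect_identical(pk$peak_type, "aldehyde")
  expect_lt(abs(pk$shift_ppm - 9.95), 0.005)
})

test_that("a flat noise trace yields no peaks and empty input errors", {
  set.seed(5)
  flat <- data.frame(ppm = seq(0, 12, by = 0.002),
                     amplitude = rnorm(6001, 0, 1))
  expect_equal(nrow(pick_peaks(flat, snr_threshold = 10)), 0)
  expect_error(pick_peaks(data.frame(ppm = numeric(),
                                     amplitude = numeric())), "empty")
})

test_that("planted multi-peak spectra are recovered at the planted shifts", {
  spec <- data.frame(ppm = c(10.0, 8.75, 8.55, 7.4, 7.1),
                     integral = c(0.03, 1, 0.4, 2, 1.5))
  syn <- synth_nmr(spec, linewidth_hz = 2, noise_sd = 2e-4, seed = 17)
  pk <- pick_peaks(syn$spectrum, snr_threshold = 20)
  expect_equal(nrow(pk), 5)
  expect_true(all(abs(sort(pk$shift_ppm) - sort(spec$ppm)) <= 0.005))
  expect_identical(pk$peak_type[1], "aldehyde")
  expect_setequal(pk$peak_type, c("aldehyde", "imine_cage", "aromatic"))
})

test_that("conversion triage reproduces the category rules", {
  mk <- function(ald_amp, ref_amp = 100) {
    data.frame(peak_type = c("aldehyde", "imine_cage"),
               shift_ppm = c(10, 8.6), amplitude = c(ald_amp, ref_amp))
  }
  r <- aldehyde_conversion(mk(0.5))
  expect_equal(r$residual_aldehyde_pct, 0.5)
  expect_identical(r$category, "minor")
  r <- aldehyde_conversion(mk(3))
  expect_equal(r$residual_aldehyde_pct, 3)
  expect_identical(r$category, "still considered for scale-up")
  r <- aldehyde_conversion(mk(8))
  expect_identical(r$category, "conversion not satisfactory")
  # absent aldehyde counts as zero residual
  no_ald <- data.frame(peak_type = "imine_cage", shift_ppm = 8.6,
                       amplitude = 100)
  r <- aldehyde_conversion(no_ald)
  expect_equal(r$residual_aldehyde_pct, 0)
  expect_identical(r$category, "minor")
  only_ald <- data.frame(peak_type = "aldehyde", shift_ppm = 10, amplitude = 1)
  expect_error(aldehyde_conversion(only_ald), "no cage/imine reference")
})

test_that("category boundaries are deterministic with a closed middle bin", {
  mk <- function(pct) data.frame(peak_type = c("aldehyde", "imine_cage"),
                                 shift_ppm = c(10, 8.6),
                                 amplitude = c(pct, 100))
  expect_identical(aldehyde_conversion(mk(0.999))$category, "minor")
  expect_identical(aldehyde_conversion(mk(1))$category,
                   "still considered for scale-up")
  expect_identical(aldehyde_conversion(mk(5))$category,
                   "still considered for scale-up")
  expect_identical(aldehyde_conversion(mk(5.001))$category,
                   "conversion not satisfactory")
  # coarse stoichiometry-screen bins via the same operation
  bins <- conversion_bins("stoichiometry")
  expect_identical(aldehyde_conversion(mk(3), bins)$category, "minimal")
  expect_identical(aldehyde_conversion(mk(12), bins)$category, "residual")
  expect_identical(aldehyde_conversion(mk(35), bins)$category, "significant")
})

test_that("triage is invariant to uniform amplitude scaling", {
  pk <- data.frame(peak_type = c("aldehyde", "imine_cage", "aromatic"),
                   shift_ppm = c(10, 8.6, 7.3),
                   amplitude = c(2.3, 80, 60))
  base <- aldehyde_conversion(pk)
  for (c_scale in c(0.01, 3, 1e4)) {
    scaled <- pk
    scaled$amplitude <- scaled$amplitude * c_scale
    r <- aldehyde_conversion(scaled)
    expect_equal(r$residual_aldehyde_pct, base$residual_aldehyde_pct)
    expect_identical(r$category, base$category)
  }
})

test_that("planted aldehyde fractions are recovered to 0.2 points at SNR 50", {
  for (f_pct in c(0.5, 3, 8)) {
    spec <- data.frame(ppm = c(10.0, 8.6), integral = c(f_pct / 100, 1))
    syn <- synth_nmr(spec, linewidth_hz = 2, noise_sd = 1e-5, seed = 29)
    pk <- pick_peaks(syn$spectrum, snr_threshold = 20)
    r <- aldehyde_conversion(pk)
    expect_lt(abs(r$residual_aldehyde_pct - f_pct), 0.2)
  }
})

test_that("speciation ratio divides integrals by their proton counts", {
  expect_equal(speciation_ratio(12, 9)$ratio, 1)
  expect_equal(speciation_ratio(12, 0)$ratio, 0)
  r <- speciation_ratio(12, 0.36)
  expect_equal(r$ratio, 0.04, tolerance = 1e-12)
  expect_identical(r$label, "1:0.04")
  # scale invariance
  expect_equal(speciation_ratio(1.2, 0.036)$ratio, 0.04, tolerance = 1e-12)
  expect_error(speciation_ratio(0, 1), "no tetrahedron")
})

test_that("radius ratio is inverse diffusion under Stokes-Einstein", {
  expect_equal(round(radius_ratio(7.05e-10, 8.06e-10), 2), 1.14)
  expect_equal(round(radius_ratio(7.60e-10, 8.85e-10), 2), 1.16)
  expect_equal(radius_ratio(5e-10, 5e-10), 1)
  expect_error(radius_ratio(0, 1e-10), "positive")
})

test_that("directory analysis writes per-spectrum CSVs and a JSON database", {
  dir_in <- withr::local_tempdir()
  dir_out <- withr::local_tempdir()
  s1 <- synth_nmr(data.frame(ppm = c(10, 8.6), integral = c(0.03, 1)),
                  noise_sd = 1e-5, seed = 8)
  s2 <- synth_nmr(data.frame(ppm = c(8.6, 7.2), integral = c(1, 2)),
                  noise_sd = 1e-5, seed = 9)
  write.csv(s1$spectrum, file.path(dir_in, "rxn01.csv"), row.names = FALSE)
  write.csv(s2$spectrum, file.path(dir_in, "rxn02.csv"), row.names = FALSE)
  res <- analyze_nmr_dir(dir_in, dir_out, snr_threshold = 20)
  expect_equal(nrow(res), 2)
  expect_identical(res$category,
                   c("still considered for scale-up", "minor"))
  expect_true(file.exists(file.path(dir_out, "rxn01.csv")))
  expect_identical(names(read.csv(file.path(dir_out, "rxn01.csv"))),
                   c("peak_type", "shift_ppm", "amplitude"))
  expect_true(file.exists(file.path(dir_out, "conversion.json")))
})
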