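test_that("noise-free MS generation reproduces the predicted envelopes", {
  ions <- a1_tetrahedron_ions()
  syn <- synth_ms(ions[5], intensities = 100, n_decoys = 0, jitter_ppm = 0,
                  seed = 1)
  pred <- ions[[5]]$pattern$peaks
  pred <- pred[pred$rel_intensity >= 0.5, ]
  expect_equal(syn$peaklist$mz, pred$mz)
  expect_equal(syn$peaklist$intensity, pred$rel_intensity)
})

test_that("generators are bit-identical under the same seed", {
  ions <- a1_tetrahedron_ions()
  a <- synth_ms(ions[c(3, 5)], n_decoys = 25, jitter_ppm = 2,
                intensity_noise = 0.05, seed = 99)
  b <- synth_ms(ions[c(3, 5)], n_decoys = 25, jitter_ppm = 2,
                intensity_noise = 0.05, seed = 99)
  expect_identical(a$peaklist, b$peaklist)
  c1 <- synth_nmr(data.frame(ppm = 8.6, integral = 1), noise_sd = 0.01,
                  seed = 4)
  c2 <- synth_nmr(data.frame(ppm = 8.6, integral = 1), noise_sd = 0.01,
                  seed = 4)
  expect_identical(c1$spectrum, c2$spectrum)
  grid <- data.frame(host = "h", guest = "g", timepoint = 1, Ka = 500)
  d1 <- synth_assay(grid, integral_noise_sd = 0.01, seed = 21)
  d2 <- synth_assay(grid, integral_noise_sd = 0.01, seed = 21)
  expect_identical(d1$plate, d2$plate)
  # a different seed perturbs the jittered output
  e <- synth_ms(ions[c(3, 5)], n_decoys = 25, jitter_ppm = 2,
                intensity_noise = 0.05, seed = 100)
  expect_false(identical(a$peaklist, e$peaklist))
})

test_that("planted species are recovered exactly through the matcher", {
  hyps <- a1_full_hypotheses()
  pick <- function(topo, k) {
    hit <- vapply(hyps, function(h)
      h$species$topology == topo && h$k_counterions == k, logical(1))
    hyps[[which(hit)]]
  }
  planted <- list(pick("M4L4", 4), pick("M2L3", 1), pick("free_L", 0))
  syn <- synth_ms(planted, intensities = c(100, 40, 25), n_decoys = 50,
                  jitter_ppm = 2, seed = 7)
  rec <- filter_charge_consistent(
    match_spectrum(syn$peaklist, hyps, tol_ppm = 5))
  expect_setequal(rec$formula, syn$truth$formulas)
  # the pseudo-icosahedron shares m/z with the planted tetrahedron ion
  # (3x the composition at 3x the charge); only the observed-charge filter
  # removes that degenerate candidate
  raw <- match_spectrum(syn$peaklist, hyps, tol_ppm = 5)
  expect_true(any(raw$topology == "M12L12" & !raw$charge_consistent) ||
                !any(raw$topology == "M12L12"))
})

test_that("decoy placement respects the exclusion window or errors", {
  ions <- a1_tetrahedron_ions()
  syn <- synth_ms(ions[5], n_decoys = 40, jitter_ppm = 0, seed = 15)
  planted <- ions[[5]]$pattern$peaks
  planted <- planted$mz[planted$rel_intensity >= 0.5]
  decoys <- setdiff(syn$peaklist$mz, planted)
  min_gap_ppm <- vapply(decoys, function(mz)
    min(abs(mz - planted) / mz * 1e6), numeric(1))
  expect_true(all(min_gap_ppm > 20))
  # a range lying entirely inside one exclusion window cannot host decoys
  base <- base_peak_mz(ions[[5]]$pattern)
  expect_error(
    synth_ms(ions[5], n_decoys = 5, seed = 2,
             mz_range = base + c(-0.005, 0.005)),
    "decoy placement impossible"
  )
})

test_that("noise-free NMR generation is the identity on ground truth", {
  syn <- synth_nmr(data.frame(ppm = 8.62, integral = 1), noise_sd = 0,
                   seed = 6)
  expect_equal(syn$spectrum$ppm[which.max(syn$spectrum$amplitude)], 8.62,
               tolerance = 1e-9)
  # planted 3% aldehyde fraction categorizes as the middle bin end-to-end
  syn3 <- synth_nmr(data.frame(ppm = c(10.0, 8.6), integral = c(0.03, 1)),
                    noise_sd = 0, seed = 6)
  pk <- pick_peaks(syn3$spectrum, snr_threshold = 10)
  r <- aldehyde_conversion(pk)
  expect_identical(r$category, "still considered for scale-up")
  expect_equal(r$residual_aldehyde_pct, 3, tolerance = 0.1)
  expect_error(synth_nmr(data.frame(ppm = 15, integral = 1), seed = 1),
               "outside the ppm grid")
})

test_that("noise-free assay generation inverts to the planted Ka", {
  grid <- data.frame(host = "cage1", guest = c("a", "b", "c"),
                     timepoint = 7, Ka = c(0, 1e3, 2.5e4))
  syn <- synth_assay(grid, seed = 12)
  expect_equal(syn$plate$I_HG[1], 0)  # Ka = 0 -> no complex signal
  res <- analyze_plate(syn$plate)
  expect_equal(res$Ka[1], 0)
  expect_equal(res$Ka[2], 1e3, tolerance = 1e-9)
  expect_equal(res$Ka[3], 2.5e4, tolerance = 1e-9)
})

test_that("a planted day-1/day-7 plate reproduces the bound proportion", {
  # 32 guests: 8 bound at day 1, 22 bound by day 7 (slow uptake)
  guests <- sprintf("g%02d", 1:32)
  ka1 <- rep(0, 32); ka1[1:8] <- 800
  ka7 <- rep(0, 32); ka7[1:22] <- 1200
  grid <- rbind(
    data.frame(host = "cage1", guest = guests, timepoint = 1, Ka = ka1),
    data.frame(host = "cage1", guest = guests, timepoint = 7, Ka = ka7)
  )
  res <- analyze_plate(synth_assay(grid, seed = 30)$plate)
  bound_d7 <- sum(res$Ka[res$timepoint == 7] > 0)
  expect_equal(bound_d7 / 32, 22 / 32)
  m <- heatmap_table(res)
  expect_equal(sum(!is.na(m)), 22)
})
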