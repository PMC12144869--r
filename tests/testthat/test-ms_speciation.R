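test_that("reaction enumeration is the Cartesian product of precursors", {
  s <- screen_sets()
  rx <- enumerate_reactions(s$triamines, s$aldehydes, s$salts)
  expect_equal(nrow(rx), 24)
  expect_equal(anyDuplicated(rx$reaction_id), 0)
  # the ligand set alone: one ligand per triamine x aldehyde pair
  lig <- expand.grid(t = names(s$triamines), a = names(s$aldehydes))
  expect_equal(nrow(lig), 8)
  expect_equal(nrow(enumerate_reactions(s$triamines, s$aldehydes, list())), 0)
})

test_that("candidate assemblies cover the topology set with correct charges", {
  p <- example_precursors()
  sp <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2)
  expect_length(sp, 8)
  m4l4 <- sp[[which(vapply(sp, `[[`, "", "topology") == "M4L4")]]
  expect_true(m4l4$composition == parse_formula("C168H120N24Zn4"))
  expect_equal(m4l4$total_cation_charge, 8)
  m2i3 <- sp[[which(vapply(sp, `[[`, "", "topology") == "M2I3")]]
  # 2 Zn + 3 x (A + 2*ald - 2*H2O)
  expect_true(m2i3$composition ==
                composition(Zn = 2) + 3 * parse_formula("C36H27N5"))
  expect_length(candidate_assemblies(p$A, p$`1`, p$ZnNTf2,
                                     topologies = character(0)), 0)
})

test_that("ion enumeration walks the counterion-retention ladder", {
  ions <- a1_tetrahedron_ions()
  expect_length(ions, 8)  # k = 0..7 for total cation charge 8
  expect_equal(vapply(ions, function(h) h$z_pred, integer(1)), 8:1)
  expect_equal(ions[[1]]$k_counterions, 0L)
  expect_equal(ions[[1]]$z_pred, 8L)
  p <- example_precursors()
  m2l3 <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2,
                               topologies = "M2L3")[[1]]
  expect_length(enumerate_ions(m2l3, p$NTf2), 4)
  # m/z window filtering
  expect_lt(length(enumerate_ions(m2l3, p$NTf2, mz_range = c(500, 1500))), 4)
  # free ligand gets a protonated ion
  freeL <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2,
                                topologies = "free_L")[[1]]
  hyp <- enumerate_ions(freeL, p$NTf2)
  expect_length(hyp, 1)
  expect_equal(hyp[[1]]$z_pred, 1L)
  expect_true(hyp[[1]]$composition == parse_formula("C42H31N6"))
})

test_that("charge assignment inverts isotopologue spacing", {
  expect_equal(assign_charge(c(500.0, 500.5017, 501.0034)), 2L)
  expect_equal(assign_charge(800 + cumsum(c(0, 0.2508, 0.2509, 0.2508))), 4L)
  expect_true(is.na(assign_charge(c(100, 100.50, 100.83))))  # irregular
  expect_true(is.na(assign_charge(964.5)))                   # single peak
})

test_that("a planted envelope self-matches and a 50 ppm shift does not", {
  ions <- a1_tetrahedron_ions()
  h <- ions[[5]]  # [Zn4(A1)4.(NTf2)4]4+
  pk <- h$pattern$peaks
  pl <- peak_list(pk$mz, pk$rel_intensity)
  rec <- match_spectrum(pl, list(h), tol_ppm = 5)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$found_mz, rec$predicted_mz)
  expect_equal(rec$predicted_charge, 4L)
  expect_true(rec$charge_consistent)
  shifted <- peak_list(pk$mz * (1 + 50e-6), pk$rel_intensity)
  expect_equal(nrow(match_spectrum(shifted, list(h), tol_ppm = 5)), 0)
})

test_that("match records carry the screen's six result fields in order", {
  ions <- a1_tetrahedron_ions()
  pk <- ions[[5]]$pattern$peaks
  rec <- match_spectrum(peak_list(pk$mz, pk$rel_intensity), ions, tol_ppm = 5)
  expect_identical(names(rec)[1:6],
                   c("formula", "found_mz", "found_intensity", "predicted_mz",
                     "predicted_intensity", "predicted_charge"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_match_csv(rec, path)
  expect_identical(names(read.csv(path)),
                   c("formula", "found_mz", "found_intensity", "predicted_mz",
                     "predicted_intensity", "predicted_charge"))
})

test_that("shrinking the tolerance never adds matches", {
  ions <- a1_tetrahedron_ions()
  set.seed(42)
  syn <- synth_ms(ions[c(3, 5)], intensities = c(100, 60), n_decoys = 30,
                  jitter_ppm = 2, seed = 42)
  tols <- c(20, 10, 5, 2, 1, 0.5)
  counts <- vapply(tols, function(tp)
    nrow(match_spectrum(syn$peaklist, ions, tol_ppm = tp)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("charge filtering keeps exactly the consistent records, sorted", {
  rec <- data.frame(
    formula = c("Zc", "Aa", "Bb", "Aa", "Cc"),
    found_mz = 1:5, found_intensity = 1:5, predicted_mz = 1:5,
    predicted_intensity = 1:5,
    predicted_charge = c(4L, 4L, 3L, 2L, 5L),
    observed_charge = c(4L, 2L, 3L, NA, 5L),
    charge_consistent = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    topology = "M4L4", n_matched_peaks = 3L
  )
  kept <- filter_charge_consistent(rec)
  expect_equal(nrow(kept), 3)
  expect_identical(kept$formula, c("Bb", "Cc", "Zc"))
  expect_true(all(kept$observed_charge == kept$predicted_charge))
})

test_that("reaction MS classification splits major, minor and absent", {
  ions <- a1_tetrahedron_ions()
  p <- example_precursors()
  m2l3 <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2, topologies = "M2L3")[[1]]
  m2l3_ions <- enumerate_ions(m2l3, p$NTf2)
  hyps <- c(ions, m2l3_ions)
  # plant the tetrahedron envelope as base peak and the helicate at 10%
  syn <- synth_ms(list(ions[[5]], m2l3_ions[[2]]), intensities = c(100, 10),
                  seed = 1)
  rec <- filter_charge_consistent(match_spectrum(syn$peaklist, hyps))
  status <- classify_reaction_ms(rec, syn$peaklist)
  expect_identical(unname(status["MNLN"]), "major")
  expect_identical(unname(status["M2X3"]), "minor")
  expect_identical(unname(status["free"]), "absent")
  empty <- match_spectrum(syn$peaklist, list(), tol_ppm = 5)
  all_absent <- classify_reaction_ms(empty, syn$peaklist)
  expect_true(all(all_absent == "absent"))
})
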