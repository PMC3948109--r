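# OzID product prediction, double-bond localization, geometry scoring.

test_that("aldehyde/Criegee arithmetic matches the frozen worked example", {
  prods <- predict_ozid_products(543.36561, c(2, 7, 9))
  expect_equal(prods$aldehyde_mz[prods$n_x == 9], 433.21967,
               tolerance = 2e-5)
  expect_equal(prods$criegee_mz[prods$n_x == 9], 449.21459,
               tolerance = 2e-5)
  expect_equal(prods$aldehyde_mz[prods$n_x == 7], 461.25097,
               tolerance = 2e-5)
  expect_equal(prods$aldehyde_mz[prods$n_x == 2], 531.32922,
               tolerance = 2e-5)
  # reported to nearest integer: 433/461/531 and 449/477
  expect_equal(report_mz(prods$aldehyde_mz, "text"), c(531, 461, 433))
  expect_equal(report_mz(prods$criegee_mz[prods$n_x %in% c(7, 9)], "text"),
               c(477, 449))
})

test_that("aldehyde m/z decreases linearly in x; Criegee is +O", {
  prods <- predict_ozid_products(600, 2:14)
  d <- diff(prods$aldehyde_mz)
  expect_true(all(abs(d + 14.01565) < 1e-5))
  expect_true(all(abs(prods$criegee_mz - prods$aldehyde_mz - 15.99491) <
                    1e-5))
  expect_error(predict_ozid_products(600, 1), "x >= 2")
})

test_that("the Fig-style five-peak spectrum localizes n-9/n-7/n-2", {
  spec <- spectrum(c(433, 449, 461, 477, 531), c(50, 25, 40, 20, 30),
                   stage = "OzID", precursor_mz = 543.37)
  # the published peak labels are integer-rounded, so matching them needs a
  # half-unit window rather than the 0.3 Da instrument default
  loc <- localize_double_bonds(spec, precursor_mz = 543.36561, tol_mz = 0.5)
  expect_setequal(loc$n_x, c(2, 7, 9))
  expect_equal(loc$status[loc$n_x == 9], "confirmed")
  expect_equal(loc$status[loc$n_x == 7], "confirmed")
  expect_equal(loc$status[loc$n_x == 2], "supported")
  # soundness: every reported aldehyde matched an observed peak in tolerance
  expect_true(all(abs(loc$aldehyde_mz - loc$aldehyde_matched_mz) <= 0.5))
})

test_that("empty OzID spectrum is undetermined", {
  spec <- spectrum(stage = "OzID", precursor_mz = 543.37)
  loc <- localize_double_bonds(spec, precursor_mz = 543.37)
  expect_equal(nrow(loc), 0L)
  expect_true(attr(loc, "undetermined"))
})

test_that("simulate -> localize round trip recovers known positions", {
  cfg <- simulation_config(seed = 88)
  set.seed(88)
  n_ok <- 0L; n_db <- 0L
  for (i in 1:40) {
    t <- sample_structure(cfg)
    b <- simulate_spectra(t, "Na", cfg)
    loc <- localize_double_bonds(b$ozid,
                                 precursor_mz = b$truth$exact_precursor_mz)
    confirmed <- sort(loc$n_x[loc$status == "confirmed"])
    if (identical(as.integer(confirmed),
                  as.integer(b$truth$db_positions))) n_ok <- n_ok + 1L
    if (length(b$truth$db_positions) > 0) n_db <- n_db + 1L
  }
  expect_equal(n_ok, 40L)
  expect_gt(n_db, 10L) # the draw actually exercised unsaturated TAGs
})

test_that("an n-6,9 diene yields both positions", {
  t <- tag_structure(list(
    fatty_acyl(18, 2, db_positions = c(6, 9),
               db_geometries = c("cis", "cis")),
    fatty_acyl(2, 0), fatty_acyl(2, 0)), "long-chain-at-sn-1/3")
  cfg <- simulation_config(seed = 5, noise_peaks = 0L, mz_jitter = 0,
                           precursor_ppm_sd = 0, intensity_cv = 0)
  set.seed(5)
  b <- simulate_spectra(t, "Na", cfg)
  loc <- localize_double_bonds(b$ozid,
                               precursor_mz = b$truth$exact_precursor_mz)
  expect_setequal(loc$n_x[loc$status == "confirmed"], c(6, 9))
})

test_that("geometry calls recover the simulated cis/trans ground truth", {
  refs <- c(cis = 2, trans = 8)
  mk_pairs <- function(ratio) {
    data.frame(n_x = 9L, status = "confirmed", aldehyde_mz = 433.2,
               aldehyde_matched_mz = 433.2, aldehyde_intensity = 100 * ratio,
               criegee_mz = 449.2, criegee_matched_mz = 449.2,
               criegee_intensity = 100)
  }
  expect_equal(classify_geometry(mk_pairs(2.1), refs)$call, "cis")
  expect_equal(classify_geometry(mk_pairs(7.5), refs)$call, "trans")
  # no reference -> undetermined; zero Criegee -> undetermined with reason
  expect_equal(classify_geometry(mk_pairs(2.1), NULL)$call, "undetermined")
  pz <- mk_pairs(2); pz$criegee_intensity <- 0
  gz <- classify_geometry(pz, refs)
  expect_equal(gz$call, "undetermined")
  expect_match(gz$reason, "Criegee")
  # ratio far from every reference -> undetermined
  expect_equal(classify_geometry(mk_pairs(25), refs)$call, "undetermined")
})

test_that("simulated trans bonds classify as trans end-to-end", {
  t <- tag_structure(list(
    fatty_acyl(18, 1, db_positions = 9, db_geometries = "trans"),
    fatty_acyl(2, 0), fatty_acyl(2, 0)), "long-chain-at-sn-1/3")
  cfg <- simulation_config(seed = 6)
  set.seed(6)
  b <- simulate_spectra(t, "Na", cfg)
  loc <- localize_double_bonds(b$ozid,
                               precursor_mz = b$truth$exact_precursor_mz)
  geo <- classify_geometry(loc, references = c(cis = 2, trans = 8))
  expect_equal(geo$call[geo$n_x == 9], "trans")
})
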