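# End-to-end orchestration: ranking, evidence decoration, degradation,
# determinism, monotone evidence.

test_that("full synthetic bundle for the oleoyl-ditigloyl TAG is recovered", {
  cfg <- simulation_config(seed = 42)
  set.seed(42)
  b <- simulate_spectra(example_tag(), "Na", cfg)
  rep <- elucidate(b$precursor$peaks$mz[1], "Na", b$cid, b$ozid,
                   sim_geometry_config())
  expect_equal(rep$candidates$label[1], "18:1/5:1/5:1")
  expect_equal(rep$sn$assignment, "long-chain-at-sn-1/3")
  expect_setequal(rep$positions$n_x[rep$positions$status == "confirmed"],
                  c(2, 9))
  geo <- rep$geometry
  expect_equal(geo$call[geo$n_x == 9], "cis")
  expect_equal(geo$call[geo$n_x == 2], "trans")
  # n-2 attributed to the tiglate, n-9 to the long chain
  expect_equal(rep$positions$attributed_to[rep$positions$n_x == 2], "5:1")
  expect_equal(rep$positions$attributed_to[rep$positions$n_x == 9], "18:1")
})

test_that("the published peak sets for the sodiated 543 TAG reproduce", {
  cid <- spectrum(c(443.31, 421.33, 261.11, 239.13), c(30, 100, 25, 90),
                  stage = "CID", precursor_mz = 543.37)
  ozid <- spectrum(c(433, 449, 461, 477, 531), c(50, 25, 40, 20, 30),
                   stage = "OzID", precursor_mz = 543.37)
  # integer-rounded published peak labels need a half-unit match window
  rep <- elucidate(543.37, "Na", cid, ozid, te_config(tol_mz = 0.5))
  expect_equal(rep$candidates$label[1], "18:1/5:1/5:1")
  expect_setequal(rep$positions$n_x, c(2, 7, 9))
  # n-7/n-9 on one 18:1 chain: a positional isomer mixture, flagged
  expect_true(any(grepl("isomer", rep$flags)))
})

test_that("stages degrade gracefully and never fabricate evidence", {
  rep <- elucidate(543.37, "Na")
  expect_gt(nrow(rep$candidates), 0)
  expect_false("cid_score" %in% names(rep$candidates))
  expect_identical(rep$sn, "undetermined")
  expect_identical(rep$positions, "undetermined")
  expect_identical(rep$geometry, "undetermined")
})

test_that("no candidate in tolerance reports the nearest-miss ppm", {
  rep <- elucidate(300.0, "Na")
  expect_equal(nrow(rep$candidates), 0L)
  expect_false(is.na(rep$nearest_miss_ppm))
  expect_true(any(grepl("no composition candidate", rep$flags)))
})

test_that("identical inputs and config give byte-identical reports", {
  cfg <- simulation_config(seed = 9)
  set.seed(9)
  b <- simulate_spectra(sample_structure(cfg), "Na", cfg)
  j1 <- report_json(elucidate(b$precursor$peaks$mz[1], "Na", b$cid, b$ozid,
                              sim_geometry_config()))
  j2 <- report_json(elucidate(b$precursor$peaks$mz[1], "Na", b$cid, b$ozid,
                              sim_geometry_config()))
  expect_identical(j1, j2)
})

test_that("adding a matching OzID spectrum never lowers a candidate's rank", {
  cfg <- simulation_config(seed = 10)
  set.seed(10)
  for (i in 1:10) {
    b <- simulate_spectra(sample_structure(cfg), "Na", cfg)
    r0 <- elucidate(b$precursor$peaks$mz[1], "Na", b$cid, NULL)
    r1 <- elucidate(b$precursor$peaks$mz[1], "Na", b$cid, b$ozid)
    top <- r0$candidates$label[1]
    expect_lte(match(top, r1$candidates$label),
               match(top, r0$candidates$label))
  }
})

test_that("an OzID position impossible for the top candidate is flagged", {
  # saturated TAG 18:0/2:0/2:0 but an OzID spectrum claiming an n-9 bond
  mz <- oracle_tag_mz(c(18, 2, 2), c(0, 0, 0), "Na")
  prods <- predict_ozid_products(mz, 9)
  ozid <- spectrum(c(prods$aldehyde_mz, prods$criegee_mz), c(50, 25),
                   stage = "OzID", precursor_mz = mz)
  cid_frag <- predict_cid_fragments(list(fatty_acyl(18, 0), fatty_acyl(2, 0),
                                         fatty_acyl(2, 0)), mz, "Na")
  cid <- spectrum(cid_frag$mz, rep(100, nrow(cid_frag)), stage = "CID",
                  precursor_mz = mz)
  rep <- elucidate(mz, "Na", cid, ozid)
  expect_equal(rep$candidates$label[1], "18:0/2:0/2:0")
  expect_true(any(grepl("impossible", rep$flags)))
})

test_that("report JSON carries provenance and traceable evidence", {
  cfg <- simulation_config(seed = 12)
  set.seed(12)
  b <- simulate_spectra(example_tag(), "Na", cfg)
  js <- report_json(elucidate(b$precursor$peaks$mz[1], "Na", b$cid, b$ozid,
                              sim_geometry_config()))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$schema_version, "1")
  expect_match(parsed$config_hash, "^[0-9a-f]{8}$")
  expect_equal(parsed$tolerances$tol_ppm, 20)
  expect_equal(parsed$tolerances$tol_mz, 0.3)
  # every claimed position is backed by a matched peak
  expect_true(all(!is.na(parsed$positions$aldehyde_matched_mz)))
})
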