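# CID fragment prediction, spectrum annotation, sn inference.

test_that("predicted fragment m/z match the neutral-loss arithmetic", {
  acyls <- list(fatty_acyl(18, 1), fatty_acyl(5, 1), fatty_acyl(5, 1))
  frags <- predict_cid_fragments(acyls, 543.36561, "Na")
  get <- function(acyl, channel) frags$mz[frags$acyl == acyl &
                                            frags$channel == channel]
  # frozen from the acid-mass oracle: tiglic 100.05243, oleic 282.25588
  expect_equal(get("5:1", "neutral-acid-loss"), 443.31318, tolerance = 2e-5)
  expect_equal(get("5:1", "metalated-acid-loss"), 421.33124, tolerance = 2e-5)
  expect_equal(get("18:1", "neutral-acid-loss"), 261.10973, tolerance = 2e-5)
  expect_equal(get("18:1", "metalated-acid-loss"), 239.12779, tolerance = 2e-5)
})

test_that("duplicate acyls collapse; fragment count is 2 x distinct acyls", {
  triacetin <- replicate(3, fatty_acyl(2, 0), simplify = FALSE)
  mz <- oracle_tag_mz(c(2, 2, 2), c(0, 0, 0), "Na")
  frags <- predict_cid_fragments(triacetin, mz, "Na")
  expect_equal(nrow(frags), 2L)
  set.seed(301)
  for (i in 1:10) {
    cs <- sample(2:18, 3, replace = TRUE)
    ds <- pmin(sample(0:2, 3, replace = TRUE), cs - 1)
    acyls <- mapply(fatty_acyl, cs, ds, SIMPLIFY = FALSE)
    mz <- oracle_tag_mz(cs, ds, "Na")
    frags <- predict_cid_fragments(acyls, mz, "Na")
    n_distinct <- length(unique(paste(cs, ds)))
    expect_equal(nrow(frags), 2L * n_distinct)
    # adduct consistency: channel gap = cation - proton, per acyl
    gap <- tapply(frags$mz, frags$acyl,
                  function(x) max(x) - min(x))
    expect_true(all(abs(gap - (oracle_mass[["Na"]] - oracle_mass[["H"]])) <
                      1e-9))
  }
})

test_that("inconsistent precursor/candidate errors with the ppm gap", {
  acyls <- list(fatty_acyl(18, 1), fatty_acyl(5, 1), fatty_acyl(5, 1))
  expect_error(predict_cid_fragments(acyls, 545.0, "Na"), "ppm")
})

test_that("annotate_cid ranks the generating composition first", {
  cfg <- simulation_config(seed = 77)
  set.seed(77)
  for (i in 1:25) {
    t <- sample_structure(cfg)
    b <- simulate_spectra(t, "Na", cfg)
    cands <- enumerate_acyl_compositions(b$precursor$peaks$mz[1], "Na", 20)
    ann <- annotate_cid(b$cid, cands, "Na")
    expect_equal(ann$ranking$label[1], truth_label(t))
    expect_equal(ann$ranking$cid_score[1], 1.0)
  }
})

test_that("the worked four-peak CID spectrum assigns 18:1 + 2 x 5:1", {
  # only the two tiglic-loss and two oleic-loss peaks at [M+Na]+ 543
  spec <- spectrum(c(443.313, 421.331, 261.110, 239.128),
                   c(30, 100, 20, 80), stage = "CID",
                   precursor_mz = 543.3656)
  cands <- enumerate_acyl_compositions(543.3656, "Na", 20)
  ann <- annotate_cid(spec, cands, "Na")
  expect_equal(ann$ranking$label[1], "18:1/5:1/5:1")
  expect_equal(ann$ranking$cid_score[1], 1.0)
  expect_equal(nrow(ann$unmatched_peaks), 0L)
})

test_that("empty CID spectrum scores all zero and is flagged", {
  spec <- spectrum(stage = "CID", precursor_mz = 543.3656)
  cands <- enumerate_acyl_compositions(543.3656, "Na", 20)
  ann <- annotate_cid(spec, cands, "Na")
  expect_true(all(ann$ranking$cid_score == 0))
  expect_true("no evidence" %in% ann$flags)
})

make_sn_frags <- function(abund) {
  # matched fragment table with given per-acyl intensities
  do.call(rbind, lapply(names(abund), function(acyl) {
    data.frame(acyl = acyl,
               channel = c("neutral-acid-loss", "metalated-acid-loss"),
               mz = c(1, 2), matched_mz = c(1, 2),
               matched_intensity = rep(abund[[acyl]], 2))
  }))
}

test_that("sn inference follows the suppressed-loss rule", {
  # short-chain losses suppressed -> long chain on the outer positions
  ev <- infer_sn_positions(make_sn_frags(c(`18:1` = 100, `5:1` = 20)))
  expect_equal(ev$assignment, "long-chain-at-sn-1/3")
  expect_equal(ev$proposed_sn2, "5:1")
  # long-chain loss suppressed (the lithiated 487 pattern) -> sn-2
  ev2 <- infer_sn_positions(make_sn_frags(c(`18:1` = 15, `5:1` = 100)))
  expect_equal(ev2$assignment, "long-chain-at-sn-2")
  # all losses within the decision ratio -> unresolved
  ev3 <- infer_sn_positions(make_sn_frags(c(`18:1` = 80, `5:1` = 100)))
  expect_equal(ev3$assignment, "unresolved")
})

test_that("sn inference is invariant to fragment row order and reports gaps", {
  frags <- make_sn_frags(c(`18:1` = 100, `5:1` = 10, `4:0` = 90))
  set.seed(303)
  for (i in 1:5) {
    shuffled <- frags[sample(nrow(frags)), ]
    ev <- infer_sn_positions(shuffled)
    expect_equal(ev$assignment, "long-chain-at-sn-1/3")
    expect_equal(ev$proposed_sn2, "5:1")
  }
  # an acyl with no matched fragments -> unresolved with a reason
  frags$matched_intensity[frags$acyl == "4:0"] <- NA
  frags$matched_mz[frags$acyl == "4:0"] <- NA
  ev <- infer_sn_positions(frags)
  expect_equal(ev$assignment, "unresolved")
  expect_match(ev$reason, "4:0")
})
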