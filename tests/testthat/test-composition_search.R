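# Elemental and acyl-composition search against brute-force oracles.

brute_force_formulas <- function(mz, cation, tol_ppm, bC, bH, bO) {
  # independent nested-loop enumeration with its own mass table
  target <- mz - oracle_mass[[cation]] + oracle_mass[["e"]]
  tol <- mz * tol_ppm * 1e-6
  hits <- character()
  for (nC in 0:bC) for (nH in 0:bH) for (nO in 0:bO) {
    m <- nC * oracle_mass[["C"]] + nH * oracle_mass[["H"]] +
      nO * oracle_mass[["O"]]
    if (abs(m - target) <= tol) {
      hits <- c(hits, paste(nC, nH, nO, sep = "/"))
    }
  }
  sort(hits)
}

test_that("search_formulas equals nested-loop brute force (set equality)", {
  set.seed(202)
  for (i in 1:8) {
    mz <- runif(1, 150, 600)
    cation <- sample(c("Na", "K", "Li"), 1)
    got <- search_formulas(mz, cation, tol_ppm = 25,
                           bounds = c(C = 25, H = 50, O = 6))
    expect_setequal(paste(got$C, got$H, got$O, sep = "/"),
                    brute_force_formulas(mz, cation, 25, 25, 50, 6))
  }
})

test_that("search_formulas finds the TAG composition with its DBE", {
  res <- search_formulas(559.3396, "K", tol_ppm = 20,
                         bounds = c(C = 40, H = 80, O = 8))
  row <- res[res$formula == "C31H52O6", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$dbe, 6)
  expect_true(abs(row$ppm_error) <= 20)
  # soundness: every candidate's recomputed adduct m/z is inside tolerance
  for (i in seq_len(nrow(res))) {
    f <- molecular_formula(c(C = res$C[i], H = res$H[i], O = res$O[i]))
    expect_true(abs(ion_mz(f, "K") - 559.3396) / 559.3396 * 1e6 <= 20)
  }
})

test_that("search_formulas edge cases: bare cation, below-cation error, guard", {
  res <- search_formulas(22.98922, "Na", tol_ppm = 20,
                         bounds = c(C = 2, H = 4, O = 1))
  expect_true("" %in% res$formula) # the empty formula: bare Na+
  expect_error(search_formulas(10.0, "K"), "cation mass")
  expect_error(search_formulas(500, "Na", bounds = c(C = 500, H = 1000, O = 50)),
               "1e7|combinations")
})

test_that("shrinking the ppm tolerance never adds candidates", {
  set.seed(203)
  for (i in 1:5) {
    mz <- runif(1, 200, 600)
    wide <- search_formulas(mz, "Na", tol_ppm = 30,
                            bounds = c(C = 30, H = 60, O = 6))
    narrow <- search_formulas(mz, "Na", tol_ppm = 10,
                              bounds = c(C = 30, H = 60, O = 6))
    expect_true(all(narrow$formula %in% wide$formula))
    expect_true(all(abs(narrow$ppm_error) <= 10))
  }
})

brute_force_compositions <- function(mz, cation, tol_ppm, cs) {
  hits <- character()
  for (lc in cs$long_carbons) for (ld in cs$long_db) {
    if (ld > lc - 1) next
    for (c1 in cs$short_carbons) for (d1 in cs$short_db) {
      if (d1 > c1 - 1) next
      for (c2 in cs$short_carbons) for (d2 in cs$short_db) {
        if (d2 > c2 - 1) next
        if (c2 > c1 || (c2 == c1 && d2 > d1)) next  # unordered pair
        cand <- oracle_tag_mz(c(lc, c1, c2), c(ld, d1, d2), cation)
        if (abs(cand - mz) / mz * 1e6 <= tol_ppm) {
          hits <- c(hits, sprintf("%d:%d/%d:%d/%d:%d", lc, ld, c1, d1,
                                  c2, d2))
        }
      }
    }
  }
  sort(unique(hits))
}

test_that("enumerate_acyl_compositions matches the brute-force oracle", {
  cs <- composition_constraints()
  # the two tabulated precursors plus random probes across the box range
  set.seed(204)
  probes <- c(543.37, 561.36, runif(6, 480, 580))
  for (mz in probes) {
    adduct <- if (mz %in% c(561.36)) "K" else "Na"
    got <- enumerate_acyl_compositions(mz, adduct, tol_ppm = 20,
                                       constraints = cs)
    expect_setequal(got$label, brute_force_compositions(mz, adduct, 20, cs))
  }
})

test_that("known precursors contain the published compositions", {
  got <- enumerate_acyl_compositions(543.37, "Na", 20)
  expect_true("18:1/5:1/5:1" %in% got$label)
  got_k <- enumerate_acyl_compositions(561.36, "K", 20)
  expect_true("18:0/5:1/5:1" %in% got_k$label)
  # soundness: recomputed tag_formula ion m/z within tolerance
  for (i in seq_len(nrow(got))) {
    f <- tag_formula(candidate_acyls(got[i, ]))
    expect_true(abs(ion_mz(f, "Na") - 543.37) / 543.37 * 1e6 <= 20)
  }
})

test_that("a widened box pins triacetin to its unique precursor", {
  cs <- composition_constraints(long_carbons = 2:18, long_db = 0:2,
                                short_carbons = 2:18, short_db = 0:2)
  mz <- oracle_tag_mz(c(2, 2, 2), c(0, 0, 0), "Na")
  got <- enumerate_acyl_compositions(mz, "Na", tol_ppm = 20,
                                     constraints = cs)
  expect_equal(got$label, "2:0/2:0/2:0")
})

test_that("candidate ordering is deterministic: |ppm|, then db, then label", {
  got <- enumerate_acyl_compositions(543.37, "Na", 20)
  key <- order(abs(got$ppm_error), got$total_db, got$label)
  expect_equal(key, seq_len(nrow(got)))
})
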