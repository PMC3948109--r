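# Invert an observed exact mass into candidate elemental compositions and
# candidate acyl-chain compositions under the one-long-two-short TAG motif.

#' Search elemental compositions for an observed adduct m/z
#'
#' Exhaustive CHO(N) composition search over a per-element bound box. The
#' neutral target mass is `mz - cation mass + electron mass`; a candidate is
#' kept when its computed adduct m/z lies within `tol_ppm` of the observed
#' value. Double-bond equivalents (DBE, rings plus double bonds) are reported
#' per candidate: `DBE = C - H/2 + N/2 + 1`.
#'
#' @param mz Observed m/z (singly charged adduct ion).
#' @param adduct [adduct_spec()] or cation symbol.
#' @param tol_ppm Search tolerance in parts per million. Default 20, the
#'   stated mass accuracy of the UV-LDI instrument class this targets.
#' @param bounds Named integer vector of per-element maximum counts.
#' @param dbe_filter If `TRUE`, drop candidates with negative or
#'   non-integer DBE (sensible for even-electron CHO neutrals).
#' @return data.frame with columns `formula`, `C`, `H`, `O` (and `N` if
#'   bounded), `mass`, `mz`, `ppm_error` (signed), `dbe`; sorted by
#'   `|ppm_error|`. Zero rows when nothing matches.
#' @examples
#' search_formulas(559.3396, "K", 20, c(C = 40, H = 80, O = 8))
#' @export
search_formulas <- function(mz, adduct, tol_ppm = 20,
                            bounds = c(C = 40, H = 80, O = 8),
                            dbe_filter = FALSE) {
  adduct <- as_adduct(adduct)
  stopifnot(tol_ppm > 0)
  if (mz < (adduct$cation_mass - ELECTRON_MASS) * (1 - tol_ppm * 1e-6)) {
    stop("observed m/z ", mz, " is not above the bare ", adduct$cation,
         " cation mass")
  }
  allowed <- c("C", "H", "O", "N")
  if (!all(names(bounds) %in% allowed)) {
    stop("bounds may cover only ", paste(allowed, collapse = ", "))
  }
  for (el in allowed) if (!el %in% names(bounds)) bounds[el] <- 0L
  n_combo <- prod(bounds + 1)
  if (n_combo > 1e7) {
    stop("bound box spans ", format(n_combo, big.mark = ","),
         " combinations (> 1e7); tighten the per-element bounds")
  }
  target <- mz - adduct$cation_mass + ELECTRON_MASS
  tol_da <- mz * tol_ppm * 1e-6
  mC <- ATOMIC_MASS[["C"]]; mH <- ATOMIC_MASS[["H"]]
  mO <- ATOMIC_MASS[["O"]]; mN <- ATOMIC_MASS[["N"]]

  rows <- vector("list", 0L)
  for (nN in 0:bounds[["N"]]) for (nO in 0:bounds[["O"]]) {
    base <- nN * mN + nO * mO
    for (nC in 0:bounds[["C"]]) {
      rem <- target - base - nC * mC
      # solve the H window analytically instead of looping over H
      h_lo <- max(0L, ceiling((rem - tol_da) / mH))
      h_hi <- min(bounds[["H"]], floor((rem + tol_da) / mH))
      if (h_hi < h_lo) next
      for (nH in h_lo:h_hi) {
        mass <- base + nC * mC + nH * mH
        err <- (mass - target) / mz * 1e6
        if (abs(err) > tol_ppm) next
        rows[[length(rows) + 1L]] <-
          data.frame(C = nC, H = nH, O = nO, N = nN, mass = mass,
                     ppm_error = err)
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(formula = character(), C = integer(), H = integer(),
                      O = integer(), N = integer(), mass = numeric(),
                      mz = numeric(), ppm_error = numeric(), dbe = numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  out$mz <- out$mass + adduct$cation_mass - ELECTRON_MASS
  out$dbe <- out$C - out$H / 2 + out$N / 2 + 1
  if (dbe_filter) {
    out <- out[out$dbe >= 0 & out$dbe == round(out$dbe), , drop = FALSE]
  }
  out$formula <- vapply(seq_len(nrow(out)), function(i) {
    format_formula(molecular_formula(c(C = out$C[i], H = out$H[i],
                                       O = out$O[i], N = out$N[i])))
  }, character(1))
  out <- out[order(abs(out$ppm_error), out$C, out$H, out$O, out$N), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("formula", "C", "H", "O", "N", "mass", "mz", "ppm_error", "dbe")]
}

#' Constraint box for acyl-composition enumeration
#'
#' Defaults encode the structural motif of the male-specific TAGs: one
#' long-chain fatty acyl of 16-18 carbons (0-2 double bonds) plus two
#' short-chain acyls of 2-5 carbons (0-1 double bonds) each.
#'
#' @param n_long,n_short Chain counts; must sum to 3.
#' @param long_carbons,long_db,short_carbons,short_db Inclusive integer
#'   ranges (any integer vector; the min/max span is used).
#' @return Object of class `composition_constraints`.
#' @export
composition_constraints <- function(n_long = 1L, long_carbons = 16:18,
                                    long_db = 0:2, n_short = 2L,
                                    short_carbons = 2:5, short_db = 0:1) {
  stopifnot(n_long + n_short == 3L,
            length(long_carbons) > 0L, length(long_db) > 0L,
            length(short_carbons) > 0L, length(short_db) > 0L)
  structure(
    list(n_long = as.integer(n_long),
         long_carbons = seq(min(long_carbons), max(long_carbons)),
         long_db = seq(min(long_db), max(long_db)),
         n_short = as.integer(n_short),
         short_carbons = seq(min(short_carbons), max(short_carbons)),
         short_db = seq(min(short_db), max(short_db))),
    class = "composition_constraints"
  )
}

# all valid (carbons, db) pairs for one chain under a range pair
chain_grid <- function(carbons, dbs) {
  g <- expand.grid(c = carbons, d = dbs)
  g[g$d <= g$c - 1L, , drop = FALSE]
}

#' Enumerate acyl-chain compositions matching a precursor m/z
#'
#' Exhaustively enumerates `{long, short, short}` acyl multisets inside the
#' constraint box, computes each candidate TAG's adduct m/z via
#' [tag_formula()] + [ion_mz()], and keeps candidates within `tol_ppm` of
#' the observed precursor. Isomeric acyls (branched tiglic vs a linear 5:1)
#' are mass-identical, so candidates carry no branch claim; branching is
#' resolvable only by orthogonal evidence such as GC-MS.
#'
#' @param mz Observed precursor m/z.
#' @param adduct [adduct_spec()] or cation symbol.
#' @param tol_ppm Tolerance in ppm (default 20).
#' @param constraints A [composition_constraints()].
#' @return data.frame, one candidate per row: `label` (e.g.
#'   `"18:1/5:1/5:1"`, long chain first, short chains in descending
#'   `carbons:db` order), `long_c`, `long_db`, `short1_c`, `short1_db`,
#'   `short2_c`, `short2_db`, `formula`, `mz`, `ppm_error`, `total_db`.
#'   Sorted by `|ppm_error|`, ties by fewer total double bonds, then label.
#' @export
enumerate_acyl_compositions <- function(mz, adduct, tol_ppm = 20,
                                        constraints = composition_constraints()) {
  adduct <- as_adduct(adduct)
  stopifnot(inherits(constraints, "composition_constraints"), tol_ppm > 0)
  longs <- chain_grid(constraints$long_carbons, constraints$long_db)
  shorts <- chain_grid(constraints$short_carbons, constraints$short_db)
  # unordered pairs of short chains (multisets)
  ns <- nrow(shorts)
  pair_idx <- which(upper.tri(matrix(0, ns, ns), diag = TRUE), arr.ind = TRUE)
  # vectorized mass screen over the full box; formulas are materialized
  # only for the hits (tag formula = glycerol + acids - 3 waters, i.e.
  # C(3+sum c) H(2+sum(2c-2d)) O6)
  grid <- expand.grid(li = seq_len(nrow(longs)), k = seq_len(nrow(pair_idx)))
  lc <- longs$c[grid$li]; ld <- longs$d[grid$li]
  s1 <- pair_idx[grid$k, 1]; s2 <- pair_idx[grid$k, 2]
  sc1 <- shorts$c[s1]; sd1 <- shorts$d[s1]
  sc2 <- shorts$c[s2]; sd2 <- shorts$d[s2]
  nC <- 3L + lc + sc1 + sc2
  nH <- 2L + 2L * (lc + sc1 + sc2) - 2L * (ld + sd1 + sd2)
  cand_mz <- nC * ATOMIC_MASS[["C"]] + nH * ATOMIC_MASS[["H"]] +
    6 * ATOMIC_MASS[["O"]] + adduct$cation_mass - ELECTRON_MASS
  err <- (cand_mz - mz) / mz * 1e6
  hits <- which(abs(err) <= tol_ppm)
  rows <- lapply(hits, function(h) {
    # short chains in descending c:d order for a canonical label
    sc <- data.frame(c = c(sc1[h], sc2[h]), d = c(sd1[h], sd2[h]))
    sc <- sc[order(-sc$c, -sc$d), ]
    data.frame(
      long_c = lc[h], long_db = ld[h],
      short1_c = sc$c[1], short1_db = sc$d[1],
      short2_c = sc$c[2], short2_db = sc$d[2],
      formula = format_formula(molecular_formula(
        c(C = nC[h], H = nH[h], O = 6L))),
      mz = cand_mz[h], ppm_error = err[h],
      total_db = ld[h] + sd1[h] + sd2[h]
    )
  })
  if (length(rows) == 0L) {
    out <- data.frame(label = character(), long_c = integer(),
                      long_db = integer(), short1_c = integer(),
                      short1_db = integer(), short2_c = integer(),
                      short2_db = integer(), formula = character(),
                      mz = numeric(), ppm_error = numeric(),
                      total_db = integer())
    return(out)
  }
  out <- do.call(rbind, rows)
  out$label <- paste0(out$long_c, ":", out$long_db, "/",
                      out$short1_c, ":", out$short1_db, "/",
                      out$short2_c, ":", out$short2_db)
  out <- out[order(abs(out$ppm_error), out$total_db, out$label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("label", "long_c", "long_db", "short1_c", "short1_db",
          "short2_c", "short2_db", "formula", "mz", "ppm_error",
          "total_db")]
}

#' Acyl list for one candidate row
#'
#' @param candidate One row of the [enumerate_acyl_compositions()] output.
#' @return List of three [fatty_acyl()] (long chain first).
#' @export
candidate_acyls <- function(candidate) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1L)
  list(fatty_acyl(candidate$long_c, candidate$long_db),
       fatty_acyl(candidate$short1_c, candidate$short1_db),
       fatty_acyl(candidate$short2_c, candidate$short2_db))
}
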