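# Shared fixtures and independent oracles for the test suite.
# Oracle arithmetic deliberately re-derives masses from its own constant
# table instead of calling the package's formula machinery.

oracle_mass <- c(C = 12.0, H = 1.00782503207, O = 15.9949146196,
                 Li = 7.0160034366, Na = 22.9897692809, K = 38.9637064864,
                 e = 0.00054857990)

# free-acid mass of an n:d chain, closed form
oracle_acid_mass <- function(c, d) {
  c * oracle_mass[["C"]] + (2 * c - 2 * d) * oracle_mass[["H"]] +
    2 * oracle_mass[["O"]]
}

# adduct m/z of a TAG with acyl chains (c1:d1, c2:d2, c3:d3)
oracle_tag_mz <- function(cs, ds, cation) {
  glycerol <- 3 * oracle_mass[["C"]] + 8 * oracle_mass[["H"]] +
    3 * oracle_mass[["O"]]
  water <- 2 * oracle_mass[["H"]] + oracle_mass[["O"]]
  neutral <- glycerol + sum(mapply(oracle_acid_mass, cs, ds)) - 3 * water
  neutral + oracle_mass[[cation]] - oracle_mass[["e"]]
}

# the worked example: the major male-specific TAG, oleoyl + two tiglates
example_tag <- function() {
  tag_structure(
    list(fatty_acyl(18, 1, db_positions = 9, db_geometries = "cis"),
         fatty_acyl(5, 1, db_positions = 2, db_geometries = "trans",
                    branched = TRUE),
         fatty_acyl(5, 1, db_positions = 2, db_geometries = "trans",
                    branched = TRUE)),
    sn_assignment = "long-chain-at-sn-1/3")
}

# canonical candidate label (long chain first, shorts descending) for a
# simulated structure's ground truth
truth_label <- function(t) {
  labs <- vapply(t$acyls, acyl_label, character(1))
  carbons <- vapply(t$acyls, function(a) a$n_carbons, integer(1))
  i <- which.max(carbons)
  paste(c(labs[i], sort(labs[-i], decreasing = TRUE)), collapse = "/")
}

sim_geometry_config <- function() {
  te_config(geometry_references = c(cis = 2, trans = 8))
}
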