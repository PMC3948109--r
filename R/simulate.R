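# Ground-truth generator: TAG structures, precursor/CID/OzID spectrum
# bundles with the field's abundance structure, and choice-assay counts.

#' Simulation configuration
#'
#' The generator's defaults state the world the pipeline is tested in:
#' * structures are drawn uniformly from the one-long-two-short constraint
#'   box; long-chain double bonds sit at n-9/n-7 (monoenes) or n-6,9
#'   (dienes); short-chain double bonds sit at n-2 (the tiglate motif);
#' * the long chain occupies sn-2 with probability `p_long_sn2` (0.2 —
#'   outer positions dominate in the observed TAGs), long-chain double
#'   bonds are cis with probability `p_cis` (0.9), short-chain n-2 bonds
#'   are trans (tiglic geometry);
#' * CID: the metalated-acid loss is the major channel (relative intensity
#'   1.0) and the neutral-acid loss minor (0.4); losses of the sn-2
#'   substituent are suppressed by `sn2_suppression` (0.3x);
#' * OzID: one aldehyde/Criegee pair per double-bond position with
#'   aldehyde:Criegee ratio 2 for cis and 8 for trans bonds
#'   (`geometry_ratios` — a calibration choice, well separated under the
#'   default 50% matching tolerance);
#' * noise: `noise_peaks` (5) spurious peaks per product-ion scan, uniform
#'   in m/z, log-normal intensities capped below the median true-peak
#'   intensity; true product-ion m/z are jittered uniformly within
#'   `mz_jitter` (0.05 Da, well under half the 0.3 Da match tolerance);
#'   the precursor m/z instead carries a ppm-scale error
#'   (`precursor_ppm_sd`, 5 ppm) reflecting the accurate-mass survey
#'   instrument;
#' * intensities carry multiplicative log-normal noise of
#'   `intensity_cv` (0.1).
#'
#' @param seed Integer seed; fixes all randomness of
#'   [simulate_dataset()] end-to-end.
#' @param ... Named overrides of the defaults described above.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    constraints = composition_constraints(),
    long_mono_positions = c(`7` = 0.5, `9` = 0.5),
    long_diene_positions = c(6L, 9L),
    p_cis = 0.9,
    p_long_sn2 = 0.2,
    sn2_suppression = 0.3,
    channel_intensity = c(metalated = 1.0, neutral = 0.4),
    base_intensity = 1000,
    geometry_ratios = c(cis = 2, trans = 8),
    ozid_aldehyde_intensity = 400,
    noise_peaks = 5L,
    mz_jitter = 0.05,
    precursor_ppm_sd = 5,
    intensity_cv = 0.1
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0L) stop("unknown config key(s): ",
                               paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, overrides)
  }
  if (cfg$mz_jitter > 0.3 / 2) {
    warning("mz_jitter exceeds half the default 0.3 Da match tolerance; ",
            "round trips are not guaranteed")
  }
  structure(cfg, class = "sim_config")
}

#' Sample a TAG structure with known ground truth
#'
#' Draws one structure from the constraint box: long chain uniform over its
#' carbon/double-bond ranges, two short chains uniform over theirs (a
#' double bond requires at least 3 carbons so the n-2 position exists;
#' 5-carbon monounsaturated short chains are marked branched, the tiglate).
#' Uses the current RNG state: seed at the call site, or use
#' [simulate_dataset()] for end-to-end seeding.
#'
#' @param config A [simulation_config()].
#' @return A [tag_structure()] with positions and geometries filled in and
#'   slot 2 holding the sn-2 substituent; `sn_assignment` is
#'   `"long-chain-at-sn-2"` or `"long-chain-at-sn-1/3"`.
#' @export
sample_structure <- function(config = simulation_config()) {
  cs <- config$constraints
  long_c <- sample_one(cs$long_carbons)
  long_d <- sample_one(cs$long_db)
  long_pos <- if (long_d == 1L) {
    as.integer(sample(names(config$long_mono_positions), 1L,
                      prob = config$long_mono_positions))
  } else if (long_d == 2L) {
    config$long_diene_positions
  } else integer(0)
  long_geo <- if (long_d > 0L) {
    rep(if (stats::runif(1) < config$p_cis) "cis" else "trans", long_d)
  } else NULL
  long <- fatty_acyl(long_c, long_d,
                     db_positions = if (long_d > 0L) long_pos else NULL,
                     db_geometries = long_geo)
  short <- replicate(2L, {
    c_ <- sample_one(cs$short_carbons)
    d_ <- sample_one(cs$short_db)
    if (c_ < 3L) d_ <- 0L  # n-2 needs at least 3 carbons
    fatty_acyl(c_, d_,
               db_positions = if (d_ > 0L) 2L else NULL,
               db_geometries = if (d_ > 0L) "trans" else NULL,
               branched = (c_ == 5L && d_ == 1L))
  }, simplify = FALSE)
  if (stats::runif(1) < config$p_long_sn2) {
    tag_structure(list(short[[1]], long, short[[2]]),
                  sn_assignment = "long-chain-at-sn-2")
  } else {
    tag_structure(list(long, short[[1]], short[[2]]),
                  sn_assignment = "long-chain-at-sn-1/3")
  }
}

sample_one <- function(v) if (length(v) == 1L) v else sample(v, 1L)

#' Simulate a precursor/CID/OzID spectrum bundle for a TAG
#'
#' Emits every predicted CID fragment (both channels per distinct acyl,
#' losses of the sn-2 substituent scaled by the suppression factor) and
#' every OzID aldehyde/Criegee pair (ratio set by the bond's geometry),
#' plus spurious noise peaks. True product-ion m/z are jittered uniformly
#' within `config$mz_jitter`; the precursor peak carries a ppm-scale error.
#' With `noise_peaks = 0`, `mz_jitter = 0`, `precursor_ppm_sd = 0` and
#' `intensity_cv = 0` the peak sets equal the predicted sets exactly.
#'
#' @param t A [tag_structure()] (slot 2 = sn-2 when resolved).
#' @param adduct [adduct_spec()] or cation symbol (default `"Na"`).
#' @param config A [simulation_config()].
#' @return List of class `spectrum_bundle`: `precursor`, `cid`, `ozid`
#'   ([spectrum()] objects), `truth` (the structure, adduct, and exact
#'   precursor m/z).
#' @export
simulate_spectra <- function(t, adduct = "Na",
                             config = simulation_config()) {
  stopifnot(inherits(t, "tag_structure"))
  adduct <- as_adduct(adduct)
  exact_mz <- ion_mz(tag_formula(t), adduct)
  obs_prec <- exact_mz * (1 + stats::runif(1, -1, 1) *
                            config$precursor_ppm_sd * 1e-6)

  jit <- function(mz) mz + stats::runif(length(mz), -1, 1) * config$mz_jitter
  wobble <- function(x) {
    if (config$intensity_cv <= 0) return(x)
    x * stats::rlnorm(length(x), meanlog = 0, sdlog = config$intensity_cv)
  }

  # ---- CID: per distinct acyl, intensity suppressed when the acyl sits
  # at sn-2 (slot 2)
  frags <- predict_cid_fragments(t$acyls, exact_mz, adduct)
  labels <- vapply(t$acyls, acyl_label, character(1))
  sn2_label <- if (t$sn_assignment != "unresolved") labels[2] else NA
  chan <- config$channel_intensity
  cid_int <- config$base_intensity *
    chan[ifelse(frags$channel == "metalated-acid-loss",
                "metalated", "neutral")]
  if (!is.na(sn2_label)) {
    cid_int[frags$acyl == sn2_label] <-
      cid_int[frags$acyl == sn2_label] * config$sn2_suppression
  }
  cid_mz <- jit(frags$mz)
  cid_int <- wobble(as.numeric(cid_int))

  # ---- OzID: one aldehyde/Criegee pair per distinct position; geometry
  # sets the aldehyde:Criegee ratio
  pos <- integer(0); geo <- character(0)
  for (a in t$acyls) {
    if (!is.null(a$db_positions)) {
      g <- if (is.null(a$db_geometries)) rep("unknown", length(a$db_positions))
           else a$db_geometries
      pos <- c(pos, a$db_positions); geo <- c(geo, g)
    }
  }
  keep <- !duplicated(pos)
  pos <- pos[keep]; geo <- geo[keep]
  if (length(pos) > 0L) {
    prods <- predict_ozid_products(exact_mz, pos)
    geo <- geo[match(prods$n_x, pos)]
    ratio <- config$geometry_ratios[ifelse(geo %in%
                                             names(config$geometry_ratios),
                                           geo, "cis")]
    ald_int <- rep(config$ozid_aldehyde_intensity, nrow(prods))
    crg_int <- ald_int / as.numeric(ratio)
    ozid_mz <- jit(c(prods$aldehyde_mz, prods$criegee_mz))
    ozid_int <- wobble(c(ald_int, crg_int))
  } else {
    ozid_mz <- numeric(0); ozid_int <- numeric(0)
  }

  # ---- noise: uniform m/z across the scan range, log-normal intensities
  # capped below the median true-peak intensity
  add_noise <- function(mz, int) {
    k <- config$noise_peaks
    if (k <= 0L) return(list(mz = mz, int = int))
    med <- if (length(int) > 0L) stats::median(int) else config$base_intensity
    nmz <- stats::runif(k, 100, exact_mz + 20)
    nint <- pmin(stats::rlnorm(k, meanlog = log(med / 4), sdlog = 0.5),
                 med * 0.95)
    list(mz = c(mz, nmz), int = c(int, nint))
  }
  cid_pk <- add_noise(cid_mz, cid_int)
  ozid_pk <- add_noise(ozid_mz, ozid_int)

  structure(list(
    precursor = spectrum(obs_prec, config$base_intensity,
                         stage = "precursor", adduct = adduct),
    cid = spectrum(cid_pk$mz, cid_pk$int, stage = "CID", adduct = adduct,
                   precursor_mz = obs_prec),
    ozid = spectrum(ozid_pk$mz, ozid_pk$int, stage = "OzID",
                    adduct = adduct, precursor_mz = obs_prec),
    truth = list(structure = t, adduct = adduct$cation,
                 exact_precursor_mz = exact_mz,
                 db_positions = sort(pos))
  ), class = "spectrum_bundle")
}

#' Simulate a seeded dataset of spectrum bundles
#'
#' Sets the RNG once from `config$seed` and draws `n` structures plus their
#' spectrum bundles, so the whole dataset is reproducible bit-for-bit from
#' the seed.
#'
#' @param n Number of TAGs.
#' @param adduct Cation for all bundles (default `"Na"`).
#' @param config A [simulation_config()].
#' @return List of `n` `spectrum_bundle` objects.
#' @export
simulate_dataset <- function(n, adduct = "Na",
                             config = simulation_config()) {
  set.seed(config$seed)
  replicate(n, simulate_spectra(sample_structure(config), adduct, config),
            simplify = FALSE)
}

#' Simulate a mate-choice assay
#'
#' Each of `n` trials independently ends in choice A (probability
#' `p_choice_a`), no choice (`p_no_choice`), or choice B (the remainder).
#'
#' @param n Number of trials.
#' @param p_choice_a Probability of choosing option A.
#' @param p_no_choice Probability of no choice.
#' @param seed Optional integer seed.
#' @return A [choice_assay()].
#' @export
simulate_choice_assay <- function(n, p_choice_a, p_no_choice = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  if (p_choice_a < 0 || p_choice_a > 1 || p_no_choice < 0 ||
      p_no_choice > 1 || p_choice_a + p_no_choice > 1) {
    stop("probabilities must lie in [0, 1] and sum to at most 1")
  }
  counts <- stats::rmultinom(1, n, c(p_choice_a,
                                     1 - p_choice_a - p_no_choice,
                                     p_no_choice))
  choice_assay(counts[1], counts[2], counts[3])
}
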