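# OzID product-ion prediction, double-bond localization, and cis/trans
# geometry scoring from aldehyde:Criegee abundance ratios.

#' Predict OzID aldehyde/Criegee product pairs
#'
#' Gas-phase ozonolysis of a C=C bond at position n-x (x counted from the
#' methyl terminus) cleaves off the methyl-side fragment, leaving an
#' aldehyde ion at `precursor - x*CH2 + O` and a Criegee ion one oxygen
#' heavier. For the branched tiglate the n-2 neutral loss is C2H4 (the
#' branch methyl stays on the charged fragment), which is the same
#' arithmetic.
#'
#' @param precursor_mz Precursor adduct-ion m/z.
#' @param positions Integer vector of n-x positions, each `x >= 2`.
#' @return data.frame: `n_x`, `aldehyde_mz`, `criegee_mz`, one row per
#'   position, sorted by `n_x`.
#' @examples
#' predict_ozid_products(543.36561, c(2, 7, 9))
#' @export
predict_ozid_products <- function(precursor_mz, positions) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            precursor_mz > 0)
  positions <- as.integer(positions)
  if (length(positions) == 0L) {
    return(data.frame(n_x = integer(), aldehyde_mz = numeric(),
                      criegee_mz = numeric()))
  }
  if (any(positions < 2L)) {
    stop("n-x positions require x >= 2 (no methyl-side carbons to cleave ",
         "for x < 2)")
  }
  positions <- sort(unique(positions))
  ald <- precursor_mz - positions * CH2_MASS + O_MASS
  if (any(ald <= 0)) stop("position too deep: product m/z would be <= 0")
  data.frame(n_x = positions, aldehyde_mz = ald, criegee_mz = ald + O_MASS)
}

#' Localize double bonds from an OzID spectrum
#'
#' Scans candidate n-x positions and matches their predicted aldehyde and
#' Criegee ions against the observed peaks. A position is `"supported"` when
#' its aldehyde ion matches and `"confirmed"` when both ions of the pair
#' match.
#'
#' @param spec A [spectrum()] with `stage = "OzID"`.
#' @param precursor_mz Precursor m/z; defaults to `spec$precursor_mz`.
#' @param candidate_positions Integer vector of n-x positions to test
#'   (default 2:16, covering chains up to 17 carbons past the terminus).
#' @param tol_mz Match tolerance in Da (default 0.3, ion-trap resolution).
#' @return data.frame of class `ozid_localization`: `n_x`, `status`
#'   (`"confirmed"`/`"supported"`), predicted and matched m/z and
#'   intensities for both ions. Zero rows (attribute `undetermined = TRUE`)
#'   when nothing matches.
#' @export
localize_double_bonds <- function(spec, precursor_mz = NULL,
                                  candidate_positions = 2:16,
                                  tol_mz = 0.3) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$stage != "OzID") {
    stop("spectrum stage must be OzID, got ", spec$stage)
  }
  if (is.null(precursor_mz)) precursor_mz <- spec$precursor_mz
  if (is.null(precursor_mz)) stop("precursor_mz is required")
  pred <- predict_ozid_products(precursor_mz, candidate_positions)
  pred <- pred[pred$aldehyde_mz > 0, , drop = FALSE]
  rows <- vector("list", 0L)
  if (n_peaks(spec) > 0L) {
    for (i in seq_len(nrow(pred))) {
      ald <- match_peak(spec, pred$aldehyde_mz[i], tol_mz)
      if (is.null(ald)) next
      crg <- match_peak(spec, pred$criegee_mz[i], tol_mz)
      rows[[length(rows) + 1L]] <- data.frame(
        n_x = pred$n_x[i],
        status = if (is.null(crg)) "supported" else "confirmed",
        aldehyde_mz = pred$aldehyde_mz[i],
        aldehyde_matched_mz = ald$mz,
        aldehyde_intensity = ald$intensity,
        criegee_mz = pred$criegee_mz[i],
        criegee_matched_mz = if (is.null(crg)) NA_real_ else crg$mz,
        criegee_intensity = if (is.null(crg)) NA_real_ else crg$intensity
      )
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(n_x = integer(), status = character(),
               aldehyde_mz = numeric(), aldehyde_matched_mz = numeric(),
               aldehyde_intensity = numeric(), criegee_mz = numeric(),
               criegee_matched_mz = numeric(), criegee_intensity = numeric())
  }
  rownames(out) <- NULL
  attr(out, "undetermined") <- nrow(out) == 0L
  class(out) <- c("ozid_localization", class(out))
  out
}

#' Score cis/trans double-bond geometry from aldehyde:Criegee ratios
#'
#' cis- and trans-alkenes react with ozone at different rates and partition
#' differently between the aldehyde and Criegee channels, so the observed
#' aldehyde:Criegee intensity ratio, compared against reference ratios
#' calibrated on synthetic standards, scores the geometry. No literature
#' value exists for the ratios themselves: references are user-supplied
#' calibration (see [simulation_config()] for the defaults the synthetic
#' world uses).
#'
#' @param pairs Matched pairs: an [localize_double_bonds()] result (only
#'   `"confirmed"` rows are scored).
#' @param references Named numeric vector of reference aldehyde:Criegee
#'   ratios, e.g. `c(cis = 2, trans = 8)`. `NULL` -> every call is
#'   `"undetermined"`.
#' @param rel_tol Relative tolerance around each reference (default 0.5,
#'   i.e. a match when `|observed/reference - 1| <= 0.5`).
#' @return data.frame: `n_x`, `observed_ratio`, `call` (`"cis"`,
#'   `"trans"`, or `"undetermined"`), `reference_ratio`, `reason`.
#' @export
classify_geometry <- function(pairs, references = NULL, rel_tol = 0.5) {
  stopifnot(is.data.frame(pairs))
  pairs <- pairs[pairs$status == "confirmed", , drop = FALSE]
  out <- data.frame(n_x = integer(), observed_ratio = numeric(),
                    call = character(), reference_ratio = numeric(),
                    reason = character())
  for (i in seq_len(nrow(pairs))) {
    ald <- pairs$aldehyde_intensity[i]
    crg <- pairs$criegee_intensity[i]
    if (is.na(crg) || crg <= 0) {
      out <- rbind(out, data.frame(
        n_x = pairs$n_x[i], observed_ratio = NA_real_,
        call = "undetermined", reference_ratio = NA_real_,
        reason = "Criegee intensity zero or missing: ratio undefined"))
      next
    }
    ratio <- ald / crg
    if (is.null(references) || length(references) == 0L) {
      out <- rbind(out, data.frame(
        n_x = pairs$n_x[i], observed_ratio = ratio, call = "undetermined",
        reference_ratio = NA_real_, reason = "no reference ratios configured"))
      next
    }
    hits <- which(abs(ratio / references - 1) <= rel_tol)
    if (length(hits) == 1L) {
      out <- rbind(out, data.frame(
        n_x = pairs$n_x[i], observed_ratio = ratio,
        call = names(references)[hits],
        reference_ratio = references[[hits]],
        reason = sprintf("ratio %.2f within %.0f%% of %s reference %.2f",
                         ratio, rel_tol * 100, names(references)[hits],
                         references[[hits]])))
    } else {
      out <- rbind(out, data.frame(
        n_x = pairs$n_x[i], observed_ratio = ratio, call = "undetermined",
        reference_ratio = NA_real_,
        reason = if (length(hits) == 0L) "ratio matches no reference"
                 else "ratio matches multiple references"))
    }
  }
  rownames(out) <- NULL
  out
}
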