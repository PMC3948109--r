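# CID product-ion prediction for alkali-metal TAG adducts, spectrum
# annotation, and sn-position inference from relative loss abundances.

#' Predict CID product ions for a candidate acyl composition
#'
#' Low-energy CID of a metal-adducted TAG ejects each acyl substituent
#' through two channels:
#' * `neutral-acid-loss`: loss of the free fatty acid
#'   (`m/z = precursor - acid mass`);
#' * `metalated-acid-loss`: loss of the metal carboxylate salt
#'   (`m/z = precursor - acid mass + H - cation`, atom masses) — the
#'   remaining fragment is protonated rather than metalated.
#'
#' Duplicate acyls collapse to a single fragment pair.
#'
#' @param acyls List of [fatty_acyl()] (or a [tag_structure()], or one row
#'   of [enumerate_acyl_compositions()] output).
#' @param precursor_mz Observed/selected precursor m/z; must agree with the
#'   candidate composition within `tol_ppm`.
#' @param adduct [adduct_spec()] or cation symbol.
#' @param tol_ppm Consistency check tolerance (default 20 ppm).
#' @return data.frame: `acyl` (label), `channel`, `mz`, one row per
#'   distinct acyl x channel, ordered by acyl label then channel.
#' @examples
#' acyls <- list(fatty_acyl(18, 1), fatty_acyl(5, 1), fatty_acyl(5, 1))
#' predict_cid_fragments(acyls, 543.36561, "Na")
#' @export
predict_cid_fragments <- function(acyls, precursor_mz, adduct,
                                  tol_ppm = 20) {
  adduct <- as_adduct(adduct)
  acyls <- as_acyl_list(acyls)
  theo <- ion_mz(tag_formula(acyls), adduct)
  ppm <- (precursor_mz - theo) / theo * 1e6
  if (abs(ppm) > tol_ppm) {
    stop("precursor m/z ", sprintf("%.5f", precursor_mz),
         " is inconsistent with the candidate composition (",
         sprintf("%+.1f", ppm), " ppm vs calculated ",
         sprintf("%.5f", theo), ")")
  }
  labels <- vapply(acyls, acyl_label, character(1))
  keep <- !duplicated(labels)
  acyls <- acyls[keep]; labels <- labels[keep]
  rows <- lapply(seq_along(acyls), function(i) {
    acid <- monoisotopic_mass(acyl_formula(acyls[[i]]))
    data.frame(
      acyl = labels[i],
      channel = c("neutral-acid-loss", "metalated-acid-loss"),
      mz = c(precursor_mz - acid,
             precursor_mz - acid + ATOMIC_MASS[["H"]] - adduct$cation_mass)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$acyl, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_acyl_list <- function(x) {
  if (inherits(x, "tag_structure")) return(x$acyls)
  if (is.data.frame(x)) return(candidate_acyls(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fatty_acyl"))) {
    return(x)
  }
  stop("expected a list of fatty_acyl, a tag_structure, or a candidate row")
}

#' Annotate a CID spectrum against candidate compositions
#'
#' For every candidate, predicts the fragment pairs and matches them against
#' the observed peaks. Per distinct acyl, matching both channels scores 1.0
#' and one channel 0.5 (paired losses are the diagnostic signature); the
#' candidate score is the mean over its distinct acyls, so it lies in
#' `[0, 1]`.
#'
#' @param spec A [spectrum()] with `stage = "CID"`.
#' @param candidates Output of [enumerate_acyl_compositions()] (or a
#'   compatible data.frame).
#' @param adduct [adduct_spec()] or cation symbol.
#' @param tol_mz Fragment match tolerance in Da; default 0.3 Da
#'   (unit-resolution ion trap), deliberately looser than the ppm-scale
#'   precursor tolerance.
#' @param precursor_mz Precursor m/z; defaults to `spec$precursor_mz`.
#' @return List of class `cid_annotation`:
#'   * `ranking`: `candidates` with a `cid_score` column, re-sorted by
#'     score (desc), then `|ppm_error|`, total double bonds, label;
#'   * `matches`: per ranked candidate, the predicted-fragment data.frame
#'     with `matched_mz` / `matched_intensity` (NA when unmatched);
#'   * `unmatched_peaks`: observed peaks not claimed by the top candidate;
#'   * `flags`: character vector (e.g. `"no evidence"` for an empty
#'     spectrum).
#' @export
annotate_cid <- function(spec, candidates, adduct, tol_mz = 0.3,
                         precursor_mz = NULL) {
  stopifnot(inherits(spec, "spectrum"))
  if (spec$stage != "CID") stop("spectrum stage must be CID, got ", spec$stage)
  if (nrow(candidates) == 0L) stop("candidates must be non-empty")
  if (is.null(precursor_mz)) precursor_mz <- spec$precursor_mz
  if (is.null(precursor_mz)) stop("precursor_mz is required")
  adduct <- as_adduct(adduct)
  flags <- character()
  if (n_peaks(spec) == 0L) flags <- "no evidence"

  matches <- vector("list", nrow(candidates))
  scores <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    frags <- predict_cid_fragments(candidates[i, , drop = FALSE],
                                   precursor_mz, adduct)
    frags$matched_mz <- NA_real_
    frags$matched_intensity <- NA_real_
    if (n_peaks(spec) > 0L) {
      for (j in seq_len(nrow(frags))) {
        hit <- match_peak(spec, frags$mz[j], tol_mz)
        if (!is.null(hit)) {
          frags$matched_mz[j] <- hit$mz
          frags$matched_intensity[j] <- hit$intensity
        }
      }
    }
    per_acyl <- tapply(!is.na(frags$matched_mz), frags$acyl, sum)
    scores[i] <- mean(ifelse(per_acyl >= 2, 1, ifelse(per_acyl == 1, 0.5, 0)))
    matches[[i]] <- frags
  }
  ranking <- candidates
  ranking$cid_score <- scores
  ord <- order(-ranking$cid_score, abs(ranking$ppm_error),
               ranking$total_db, ranking$label)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  matches <- matches[ord]
  names(matches) <- ranking$label

  unmatched <- spec$peaks
  if (nrow(ranking) > 0L && n_peaks(spec) > 0L) {
    top <- matches[[1]]
    claimed <- top$matched_mz[!is.na(top$matched_mz)]
    unmatched <- spec$peaks[!spec$peaks$mz %in% claimed, , drop = FALSE]
  }
  structure(list(ranking = ranking, matches = matches,
                 unmatched_peaks = unmatched, flags = flags,
                 precursor_mz = precursor_mz, tol_mz = tol_mz),
            class = "cid_annotation")
}

#' @export
print.cid_annotation <- function(x, ...) {
  cat("<cid_annotation> ", nrow(x$ranking), " candidate(s)\n", sep = "")
  print(utils::head(x$ranking[, c("label", "cid_score", "ppm_error")], 5))
  invisible(x)
}

#' Infer glycerol backbone (sn) positions from CID loss abundances
#'
#' Fragments reflecting loss of the sn-2 substituent (middle of the glycerol
#' backbone) are less abundant than losses from the outer sn-1/sn-3
#' positions. Per distinct acyl, the mean matched-loss intensity is taken
#' relative to the base (most intense) matched fragment; the acyl with the
#' smallest relative abundance is proposed for sn-2 when its abundance falls
#' below `ratio` times the smallest of the other acyls' abundances.
#' sn-1 vs sn-3 are never distinguished.
#'
#' @param annotated Either a `cid_annotation` (its top candidate is used) or
#'   a matched-fragment data.frame as stored in `annotation$matches`.
#' @param long_acyl Label of the long-chain acyl (e.g. `"18:1"`); defaults
#'   to the acyl with the most carbons among those present.
#' @param ratio sn-2 decision ratio (default 0.5). The abundance rule in the
#'   literature is qualitative; 0.5 is this package's configurable default
#'   and is echoed in every report.
#' @return List of class `sn_evidence`: `per_acyl` (named mean relative
#'   abundances), `assignment` (one of `"long-chain-at-sn-1/3"`,
#'   `"long-chain-at-sn-2"`, `"unresolved"`), `proposed_sn2` (acyl label or
#'   NA), `confidence_ratio` (min abundance over next-smallest),
#'   `decision_ratio`, `reason`.
#' @export
infer_sn_positions <- function(annotated, long_acyl = NULL, ratio = 0.5) {
  frags <- if (inherits(annotated, "cid_annotation")) {
    if (length(annotated$matches) == 0L) stop("annotation has no candidates")
    annotated$matches[[1]]
  } else {
    annotated
  }
  stopifnot(is.data.frame(frags),
            all(c("acyl", "matched_intensity") %in% names(frags)))
  res <- function(assignment, proposed, conf, reason, per_acyl = NULL) {
    structure(list(per_acyl = per_acyl, assignment = assignment,
                   proposed_sn2 = proposed, confidence_ratio = conf,
                   decision_ratio = ratio, reason = reason),
              class = "sn_evidence")
  }
  matched <- frags[!is.na(frags$matched_intensity), , drop = FALSE]
  missing <- setdiff(unique(frags$acyl), unique(matched$acyl))
  if (length(missing) > 0L) {
    return(res("unresolved", NA_character_, NA_real_,
               paste0("no matched fragments for acyl(s): ",
                      paste(missing, collapse = ", "))))
  }
  base <- max(matched$matched_intensity)
  if (base <= 0) {
    return(res("unresolved", NA_character_, NA_real_,
               "all matched intensities are zero"))
  }
  per_acyl <- tapply(matched$matched_intensity / base, matched$acyl, mean)
  per_acyl <- stats::setNames(as.numeric(per_acyl), names(per_acyl))
  if (length(per_acyl) < 2L) {
    return(res("unresolved", NA_character_, NA_real_,
               "single distinct acyl: loss abundances carry no positional contrast",
               per_acyl))
  }
  if (is.null(long_acyl)) {
    carbons <- as.integer(sub(":.*$", "", names(per_acyl)))
    long_acyl <- names(per_acyl)[which.max(carbons)]
  }
  lo <- which.min(per_acyl)
  others_min <- min(per_acyl[-lo])
  conf <- per_acyl[[lo]] / others_min
  if (per_acyl[[lo]] < ratio * others_min) {
    proposed <- names(per_acyl)[lo]
    assignment <- if (proposed == long_acyl) "long-chain-at-sn-2"
                  else "long-chain-at-sn-1/3"
    return(res(assignment, proposed, conf,
               paste0("loss of ", proposed, " suppressed ",
                      sprintf("%.2f", conf), "-fold vs others"),
               per_acyl))
  }
  res("unresolved", NA_character_, conf,
      paste0("no acyl suppressed below ", ratio,
             " x the others (min ratio ", sprintf("%.2f", conf), ")"),
      per_acyl)
}

#' @export
print.sn_evidence <- function(x, ...) {
  cat("<sn_evidence> ", x$assignment, " (", x$reason, ")\n", sep = "")
  invisible(x)
}
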