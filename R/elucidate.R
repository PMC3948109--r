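# Orchestration: composition search -> CID annotation -> sn inference ->
# OzID localization -> geometry scoring, in one evidence-carrying report.

#' Elucidate a TAG structure from precursor, CID, and OzID evidence
#'
#' Stages degrade gracefully: with only a precursor, the report carries
#' composition candidates and `"undetermined"` structure fields; adding a
#' CID spectrum ranks candidates and infers backbone positions; adding an
#' OzID spectrum localizes double bonds and, when reference ratios are
#' configured, scores geometry. Candidate ranking uses only the composition
#' and CID stages (score desc, then `|ppm_error|`, then fewer double
#' bonds), so supplying OzID evidence can decorate but never demote a
#' candidate. Conflicts (e.g. a localized position impossible for every
#' acyl of the top candidate) are surfaced as flags, never silently
#' resolved.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param adduct [adduct_spec()] or cation symbol.
#' @param cid_spectrum Optional [spectrum()] with stage `"CID"`.
#' @param ozid_spectrum Optional [spectrum()] with stage `"OzID"`.
#' @param config A [te_config()].
#' @return Object of class `elucidation_report` with fields
#'   `precursor_mz`, `adduct`, `candidates` (ranked data.frame, with
#'   `cid_score` when CID evidence exists), `cid` (annotation or NULL),
#'   `sn` (sn_evidence or `"undetermined"`), `positions` (localization
#'   with per-position acyl attribution, or `"undetermined"`), `geometry`
#'   (calls or `"undetermined"`), `flags`, `nearest_miss_ppm` (when no
#'   candidate fits), `config`, `config_hash`.
#' @export
elucidate <- function(precursor_mz, adduct, cid_spectrum = NULL,
                      ozid_spectrum = NULL, config = te_config()) {
  stopifnot(inherits(config, "te_config"))
  adduct <- as_adduct(adduct)
  flags <- character()

  candidates <- enumerate_acyl_compositions(
    precursor_mz, adduct, tol_ppm = config$tol_ppm,
    constraints = config$constraints)
  nearest_miss <- NA_real_
  if (nrow(candidates) == 0L) {
    wide <- enumerate_acyl_compositions(precursor_mz, adduct,
                                        tol_ppm = 1e6,
                                        constraints = config$constraints)
    if (nrow(wide) > 0L) nearest_miss <- wide$ppm_error[1]
    flags <- c(flags, "no composition candidate within tolerance")
  }

  cid_ann <- NULL
  sn <- "undetermined"
  if (!is.null(cid_spectrum) && nrow(candidates) > 0L) {
    cid_ann <- annotate_cid(cid_spectrum, candidates, adduct,
                            tol_mz = config$tol_mz,
                            precursor_mz = precursor_mz)
    candidates <- cid_ann$ranking
    flags <- c(flags, cid_ann$flags)
    sn <- tryCatch(
      infer_sn_positions(cid_ann, ratio = config$sn_ratio),
      error = function(e) "undetermined")
    # report isobaric co-candidates at the top score rather than merging
    if (nrow(candidates) > 1L &&
        sum(candidates$cid_score == candidates$cid_score[1]) > 1L) {
      flags <- c(flags, "isobaric co-candidates share the top CID score")
    }
  }

  positions <- "undetermined"
  geometry <- "undetermined"
  if (!is.null(ozid_spectrum)) {
    loc <- localize_double_bonds(ozid_spectrum, precursor_mz = precursor_mz,
                                 candidate_positions = config$candidate_positions,
                                 tol_mz = config$tol_mz)
    if (attr(loc, "undetermined")) {
      flags <- c(flags, "OzID: no double-bond position supported")
    } else {
      if (nrow(candidates) > 0L) {
        attribution <- attribute_positions(
          candidate_acyls(candidates[1, , drop = FALSE]), loc$n_x)
        loc$attributed_to <- attribution$acyls
        loc$attribution_ambiguous <- attribution$ambiguous
        if (any(attribution$conflict)) {
          flags <- c(flags,
                     paste0("OzID position(s) impossible for the top ",
                            "candidate: n-",
                            paste(loc$n_x[attribution$conflict],
                                  collapse = ", n-")))
        }
        if (any(attribution$isomer_mixture)) {
          flags <- c(flags, "positional isomer mixture on one acyl")
        }
      }
      positions <- loc
      geometry <- classify_geometry(loc,
                                    references = config$geometry_references,
                                    rel_tol = config$geometry_rel_tol)
    }
  }

  structure(
    list(precursor_mz = precursor_mz, adduct = adduct,
         candidates = candidates, cid = cid_ann, sn = sn,
         positions = positions, geometry = geometry,
         flags = unique(flags), nearest_miss_ppm = nearest_miss,
         config = config, config_hash = config_hash(config)),
    class = "elucidation_report"
  )
}

# Attribute each localized n-x position to candidate acyls. A position is
# feasible for an acyl when the acyl is unsaturated and 2 <= x <= n-1.
# Among feasible acyls the shortest chain claims the position (its double
# bond has the fewest places to be); equal-length distinct acyls are
# flagged ambiguous; an acyl claiming more positions than it has double
# bonds indicates a positional isomer mixture.
attribute_positions <- function(acyls, positions) {
  labels <- vapply(acyls, acyl_label, character(1))
  keep <- !duplicated(labels)
  acyls <- acyls[keep]; labels <- labels[keep]
  n <- vapply(acyls, function(a) a$n_carbons, integer(1))
  d <- vapply(acyls, function(a) a$n_double_bonds, integer(1))
  out <- data.frame(n_x = positions, acyls = NA_character_,
                    ambiguous = FALSE, conflict = FALSE,
                    isomer_mixture = FALSE)
  claimed <- stats::setNames(integer(length(labels)), labels)
  for (i in seq_along(positions)) {
    x <- positions[i]
    feas <- which(d >= 1L & x >= 2L & x <= n - 1L)
    if (length(feas) == 0L) {
      out$conflict[i] <- TRUE
      next
    }
    best <- feas[n[feas] == min(n[feas])]
    out$acyls[i] <- paste(labels[best], collapse = ",")
    out$ambiguous[i] <- length(unique(labels[best])) > 1L
    claimed[labels[best]] <- claimed[labels[best]] + 1L
  }
  over <- names(claimed)[claimed > d[match(names(claimed), labels)]]
  if (length(over) > 0L) {
    out$isomer_mixture <- vapply(strsplit(out$acyls, ","), function(a) {
      any(a %in% over)
    }, logical(1))
    out$isomer_mixture[is.na(out$acyls)] <- FALSE
  }
  out
}

#' @export
print.elucidation_report <- function(x, ...) {
  cat("<elucidation_report> precursor m/z ", sprintf("%.4f", x$precursor_mz),
      " [M+", x$adduct$cation, "]+, config ", x$config_hash, "\n", sep = "")
  if (nrow(x$candidates) == 0L) {
    cat("  no composition candidate within tolerance")
    if (!is.na(x$nearest_miss_ppm)) {
      cat(" (nearest miss ", sprintf("%+.1f", x$nearest_miss_ppm), " ppm)",
          sep = "")
    }
    cat("\n")
  } else {
    cols <- intersect(c("label", "ppm_error", "cid_score"),
                      names(x$candidates))
    cat("  top candidates:\n")
    print(utils::head(x$candidates[, cols, drop = FALSE], 3))
  }
  if (inherits(x$sn, "sn_evidence")) {
    cat("  sn: ", x$sn$assignment, "\n", sep = "")
  } else cat("  sn: undetermined\n")
  if (is.data.frame(x$positions) && nrow(x$positions) > 0L) {
    cat("  double bonds: ",
        paste0("n-", x$positions$n_x, " (", x$positions$status, ")",
               collapse = ", "), "\n", sep = "")
  } else cat("  double bonds: undetermined\n")
  if (is.data.frame(x$geometry) && nrow(x$geometry) > 0L) {
    cat("  geometry: ",
        paste0("n-", x$geometry$n_x, ": ", x$geometry$call,
               collapse = ", "), "\n", sep = "")
  } else cat("  geometry: undetermined\n")
  for (f in x$flags) cat("  flag: ", f, "\n", sep = "")
  invisible(x)
}

#' Serialize an elucidation report to JSON
#'
#' Deterministic serialization (schema version `"1"`, no timestamps):
#' identical inputs and configuration give byte-identical JSON.
#'
#' @param report An `elucidation_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "elucidation_report"))
  payload <- list(
    schema_version = "1",
    precursor_mz = report$precursor_mz,
    adduct = report$adduct$cation,
    config_hash = report$config_hash,
    tolerances = list(tol_ppm = report$config$tol_ppm,
                      tol_mz = report$config$tol_mz,
                      sn_ratio = report$config$sn_ratio,
                      geometry_rel_tol = report$config$geometry_rel_tol),
    candidates = report$candidates,
    sn = if (inherits(report$sn, "sn_evidence")) {
      report$sn[c("assignment", "proposed_sn2", "confidence_ratio",
                  "decision_ratio", "reason")]
    } else "undetermined",
    positions = if (is.data.frame(report$positions)) {
      as.data.frame(report$positions)
    } else "undetermined",
    geometry = if (is.data.frame(report$geometry)) report$geometry
               else "undetermined",
    flags = report$flags,
    nearest_miss_ppm = report$nearest_miss_ppm
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
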