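# Quantification and behavioral statistics: reference-peak normalization,
# TLC band normalization, mate-choice preference scores and exact tests.

#' Normalize peak intensities to a reference peak
#'
#' Each target's relative intensity is its matched intensity divided by the
#' reference peak's intensity (the cuticular hydrocarbon C35:2 at
#' [M+K]+ 527.5 is the conventional reference for these profiles). The
#' profile is scale-invariant: multiplying all intensities by a constant
#' leaves it unchanged. A target with no matching peak gets relative
#' intensity 0; an absent reference peak is an error.
#'
#' @param peaks A [spectrum()].
#' @param reference_mz m/z of the reference peak.
#' @param target_mzs Numeric vector of target m/z values.
#' @param tol_mz Match tolerance in Da.
#' @return data.frame of class `normalized_profile`: `target_mz`,
#'   `matched_mz`, `intensity`, `relative_intensity`; the reference
#'   identity is carried in attributes `reference_mz` /
#'   `reference_intensity`.
#' @export
normalize_to_reference <- function(peaks, reference_mz, target_mzs,
                                   tol_mz = 0.3) {
  stopifnot(inherits(peaks, "spectrum"), tol_mz > 0)
  ref <- match_peak(peaks, reference_mz, tol_mz)
  if (is.null(ref) || ref$intensity <= 0) {
    stop("reference not found: no peak within ", tol_mz, " Da of m/z ",
         reference_mz, " with positive intensity")
  }
  out <- data.frame(target_mz = as.numeric(target_mzs),
                    matched_mz = NA_real_, intensity = 0,
                    relative_intensity = 0)
  for (i in seq_len(nrow(out))) {
    hit <- match_peak(peaks, out$target_mz[i], tol_mz)
    if (!is.null(hit)) {
      out$matched_mz[i] <- hit$mz
      out$intensity[i] <- hit$intensity
      out$relative_intensity[i] <- hit$intensity / ref$intensity
    }
  }
  attr(out, "reference_mz") <- ref$mz
  attr(out, "reference_intensity") <- ref$intensity
  class(out) <- c("normalized_profile", class(out))
  out
}

#' Normalize TLC band intensities to a control band
#'
#' Per lane, each fraction's intensity is divided by that lane's control
#' band (the band at the origin in direct-tissue TLC).
#'
#' @param band_intensities Named numeric vector (one lane) or a data.frame /
#'   matrix with one row per lane and one column per band.
#' @param control_band Name (or index) of the control band.
#' @return Same shape as the input, control band normalized to 1.
#' @export
tlc_normalize <- function(band_intensities, control_band) {
  if (is.numeric(band_intensities) && is.null(dim(band_intensities))) {
    ctrl <- band_intensities[[control_band]]
    if (is.null(ctrl) || is.na(ctrl)) {
      stop("control band ", sQuote(control_band), " not present")
    }
    if (ctrl <= 0) stop("control band intensity must be > 0")
    return(band_intensities / ctrl)
  }
  bands <- as.data.frame(band_intensities)
  if (is.character(control_band) && !control_band %in% names(bands)) {
    stop("control band ", sQuote(control_band), " not present")
  }
  ctrl <- bands[[control_band]]
  if (any(is.na(ctrl)) || any(ctrl <= 0)) {
    stop("control band intensity must be > 0 in every lane")
  }
  out <- bands
  for (nm in names(bands)) out[[nm]] <- bands[[nm]] / ctrl
  out
}

#' Construct a mate-choice assay record
#'
#' @param n_choice_a Trials where the focal male chose option A first
#'   (e.g. the virgin female, or the solvent control).
#' @param n_choice_b Trials where option B was chosen first (e.g. the
#'   mated or perfumed female).
#' @param n_no_choice Trials with no courtship initiation.
#' @return Object of class `choice_assay` with `n_trials` derived.
#' @export
choice_assay <- function(n_choice_a, n_choice_b, n_no_choice = 0L) {
  counts <- c(n_choice_a, n_choice_b, n_no_choice)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("choice counts must be non-negative integers")
  }
  structure(list(n_choice_a = as.integer(n_choice_a),
                 n_choice_b = as.integer(n_choice_b),
                 n_no_choice = as.integer(n_no_choice),
                 n_trials = as.integer(sum(counts))),
            class = "choice_assay")
}

#' Preference score and exact binomial test for a choice assay
#'
#' `score = (A - B) / (A + B)`: +1 when every male chose option A first,
#' -1 when every male chose B. No-choice trials are excluded from the
#' denominator (the scored event is which female the male courts first).
#' The p-value is the exact two-sided binomial test of the choosers against
#' p0 = 0.5, computed by summing all outcomes whose probability does not
#' exceed that of the observed count.
#'
#' @param assay A [choice_assay()], or `n_choice_a` when the counts are
#'   passed separately.
#' @param n_choice_b,n_no_choice Counts, when not passing a `choice_assay`.
#' @return List of class `preference_result`: `score`, `p_value`,
#'   `n_choosers`, `n_no_choice`. With zero choosers the score and p-value
#'   are `NA` (reported as undefined, not an error).
#' @examples
#' preference_score(choice_assay(17, 3))
#' @export
preference_score <- function(assay, n_choice_b = NULL, n_no_choice = 0L) {
  if (!inherits(assay, "choice_assay")) {
    assay <- choice_assay(assay, n_choice_b, n_no_choice)
  }
  a <- assay$n_choice_a; b <- assay$n_choice_b
  n <- a + b
  if (n == 0L) {
    return(structure(list(score = NA_real_, p_value = NA_real_,
                          n_choosers = 0L,
                          n_no_choice = assay$n_no_choice),
                     class = "preference_result"))
  }
  structure(list(score = (a - b) / n,
                 p_value = exact_binomial_p(a, n),
                 n_choosers = n, n_no_choice = assay$n_no_choice),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  if (is.na(x$score)) {
    cat("<preference_result> undefined (no choosers)\n")
  } else {
    cat("<preference_result> score ", sprintf("%.3f", x$score),
        ", exact binomial p = ", format(x$p_value, digits = 4),
        " (n = ", x$n_choosers, " choosers)\n", sep = "")
  }
  invisible(x)
}

#' Exact two-sided binomial test against p0 = 1/2
#'
#' Sums the probabilities of all counts `k` in `0:n` whose point probability
#' under Binomial(n, 1/2) is at most that of the observed count (with a
#' small relative slack for floating-point ties). Probabilities are computed
#' directly as `choose(n, k) / 2^n`.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @return Two-sided p-value.
#' @export
exact_binomial_p <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  pmf <- choose(n, 0:n) / 2^n
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

#' Fisher's exact test for a 2x2 choice comparison
#'
#' Secondary test for comparing two assays (e.g. perfumed vs control
#' lure): the 2x2 table of (chose A, chose B) by condition, evaluated with
#' the exact hypergeometric test.
#'
#' @param a1,b1 Choice counts under condition 1.
#' @param a2,b2 Choice counts under condition 2.
#' @return `htest` object from [stats::fisher.test()].
#' @export
choice_fisher_test <- function(a1, b1, a2, b2) {
  tab <- matrix(c(a1, b1, a2, b2), nrow = 2,
                dimnames = list(choice = c("A", "B"),
                                condition = c("1", "2")))
  stats::fisher.test(tab)
}

#' Tidy long-format table of preference results
#'
#' @param assays Named list of [choice_assay()] objects.
#' @return data.frame: `assay`, `n_trials`, `n_choice_a`, `n_choice_b`,
#'   `n_no_choice`, `score`, `p_value`.
#' @export
preference_table <- function(assays) {
  stopifnot(is.list(assays), length(assays) > 0L,
            !is.null(names(assays)))
  rows <- lapply(names(assays), function(nm) {
    a <- assays[[nm]]
    r <- preference_score(a)
    data.frame(assay = nm, n_trials = a$n_trials,
               n_choice_a = a$n_choice_a, n_choice_b = a$n_choice_b,
               n_no_choice = a$n_no_choice, score = r$score,
               p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
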