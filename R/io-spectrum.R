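# Spectrum container and peak-list readers/writers (CSV and minimal MGF).

SPECTRUM_STAGES <- c("precursor", "CID", "OzID")

#' Construct a stage-tagged spectrum
#'
#' A spectrum is a peak list (m/z, intensity) tagged with the acquisition
#' stage and optional adduct/precursor metadata. Peaks are stored sorted
#' ascending by m/z; m/z must be strictly positive and intensities
#' non-negative and finite (silently-corrupting values are rejected, never
#' coerced).
#'
#' @param mz Numeric vector of peak m/z values.
#' @param intensity Numeric vector of intensities, same length.
#' @param stage One of `"precursor"`, `"CID"`, `"OzID"`.
#' @param adduct Optional [adduct_spec()] or cation symbol.
#' @param precursor_mz Optional precursor m/z (for product-ion stages).
#' @param source Optional source path, carried for provenance.
#' @return Object of class `spectrum`: a list with a `peaks` data.frame
#'   (`mz`, `intensity`) plus metadata.
#' @export
spectrum <- function(mz = numeric(), intensity = numeric(),
                     stage = c("precursor", "CID", "OzID"),
                     adduct = NULL, precursor_mz = NULL, source = NULL) {
  stage <- match.arg(stage)
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (anyNA(mz) || anyNA(intensity) || any(!is.finite(c(mz, intensity)))) {
    stop("peak list contains NA/NaN/Inf values")
  }
  if (any(mz <= 0)) stop("m/z values must be strictly positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  ord <- order(mz)
  if (!is.null(adduct)) adduct <- as_adduct(adduct)
  if (!is.null(precursor_mz)) {
    stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
              is.finite(precursor_mz), precursor_mz > 0)
  }
  structure(
    list(peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
         stage = stage, adduct = adduct, precursor_mz = precursor_mz,
         source = source),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> stage=", x$stage, ", ", nrow(x$peaks), " peak(s)",
      if (!is.null(x$precursor_mz)) {
        paste0(", precursor m/z ", sprintf("%.4f", x$precursor_mz))
      } else "",
      if (!is.null(x$adduct)) paste0(", [M+", x$adduct$cation, "]+") else "",
      "\n", sep = "")
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)

#' Find the most intense peak within a tolerance window
#'
#' @param s A [spectrum()].
#' @param mz Target m/z.
#' @param tol_mz Absolute half-window in Da.
#' @return One-row data.frame (`mz`, `intensity`) or `NULL` if no peak lies
#'   within the window. Ties on intensity break toward the smaller |delta m/z|.
#' @export
match_peak <- function(s, mz, tol_mz) {
  stopifnot(inherits(s, "spectrum"), tol_mz > 0)
  hit <- which(abs(s$peaks$mz - mz) <= tol_mz)
  if (length(hit) == 0L) return(NULL)
  hit <- hit[order(-s$peaks$intensity[hit], abs(s$peaks$mz[hit] - mz))]
  s$peaks[hit[1], , drop = FALSE]
}

# ---- readers / writers -----------------------------------------------------

#' Read a peak list from disk
#'
#' Two plain-text formats are supported:
#' * `"csv"`: header `mz,intensity`, one peak per row.
#' * `"mgf"`: a minimal single-spectrum Mascot generic format block
#'   (`BEGIN IONS` / `PEPMASS=` / `m/z intensity` lines / `END IONS`).
#'
#' Malformed rows are reported with their line numbers; negative intensities
#' and non-numeric fields are errors, not silent coercions.
#'
#' @param path File path.
#' @param format `"csv"` or `"mgf"`; default guessed from the extension.
#' @param stage,adduct,precursor_mz Passed to [spectrum()]; an MGF `PEPMASS`
#'   header populates `precursor_mz` when the argument is `NULL`.
#' @return A [spectrum()].
#' @export
read_peaklist <- function(path, format = NULL,
                          stage = c("precursor", "CID", "OzID"),
                          adduct = NULL, precursor_mz = NULL) {
  stage <- match.arg(stage)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "mgf")) {
      stop("cannot guess format from extension ", sQuote(format),
           "; pass format = \"csv\" or \"mgf\"")
    }
  }
  format <- match.arg(format, c("csv", "mgf"))
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("mz", "intensity")
    if (!all(need %in% names(df))) {
      stop("CSV peak list must have columns ",
           paste(need, collapse = ", "), " (got: ",
           paste(names(df), collapse = ", "), ")")
    }
    bad <- which(!vapply(df$mz, is.numeric, logical(1)) |
                   !vapply(df$intensity, is.numeric, logical(1)) |
                   is.na(df$mz) | is.na(df$intensity))
    if (length(bad) > 0L) {
      stop("non-numeric or missing peak values at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    return(spectrum(df$mz, df$intensity, stage = stage, adduct = adduct,
                    precursor_mz = precursor_mz, source = path))
  }
  # minimal MGF
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != 1L || length(end) != 1L || end < begin) {
    stop("expected exactly one BEGIN IONS / END IONS block in ", path)
  }
  body <- lines[(begin + 1L):(end - 1L)]
  idx <- (begin + 1L):(end - 1L)
  pep <- grep("^PEPMASS=", body, value = TRUE)
  if (is.null(precursor_mz) && length(pep) >= 1L) {
    precursor_mz <- as.numeric(strsplit(sub("^PEPMASS=", "", pep[1]),
                                        "[ \t]+")[[1]][1])
  }
  is_peak <- grepl("^[0-9]", body)
  mzv <- numeric(0); intv <- numeric(0)
  for (i in which(is_peak)) {
    fields <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(fields) < 2L) {
      stop("malformed peak line ", idx[i], " in ", path, ": ",
           sQuote(body[i]))
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      stop("non-numeric peak at line ", idx[i], " in ", path, ": ",
           sQuote(body[i]))
    }
    mzv <- c(mzv, vals[1]); intv <- c(intv, vals[2])
  }
  spectrum(mzv, intv, stage = stage, adduct = adduct,
           precursor_mz = precursor_mz, source = path)
}

#' Write a spectrum to disk
#'
#' Full-precision round trip: values are written with 17 significant digits
#' so `read_peaklist(write_peaklist(s))` reproduces the peaks exactly.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @param format `"csv"` or `"mgf"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(s, path, format = c("csv", "mgf")) {
  stopifnot(inherits(s, "spectrum"))
  format <- match.arg(format)
  num <- function(x) sprintf("%.17g", x)
  if (format == "csv") {
    lines <- c("mz,intensity",
               paste(num(s$peaks$mz), num(s$peaks$intensity), sep = ","))
  } else {
    hdr <- c("BEGIN IONS", paste0("TITLE=stage:", s$stage))
    if (!is.null(s$precursor_mz)) {
      hdr <- c(hdr, paste0("PEPMASS=", num(s$precursor_mz)))
    }
    hdr <- c(hdr, "CHARGE=1+")
    lines <- c(hdr, paste(num(s$peaks$mz), num(s$peaks$intensity)),
               "END IONS")
  }
  writeLines(lines, path)
  invisible(path)
}
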