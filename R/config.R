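# Layered configuration shared by the elucidation pipeline and the CLI.
# Precedence: package defaults < config file < explicit arguments.

#' Pipeline configuration
#'
#' One object carrying every tolerance and rule parameter. Defaults:
#' * `tol_ppm = 20` — precursor/composition search tolerance (instrument
#'   mass accuracy);
#' * `tol_mz = 0.3` Da — CID/OzID fragment match tolerance (unit-resolution
#'   ion trap);
#' * `sn_ratio = 0.5` — sn-2 suppression decision ratio;
#' * `geometry_references = NULL` — aldehyde:Criegee reference ratios; must
#'   be calibrated (e.g. against synthetic standards) before geometry is
#'   called;
#' * `geometry_rel_tol = 0.5` — relative tolerance around a reference;
#' * `constraints` — the one-long-two-short acyl constraint box;
#' * `candidate_positions = 2:16` — n-x double-bond search range.
#'
#' @param ... Named overrides of the defaults above.
#' @param file Optional path to a `key = value` config file applied between
#'   defaults and `...`. Values are parsed with `type.convert`; vector
#'   values are comma-separated.
#' @return List of class `te_config`.
#' @export
te_config <- function(..., file = NULL) {
  cfg <- list(
    tol_ppm = 20,
    tol_mz = 0.3,
    sn_ratio = 0.5,
    geometry_references = NULL,
    geometry_rel_tol = 0.5,
    constraints = composition_constraints(),
    candidate_positions = 2:16
  )
  if (!is.null(file)) {
    cfg <- utils::modifyList(cfg, read_config_file(file))
  }
  overrides <- list(...)
  if (length(overrides) > 0L) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0L || is.null(names(overrides))) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = "te_config")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", sQuote(ln))
    key <- trimws(kv[1])
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    parsed <- utils::type.convert(vals, as.is = TRUE)
    out[[key]] <- parsed
  }
  out
}

#' Stable hash of a configuration
#'
#' FNV-1a 32-bit hash over the deparsed configuration; embedded in every
#' report so results are traceable to the exact parameter set.
#'
#' @param cfg A [te_config()] (any R object works).
#' @return 8-character lowercase hex string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keeps h a plain double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit FNV prime multiply, split 16/16 to stay inside double precision
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619) %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
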