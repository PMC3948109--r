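# Lipid shorthand grammar: "TG(18:1(n-9,cis)/5:1/5:1)" <-> tag_structure.
#
# Following LIPID MAPS conventions, "/" separators mean the slot order is
# the resolved sn-1/sn-2/sn-3 order; "_" separators mean backbone positions
# are unresolved. Per-acyl annotations in parentheses are a comma-separated
# mix of n-x double-bond positions (each optionally suffixed with a cis or
# trans geometry) and the token "Me" for a methyl branch.

#' Parse lipid shorthand into a TAG structure
#'
#' @param text e.g. `"TG(18:1(n-9,cis)/5:1/5:1)"` or `"TG(18:1_5:1_5:1)"`.
#' @return A [tag_structure()]; `/`-separated forms get
#'   `sn_assignment = "fully-resolved"`, `_`-separated forms `"unresolved"`.
#' @export
parse_lipid_shorthand <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  m <- regmatches(text, regexec("^TG\\((.*)\\)$", text))[[1]]
  if (length(m) != 2L) {
    stop("shorthand must have the form TG(...): got ", sQuote(text))
  }
  body <- m[2]
  sep <- if (grepl("_", body, fixed = TRUE)) "_" else "/"
  # split on the separator only at depth 0 (annotations contain none, but be safe)
  parts <- character(); depth <- 0L; cur <- ""
  for (ch in strsplit(body, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L) { parts <- c(parts, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  parts <- c(parts, cur)
  if (length(parts) != 3L) {
    stop("a TAG shorthand needs exactly three acyl slots: got ",
         length(parts), " in ", sQuote(text))
  }
  acyls <- lapply(parts, parse_acyl_shorthand)
  tag_structure(acyls, sn_assignment =
                  if (sep == "/") "fully-resolved" else "unresolved")
}

parse_acyl_shorthand <- function(part) {
  m <- regmatches(part,
                  regexec("^([0-9]+):([0-9]+)(\\((.*)\\))?$", part))[[1]]
  if (length(m) == 0L) stop("malformed acyl shorthand: ", sQuote(part))
  n <- as.integer(m[2]); d <- as.integer(m[3])
  positions <- NULL; geometries <- NULL; branched <- FALSE
  if (nzchar(m[5])) {
    tokens <- trimws(strsplit(m[5], ",")[[1]])
    pos <- integer(); geo <- character()
    i <- 1L
    while (i <= length(tokens)) {
      tok <- tokens[i]
      if (tok == "Me") {
        branched <- TRUE; i <- i + 1L
      } else if (grepl("^n-[0-9]+$", tok)) {
        pos <- c(pos, as.integer(sub("^n-", "", tok)))
        # a following bare cis/trans token annotates this position
        if (i + 1L <= length(tokens) && tokens[i + 1L] %in% c("cis", "trans")) {
          geo <- c(geo, tokens[i + 1L]); i <- i + 2L
        } else {
          geo <- c(geo, "unknown"); i <- i + 1L
        }
      } else {
        stop("unrecognized annotation token ", sQuote(tok), " in ",
             sQuote(part))
      }
    }
    if (length(pos) > 0L) {
      if (length(pos) != d) {
        stop("acyl ", sQuote(part), " declares ", d, " double bond(s) but ",
             length(pos), " position annotation(s)")
      }
      ord <- order(pos)
      positions <- pos[ord]
      geometries <- if (all(geo == "unknown")) NULL else geo[ord]
    }
  }
  fatty_acyl(n, d, db_positions = positions, db_geometries = geometries,
             branched = branched)
}

#' Format a TAG structure as lipid shorthand
#'
#' Inverse of [parse_lipid_shorthand()] on canonical forms.
#'
#' @param t A [tag_structure()].
#' @return Single string.
#' @export
format_lipid_shorthand <- function(t) {
  stopifnot(inherits(t, "tag_structure"))
  sep <- if (t$sn_assignment == "unresolved") "_" else "/"
  paste0("TG(", paste(vapply(t$acyls, format_acyl_shorthand, character(1)),
                      collapse = sep), ")")
}

format_acyl_shorthand <- function(a) {
  ann <- character()
  if (!is.null(a$db_positions)) {
    geo <- a$db_geometries
    for (i in seq_along(a$db_positions)) {
      ann <- c(ann, paste0("n-", a$db_positions[i]))
      if (!is.null(geo) && geo[i] != "unknown") ann <- c(ann, geo[i])
    }
  }
  if (a$branched) ann <- c(ann, "Me")
  paste0(acyl_label(a),
         if (length(ann) > 0L) paste0("(", paste(ann, collapse = ","), ")")
         else "")
}
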