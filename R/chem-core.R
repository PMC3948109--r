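# Exact molecular-formula arithmetic, fatty-acyl and glyceride formula
# construction, and adduct-ion m/z computation.

#' Monoisotopic atomic masses
#'
#' Fixed CODATA-derived monoisotopic masses (Da) for the elements this
#' package manipulates, plus the electron mass. All downstream m/z
#' arithmetic resolves against this single table, so golden values in the
#' test suite are stable.
#'
#' @format Named numeric vector, Da.
#' @export
ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Li = 7.0160034366,
  Na = 22.9897692809,
  K  = 38.9637064864
)

#' Electron rest mass in Da
#' @export
ELECTRON_MASS <- 0.00054857990

# mass of one methylene unit and one oxygen; used by the OzID arithmetic
CH2_MASS <- ATOMIC_MASS[["C"]] + 2 * ATOMIC_MASS[["H"]]
O_MASS   <- ATOMIC_MASS[["O"]]

#' Construct a molecular formula
#'
#' @param counts Named integer vector or list, element symbol -> count.
#'   Counts must be non-negative; elements absent from [ATOMIC_MASS] are
#'   rejected. Zero counts are dropped.
#' @return An object of class `molecular_formula` (named integer vector in
#'   Hill order: C, then H, then remaining elements alphabetically).
#' @export
molecular_formula <- function(counts = integer()) {
  counts <- unlist(counts)
  if (length(counts) == 0L) {
    out <- structure(integer(), names = character(), class = "molecular_formula")
    return(out)
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("formula counts must be a named vector (element -> count)")
  }
  unknown <- setdiff(names(counts), names(ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) {
    bad <- names(counts)[counts < 0]
    stop("negative element count for: ", paste(bad, collapse = ", "))
  }
  if (any(counts != round(counts))) stop("element counts must be integers")
  counts <- counts[counts > 0]
  counts <- tapply(as.integer(counts), names(counts), sum) # merge duplicates
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(counts[hill_order(names(counts))], class = "molecular_formula")
}

hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  intersect(c("C", "H", rest), symbols)
}

#' Parse a molecular formula string
#'
#' Accepts strings like `"C31H52O6"` or `"H2O"`: one- or two-letter element
#' symbols each followed by an optional positive count.
#'
#' @param text A single formula string.
#' @return A [molecular_formula()].
#' @examples
#' parse_formula("C31H52O6")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(molecular_formula())
  token_re <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(token_re, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    # locate the first offending character run
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) {
      covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    }
    bad_at <- which(!covered)[1]
    stop("malformed formula token at position ", bad_at, " in ",
         sQuote(text), ": ", sQuote(substr(text, bad_at, bad_at)))
  }
  syms <- sub(token_re, "\\1", tokens, perl = TRUE)
  cnts <- sub(token_re, "\\2", tokens, perl = TRUE)
  cnts <- ifelse(cnts == "", 1L, suppressWarnings(as.integer(cnts)))
  unknown <- setdiff(syms, names(ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s) in ", sQuote(text), ": ",
         paste(unique(unknown), collapse = ", "))
  }
  molecular_formula(stats::setNames(cnts, syms))
}

#' Format a molecular formula as a Hill-order string
#' @param f A [molecular_formula()].
#' @return Single string, e.g. `"C31H52O6"`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format_formula(x), "  (",
      sprintf("%.5f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Add or subtract molecular formulas
#'
#' `formula_add()` merges counts; `formula_subtract()` errors if any element
#' would go negative (mass bookkeeping must stay physical).
#'
#' @param f1,f2 [molecular_formula()] objects.
#' @return A [molecular_formula()].
#' @export
formula_add <- function(f1, f2) {
  molecular_formula(c(unclass(f1), unclass(f2)))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  res <- unclass(f1)
  for (el in names(f2)) {
    res[el] <- (if (el %in% names(res)) res[[el]] else 0L) - f2[[el]]
  }
  if (any(res < 0)) {
    bad <- names(res)[res < 0]
    stop("subtraction drives element count negative: ",
         paste(bad, collapse = ", "))
  }
  molecular_formula(res)
}

#' Multiply a formula by a non-negative integer
#' @param f A [molecular_formula()].
#' @param k Non-negative integer.
#' @export
formula_multiply <- function(f, k) {
  stopifnot(k >= 0, k == round(k))
  molecular_formula(unclass(f) * as.integer(k))
}

#' Monoisotopic mass of a formula
#'
#' @param f A [molecular_formula()].
#' @return Mass in Da (sum over elements of count times monoisotopic atomic
#'   mass). The empty formula has mass 0.
#' @examples
#' monoisotopic_mass(parse_formula("C31H52O6")) # 520.37639
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  if (length(f) == 0L) return(0)
  missing <- setdiff(names(f), names(ATOMIC_MASS))
  if (length(missing) > 0L) {
    stop("element(s) missing from atomic-mass table: ",
         paste(missing, collapse = ", "))
  }
  sum(unclass(f) * ATOMIC_MASS[names(f)])
}

# ---- fatty acyls and TAG structures ---------------------------------------

#' Construct a fatty acyl chain
#'
#' Shorthand `n:d` denotes a chain of `n` carbons with `d` carbon-carbon
#' double bonds (e.g. `5:1` is the tiglic/2-methylbutenoic acyl, `18:1`
#' oleoyl). Double-bond positions use n-x nomenclature: `x` is counted from
#' the methyl (omega) terminus, so `x` must satisfy `2 <= x <= n - 1`.
#'
#' @param n_carbons Integer >= 2.
#' @param n_double_bonds Integer >= 0, at most `n_carbons - 1`.
#' @param db_positions Optional integer vector of n-x positions, length
#'   `n_double_bonds`.
#' @param db_geometries Optional character vector (`"cis"`, `"trans"`,
#'   `"unknown"`), same length as `db_positions`.
#' @param branched Logical flag: methyl-branched chain (e.g. tiglic). The
#'   branch does not change the elemental formula.
#' @return Object of class `fatty_acyl`.
#' @export
fatty_acyl <- function(n_carbons, n_double_bonds,
                       db_positions = NULL, db_geometries = NULL,
                       branched = FALSE) {
  stopifnot(length(n_carbons) == 1L, length(n_double_bonds) == 1L)
  n <- as.integer(n_carbons); d <- as.integer(n_double_bonds)
  if (is.na(n) || n < 2L) stop("fatty acyl needs at least 2 carbons")
  if (is.na(d) || d < 0L) stop("double-bond count must be >= 0")
  if (d > n - 1L) {
    stop("double-bond count ", d, " exceeds the maximum ", n - 1L,
         " for a ", n, "-carbon chain")
  }
  if (!is.null(db_positions)) {
    db_positions <- as.integer(db_positions)
    if (length(db_positions) != d) {
      stop("db_positions has length ", length(db_positions),
           " but the chain has ", d, " double bond(s)")
    }
    if (any(db_positions < 2L | db_positions > n - 1L)) {
      stop("each n-x position must satisfy 2 <= x <= n_carbons - 1")
    }
    db_positions <- sort(db_positions)
  }
  if (!is.null(db_geometries)) {
    db_geometries <- match.arg(db_geometries, c("cis", "trans", "unknown"),
                               several.ok = TRUE)
    if (length(db_geometries) != d) {
      stop("db_geometries must have one entry per double bond")
    }
  }
  structure(
    list(n_carbons = n, n_double_bonds = d,
         db_positions = db_positions, db_geometries = db_geometries,
         branched = isTRUE(branched)),
    class = "fatty_acyl"
  )
}

#' Shorthand label of a fatty acyl, e.g. "18:1"
#' @param a A [fatty_acyl()].
#' @export
acyl_label <- function(a) {
  stopifnot(inherits(a, "fatty_acyl"))
  paste0(a$n_carbons, ":", a$n_double_bonds)
}

#' @export
print.fatty_acyl <- function(x, ...) {
  pos <- if (!is.null(x$db_positions)) {
    paste0(" (", paste0("n-", x$db_positions, collapse = ","), ")")
  } else ""
  cat("<fatty_acyl> ", acyl_label(x), pos,
      if (x$branched) " branched" else "", "\n", sep = "")
  invisible(x)
}

#' Elemental formula of the free fatty acid of an acyl chain
#'
#' A chain of `n` carbons with `d` double bonds corresponds to the free acid
#' `CnH(2n-2d)O2`. Branching does not change the formula.
#'
#' @param a A [fatty_acyl()].
#' @return A [molecular_formula()].
#' @examples
#' acyl_formula(fatty_acyl(5, 1))  # C5H8O2, tiglic acid
#' @export
acyl_formula <- function(a) {
  stopifnot(inherits(a, "fatty_acyl"))
  molecular_formula(c(C = a$n_carbons,
                      H = 2L * a$n_carbons - 2L * a$n_double_bonds,
                      O = 2L))
}

SN_ASSIGNMENTS <- c("fully-resolved", "long-chain-at-sn-1/3",
                    "long-chain-at-sn-2", "unresolved")

#' Construct a triacylglyceride structure
#'
#' Exactly three acyl slots on a glycerol backbone. When `sn_assignment` is
#' anything other than `"unresolved"`, slot 2 of `acyls` is the sn-2
#' substituent (sn-1 vs sn-3 are never distinguished: CID abundance patterns
#' cannot separate the two outer positions).
#'
#' @param acyls List of three [fatty_acyl()] objects.
#' @param sn_assignment One of `"fully-resolved"`, `"long-chain-at-sn-1/3"`,
#'   `"long-chain-at-sn-2"`, `"unresolved"`.
#' @return Object of class `tag_structure`.
#' @export
tag_structure <- function(acyls, sn_assignment = "unresolved") {
  if (!is.list(acyls) || length(acyls) != 3L ||
      !all(vapply(acyls, inherits, logical(1), "fatty_acyl"))) {
    stop("acyls must be a list of exactly three fatty_acyl objects")
  }
  sn_assignment <- match.arg(sn_assignment, SN_ASSIGNMENTS)
  structure(list(acyls = acyls, sn_assignment = sn_assignment),
            class = "tag_structure")
}

#' @export
print.tag_structure <- function(x, ...) {
  cat("<tag_structure> ", format_lipid_shorthand(x),
      "  [", x$sn_assignment, "]\n", sep = "")
  invisible(x)
}

GLYCEROL_FORMULA <- molecular_formula(c(C = 3L, H = 8L, O = 3L))
THREE_WATERS <- molecular_formula(c(H = 6L, O = 3L))

#' Elemental formula of a TAG
#'
#' Glycerol (`C3H8O3`) plus the three free acids minus three waters; the
#' result is independent of acyl order.
#'
#' @param t A [tag_structure()] or a list of three [fatty_acyl()].
#' @return A [molecular_formula()].
#' @examples
#' tg <- tag_structure(list(fatty_acyl(18, 1), fatty_acyl(5, 1), fatty_acyl(5, 1)))
#' format_formula(tag_formula(tg)) # "C31H52O6"
#' @export
tag_formula <- function(t) {
  acyls <- if (inherits(t, "tag_structure")) t$acyls else t
  if (!is.list(acyls) || length(acyls) != 3L) {
    stop("a TAG has exactly three acyl slots")
  }
  f <- GLYCEROL_FORMULA
  for (a in acyls) f <- formula_add(f, acyl_formula(a))
  formula_subtract(f, THREE_WATERS)
}

# ---- adduct ions ----------------------------------------------------------

SUPPORTED_CATIONS <- c("H", "Li", "Na", "K", "NH4")

#' Specify a singly-charged cation adduct
#'
#' @param cation One of `"H"`, `"Li"`, `"Na"`, `"K"`, `"NH4"`.
#' @return Object of class `adduct_spec` with the cation's monoisotopic
#'   (atom/group) mass attached. Charge is fixed at +1.
#' @export
adduct_spec <- function(cation = c("Na", "K", "Li", "H", "NH4")) {
  cation <- match.arg(cation, SUPPORTED_CATIONS)
  mass <- if (cation == "NH4") {
    ATOMIC_MASS[["N"]] + 4 * ATOMIC_MASS[["H"]]
  } else {
    ATOMIC_MASS[[cation]]
  }
  structure(list(cation = cation, charge = 1L, cation_mass = mass),
            class = "adduct_spec")
}

as_adduct <- function(adduct) {
  if (inherits(adduct, "adduct_spec")) return(adduct)
  if (is.character(adduct) && length(adduct) == 1L) {
    if (!adduct %in% SUPPORTED_CATIONS) {
      stop("unsupported cation ", sQuote(adduct), "; supported: ",
           paste(SUPPORTED_CATIONS, collapse = ", "))
    }
    return(adduct_spec(adduct))
  }
  stop("adduct must be an adduct_spec or a cation symbol")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct_spec> [M+", x$cation, "]+\n", sep = "")
  invisible(x)
}

#' m/z of a singly-charged cation adduct ion
#'
#' `m/z = monoisotopic_mass(f) + cation mass - electron mass`. The electron
#' subtraction (0.00054858 Da) is the fixed convention here; at the 2-decimal
#' reporting scale it is invisible, but internal arithmetic keeps it.
#'
#' @param f A [molecular_formula()] (the neutral species).
#' @param adduct An [adduct_spec()] or cation symbol.
#' @return m/z in Th (numeric, full precision).
#' @examples
#' ion_mz(parse_formula("C31H52O6"), "K") # 559.33955
#' @export
ion_mz <- function(f, adduct) {
  adduct <- as_adduct(adduct)
  monoisotopic_mass(f) + adduct$cation_mass - ELECTRON_MASS
}

#' Round an m/z for reporting
#'
#' Two conventions coexist in the source literature for these lipids:
#' tabulated calculated values carry 2 decimals (`mode = "table"`), in-text
#' ion labels are nearest-integer (`mode = "text"`).
#'
#' @param mz Numeric m/z values.
#' @param mode `"table"` (2 decimals) or `"text"` (nearest integer).
#' @param digits Explicit decimal count, overriding `mode`.
#' @export
report_mz <- function(mz, mode = c("table", "text"), digits = NULL) {
  if (is.null(digits)) {
    mode <- match.arg(mode)
    digits <- if (mode == "table") 2L else 0L
  }
  round(mz, digits)
}
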