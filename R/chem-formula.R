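# Elemental-composition arithmetic: the unit of all mass calculations in the
# package. A composition is a named count vector plus an integer charge; all
# masses are monoisotopic and ions are electron-mass corrected.

# Monoisotopic atomic masses (u). Source: CODATA 2010 / IUPAC-CIAAW 2012
# (12C is exact by definition). Held to >= 10 significant figures; values are
# immutable package constants. S and P are carried for extensibility only --
# the aporphine chemistry in scope needs C/H/N/O.
.atomic_masses <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

# CODATA 2010 electron mass (u).
.electron_mass <- 0.00054857990907

#' Monoisotopic atomic masses used by the package
#'
#' Returns the pinned table of monoisotopic atomic masses (in u, CODATA
#' 2010/IUPAC-CIAAW values) together with the electron mass, which is
#' subtracted once per positive charge when computing ion m/z.
#'
#' @return A list with elements `atoms` (named numeric vector of monoisotopic
#'   masses in u) and `electron` (electron mass in u).
#' @examples
#' mass_constants()$atoms[["H"]]
#' @export
mass_constants <- function() {
  list(atoms = .atomic_masses, electron = .electron_mass)
}

#' Construct an elemental composition
#'
#' @param counts Named numeric vector of non-negative integer element counts,
#'   e.g. `c(C = 20, H = 24, N = 1, O = 4)`. At least one count must be
#'   positive.
#' @param charge Integer charge. Mass routines accept 0 (neutral) or +1
#'   (singly charged cation); other values are rejected there.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(c(C = 20, H = 24, N = 1, O = 4), charge = 1)
#' @export
chem_formula <- function(counts, charge = 0L) {
  if (length(counts) == 0L || is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a named vector of element counts", call. = FALSE)
  unknown <- setdiff(names(counts), names(.atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers", call. = FALSE)
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    stop("empty formula: at least one element count must be positive", call. = FALSE)
  if (length(charge) != 1L || is.na(charge) || charge != round(charge))
    stop("'charge' must be a single integer", call. = FALSE)
  structure(list(counts = round(counts), charge = as.integer(charge)),
            class = "chem_formula")
}

#' Parse a molecular formula string
#'
#' Accepts the usual element-symbol/count grammar with implicit count 1
#' (`"C20H24NO4"`, `"H2O"`, `"N"`). Repeated symbols are summed.
#'
#' @param text A single formula string.
#' @param charge Integer charge to attach (default 0).
#' @return A [chem_formula()] object.
#' @examples
#' parse_formula("C20H24NO4", charge = 1)
#' parse_formula("C2H7N")
#' @export
parse_formula <- function(text, charge = 0L) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("cannot parse an empty formula string", call. = FALSE)
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (length(tokens) == 0L || sum(nchar(tokens)) != nchar(text))
    stop("malformed formula string: '", text, "'", call. = FALSE)
  counts <- numeric(0)
  for (tok in tokens) {
    sym <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(.atomic_masses))
      stop("unknown element symbol: '", sym, "'", call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) +
      (if (nzchar(n)) as.integer(n) else 1L)
  }
  chem_formula(counts, charge = charge)
}

#' Canonical (Hill order) formula string
#'
#' Serializes a composition as C, then H, then all other elements
#' alphabetically, with count 1 implicit. `parse_formula()` of the result
#' round-trips to the same composition.
#'
#' @param formula A [chem_formula()] object.
#' @return A single character string.
#' @export
formula_string <- function(formula) {
  stopifnot(inherits(formula, "chem_formula"))
  cnt <- formula$counts
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] == 1, "", cnt[ord]), collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) {
  chg <- if (x$charge == 0L) "" else if (x$charge > 0L)
    paste0("^", if (x$charge == 1L) "" else x$charge, "+") else
    paste0("^", if (x$charge == -1L) "" else -x$charge, "-")
  paste0(formula_string(x), chg)
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add two elemental compositions
#'
#' Element-wise sum of counts; the charge of `a` is preserved.
#'
#' @param a,b [chem_formula()] objects.
#' @return A [chem_formula()] object.
#' @export
formula_add <- function(a, b) {
  stopifnot(inherits(a, "chem_formula"), inherits(b, "chem_formula"))
  els <- union(names(a$counts), names(b$counts))
  cnt <- setNames(numeric(length(els)), els)
  cnt[names(a$counts)] <- a$counts
  cnt[names(b$counts)] <- cnt[names(b$counts)] + b$counts
  chem_formula(cnt, charge = a$charge)
}

#' Subtract one elemental composition from another
#'
#' Element-wise difference `a - b`; the charge of `a` is preserved. A negative
#' resulting count (the transformation is chemically infeasible on `a`) is an
#' error.
#'
#' @param a,b [chem_formula()] objects.
#' @return A [chem_formula()] object.
#' @export
formula_subtract <- function(a, b) {
  stopifnot(inherits(a, "chem_formula"), inherits(b, "chem_formula"))
  els <- union(names(a$counts), names(b$counts))
  cnt <- setNames(numeric(length(els)), els)
  cnt[names(a$counts)] <- a$counts
  cnt[names(b$counts)] <- cnt[names(b$counts)] - b$counts
  if (any(cnt < 0))
    stop("infeasible transformation: negative count for ",
         paste(names(cnt)[cnt < 0], collapse = ", "), call. = FALSE)
  chem_formula(cnt, charge = a$charge)
}

#' Protonate a neutral composition
#'
#' Adds one hydrogen and sets charge +1: the \eqn{[M+H]^+} species of a
#' neutral molecule.
#'
#' @param formula A neutral [chem_formula()].
#' @return A [chem_formula()] with one extra H and charge +1.
#' @export
protonate <- function(formula) {
  stopifnot(inherits(formula, "chem_formula"))
  if (formula$charge != 0L)
    stop("can only protonate a neutral composition", call. = FALSE)
  out <- formula_add(formula, chem_formula(c(H = 1)))
  out$charge <- 1L
  out
}

#' Monoisotopic mass-to-charge ratio
#'
#' Sum of monoisotopic atomic masses minus one electron mass per positive
#' charge. Only neutral (charge 0) and singly charged positive (+1) species
#' are in scope; other charges are rejected.
#'
#' @param formula A [chem_formula()] object, or a formula string (parsed with
#'   `charge`).
#' @param charge Charge used when `formula` is given as a string.
#' @return The monoisotopic m/z in u (full double precision; use
#'   [round_mz()] for 4-decimal reporting).
#' @examples
#' monoisotopic_mz("C20H24NO4", charge = 1)  # intact aporphinium cation
#' monoisotopic_mz(parse_formula("H2O"))
#' @export
monoisotopic_mz <- function(formula, charge = 0L) {
  if (is.character(formula)) formula <- parse_formula(formula, charge = charge)
  stopifnot(inherits(formula, "chem_formula"))
  if (!formula$charge %in% c(0L, 1L))
    stop("unsupported charge ", formula$charge, ": mass routines accept 0 or +1",
         call. = FALSE)
  sum(formula$counts * .atomic_masses[names(formula$counts)]) -
    formula$charge * .electron_mass
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z; must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6` (full precision;
#'   reports round to 2 decimals).
#' @examples
#' ppm_error(342.1703, monoisotopic_mz("C20H24NO4", charge = 1))
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("'theoretical' m/z must be positive", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Round m/z for reporting
#'
#' Rounds half away from zero (not banker's rounding) to the given number of
#' decimals; 4 decimals reproduces the library's reference masses at their
#' published precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals (default 4).
#' @return Rounded numeric vector.
#' @export
round_mz <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
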