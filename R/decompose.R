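# Accurate-mass molecular formula decomposition: enumerate all elemental
# compositions whose theoretical m/z falls inside a tolerance window around an
# observed m/z, under per-element count bounds.

#' Element-count bounds for formula decomposition
#'
#' Defaults follow common practice for aporphine-sized alkaloids:
#' C <= 30, H <= 60, N <= 10, O <= 20.
#'
#' @param ... Named per-element maxima, e.g. `element_bounds(C = 15, H = 25)`.
#'   Omitted elements are excluded from the search entirely.
#' @return A named integer vector of class `element_bounds`.
#' @examples
#' element_bounds()
#' element_bounds(C = 15, H = 25, N = 3, O = 6)
#' @export
element_bounds <- function(...) {
  b <- c(...)
  if (length(b) == 0L) b <- c(C = 30, H = 60, N = 10, O = 20)
  if (is.null(names(b)) || any(!nzchar(names(b))))
    stop("bounds must be named per element", call. = FALSE)
  unknown <- setdiff(names(b), names(.atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s) in bounds: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(b < 0) || any(b != round(b)))
    stop("bounds must be non-negative integers", call. = FALSE)
  structure(setNames(as.integer(b), names(b)), class = "element_bounds")
}

#' Mass tolerance with an absolute floor
#'
#' The effective matching window at mass m is `max(ppm * m / 1e6, floor)`.
#' The absolute floor (default 0.0015 u = 1.5 mDa) keeps low-mass matching
#' meaningful: at m/z 58 a 10-ppm window is only 0.6 mDa, narrower than the
#' deviations routinely observed for the aporphine family ion, so a pure ppm
#' criterion would reject its own diagnostic fragment.
#'
#' @param ppm Relative tolerance in parts per million (positive).
#' @param floor Absolute tolerance floor in u (non-negative); set 0 to disable.
#' @return A list of class `mass_tolerance`.
#' @examples
#' mass_tolerance(5)
#' mass_tolerance(10, floor = 0)
#' @export
mass_tolerance <- function(ppm = 5, floor = 0.0015) {
  if (length(ppm) != 1L || is.na(ppm) || ppm < 0)
    stop("'ppm' must be a single non-negative number", call. = FALSE)
  if (length(floor) != 1L || is.na(floor) || floor < 0)
    stop("'floor' must be a single non-negative mass in u", call. = FALSE)
  structure(list(ppm = as.numeric(ppm), floor = as.numeric(floor)),
            class = "mass_tolerance")
}

#' Effective tolerance window at a given mass
#'
#' @param tol A [mass_tolerance()] object.
#' @param mz Mass (or m/z) at which the window is evaluated.
#' @return Window half-width in u.
#' @export
tolerance_window <- function(tol, mz) {
  stopifnot(inherits(tol, "mass_tolerance"))
  pmax(tol$ppm * mz / 1e6, tol$floor)
}

.decompose_result <- function(counts_mat, elements, mz, charge) {
  # counts_mat: one row per candidate, one column per element
  if (is.null(counts_mat) || nrow(counts_mat) == 0L) {
    return(data.frame(formula = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE))
  }
  masses <- as.vector(counts_mat %*% .atomic_masses[elements]) -
    charge * .electron_mass
  fml <- apply(counts_mat, 1L, function(cnt) {
    formula_string(chem_formula(setNames(cnt, elements), charge = charge))
  })
  ppm <- ppm_error(mz, masses)
  ord <- order(abs(ppm), fml)
  data.frame(formula = fml[ord], theoretical_mz = masses[ord],
             ppm_error = ppm[ord], stringsAsFactors = FALSE)
}

#' Decompose an accurate mass into candidate elemental compositions
#'
#' Enumerates every composition within `bounds` whose ion m/z (at the given
#' charge) lies within the tolerance window of `mz`. The search iterates over
#' all non-hydrogen count combinations and solves the hydrogen count
#' arithmetically from the residual mass, which makes it complete: the result
#' set equals the brute-force enumeration over the full grid (see
#' [brute_force_decompose()]). No valence or ring-double-bond filtering is
#' applied.
#'
#' @param mz Observed m/z (positive).
#' @param charge Ion charge, 0 or 1 (default 1; positive-mode singly charged
#'   ions).
#' @param tol A [mass_tolerance()] object (default 5 ppm, 1.5 mDa floor).
#' @param bounds An [element_bounds()] vector.
#' @return A data frame with columns `formula`, `theoretical_mz`,
#'   `ppm_error`, ordered by absolute ppm error, ties broken by formula
#'   string.
#' @examples
#' decompose_mz(342.1703, charge = 1, tol = mass_tolerance(5))
#' @export
decompose_mz <- function(mz, charge = 1L, tol = mass_tolerance(),
                         bounds = element_bounds()) {
  if (length(mz) != 1L || is.na(mz) || mz <= 0)
    stop("'mz' must be a single positive number", call. = FALSE)
  if (!inherits(bounds, "element_bounds")) bounds <- do.call(element_bounds, as.list(bounds))
  if (length(bounds) == 0L) stop("empty element bounds", call. = FALSE)
  if (!charge %in% c(0L, 1L)) stop("charge must be 0 or 1", call. = FALSE)
  stopifnot(inherits(tol, "mass_tolerance"))

  window <- tolerance_window(tol, mz)
  target <- mz + charge * .electron_mass  # mass of the bare atom ensemble
  elements <- names(bounds)
  heavy <- setdiff(elements, "H")
  m_h <- .atomic_masses[["H"]]

  if (length(heavy) == 0L) {
    # hydrogen-only search space
    if (!"H" %in% elements) return(.decompose_result(NULL, elements, mz, charge))
    h <- seq.int(max(1L, ceiling((target - window) / m_h)),
                 min(bounds[["H"]], floor((target + window) / m_h)))
    h <- h[h >= 1L]
    if (length(h) == 0L) return(.decompose_result(NULL, "H", mz, charge))
    return(.decompose_result(matrix(h, ncol = 1L), "H", mz, charge))
  }

  grid <- as.matrix(expand.grid(lapply(bounds[heavy], function(mx) 0:mx),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- heavy
  partial <- as.vector(grid %*% .atomic_masses[heavy])
  keep <- partial <= target + window
  grid <- grid[keep, , drop = FALSE]
  partial <- partial[keep]

  h_max_bound <- if ("H" %in% elements) bounds[["H"]] else 0L
  resid <- target - partial
  h_lo <- pmax(0L, ceiling((resid - window) / m_h))
  h_hi <- pmin(h_max_bound, floor((resid + window) / m_h))
  n_h <- pmax(0L, h_hi - h_lo + 1L)
  keep <- n_h > 0L
  if (!any(keep)) return(.decompose_result(NULL, elements, mz, charge))

  idx <- rep.int(which(keep), n_h[keep])
  h_counts <- unlist(lapply(which(keep), function(i) seq.int(h_lo[i], h_hi[i])),
                     use.names = FALSE)
  counts <- cbind(grid[idx, , drop = FALSE], H = h_counts)
  # exact window check (the H range above is already exact, but recheck to be
  # robust against floating-point edge cases) and drop the empty composition
  masses <- partial[idx] + h_counts * m_h
  ok <- abs(masses - target) <= window & rowSums(counts) > 0
  counts <- counts[ok, , drop = FALSE]
  .decompose_result(counts[, elements[elements %in% colnames(counts)], drop = FALSE],
                    intersect(elements, colnames(counts)), mz, charge)
}

#' Brute-force reference decomposition
#'
#' Enumerates the full grid of counts within `bounds` (every element
#' including hydrogen) and filters by the tolerance window. Contractually
#' identical to [decompose_mz()]; intended as an independent correctness
#' oracle for tests with small bounds, not for production use.
#'
#' @inheritParams decompose_mz
#' @return Same shape and ordering as [decompose_mz()].
#' @export
brute_force_decompose <- function(mz, charge = 1L, tol = mass_tolerance(),
                                  bounds = element_bounds()) {
  if (length(mz) != 1L || is.na(mz) || mz <= 0)
    stop("'mz' must be a single positive number", call. = FALSE)
  if (!inherits(bounds, "element_bounds")) bounds <- do.call(element_bounds, as.list(bounds))
  if (length(bounds) == 0L) stop("empty element bounds", call. = FALSE)
  if (!charge %in% c(0L, 1L)) stop("charge must be 0 or 1", call. = FALSE)
  stopifnot(inherits(tol, "mass_tolerance"))

  window <- tolerance_window(tol, mz)
  elements <- names(bounds)
  grid <- as.matrix(expand.grid(lapply(bounds, function(mx) 0:mx),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- elements
  masses <- as.vector(grid %*% .atomic_masses[elements]) -
    charge * .electron_mass
  keep <- abs(masses - mz) <= window & rowSums(grid) > 0
  .decompose_result(grid[keep, , drop = FALSE], elements, mz, charge)
}
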