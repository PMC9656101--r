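# Neutral-loss / diagnostic-fragment-ion rulebase. Aporphine alkaloids eject
# a small amine-containing neutral whose composition reports the substitution
# state of the ring nitrogen: C2H7N (quaternary N,N-dimethyl ammonium ions),
# CH3NH2 (tertiary N-methyl amines), NH3 (secondary N-H amines), with NH and
# C2H5NO as the analogous losses of N-oxo / N-acyl compounds. Small
# oxygen-side losses (CH3OH, CH3O, CO, H2O, CH3) recur across the family but
# carry no class information. The m/z ~58.065 C3H8N+ fragment is a family-
# level diagnostic ion.

.class_levels <- c("quaternary", "tertiary", "secondary", "N_acyl_or_oxo")

# Precedence when several class-bearing losses match, from the most
# N-H-dependent loss downward. The C2H7N ring-opening loss occurs from both
# quaternary ammonium [M]+ ions and protonated tertiary amines (the proton
# supplies the extra N-H), whereas a CH3NH2 loss requires an N-methyl with an
# available N-H (tertiary) and an NH3 loss a free N-H pair (secondary), so
# the smaller amine is the more specific indicator and wins.
.class_precedence <- c("secondary", "tertiary", "quaternary", "N_acyl_or_oxo")

#' Neutral-loss rule table
#'
#' Loads the packaged rulebase (or a user-edited copy in the same CSV layout:
#' `label, composition, implication, note`) and attaches exact and nominal
#' masses computed from the pinned atomic masses. Multi-step fragmentation
#' chains are represented precursor-relative as their cumulative composition.
#'
#' @param path CSV to read; defaults to the packaged rule table.
#' @return A data frame with columns `label`, `composition`, `implication`,
#'   `exact_mass` (u), `nominal_mass` (integer), `note`.
#' @examples
#' neutral_loss_rules()[, c("label", "exact_mass", "implication")]
#' @export
neutral_loss_rules <- function(path = system.file("extdata", "neutral_loss_rules.csv",
                                                  package = "aporphiner")) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "composition", "implication") %in% names(rules)))
  bad <- setdiff(rules$implication, c(.class_levels, "generic"))
  if (length(bad))
    stop("unknown class implication(s): ", paste(bad, collapse = ", "), call. = FALSE)
  parsed <- lapply(rules$composition, parse_formula)
  rules$exact_mass <- vapply(parsed, monoisotopic_mz, numeric(1))
  nominal <- c(H = 1, C = 12, N = 14, O = 16, S = 32, P = 31)
  rules$nominal_mass <- vapply(parsed, function(f)
    as.integer(sum(f$counts * nominal[names(f$counts)])), integer(1))
  if (!"note" %in% names(rules)) rules$note <- ""
  rules
}

#' Diagnostic fragment ion table
#'
#' The aporphine family ion: the C3H8N+ iminium fragment near m/z 58.065,
#' shared across quaternary, tertiary and secondary members. Matched against
#' fragment m/z with the absolute-floor tolerance.
#'
#' @return A data frame with columns `label`, `composition`, `mz`.
#' @export
diagnostic_ions <- function() {
  data.frame(label = "aporphine family ion", composition = "C3H8N",
             mz = monoisotopic_mz("C3H8N", charge = 1L),
             stringsAsFactors = FALSE)
}

#' Precursor-relative neutral losses of a spectrum
#'
#' One entry per fragment peak: `loss_mass = precursor_mz - fragment_mz`.
#' Multi-step fragmentation paths therefore appear as their cumulative loss.
#' Fragments at or above the precursor are skipped with a message.
#'
#' @param spectrum An [new_spectrum()] object.
#' @return Data frame with columns `fragment_mz`, `loss_mass`.
#' @export
extract_neutral_losses <- function(spectrum) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  mz <- spectrum$peaks$mz
  above <- mz >= spectrum$precursor_mz
  if (any(above))
    message(sum(above), " fragment peak(s) at or above the precursor skipped in '",
            spectrum$spectrum_id, "'")
  mz <- mz[!above]
  data.frame(fragment_mz = mz, loss_mass = spectrum$precursor_mz - mz)
}

#' Match a neutral-loss mass against the rulebase
#'
#' Picks the rule with the smallest absolute deviation whose exact mass lies
#' within `max(ppm-window, floor)` of `loss_mass`. Exact masses disambiguate
#' rules sharing a nominal mass (CH3NH2 at 31.0422 u versus the CH3O radical
#' at 31.0184 u).
#'
#' @param loss_mass Observed neutral-loss mass (u, positive).
#' @param tol A [mass_tolerance()]; the default 10 ppm with 1.5 mDa floor is
#'   floor-dominated for all losses in the rulebase.
#' @param rules Rule table from [neutral_loss_rules()].
#' @return The matching rule row (single-row data frame with an extra
#'   `deviation` column, u), or `NULL` when nothing matches.
#' @examples
#' match_loss(31.0422)$label
#' @export
match_loss <- function(loss_mass, tol = mass_tolerance(10, 0.0015),
                       rules = neutral_loss_rules()) {
  if (length(loss_mass) != 1L || is.na(loss_mass) || loss_mass <= 0)
    stop("'loss_mass' must be a single positive mass", call. = FALSE)
  dev <- loss_mass - rules$exact_mass
  ok <- abs(dev) <= tolerance_window(tol, loss_mass)
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(abs(dev[ok]))]
  cbind(rules[i, , drop = FALSE], deviation = dev[i], row.names = NULL)
}

#' Classify the nitrogen substitution type of a spectrum
#'
#' Matches every precursor-relative neutral loss against the rulebase and the
#' fragment peaks against the family diagnostic ion, then assigns the
#' nitrogen class by specificity precedence secondary > tertiary >
#' quaternary > N-acyl/oxo: the C2H7N ring-opening loss is shared by
#' quaternary cations and protonated tertiary amines, while CH3NH2 and NH3
#' losses require free N-H and are observed only in their own classes.
#' Generic losses are recorded as evidence but never set the class;
#' a spectrum with no class-bearing match is `"unknown"`.
#'
#' @param spectrum An [new_spectrum()] object.
#' @param tol A [mass_tolerance()] for loss and diagnostic-ion matching.
#' @param rules Rule table from [neutral_loss_rules()].
#' @return A list of class `class_evidence`: `assigned_class`,
#'   `matched_rules` (data frame: `rule_label`, `fragment_mz`, `loss_mass`,
#'   `deviation_mda`, `implication`), `family_ion_present`,
#'   `family_ion_mz` (`NA` when absent).
#' @examples
#' sp <- new_spectrum("std", 282.1495,
#'                    peaks = data.frame(mz = 251.1067, intensity = 1e5))
#' classify_spectrum(sp)$assigned_class
#' @export
classify_spectrum <- function(spectrum, tol = mass_tolerance(10, 0.0015),
                              rules = neutral_loss_rules()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  losses <- extract_neutral_losses(spectrum)
  hits <- do.call(rbind, lapply(seq_len(nrow(losses)), function(i) {
    m <- match_loss(losses$loss_mass[i], tol = tol, rules = rules)
    if (is.null(m)) return(NULL)
    data.frame(rule_label = m$label, fragment_mz = losses$fragment_mz[i],
               loss_mass = losses$loss_mass[i],
               deviation_mda = m$deviation * 1e3,
               implication = m$implication, stringsAsFactors = FALSE)
  }))
  if (is.null(hits))
    hits <- data.frame(rule_label = character(0), fragment_mz = numeric(0),
                       loss_mass = numeric(0), deviation_mda = numeric(0),
                       implication = character(0))

  dfi <- diagnostic_ions()
  dev <- spectrum$peaks$mz - dfi$mz[1]
  in_win <- abs(dev) <= tolerance_window(tol, dfi$mz[1])
  family_present <- any(in_win)
  family_mz <- if (family_present) spectrum$peaks$mz[in_win][which.min(abs(dev[in_win]))] else NA_real_

  present <- intersect(.class_precedence, hits$implication)
  structure(list(assigned_class = if (length(present)) present[1] else "unknown",
                 matched_rules = hits,
                 family_ion_present = family_present,
                 family_ion_mz = family_mz),
            class = "class_evidence")
}

#' @export
print.class_evidence <- function(x, ...) {
  cat(sprintf("<class_evidence> class: %s  (family ion: %s)\n",
              x$assigned_class, if (x$family_ion_present) "present" else "absent"))
  if (nrow(x$matched_rules)) {
    print(x$matched_rules, row.names = FALSE, digits = 6)
  } else cat("  no rule matched\n")
  invisible(x)
}

# compact one-string rendering for report tables
.evidence_string <- function(ev) {
  parts <- character(0)
  if (nrow(ev$matched_rules))
    parts <- sprintf("-%s@%.4f", ev$matched_rules$rule_label, ev$matched_rules$fragment_mz)
  if (ev$family_ion_present)
    parts <- c(parts, sprintf("DFI@%.4f", ev$family_ion_mz))
  paste(parts, collapse = "|")
}
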