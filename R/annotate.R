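# End-to-end annotation: match MS2 spectra against a candidate library on
# precursor mass (and optionally retention time), attach neutral-loss class
# evidence and reference-fragment match counts, and emit a report table.

.annotation_columns <- c("spectrum_id", "rt_min", "experimental_mz", "species",
                         "ion_formula", "theoretical_mz", "ppm_error",
                         "identification", "nitrogen_class", "assigned_class",
                         "matched_fragments", "evidence", "rank")

.empty_annotation <- function() {
  out <- data.frame(spectrum_id = character(0), rt_min = numeric(0),
                    experimental_mz = numeric(0), species = character(0),
                    ion_formula = character(0), theoretical_mz = numeric(0),
                    ppm_error = numeric(0), identification = character(0),
                    nitrogen_class = character(0), assigned_class = character(0),
                    matched_fragments = integer(0), evidence = character(0),
                    rank = integer(0), stringsAsFactors = FALSE)
  out
}

#' Annotate a single MS2 spectrum against a candidate library
#'
#' Retains every library entry whose ion m/z lies within the precursor
#' tolerance of the spectrum's precursor (and, when `rt_window` is given and
#' both retention times are known, within that window). Peaks below
#' `min_intensity` are dropped before any fragment matching; a spectrum left
#' with no peaks still receives precursor-only annotations with empty
#' evidence. Each retained candidate is scored by the number of its
#' reference fragments found in the spectrum within the fragment tolerance.
#'
#' Ranking: matched reference fragments (descending), then retention-time
#' proximity when both sides carry a retention time (positional isomers share
#' composition and fragments, so elution order is the only printed
#' discriminator -- proximity is used as a tie-break even when window
#' filtering is off), then absolute precursor ppm error, then name.
#'
#' @param spectrum An [new_spectrum()] object.
#' @param library A `candidate_library` from [load_curated_library()], or any
#'   data frame with columns `name`, `species`, `ion_formula`,
#'   `theoretical_mz` (optional: `peak_id`, `nitrogen_class`, `reference_rt`,
#'   `reference_fragments`).
#' @param ms1_tol Precursor [mass_tolerance()] (default 5 ppm).
#' @param ms2_tol Fragment [mass_tolerance()] (default 10 ppm).
#' @param rt_window Retention-time window in minutes used to *filter*
#'   candidates, or `NULL` (default) to disable RT filtering.
#' @param min_intensity Minimum peak intensity retained (default 10000).
#' @param rules Neutral-loss rule table for class evidence.
#' @return A data frame with one row per retained candidate (zero rows if
#'   none): `spectrum_id`, `rt_min`, `experimental_mz`, `species`,
#'   `ion_formula`, `theoretical_mz`, `ppm_error`, `identification`,
#'   `nitrogen_class` (library class), `assigned_class` (from fragment
#'   evidence), `matched_fragments`, `evidence`, `rank` (1 = best).
#' @examples
#' lib <- load_curated_library()
#' sp <- new_spectrum("x", 342.1703, rt = 7.58,
#'                    peaks = data.frame(mz = c(58.0658, 297.1123),
#'                                       intensity = c(9e5, 1e6)))
#' annotate_spectrum(sp, lib)[1, c("identification", "assigned_class")]
#' @export
annotate_spectrum <- function(spectrum, library,
                              ms1_tol = mass_tolerance(5),
                              ms2_tol = mass_tolerance(10),
                              rt_window = NULL, min_intensity = 10000,
                              rules = neutral_loss_rules()) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  if (is.null(library) || nrow(library) == 0L)
    stop("'library' must be a non-empty candidate table", call. = FALSE)

  filtered <- spectrum
  filtered$peaks <- spectrum$peaks[spectrum$peaks$intensity >= min_intensity, ,
                                   drop = FALSE]

  dev <- spectrum$precursor_mz - library$theoretical_mz
  keep <- abs(dev) <= tolerance_window(ms1_tol, spectrum$precursor_mz)
  if (!is.null(rt_window) && "reference_rt" %in% names(library) &&
      !is.na(spectrum$rt)) {
    rt_ok <- is.na(library$reference_rt) |
      abs(library$reference_rt - spectrum$rt) <= rt_window
    keep <- keep & rt_ok
  }
  cand <- library[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_annotation())

  evidence <- classify_spectrum(filtered, tol = ms2_tol, rules = rules)
  ev_str <- .evidence_string(evidence)

  n_matched <- vapply(seq_len(nrow(cand)), function(i) {
    refs <- if ("reference_fragments" %in% names(cand)) cand$reference_fragments[[i]] else numeric(0)
    if (length(refs) == 0L || nrow(filtered$peaks) == 0L) return(0L)
    sum(vapply(refs, function(r)
      any(abs(filtered$peaks$mz - r) <= tolerance_window(ms2_tol, r)), logical(1)))
  }, integer(1))

  ppm <- ppm_error(spectrum$precursor_mz, cand$theoretical_mz)
  rt_dist <- if ("reference_rt" %in% names(cand) && !is.na(spectrum$rt))
    abs(cand$reference_rt - spectrum$rt) else rep(NA_real_, nrow(cand))
  rt_dist[is.na(rt_dist)] <- Inf

  ord <- order(-n_matched, rt_dist, abs(ppm), cand$name)
  out <- data.frame(spectrum_id = spectrum$spectrum_id,
                    rt_min = spectrum$rt,
                    experimental_mz = spectrum$precursor_mz,
                    species = cand$species[ord],
                    ion_formula = cand$ion_formula[ord],
                    theoretical_mz = cand$theoretical_mz[ord],
                    ppm_error = ppm[ord],
                    identification = cand$name[ord],
                    nitrogen_class = if ("nitrogen_class" %in% names(cand))
                      cand$nitrogen_class[ord] else NA_character_,
                    assigned_class = evidence$assigned_class,
                    matched_fragments = n_matched[ord],
                    evidence = ev_str,
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate a set of spectra and build a report table
#'
#' Runs [annotate_spectrum()] over every spectrum, concatenates the per-
#' candidate rows, and orders the report by retention time then precursor
#' m/z. Unreadable entries (anything that is not an `ms2_spectrum`, or that
#' fails annotation) are skipped and counted.
#'
#' @param spectra A list of [new_spectrum()] objects.
#' @inheritParams annotate_spectrum
#' @return A data frame of class `annotation_report`: one row per spectrum x
#'   retained candidate, with attributes `n_spectra` (input count),
#'   `n_annotated` (spectra with at least one annotation) and `warnings`
#'   (character vector describing skipped records).
#' @examples
#' fx <- build_fixture_set()
#' rep <- annotate_run(fx$spectra[1:3], load_curated_library())
#' attr(rep, "n_annotated")
#' @export
annotate_run <- function(spectra, library,
                         ms1_tol = mass_tolerance(5),
                         ms2_tol = mass_tolerance(10),
                         rt_window = NULL, min_intensity = 10000,
                         rules = neutral_loss_rules()) {
  warnings <- character(0)
  annotated_ids <- character(0)
  parts <- list()
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (!inherits(sp, "ms2_spectrum")) {
      warnings <- c(warnings, sprintf("record %d skipped: not an ms2_spectrum", i))
      next
    }
    ann <- tryCatch(
      annotate_spectrum(sp, library, ms1_tol = ms1_tol, ms2_tol = ms2_tol,
                        rt_window = rt_window, min_intensity = min_intensity,
                        rules = rules),
      error = function(e) {
        warnings <<- c(warnings, sprintf("record %d (%s) skipped: %s",
                                         i, sp$spectrum_id, conditionMessage(e)))
        NULL
      })
    if (is.null(ann)) next
    if (nrow(ann)) {
      # count spectra (occurrences), not unique compounds
      annotated_ids <- c(annotated_ids, paste0(i, ":", sp$spectrum_id))
      parts[[length(parts) + 1L]] <- ann
    }
  }
  out <- if (length(parts)) do.call(rbind, parts) else .empty_annotation()
  if (nrow(out)) {
    ord <- order(out$rt_min, out$experimental_mz, out$rank)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("annotation_report", "data.frame"),
            n_spectra = length(spectra), n_annotated = length(annotated_ids),
            warnings = warnings)
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf("<annotation_report> %d spectra, %d with >=1 annotation, %d rows\n",
              attr(x, "n_spectra"), attr(x, "n_annotated"), nrow(x)))
  w <- attr(x, "warnings")
  if (length(w)) cat("warnings:\n", paste(" -", w, collapse = "\n"), "\n")
  NextMethod()
}
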