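# Fixture generation: rebuild the 70 reference spectra from the curated
# library (precursor = recorded experimental m/z, fragments = recorded
# reference lists), plus seeded mass jitter and decoy spectra for negative
# controls. Everything here is a pure function of (parameters, seed).

# Printed relative abundances exist only for the lirinidine-type spectra
# (peaks 23/31/45); all other intensities are synthetic rank-decreasing
# values and never influence annotation beyond the intensity floor.
.printed_abundance <- c("58.0660" = 90, "191.0855" = 5, "219.0806" = 23,
                        "237.0911" = 100)

.fixture_intensity <- function(frag_mz, base = 1e6, decay = 0.7) {
  ints <- round(base * decay^(seq_along(frag_mz) - 1))
  printed <- .printed_abundance[sprintf("%.4f", frag_mz)]
  ints[!is.na(printed)] <- printed[!is.na(printed)] * 1e4
  ints
}

#' Build the packaged fixture spectrum set
#'
#' Reconstructs one centroided MS2 spectrum per curated library entry:
#' precursor = the recorded experimental m/z, retention time = the recorded
#' elution time, fragment m/z = the entry's reference fragment list.
#' Intensities are synthetic (rank-decreasing from `base_intensity`, all at
#' or above the default processing floor of 10000), except where a printed
#' relative abundance is recorded. The accompanying manifest classifies each
#' rebuilt spectrum with the neutral-loss rulebase and states, entry by
#' entry, whether a class-bearing loss is present and whether the assigned
#' class agrees with the curated class -- disagreements are enumerated, not
#' hidden.
#'
#' @param library Curated library (default [load_curated_library()]).
#' @param base_intensity Intensity of the first-listed fragment.
#' @return A list with `spectra` (list of [new_spectrum()], one per entry,
#'   ids `"peak_<id>"`) and `manifest` (data frame: `peak_id`, `rt_min`,
#'   `precursor_mz`, `n_fragments`, `expected_name`, `expected_class`,
#'   `n_acyl_or_oxo`, `assigned_class`, `has_class_loss`, `class_agrees`,
#'   `family_ion_present`).
#' @examples
#' fx <- build_fixture_set()
#' length(fx$spectra)
#' subset(fx$manifest, !class_agrees & has_class_loss)
#' @export
build_fixture_set <- function(library = load_curated_library(),
                              base_intensity = 1e6) {
  rules <- neutral_loss_rules()
  spectra <- vector("list", nrow(library))
  rows <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    frags <- library$reference_fragments[[i]]
    if (any(frags >= library$experimental_mz[i]))
      stop("fixture build error for peak_id ", library$peak_id[i],
           ": fragment at or above precursor", call. = FALSE)
    sp <- new_spectrum(paste0("peak_", library$peak_id[i]),
                       precursor_mz = library$experimental_mz[i],
                       rt = library$reference_rt[i],
                       peaks = data.frame(mz = frags,
                                          intensity = .fixture_intensity(frags, base_intensity)))
    ev <- classify_spectrum(sp, rules = rules)
    expected <- library$nitrogen_class[i]
    agrees <- ev$assigned_class == expected ||
      (library$n_acyl_or_oxo[i] && ev$assigned_class == "N_acyl_or_oxo")
    spectra[[i]] <- sp
    rows[[i]] <- data.frame(peak_id = library$peak_id[i],
                            rt_min = library$reference_rt[i],
                            precursor_mz = library$experimental_mz[i],
                            n_fragments = length(frags),
                            expected_name = library$name[i],
                            expected_class = expected,
                            n_acyl_or_oxo = library$n_acyl_or_oxo[i],
                            assigned_class = ev$assigned_class,
                            has_class_loss = ev$assigned_class != "unknown",
                            class_agrees = agrees,
                            family_ion_present = ev$family_ion_present,
                            stringsAsFactors = FALSE)
  }
  list(spectra = spectra, manifest = do.call(rbind, rows))
}

#' Apply seeded ppm mass jitter to spectra
#'
#' Multiplies every m/z (precursor and fragments) by `1 + e/1e6` with
#' `e ~ N(0, ppm_sd)`, reproducibly under the given seed. `ppm_sd = 0`
#' returns the input unchanged.
#'
#' @param spectra List of [new_spectrum()] objects.
#' @param ppm_sd Standard deviation of the jitter in ppm (>= 0).
#' @param seed Integer seed.
#' @return A list of jittered spectra.
#' @export
jitter_spectra <- function(spectra, ppm_sd, seed) {
  if (ppm_sd < 0) stop("'ppm_sd' must be >= 0", call. = FALSE)
  if (ppm_sd == 0) return(spectra)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(spectra, function(sp) {
    sp$precursor_mz <- sp$precursor_mz * (1 + stats::rnorm(1, 0, ppm_sd) / 1e6)
    if (nrow(sp$peaks)) {
      sp$peaks$mz <- sp$peaks$mz *
        (1 + stats::rnorm(nrow(sp$peaks), 0, ppm_sd) / 1e6)
      sp$peaks <- sp$peaks[order(sp$peaks$mz), , drop = FALSE]
    }
    sp
  })
}

#' Generate decoy spectra that never match the library
#'
#' Draws precursor m/z uniformly over `mz_range` (the acquisition mass
#' range), rejecting any draw within `exclusion_ppm` of a library ion, so
#' the decoys cannot annotate at the 5 ppm precursor tolerance. Each decoy
#' carries two synthetic fragment peaks.
#'
#' @param n Number of decoys (>= 0).
#' @param seed Integer seed.
#' @param library Library whose ion masses are avoided.
#' @param mz_range Precursor range (default c(120, 1000)).
#' @param exclusion_ppm Half-width of the exclusion zone around each library
#'   ion, in ppm (default 10).
#' @return A list of [new_spectrum()] objects.
#' @export
make_decoy_spectra <- function(n, seed, library = load_curated_library(),
                               mz_range = c(120, 1000), exclusion_ppm = 10) {
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  if (n == 0) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ions <- library$theoretical_mz
  out <- vector("list", n)
  made <- 0L
  while (made < n) {
    mz <- stats::runif(1, mz_range[1], mz_range[2])
    if (any(abs(mz - ions) <= exclusion_ppm * ions / 1e6)) next
    made <- made + 1L
    frag <- sort(stats::runif(2, 50, mz - 20))
    out[[made]] <- new_spectrum(paste0("decoy_", made), mz,
                                peaks = data.frame(mz = frag,
                                                   intensity = c(2e5, 1e5)))
  }
  out
}
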