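# Curated aporphine reference library and in-silico candidate generation.
#
# The library holds 70 curated identifications (quaternary aporphinium
# cations detected as [M]+, tertiary/secondary amines as [M+H]+), each with
# retention time, printed theoretical/experimental m/z, resolved ion
# composition, nitrogen class and reference fragment list. Transcription
# corrections are never silent: they ship as an errata table
# (see library_errata()).

#' Load the curated aporphine alkaloid library
#'
#' Reads the packaged 70-entry reference library, recomputes every
#' theoretical ion m/z from the resolved ion composition and self-checks it
#' against the recorded experimental m/z (must agree within 5 ppm; a failing
#' row aborts the load, naming the entry).
#'
#' Ion compositions are stored already resolved: where the original "+H"
#' notation's hydrogen count already included the proton (see
#' [library_errata()]), `ion_formula` is the printed composition itself, and
#' otherwise it is the neutral composition plus one H. All ion compositions
#' have charge +1.
#'
#' @param path CSV resource to read; defaults to the packaged library.
#' @return A data frame of class `candidate_library` with one row per entry:
#'   `peak_id`, `name`, `species` (`"[M]+"` or `"[M+H]+"`), `ion_formula`,
#'   `nitrogen_class`, `n_acyl_or_oxo`, `novel_flag`, `reference_rt` (min),
#'   `theoretical_mz` (recomputed, unrounded), `experimental_mz`,
#'   `theoretical_mz_printed`, `ppm_printed`, `reference_fragments`
#'   (list-column of numeric m/z), `note`.
#' @examples
#' lib <- load_curated_library()
#' nrow(lib)
#' lib[lib$peak_id == 27, c("name", "species", "ion_formula", "nitrogen_class")]
#' @export
load_curated_library <- function(path = system.file("extdata", "curated_library.csv",
                                                    package = "aporphiner")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  theo <- vapply(raw$ion_formula, function(f) monoisotopic_mz(f, charge = 1L),
                 numeric(1), USE.NAMES = FALSE)
  ppm <- ppm_error(raw$experimental_mz, theo)
  bad <- which(abs(ppm) > 5)
  if (length(bad))
    stop("curated library failed its mass self-check (>5 ppm) for peak_id ",
         paste(raw$peak_id[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(peak_id = raw$peak_id, name = raw$name, species = raw$species,
                    ion_formula = raw$ion_formula,
                    nitrogen_class = raw$nitrogen_class,
                    n_acyl_or_oxo = raw$n_acyl_or_oxo,
                    novel_flag = raw$novel_flag,
                    reference_rt = raw$rt_min,
                    theoretical_mz = theo,
                    experimental_mz = raw$experimental_mz,
                    theoretical_mz_printed = raw$theoretical_mz_printed,
                    ppm_printed = raw$ppm_printed,
                    note = raw$conv_note,
                    stringsAsFactors = FALSE)
  out$reference_fragments <- lapply(strsplit(raw$fragments, ";", fixed = TRUE),
                                    as.numeric)
  if (nrow(out) != 70L)
    stop("curated library must have exactly 70 entries, got ", nrow(out),
         call. = FALSE)
  class(out) <- c("candidate_library", "data.frame")
  out
}

#' Documented transcription corrections for the curated library
#'
#' Every place where the packaged library deviates from the printed source
#' table (conflicting formulas resolved by mass, a restored missing row,
#' "+H" notations whose hydrogen count already includes the proton,
#' truncated theoretical masses, and the not-novel curation choice) is
#' recorded here rather than applied silently.
#'
#' @return A data frame with columns `peak_id`, `field`, `printed`,
#'   `corrected`, `reason`.
#' @export
library_errata <- function() {
  utils::read.csv(system.file("extdata", "library_errata.csv",
                              package = "aporphiner"),
                  stringsAsFactors = FALSE)
}

#' Substituent transformation table
#'
#' Elemental-composition deltas for the substituent chemistry observed on
#' aporphine scaffolds: methyl/hydroxy/methoxy gains and losses, oxidation of
#' a methylene to a ketone, methylenedioxy bridge formation from adjacent
#' OH/OCH3 (net -H2 after the separate demethylation), O-acetylation,
#' glucosylation, and +/- H2.
#'
#' @return A data frame with columns `label`, `delta` (signed composition as
#'   a list-column of named numeric vectors), `delta_string`.
#' @examples
#' transformations()$label
#' @export
transformations <- function() {
  deltas <- list(
    methylation = c(C = 1, H = 2),
    demethylation = c(C = -1, H = -2),
    hydroxylation = c(O = 1),
    dehydroxylation = c(O = -1),
    methoxylation = c(C = 1, H = 2, O = 1),
    demethoxylation = c(C = -1, H = -2, O = -1),
    methylene_to_ketone = c(O = 1, H = -2),
    methylenedioxy_formation = c(H = -2),
    acetylation = c(C = 2, H = 2, O = 1),
    glucosylation = c(C = 6, H = 10, O = 5),
    hydrogenation = c(H = 2),
    dehydrogenation = c(H = -2)
  )
  data.frame(label = names(deltas),
             delta = I(unname(deltas)),
             delta_string = vapply(deltas, function(d)
               paste0(ifelse(d > 0, "+", "-"), names(d), abs(d), collapse = ""),
               character(1)),
             stringsAsFactors = FALSE)
}

#' Template scaffolds for candidate enumeration
#'
#' The two enumeration templates: magnoflorine as the permanent aporphinium
#' cation (C20H24NO4+, detected as \eqn{[M]^+}) and roemerine as a neutral
#' tertiary amine (C18H17NO2, detected as \eqn{[M+H]^+}).
#'
#' @return A data frame with columns `name`, `base_formula` (composition the
#'   transformations act on), `species`.
#' @export
scaffolds <- function() {
  data.frame(name = c("magnoflorine", "roemerine"),
             base_formula = c("C20H24NO4", "C18H17NO2"),
             species = c("[M]+", "[M+H]+"),
             stringsAsFactors = FALSE)
}

.ion_of <- function(base_formula, species) {
  f <- parse_formula(base_formula)
  if (species == "[M]+") { f$charge <- 1L; f } else protonate(f)
}

#' Enumerate derivative candidates from scaffolds
#'
#' Applies up to `max_depth` substituent transformations (in every order) to
#' each scaffold's base composition, silently skipping branches that would
#' drive an element count negative, and deduplicates by (ion formula,
#' species), keeping the shallowest (then lexicographically first)
#' provenance. The scaffolds themselves (depth 0) are always included.
#'
#' @param scaffold_table Data frame as returned by [scaffolds()].
#' @param transform_table Data frame as returned by [transformations()].
#' @param max_depth Maximum number of stacked transformations (default 2;
#'   deeper enumeration grows combinatorially).
#' @return A data frame with columns `name` (provenance string), `scaffold`,
#'   `species`, `ion_formula`, `theoretical_mz`, `depth`, ordered by mass
#'   then provenance.
#' @examples
#' cand <- enumerate_candidates(max_depth = 1)
#' subset(cand, ion_formula == "C20H24NO5")  # hydroxylated magnoflorine
#' @export
enumerate_candidates <- function(scaffold_table = scaffolds(),
                                 transform_table = transformations(),
                                 max_depth = 2L) {
  if (max_depth < 1L) stop("'max_depth' must be >= 1", call. = FALSE)
  rows <- list()
  for (s in seq_len(nrow(scaffold_table))) {
    frontier <- list(list(counts = .ion_of(scaffold_table$base_formula[s],
                                           scaffold_table$species[s])$counts,
                          labels = character(0)))
    for (depth in 0:max_depth) {
      for (node in frontier) {
        rows[[length(rows) + 1L]] <- list(
          scaffold = scaffold_table$name[s],
          species = scaffold_table$species[s],
          counts = node$counts, labels = node$labels, depth = depth)
      }
      if (depth == max_depth) break
      nxt <- list()
      for (node in frontier) {
        for (t in seq_len(nrow(transform_table))) {
          d <- transform_table$delta[[t]]
          cnt <- node$counts
          els <- union(names(cnt), names(d))
          new <- setNames(numeric(length(els)), els)
          new[names(cnt)] <- cnt
          new[names(d)] <- new[names(d)] + d
          if (any(new < 0) || sum(new) == 0) next  # infeasible branch
          nxt[[length(nxt) + 1L]] <- list(counts = new[new > 0],
                                          labels = c(node$labels,
                                                     transform_table$label[t]))
        }
      }
      frontier <- nxt
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    f <- chem_formula(r$counts, charge = 1L)
    prov <- paste(c(r$scaffold, r$labels), collapse = " + ")
    data.frame(name = prov, scaffold = r$scaffold, species = r$species,
               ion_formula = formula_string(f),
               theoretical_mz = monoisotopic_mz(f),
               depth = r$depth, stringsAsFactors = FALSE)
  }))
  # dedupe by (ion formula, species): keep shallowest, then first provenance
  out <- out[order(out$depth, out$name), ]
  out <- out[!duplicated(out[, c("ion_formula", "species")]), ]
  out <- out[order(out$theoretical_mz, out$name), ]
  rownames(out) <- NULL
  out
}

#' Build a PRM inclusion list
#'
#' One target row per candidate: the precursor m/z (4 decimals), ion species,
#' isolation window and provenance, sorted by m/z. Accepts either the
#' curated library or an [enumerate_candidates()] table (any data frame with
#' `theoretical_mz`, `species` and `name`).
#'
#' @param candidates Candidate table.
#' @param window_mz Isolation window width in m/z units (default 3.0).
#' @return A data frame with columns `mz`, `species`, `window_mz`, `name`.
#' @examples
#' head(build_inclusion_list(load_curated_library()))
#' @export
build_inclusion_list <- function(candidates, window_mz = 3.0) {
  if (length(window_mz) != 1L || is.na(window_mz) || window_mz <= 0)
    stop("'window_mz' must be a single positive width", call. = FALSE)
  need <- c("theoretical_mz", "species", "name")
  if (!all(need %in% names(candidates)))
    stop("'candidates' needs columns ", paste(need, collapse = ", "), call. = FALSE)
  out <- data.frame(mz = round_mz(candidates$theoretical_mz),
                    species = candidates$species,
                    window_mz = rep(window_mz, nrow(candidates)),
                    name = candidates$name, stringsAsFactors = FALSE)
  out <- out[order(out$mz, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
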