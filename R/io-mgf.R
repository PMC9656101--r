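# MGF reading/writing (standard BEGIN IONS / END IONS dialect) and the
# annotation report writer. Reports are bit-stable: fixed column order, m/z
# at 4 decimals, ppm at 2, intensities as integers.

#' Read an MGF peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. The first `PEPMASS` token is the
#' precursor m/z; `RTINSECONDS` is converted to minutes; `TITLE` becomes the
#' spectrum id (falling back to the block index); any other `KEY=value`
#' header is preserved in the spectrum metadata. A block without `PEPMASS`
#' is skipped with a warning; a malformed line aborts with its line number.
#'
#' @param path Path to an MGF file.
#' @return A list of [new_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  hdr <- list(); pk_mz <- numeric(0); pk_int <- numeric(0)
  block_no <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("malformed MGF: nested BEGIN IONS at line ", i, call. = FALSE)
      in_block <- TRUE; block_no <- block_no + 1L
      hdr <- list(); pk_mz <- numeric(0); pk_int <- numeric(0)
    } else if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF: stray END IONS at line ", i, call. = FALSE)
      in_block <- FALSE
      if (is.null(hdr$PEPMASS)) {
        warning("MGF block ", block_no, " has no PEPMASS; skipped", call. = FALSE)
        next
      }
      pep <- as.numeric(strsplit(trimws(hdr$PEPMASS), "[ \t]+")[[1]][1])
      rt <- if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) / 60 else NA_real_
      id <- if (!is.null(hdr$TITLE)) hdr$TITLE else paste0("spectrum_", block_no)
      meta <- hdr[setdiff(names(hdr), c("PEPMASS", "RTINSECONDS", "TITLE"))]
      spectra[[length(spectra) + 1L]] <-
        new_spectrum(id, pep, rt = rt,
                     peaks = data.frame(mz = pk_mz, intensity = pk_int),
                     metadata = meta)
    } else if (in_block) {
      if (grepl("=", ln, fixed = TRUE)) {
        key <- sub("=.*$", "", ln)
        hdr[[key]] <- sub("^[^=]*=", "", ln)
      } else {
        tok <- strsplit(ln, "[ \t]+")[[1]]
        vals <- suppressWarnings(as.numeric(tok))
        if (length(tok) < 2L || any(is.na(vals[1:2])))
          stop("malformed MGF peak line at line ", i, ": '", ln, "'", call. = FALSE)
        pk_mz <- c(pk_mz, vals[1]); pk_int <- c(pk_int, vals[2])
      }
    }
    # content outside blocks (other than comments) is ignored, as in common
    # MGF dialects
  }
  if (in_block) stop("malformed MGF: unterminated block at end of file", call. = FALSE)
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: m/z serialized at 4 decimals, intensities as
#' integers, retention time as `RTINSECONDS`. Byte-stable for identical
#' input.
#'
#' @param spectra List of [new_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "ms2_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.4f", sp$precursor_mz), con)
    if (!is.na(sp$rt))
      writeLines(sprintf("RTINSECONDS=%.6g", sp$rt * 60), con)
    for (key in names(sp$metadata))
      writeLines(paste0(key, "=", sp$metadata[[key]]), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.4f %d", sp$peaks$mz, as.integer(round(sp$peaks$intensity))), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Write an annotation report as CSV
#'
#' Fixed column order; m/z columns rounded half-away-from-zero to 4
#' decimals, ppm to 2. An empty annotation table yields a header-only CSV.
#'
#' @param annotations Output of [annotate_run()] or [annotate_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(annotations, path) {
  out <- as.data.frame(annotations)[, .annotation_columns, drop = FALSE]
  out$experimental_mz <- sprintf("%.4f", round_mz(out$experimental_mz))
  out$theoretical_mz <- sprintf("%.4f", round_mz(out$theoretical_mz))
  out$ppm_error <- sprintf("%.2f", round_mz(out$ppm_error, 2L))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
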