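# Minimal centroided MS2 spectrum container used across the package.

#' Construct an MS2 spectrum
#'
#' @param spectrum_id Identifier (character or integer-like).
#' @param precursor_mz Precursor m/z (positive). All spectra in scope are
#'   assumed singly charged positive ions.
#' @param rt Retention time in minutes, or `NA` if unknown.
#' @param peaks Data frame (or two-column matrix) with columns `mz` and
#'   `intensity`; intensities must be finite and non-negative. Peaks are
#'   stored sorted by m/z.
#' @param metadata Optional named list of extra header fields.
#' @return An object of class `ms2_spectrum`.
#' @examples
#' new_spectrum("std_27", 342.1703, rt = 7.58,
#'              peaks = data.frame(mz = c(58.0658, 297.1123),
#'                                 intensity = c(9e5, 1e6)))
#' @export
new_spectrum <- function(spectrum_id, precursor_mz, rt = NA_real_,
                         peaks = data.frame(mz = numeric(0), intensity = numeric(0)),
                         metadata = list()) {
  if (length(precursor_mz) != 1L || is.na(precursor_mz) || precursor_mz <= 0)
    stop("'precursor_mz' must be a single positive number", call. = FALSE)
  peaks <- as.data.frame(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks)))
    stop("'peaks' needs columns 'mz' and 'intensity'", call. = FALSE)
  if (nrow(peaks)) {
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0))
      stop("peak m/z values must be finite and positive", call. = FALSE)
    if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0))
      stop("peak intensities must be finite and non-negative", call. = FALSE)
    peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
    rownames(peaks) <- NULL
  } else {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  }
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 rt = as.numeric(rt), peaks = peaks, metadata = metadata),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s  precursor %.4f  rt %s min  %d peaks\n",
              x$spectrum_id, x$precursor_mz,
              if (is.na(x$rt)) "NA" else sprintf("%.2f", x$rt),
              nrow(x$peaks)))
  invisible(x)
}
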