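# Run configuration: one plain-text (YAML) object mirroring every pipeline
# flag, so a run is reproducible from a single file.

#' Assemble a run configuration
#'
#' Defaults reproduce the package's reference acquisition/processing
#' settings: 5 ppm precursor and 10 ppm fragment tolerances with a 1.5 mDa
#' absolute floor, element bounds C30/H60/N10/O20, minimum peak intensity
#' 10000, a 3.0 m/z PRM isolation window, and RT filtering off.
#'
#' @param ms1_ppm,ms2_ppm Precursor/fragment tolerances in ppm.
#' @param floor Absolute tolerance floor in u.
#' @param bounds Named element maxima (see [element_bounds()]).
#' @param min_intensity Minimum retained peak intensity.
#' @param rt_window RT filter window in minutes, or `NULL` for off.
#' @param isolation_window_mz PRM isolation window width.
#' @param library_path Path of the candidate library CSV ("builtin" for the
#'   packaged curated library).
#' @param seed Integer seed for randomized steps (jitter, decoys).
#' @return A list of class `run_config`.
#' @export
run_config <- function(ms1_ppm = 5, ms2_ppm = 10, floor = 0.0015,
                       bounds = c(C = 30, H = 60, N = 10, O = 20),
                       min_intensity = 10000, rt_window = NULL,
                       isolation_window_mz = 3.0,
                       library_path = "builtin", seed = 1L) {
  cfg <- list(ms1_ppm = ms1_ppm, ms2_ppm = ms2_ppm, floor = floor,
              bounds = as.list(bounds), min_intensity = min_intensity,
              rt_window = rt_window, isolation_window_mz = isolation_window_mz,
              library_path = library_path, seed = as.integer(seed))
  # validate tolerances/bounds eagerly
  mass_tolerance(cfg$ms1_ppm, cfg$floor)
  mass_tolerance(cfg$ms2_ppm, cfg$floor)
  do.call(element_bounds, cfg$bounds)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration file
#'
#' YAML round-trip of [run_config()].
#'
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @param config A `run_config` object.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
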