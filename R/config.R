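#' ENMO intensity cut-points
#'
#' Wrist ENMO thresholds (milli-g) separating sedentary from light and light
#' from moderate-to-vigorous activity. The defaults are the adult
#' non-dominant-wrist values of the Hildebrand regression equations
#' (44.8 mg and 100.6 mg). The boundary convention is half-open with the
#' upper class winning: an ENMO value exactly at a cut-point is assigned the
#' higher class.
#'
#' @param sed_lpa Threshold (mg) between SED and LPA.
#' @param lpa_mvpa Threshold (mg) between LPA and MVPA.
#' @param source_label Free-text provenance tag carried into outputs.
#' @return A `cut_points` list.
#' @export
cut_points <- function(sed_lpa = 44.8, lpa_mvpa = 100.6,
                       source_label = "hildebrand-adult-nondominant-wrist") {
  stopifnot(is.numeric(sed_lpa), is.numeric(lpa_mvpa))
  if (!(sed_lpa > 0 && sed_lpa < lpa_mvpa)) {
    abort("cut-points must satisfy 0 < sed_lpa < lpa_mvpa")
  }
  structure(list(sed_lpa = sed_lpa, lpa_mvpa = lpa_mvpa,
                 source_label = source_label),
            class = "wpa_cut_points")
}

#' Study-level analysis configuration
#'
#' Bundles every tunable of the processing chain with its default. All
#' defaults are ordinary config values, never hard-coded in the algorithms,
#' so that reference drift (e.g. a different cut-point set) cannot silently
#' change results.
#'
#' @param cuts ENMO [cut_points()].
#' @param met_breakpoints Breakpoints (MET) between SED/LPA, LPA/MPA and
#'   MPA/VPA. Continuous half-open bands: SED `<= b1`, LPA `(b1, b2)`,
#'   MPA `[b2, b3)`, VPA `>= b3`.
#' @param choi_window Minimum non-wear run length (minutes).
#' @param choi_spike_tol Maximum artifactual nonzero spike length (minutes).
#' @param choi_spike_win Zero minutes required on each side of a spike.
#' @param epoch_s Epoch length in seconds (must divide 3600).
#' @param coverage_min Minimum fraction of expected samples for a second of
#'   ENMO to count as observed.
#' @param epoch_missing_tol Missing seconds tolerated before an epoch is
#'   invalid.
#' @param stillness_floor Movement-proxy floor (mg); per-minute mean ENMO
#'   below it maps to a zero "count".
#' @param calib_sd_thresh Per-axis SD (g) below which a second is static.
#' @param calib_min_windows Minimum static windows required to calibrate.
#' @param valid_day_min Minimum valid minutes for a day to enter min/day
#'   averages (0 includes any day with valid time).
#' @param ci_level Confidence level for test-method intervals.
#' @param ez_granularity Equivalence-zone step (percentage points).
#' @param seed Default simulation seed.
#' @return A validated `wpa_config` list.
#' @export
study_config <- function(cuts = cut_points(),
                         met_breakpoints = c(1.5, 3.0, 6.0),
                         choi_window = 90,
                         choi_spike_tol = 2,
                         choi_spike_win = 30,
                         epoch_s = 60,
                         coverage_min = 0.5,
                         epoch_missing_tol = 0,
                         stillness_floor = 1,
                         calib_sd_thresh = 0.013,
                         calib_min_windows = 10,
                         valid_day_min = 0,
                         ci_level = 0.90,
                         ez_granularity = 0.1,
                         seed = 1L) {
  cfg <- list(
    cuts = cuts, met_breakpoints = met_breakpoints,
    choi_window = choi_window, choi_spike_tol = choi_spike_tol,
    choi_spike_win = choi_spike_win, epoch_s = epoch_s,
    coverage_min = coverage_min, epoch_missing_tol = epoch_missing_tol,
    stillness_floor = stillness_floor, calib_sd_thresh = calib_sd_thresh,
    calib_min_windows = calib_min_windows, valid_day_min = valid_day_min,
    ci_level = ci_level, ez_granularity = ez_granularity,
    seed = as.integer(seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg$cuts, "wpa_cut_points")) {
    cfg$cuts <- do.call(cut_points, cfg$cuts)
  }
  stopifnot(
    length(cfg$met_breakpoints) == 3,
    all(diff(cfg$met_breakpoints) > 0),
    cfg$choi_window > 0, cfg$choi_spike_tol >= 0, cfg$choi_spike_win >= 0,
    cfg$epoch_s > 0, 3600 %% cfg$epoch_s == 0,
    cfg$coverage_min >= 0, cfg$coverage_min <= 1,
    cfg$epoch_missing_tol >= 0,
    cfg$stillness_floor >= 0,
    cfg$ci_level > 0, cfg$ci_level < 1,
    cfg$ez_granularity > 0
  )
  structure(cfg, class = "wpa_config")
}

#' Read a study configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly
#' instead of silently falling back to defaults.
#'
#' @param path YAML file path.
#' @return A `wpa_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$cuts)) raw$cuts <- do.call(cut_points, raw$cuts)
  do.call(study_config, raw)
}

#' Write a study configuration as YAML
#'
#' @param config A `wpa_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  x <- unclass(config)
  x$cuts <- unclass(x$cuts)
  yaml::write_yaml(x, path)
  invisible(path)
}
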