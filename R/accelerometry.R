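infer_fs <- function(stream) {
  dt <- diff(as.numeric(stream$timestamp))
  dt <- dt[dt > 0]
  round(1 / stats::median(dt))
}

#' Calibrate a raw acceleration stream against gravity
#'
#' Estimates per-axis gain and offset from static windows (seconds whose
#' per-axis standard deviation falls below a stillness threshold) by
#' iterative least squares so that static vector norms approach 1 g, and
#' applies them to every sample. The procedure is a simplified static
#' calibration: it needs static windows spanning several orientations to be
#' identifiable. If too few (or insufficiently spread) static windows are
#' found, the stream is returned unchanged and flagged uncalibrated.
#'
#' @param stream Tibble `timestamp, x, y, z` with at least 10 minutes of
#'   data.
#' @param sd_thresh Per-axis SD threshold (g) defining a static second.
#' @param min_windows Minimum static windows required.
#' @param min_spread Minimum per-axis range (g) of static-window means
#'   required for identifiability.
#' @param max_iter,tol Iteration control for the least-squares refinement.
#' @return The calibrated stream with attribute `calibration` (a list with
#'   `calibrated`, `offset`, `gain`, `n_windows`).
#' @export
calibrate_accel <- function(stream, sd_thresh = 0.013, min_windows = 10,
                            min_spread = 0.25, max_iter = 50, tol = 1e-10) {
  span <- diff(range(as.numeric(stream$timestamp)))
  if (span < 600) abort("calibration requires at least 10 minutes of data")
  sec <- floor(as.numeric(stream$timestamp))
  g <- sec - min(sec) + 1
  n_sec <- max(g)
  cnt <- tabulate(g, n_sec)
  ok <- cnt > 1
  sums <- function(v) {
    s <- numeric(n_sec); s[sort(unique(g))] <- rowsum(v, g)[, 1]; s
  }
  mx <- sums(stream$x); my <- sums(stream$y); mz <- sums(stream$z)
  sx2 <- sums(stream$x^2); sy2 <- sums(stream$y^2); sz2 <- sums(stream$z^2)
  mean_ <- function(s) ifelse(ok, s / pmax(cnt, 1), NA_real_)
  var_ <- function(s2, s) {
    ifelse(ok, pmax(0, (s2 - s^2 / pmax(cnt, 1)) / pmax(cnt - 1, 1)), NA_real_)
  }
  static <- ok &
    sqrt(var_(sx2, mx)) < sd_thresh &
    sqrt(var_(sy2, my)) < sd_thresh &
    sqrt(var_(sz2, mz)) < sd_thresh
  static[is.na(static)] <- FALSE
  m <- cbind(mean_(mx)[static], mean_(my)[static], mean_(mz)[static])
  flag_out <- function(calibrated, offset = c(0, 0, 0), gain = c(1, 1, 1)) {
    out <- stream
    if (calibrated) {
      out$x <- offset[1] + gain[1] * stream$x
      out$y <- offset[2] + gain[2] * stream$y
      out$z <- offset[3] + gain[3] * stream$z
    }
    attr(out, "calibration") <- list(calibrated = calibrated,
                                     offset = offset, gain = gain,
                                     n_windows = nrow(m))
    out
  }
  if (nrow(m) < min_windows) {
    warn("too few static windows; stream left uncalibrated")
    return(flag_out(FALSE))
  }
  spread <- apply(m, 2, function(v) diff(range(v)))
  if (any(spread < min_spread)) {
    warn("static windows poorly spread over orientations; stream left uncalibrated")
    return(flag_out(FALSE))
  }
  offset <- c(0, 0, 0); gain <- c(1, 1, 1)
  for (it in seq_len(max_iter)) {
    v <- sweep(sweep(m, 2, gain, `*`), 2, offset, `+`)
    nrm <- sqrt(rowSums(v^2))
    tgt <- v / nrm
    new_o <- offset; new_g <- gain
    for (a in 1:3) {
      fit <- stats::lm.fit(cbind(1, m[, a]), tgt[, a])
      new_o[a] <- fit$coefficients[1]
      new_g[a] <- fit$coefficients[2]
    }
    delta <- max(abs(c(new_o - offset, new_g - gain)))
    offset <- new_o; gain <- new_g
    if (delta < tol) break
  }
  flag_out(TRUE, offset, gain)
}

#' Per-second ENMO from a raw stream
#'
#' ENMO (Euclidean norm minus one) per sample is
#' `max(sqrt(x^2 + y^2 + z^2) - 1, 0)`, in milli-g; the per-second value is
#' the arithmetic mean of the sample ENMOs within that wall-clock second.
#' Seconds with fewer than `coverage_min` of the expected samples are marked
#' missing (`NA`), and the returned grid is contiguous across the recording
#' span so that classified + missing seconds always add up to it.
#'
#' @param stream Tibble `timestamp, x, y, z` (calibrated).
#' @param fs Nominal sampling rate (Hz); inferred from timestamps if `NULL`.
#' @param coverage_min Minimum fraction of expected samples per second.
#' @return Tibble `second, enmo_mg, coverage`.
#' @export
compute_enmo <- function(stream, fs = NULL, coverage_min = 0.5) {
  if (is.null(fs)) fs <- infer_fs(stream)
  e <- pmax(sqrt(stream$x^2 + stream$y^2 + stream$z^2) - 1, 0) * 1000
  sec <- floor(as.numeric(stream$timestamp))
  s0 <- min(sec)
  g <- sec - s0 + 1
  n_sec <- max(g)
  cnt <- tabulate(g, n_sec)
  sums <- numeric(n_sec)
  sums[sort(unique(g))] <- rowsum(e, g)[, 1]
  enmo <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
  coverage <- pmin(cnt / fs, 1)
  enmo[coverage < coverage_min] <- NA_real_
  tibble::tibble(
    second = as.POSIXct(s0 + seq_len(n_sec) - 1, origin = "1970-01-01",
                        tz = "UTC"),
    enmo_mg = enmo, coverage = coverage
  )
}

#' Classify per-second ENMO into intensity classes
#'
#' Half-open bands with the upper class winning at a threshold:
#' SED below `sed_lpa`, LPA from `sed_lpa` up to (not including) `lpa_mvpa`,
#' MVPA at or above `lpa_mvpa`. Missing seconds stay missing.
#'
#' @param enmo Tibble from [compute_enmo()].
#' @param cuts A [cut_points()].
#' @return `enmo` with an added ordered factor column `class`.
#' @export
classify_seconds <- function(enmo, cuts = cut_points()) {
  v <- enmo$enmo_mg
  cl <- ifelse(v < cuts$sed_lpa, "SED",
               ifelse(v < cuts$lpa_mvpa, "LPA", "MVPA"))
  dplyr::mutate(enmo, class = factor(cl, levels = .ACC_CLASSES,
                                     ordered = TRUE))
}

#' Collapse per-second classes into epoch records
#'
#' Epochs are aligned to wall-clock minute boundaries (required for
#' cross-device merging), tally seconds per class, and are valid when their
#' missing seconds do not exceed the tolerance.
#'
#' @param classified Tibble from [classify_seconds()].
#' @param epoch_s Epoch length (s); must divide 3600.
#' @param missing_tol Missing seconds tolerated before `valid = FALSE`.
#' @return Tibble `epoch_start, sed_s, lpa_s, mvpa_s, missing_s,
#'   mean_enmo_mg, valid`.
#' @export
collapse_to_epochs <- function(classified, epoch_s = 60, missing_tol = 0) {
  stopifnot(3600 %% epoch_s == 0)
  sec <- as.numeric(classified$second)
  ep <- floor(sec / epoch_s) * epoch_s
  e0 <- min(ep)
  grid <- seq(e0, max(ep), by = epoch_s)
  g <- match(ep, grid)
  count_class <- function(cl) {
    x <- as.integer(!is.na(classified$class) & classified$class == cl)
    s <- integer(length(grid)); s[sort(unique(g))] <- rowsum(x, g)[, 1]; s
  }
  sed <- count_class("SED"); lpa <- count_class("LPA")
  mvpa <- count_class("MVPA")
  pres <- as.integer(!is.na(classified$enmo_mg))
  npres <- integer(length(grid))
  npres[sort(unique(g))] <- rowsum(pres, g)[, 1]
  esum <- numeric(length(grid))
  ev <- ifelse(is.na(classified$enmo_mg), 0, classified$enmo_mg)
  esum[sort(unique(g))] <- rowsum(ev, g)[, 1]
  tibble::tibble(
    epoch_start = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    sed_s = sed, lpa_s = lpa, mvpa_s = mvpa,
    missing_s = epoch_s - npres,
    mean_enmo_mg = ifelse(npres > 0, esum / pmax(npres, 1), NA_real_),
    valid = (epoch_s - npres) <= missing_tol
  )
}

#' Raw stream to epoch records in one call
#'
#' Convenience chain: optional static calibration, per-second ENMO,
#' cut-point classification, and epoch collapsing.
#'
#' @param stream Tibble `timestamp, x, y, z`.
#' @param config A [study_config()].
#' @param fs Nominal sampling rate (Hz); inferred if `NULL`.
#' @param calibrate Run [calibrate_accel()] first?
#' @return Epoch tibble, as [collapse_to_epochs()].
#' @export
accel_epochs <- function(stream, config = study_config(), fs = NULL,
                         calibrate = TRUE) {
  if (calibrate) {
    stream <- suppressWarnings(
      calibrate_accel(stream, sd_thresh = config$calib_sd_thresh,
                      min_windows = config$calib_min_windows)
    )
  }
  stream |>
    compute_enmo(fs = fs, coverage_min = config$coverage_min) |>
    classify_seconds(config$cuts) |>
    collapse_to_epochs(epoch_s = config$epoch_s,
                       missing_tol = config$epoch_missing_tol)
}
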