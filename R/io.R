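read_checked_csv <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  pr <- readr::problems(df) # parse issues are escalated to errors below
  if (nrow(pr)) {
    abort(paste0("corrupt CSV ", path, ": row ", pr$row[1], ", ",
                 pr$expected[1], " but got '", pr$actual[1], "'"))
  }
  df
}

#' Read a raw acceleration CSV
#'
#' Expects the dialect `timestamp,x,y,z` with ISO-8601 timestamps and axes
#' in g.
#'
#' @param path File path.
#' @return Tibble `timestamp, x, y, z`.
#' @export
read_accel_csv <- function(path) {
  df <- read_checked_csv(path, readr::cols(
    timestamp = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), z = readr::col_double()
  ))
  df$timestamp <- parse_time(df$timestamp)
  if (anyNA(df$timestamp)) abort(paste0("unparseable timestamps in ", path))
  if (is.unsorted(df$timestamp, strictly = TRUE)) {
    abort(paste0("timestamps not strictly increasing in ", path))
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort(paste0("non-finite acceleration values in ", path))
  }
  df
}

#' Write a raw acceleration CSV
#' @param stream Tibble `timestamp, x, y, z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(stream, path) {
  out <- dplyr::mutate(stream, timestamp = fmt_time(.data$timestamp))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a breath-by-breath calorimetry CSV
#'
#' Dialect `timestamp,vo2_ml_min`; an optional `vco2_ml_min` column is
#' ignored.
#'
#' @param path File path.
#' @return Tibble `timestamp, vo2_ml_min`.
#' @export
read_breath_csv <- function(path) {
  df <- read_checked_csv(path, readr::cols(
    timestamp = readr::col_character(),
    vo2_ml_min = readr::col_double(),
    .default = readr::col_skip()
  ))
  df$timestamp <- parse_time(df$timestamp)
  if (anyNA(df$timestamp)) abort(paste0("unparseable timestamps in ", path))
  if (any(df$vo2_ml_min < 0)) abort(paste0("negative VO2 in ", path))
  df
}

#' Write a breath CSV
#' @param breaths Tibble `timestamp, vo2_ml_min`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breath_csv <- function(breaths, path) {
  out <- tibble::tibble(timestamp = fmt_time(breaths$timestamp),
                        vo2_ml_min = breaths$vo2_ml_min)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sleep / non-wear log CSV
#'
#' Dialect `participant,date,sleep_start,sleep_end,nonwear_start,nonwear_end`
#' with one interval per row (the unused pair left blank).
#'
#' @param path File path.
#' @return Tibble with POSIXct interval columns.
#' @export
read_log_csv <- function(path) {
  df <- read_checked_csv(path, readr::cols(
    participant = readr::col_character(), date = readr::col_character(),
    sleep_start = readr::col_character(), sleep_end = readr::col_character(),
    nonwear_start = readr::col_character(),
    nonwear_end = readr::col_character()
  ))
  for (cl in c("sleep_start", "sleep_end", "nonwear_start", "nonwear_end")) {
    df[[cl]] <- parse_time(df[[cl]])
  }
  df
}

write_log_csv <- function(log, path) {
  out <- log
  for (cl in c("sleep_start", "sleep_end", "nonwear_start", "nonwear_end")) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), "", fmt_time(out[[cl]]))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write epoch records as CSV
#'
#' Dialect `epoch_start,sed_s,lpa_s,mvpa_s,mean_enmo_mg,valid,wear`.
#'
#' @param epochs Epoch tibble from [collapse_to_epochs()].
#' @param path Output path.
#' @param wear Optional logical wear flags aligned with `epochs`.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epochs, path, wear = NA) {
  out <- tibble::tibble(
    epoch_start = fmt_time(epochs$epoch_start),
    sed_s = epochs$sed_s, lpa_s = epochs$lpa_s, mvpa_s = epochs$mvpa_s,
    mean_enmo_mg = epochs$mean_enmo_mg, valid = epochs$valid, wear = wear
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a wear mask as CSV (`epoch_start,wear,sleep,invalid`)
#' @param mask Mask tibble from [build_wear_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  out <- dplyr::mutate(mask, epoch_start = fmt_time(.data$epoch_start))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write activity summaries as CSV
#' @param summaries Summary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  readr::write_csv(summaries, path, progress = FALSE)
  invisible(path)
}
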