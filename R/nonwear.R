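#' Choi non-wear detection on a per-minute movement series
#'
#' A non-wear interval is any maximal run of zero (or artifactual) minutes
#' whose total length reaches the window (default 90 minutes). A nonzero
#' run of at most `spike_tol` minutes counts as artifactual device movement
#' if and only if it is flanked on both sides by at least `spike_win`
#' consecutive zero minutes. All other minutes are wear.
#'
#' @param movement Non-negative numeric vector on a contiguous minute grid
#'   (missing values are treated as zero).
#' @param window Minimum non-wear run length (minutes).
#' @param spike_tol Maximum artifactual spike length (minutes).
#' @param spike_win Zero minutes required on each flank of a spike.
#' @return Logical vector: `TRUE` where the device was worn.
#' @export
choi_nonwear <- function(movement, window = 90, spike_tol = 2,
                         spike_win = 30) {
  movement[is.na(movement)] <- 0
  if (any(movement < 0)) abort("movement series must be non-negative")
  n <- length(movement)
  if (n == 0) return(logical(0))
  zero <- movement == 0
  r <- rle(zero)
  k <- length(r$lengths)
  # artifactual nonzero runs: short, with long zero runs on both flanks
  art <- !r$values & r$lengths <= spike_tol
  if (any(art)) {
    left_ok <- c(FALSE, r$values[-k] & r$lengths[-k] >= spike_win)
    right_ok <- c(r$values[-1] & r$lengths[-1] >= spike_win, FALSE)
    art <- art & left_ok & right_ok
  }
  cand_run <- r$values | art
  cand <- inverse.rle(list(lengths = r$lengths, values = cand_run))
  cr <- rle(cand)
  nonwear_run <- cr$values & cr$lengths >= window
  nonwear <- inverse.rle(list(lengths = cr$lengths, values = nonwear_run))
  !nonwear
}

#' Per-minute movement proxy from epoch records
#'
#' The zero-count analogue used to drive [choi_nonwear()] on ENMO epochs:
#' per-minute movement is the rounded mean ENMO (mg), with means below the
#' stillness floor (and missing epochs) mapped to zero.
#'
#' @param epochs Epoch tibble from [collapse_to_epochs()] on a 60-s grid.
#' @param stillness_floor Floor (mg) below which a minute counts as zero.
#' @return Tibble `epoch_start, movement`.
#' @export
movement_proxy <- function(epochs, stillness_floor = 1) {
  m <- epochs$mean_enmo_mg
  mv <- ifelse(is.na(m) | m < stillness_floor, 0, round(m))
  tibble::tibble(epoch_start = epochs$epoch_start, movement = mv)
}

#' Build the shared wear/sleep/validity mask
#'
#' Wear is detected by [choi_nonwear()] on the criterion stream's movement
#' proxy (one shared mask avoids differential exclusion bias); sleep minutes
#' come from the self-report log; minutes are invalid where the test-device
#' epoch is not valid (device dropout) or either stream is missing. The mask
#' applies to both devices identically, and the analysis set is
#' `wear & !sleep & !invalid`.
#'
#' @param epochs_test,epochs_criterion Epoch tibbles on the same 60-s grid.
#' @param log Optional tibble with `sleep_start`/`sleep_end` POSIXct
#'   columns (rows with missing values ignored). Intervals outside the
#'   recording span are clipped with a warning.
#' @param config A [study_config()] (Choi parameters, stillness floor).
#' @return Tibble `epoch_start, wear, sleep, invalid`.
#' @export
build_wear_mask <- function(epochs_test, epochs_criterion, log = NULL,
                            config = study_config()) {
  grid <- tibble::tibble(epoch_start = sort(unique(c(
    epochs_test$epoch_start, epochs_criterion$epoch_start
  ))))
  gt <- dplyr::left_join(
    grid, dplyr::select(epochs_test, "epoch_start", test_valid = "valid"),
    by = "epoch_start"
  )
  gc <- dplyr::left_join(
    grid,
    dplyr::select(epochs_criterion, "epoch_start", crit_valid = "valid",
                  "mean_enmo_mg"),
    by = "epoch_start"
  )
  proxy <- movement_proxy(
    tibble::tibble(epoch_start = grid$epoch_start,
                   mean_enmo_mg = gc$mean_enmo_mg),
    stillness_floor = config$stillness_floor
  )
  wear <- choi_nonwear(proxy$movement, window = config$choi_window,
                       spike_tol = config$choi_spike_tol,
                       spike_win = config$choi_spike_win)
  sleep <- rep(FALSE, nrow(grid))
  if (!is.null(log) && nrow(log)) {
    span <- range(as.numeric(grid$epoch_start))
    t <- as.numeric(grid$epoch_start)
    ivs <- log[!is.na(log$sleep_start) & !is.na(log$sleep_end), ]
    for (i in seq_len(nrow(ivs))) {
      a <- as.numeric(ivs$sleep_start[i]); b <- as.numeric(ivs$sleep_end[i])
      if (b <= span[1] || a > span[2] + 60) {
        warn("sleep interval outside recording span; clipped")
        next
      }
      sleep <- sleep | (t >= a & t < b)
    }
  }
  invalid <- is.na(gt$test_valid) | !gt$test_valid |
    is.na(gc$crit_valid) | !gc$crit_valid
  tibble::tibble(epoch_start = grid$epoch_start, wear = wear,
                 sleep = sleep, invalid = invalid)
}
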