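#' Plan a multi-day free-living recording
#'
#' Realizes a concrete, seeded plan for a free-living week: per-day waking
#' windows, one daytime non-wear gap per day (long enough for the Choi rule
#' to find it), random activity bouts with known intensity targets filling
#' the rest of the waking hours, overnight off-wrist periods matching the
#' sleep log, and minute-aligned test-device dropout gaps on selected days.
#'
#' Every interval is aligned to whole minutes so that epoch-level ground
#' truth is exact by construction.
#'
#' @param days Number of days (default 7).
#' @param start Midnight starting the first day (POSIXct).
#' @param waking Length-2 numeric, waking window in hours of day.
#' @param nonwear_min Range (minutes) of the daily non-wear gap; the lower
#'   bound should be at least the Choi window for the gap to be detectable.
#' @param dropout_days Day indices receiving a test-device dropout gap.
#' @param dropout_min Range (minutes) of dropout gap length.
#' @param seed RNG seed realizing the plan.
#' @return A `wpa_week_plan` list with `blocks`, `sleep`, `nonwear`,
#'   `dropout` tibbles.
#' @export
week_plan <- function(days = 7,
                      start = as.POSIXct("2021-03-01 00:00:00", tz = "UTC"),
                      waking = c(8, 22),
                      nonwear_min = c(95, 150),
                      dropout_days = intersect(c(2, 5), seq_len(days)),
                      dropout_min = c(10, 30),
                      seed = 1L) {
  stopifnot(days >= 0, waking[1] < waking[2], waking[1] >= 0, waking[2] <= 24)
  with_local_seed(seed, {
    blocks <- list(); sleeps <- list(); gaps <- list(); drops <- list()
    for (d in seq_len(days)) {
      day0 <- start + (d - 1) * 86400
      wake_a <- waking[1] * 60; wake_b <- waking[2] * 60 # minutes of day
      w_len <- wake_b - wake_a
      gap_len <- min(sample(seq(nonwear_min[1], nonwear_min[2]), 1), w_len)
      gap_at <- sample(0:(w_len - gap_len), 1)
      segs <- list(c(0, gap_at), c(gap_at + gap_len, w_len))
      day_blocks <- list(off_block(day0, wake_a, d)) # 00:00 .. waking start
      for (seg in segs) {
        rem <- seg[2] - seg[1]; cur <- seg[1]
        while (rem > 0) {
          cls <- sample(c("SED", "LPA", "MVPA"), 1, prob = c(0.5, 0.3, 0.2))
          len <- switch(cls, SED = sample(15:45, 1), LPA = sample(5:20, 1),
                        MVPA = sample(3:10, 1))
          len <- min(len, rem)
          enmo <- switch(cls, SED = runif(1, 3, 15), LPA = runif(1, 50, 95),
                         MVPA = runif(1, 130, 400))
          met <- switch(cls, SED = runif(1, 1.0, 1.45),
                        LPA = runif(1, 1.7, 2.8), MVPA = runif(1, 3.2, 7.5))
          day_blocks <- c(day_blocks, list(tibble::tibble(
            day = d, start = day0 + (wake_a + cur) * 60,
            label = paste0("bout-", cls), intensity_class = cls,
            duration_s = len * 60, target_met = met, target_enmo = enmo,
            freq_hz = ifelse(cls == "MVPA", 2, 1), truth_class = cls
          )))
          cur <- cur + len; rem <- rem - len
        }
        if (seg[1] == 0) { # the non-wear gap sits between the two segments
          day_blocks <- c(day_blocks,
                          list(off_block(day0 + (wake_a + gap_at) * 60,
                                         gap_len, d, at_min = NULL)))
        }
      }
      day_blocks <- c(day_blocks,
                      list(off_block(day0 + wake_b * 60, 1440 - wake_b, d,
                                     at_min = NULL)))
      blocks[[d]] <- dplyr::bind_rows(day_blocks)
      sleeps[[d]] <- tibble::tibble(
        day = d,
        start = c(day0, day0 + wake_b * 60),
        end = c(day0 + wake_a * 60, day0 + 86400)
      )
      gaps[[d]] <- tibble::tibble(
        day = d, start = day0 + (wake_a + gap_at) * 60,
        end = day0 + (wake_a + gap_at + gap_len) * 60
      )
      if (d %in% dropout_days) {
        dlen <- min(sample(seq(dropout_min[1], dropout_min[2]), 1), w_len)
        dat <- sample(0:(w_len - dlen), 1)
        drops[[length(drops) + 1]] <- tibble::tibble(
          day = d, start = day0 + (wake_a + dat) * 60,
          end = day0 + (wake_a + dat + dlen) * 60
        )
      }
    }
    structure(list(
      days = days, start = start, waking = waking,
      blocks = dplyr::bind_rows(blocks),
      sleep = dplyr::bind_rows(sleeps),
      nonwear = dplyr::bind_rows(gaps),
      dropout = if (length(drops)) dplyr::bind_rows(drops) else
        tibble::tibble(day = integer(), start = as.POSIXct(character(), tz = "UTC"),
                       end = as.POSIXct(character(), tz = "UTC")),
      seed = as.integer(seed)
    ), class = "wpa_week_plan")
  })
}

# Off-wrist (device removed) block: pure gravity, tiny electronic noise.
off_block <- function(start, dur_min, day, at_min = 0) {
  tibble::tibble(
    day = day, start = if (is.null(at_min)) start else start + at_min * 60,
    label = "off-wrist", intensity_class = "OFF", duration_s = dur_min * 60,
    target_met = 0.9, target_enmo = 0, freq_hz = 1, truth_class = "NONWEAR"
  )
}

#' Simulate one day of a week plan
#'
#' Generates the co-worn device streams and per-second truth for a single
#' day of a [week_plan()]. Day-by-day simulation keeps memory bounded on
#' long recordings.
#'
#' @param plan A `wpa_week_plan`.
#' @param cfg A [sim_config()].
#' @param day Day index.
#' @return List with `test`, `criterion`, `truth` tibbles.
#' @export
simulate_week_day <- function(plan, cfg, day) {
  blk <- dplyr::filter(plan$blocks, .data$day == .env$day)
  stopifnot(nrow(blk) > 0)
  drop_d <- dplyr::filter(plan$dropout, .data$day == .env$day)
  check_no_overlap(drop_d, "dropout")
  start_time <- blk$start[1]
  day_cfg <- cfg
  day_cfg$seed <- cfg$seed + 131L * day
  with_local_seed(day_cfg$seed, {
    criterion <- gen_device_stream(blk, day_cfg, start_time,
                                   cfg$fs_criterion, bias = 0)
    test <- gen_device_stream(blk, day_cfg, start_time, cfg$fs_test,
                              bias = cfg$inter_device_bias,
                              dropout_gaps = drop_d)
    truth <- protocol_truth_seconds(blk, start_time)
    list(test = test, criterion = criterion, truth = truth)
  })
}

simulate_week_days <- function(plan, cfg) {
  lapply(seq_len(plan$days), function(d) simulate_week_day(plan, cfg, d))
}

#' Ground-truth analysis minutes per class of a week plan
#'
#' Counts the minutes per intensity class a perfect pipeline should report:
#' worn waking minutes, excluding off-wrist periods and any minute touched
#' by a test-device dropout gap (those minutes are invalid for both devices
#' by the shared-mask rule).
#'
#' @param plan A `wpa_week_plan`.
#' @return Tibble `class, minutes`.
#' @export
week_truth_minutes <- function(plan) {
  b <- plan$blocks
  mins <- purrr::pmap(list(b$start, b$duration_s, b$truth_class),
                      function(s, d, cl) {
                        tibble::tibble(
                          minute = as.numeric(s) + 60 * (seq_len(d / 60) - 1),
                          class = cl
                        )
                      })
  grid <- dplyr::bind_rows(mins)
  if (nrow(plan$dropout)) {
    bad <- rep(FALSE, nrow(grid))
    for (i in seq_len(nrow(plan$dropout))) {
      bad <- bad | (grid$minute < as.numeric(plan$dropout$end[i]) &
                      grid$minute + 60 > as.numeric(plan$dropout$start[i]))
    }
    grid <- grid[!bad, ]
  }
  grid |>
    dplyr::filter(.data$class %in% .ACC_CLASSES) |>
    dplyr::count(.data$class, name = "minutes") |>
    dplyr::mutate(class = factor(.data$class, levels = .ACC_CLASSES)) |>
    tidyr::complete(class = factor(.ACC_CLASSES, levels = .ACC_CLASSES),
                    fill = list(minutes = 0L)) |>
    dplyr::arrange(.data$class)
}
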