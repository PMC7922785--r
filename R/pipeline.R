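#' Simulate a study to disk
#'
#' Thin orchestration wrapper around [write_fixture_study()] matching the
#' command-line `simulate` subcommand.
#'
#' @param outdir Output directory.
#' @param n_participants Number of participants (default 20).
#' @param cfg A [sim_config()].
#' @param days Free-living days per participant.
#' @param waking Waking window in hours of day.
#' @return Manifest tibble, invisibly.
#' @export
simulate_study <- function(outdir, n_participants = 20, cfg = sim_config(),
                           days = 7, waking = c(8, 22)) {
  write_fixture_study(outdir, n_participants = n_participants, cfg = cfg,
                      days = days, waking = waking)
}

process_session <- function(dir, pid, body_mass, config, with_breath = TRUE) {
  test <- read_accel_csv(file.path(dir, "protocol_test.csv"))
  crit <- read_accel_csv(file.path(dir, "protocol_criterion.csv"))
  ep_t <- accel_epochs(test, config)
  ep_c <- accel_epochs(crit, config)
  sources <- list(TEST = ep_t, CRITERION = ep_c)
  breath_path <- file.path(dir, "protocol_breath.csv")
  if (with_breath && file.exists(breath_path)) {
    breaths <- read_breath_csv(breath_path)
    sources$CALORIMETRY <- met_epochs(breaths, body_mass, config)
  } else if (with_breath) {
    warn(paste0("no breath file for ", pid, "; calorimetry stage skipped"))
  }
  mask <- build_wear_mask(ep_t, ep_c, log = NULL, config = config)
  merged <- merge_epochs(sources, mask)
  summarize_activity(merged, period = "session") |>
    dplyr::mutate(participant = pid, period = "session", .before = 1)
}

process_week <- function(dir, pid, log, config) {
  test <- read_accel_csv(file.path(dir, "week_test.csv"))
  crit <- read_accel_csv(file.path(dir, "week_criterion.csv"))
  ep_t <- accel_epochs(test, config)
  ep_c <- accel_epochs(crit, config)
  plog <- if (!is.null(log)) dplyr::filter(log, .data$participant == pid)
  mask <- build_wear_mask(ep_t, ep_c, log = plog, config = config)
  merged <- merge_epochs(list(TEST = ep_t, CRITERION = ep_c), mask)
  daily <- summarize_activity(merged, period = "day") |>
    dplyr::mutate(participant = pid, .before = 1)
  daily_average(daily, valid_day_min = config$valid_day_min) |>
    dplyr::mutate(period = "day", .after = "device")
}

#' Process a study directory into activity summaries
#'
#' Reads every participant's raw device and breath CSVs, runs the full
#' chain (calibration, ENMO, classification, epochs, shared wear mask,
#' merge), and returns one summary row per participant, device and period:
#' min/session for the lab protocol and min/day for the free-living week.
#'
#' @param indir Study directory as written by [simulate_study()].
#' @param config A [study_config()].
#' @param outdir Optional directory for `summary.csv`.
#' @return Summary tibble.
#' @export
process_study <- function(indir, config = study_config(), outdir = NULL) {
  ptab <- read_checked_csv(file.path(indir, "participants.csv"),
                           readr::cols(participant = readr::col_character(),
                                       body_mass_kg = readr::col_double()))
  log_path <- file.path(indir, "log.csv")
  log <- if (file.exists(log_path)) read_log_csv(log_path)
  out <- purrr::pmap(list(ptab$participant, ptab$body_mass_kg),
                     function(pid, mass) {
    pdir <- file.path(indir, pid)
    res <- list()
    if (file.exists(file.path(pdir, "protocol_test.csv"))) {
      res$session <- process_session(pdir, pid, mass, config)
    }
    if (file.exists(file.path(pdir, "week_test.csv"))) {
      res$week <- process_week(pdir, pid, log, config)
    }
    dplyr::bind_rows(res)
  })
  summaries <- dplyr::bind_rows(out)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_summary_csv(summaries, file.path(outdir, "summary.csv"))
  }
  summaries
}

summary_to_pairs <- function(summaries, criterion_device, period) {
  long <- summaries |>
    dplyr::filter(.data$period == .env$period) |>
    tidyr::pivot_longer(cols = c("sed_min", "lpa_min", "mvpa_min",
                                 "tpa_min"),
                        names_to = "class", values_to = "minutes") |>
    dplyr::mutate(class = toupper(sub("_min$", "", .data$class)))
  crit <- dplyr::filter(long, .data$device == criterion_device)
  test <- dplyr::filter(long, .data$device == "TEST")
  dplyr::inner_join(
    dplyr::select(crit, "participant", "class", criterion = "minutes"),
    dplyr::select(test, "participant", "class", test = "minutes"),
    by = c("participant", "class")
  ) |>
    dplyr::mutate(comparison = paste0("TEST_vs_", criterion_device),
                  class = factor(.data$class,
                                 levels = c("SED", "LPA", "MVPA", "TPA")))
}

#' Validate the test device against the criterion methods
#'
#' Builds per-participant paired estimates for each intensity class (SED,
#' LPA, MVPA, TPA) and runs the agreement suite for the test device against
#' the criterion accelerometer (free-living min/day) and against indirect
#' calorimetry (protocol-session minutes), whichever the summaries contain.
#'
#' @param summaries Summary tibble from [process_study()].
#' @param config A [study_config()].
#' @return A `wpa_agreement` object (see [validate_methods()]).
#' @export
validate_study <- function(summaries, config = study_config()) {
  pairs <- list()
  if (any(summaries$device == "CRITERION" & summaries$period == "day")) {
    pairs$fl <- summary_to_pairs(summaries, "CRITERION", "day")
  }
  if (any(summaries$device == "CALORIMETRY")) {
    pairs$cal <- summary_to_pairs(summaries, "CALORIMETRY", "session")
  }
  if (!length(pairs)) abort("summaries contain no criterion device rows")
  validate_methods(dplyr::bind_rows(pairs), by = c("comparison", "class"),
                   ci_level = config$ci_level,
                   granularity = config$ez_granularity)
}

#' Simulate and process a free-living week in memory
#'
#' Day-by-day generation and epoching (memory stays bounded on long
#' recordings), then the shared mask, merge and summary, compared against
#' the plan's ground truth. This is the recovery experiment used to check
#' that the pipeline returns exactly the minutes the generator planted.
#'
#' @param plan A [week_plan()].
#' @param cfg A [sim_config()].
#' @param config A [study_config()].
#' @param calibrate Run static calibration inside the chain?
#' @return Tibble `class, truth_min, TEST, CRITERION`.
#' @export
run_week_recovery <- function(plan, cfg = sim_config(),
                              config = study_config(), calibrate = TRUE) {
  eps_t <- list(); eps_c <- list()
  for (d in seq_len(plan$days)) {
    day <- simulate_week_day(plan, cfg, d)
    eps_t[[d]] <- accel_epochs(day$test, config, fs = cfg$fs_test,
                               calibrate = calibrate)
    eps_c[[d]] <- accel_epochs(day$criterion, config,
                               fs = cfg$fs_criterion, calibrate = calibrate)
    rm(day)
  }
  ep_t <- dplyr::bind_rows(eps_t)
  ep_c <- dplyr::bind_rows(eps_c)
  sleep_log <- dplyr::transmute(plan$sleep, sleep_start = .data$start,
                                sleep_end = .data$end)
  mask <- build_wear_mask(ep_t, ep_c, log = sleep_log, config = config)
  merged <- merge_epochs(list(TEST = ep_t, CRITERION = ep_c), mask)
  got <- summarize_activity(merged, period = "session")
  truth <- week_truth_minutes(plan)
  wide <- got |>
    dplyr::select("device", "sed_min", "lpa_min", "mvpa_min") |>
    tidyr::pivot_longer(-"device", names_to = "class",
                        values_to = "minutes") |>
    dplyr::mutate(class = toupper(sub("_min$", "", .data$class))) |>
    tidyr::pivot_wider(names_from = "device", values_from = "minutes")
  truth |>
    dplyr::mutate(class = as.character(.data$class)) |>
    dplyr::left_join(wide, by = "class") |>
    dplyr::rename(truth_min = "minutes")
}

#' Plot a per-second ENMO trace
#'
#' @param enmo Tibble from [compute_enmo()] (optionally classified).
#' @param cuts Optional [cut_points()] drawn as horizontal references.
#' @return A ggplot object.
#' @export
plot_enmo <- function(enmo, cuts = NULL) {
  p <- ggplot2::ggplot(enmo,
                       ggplot2::aes(x = .data$second, y = .data$enmo_mg)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "ENMO (mg)") +
    ggplot2::theme_minimal()
  if (!is.null(cuts)) {
    p <- p + ggplot2::geom_hline(yintercept = c(cuts$sed_lpa,
                                                cuts$lpa_mvpa),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
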