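#' Write a complete synthetic validation study to disk
#'
#' Emulates the full data deposit of a device-validation study: for each
#' participant, raw acceleration CSVs for both devices and both sessions
#' (the 62-minute simulated free-living protocol and the free-living week),
#' a breath CSV for the protocol session, plus study-level participant,
#' sleep/non-wear-log and ground-truth tables, and a manifest with MD5
#' checksums and the seed used.
#'
#' @param outdir Output directory (created if needed).
#' @param n_participants Number of participants.
#' @param cfg Base [sim_config()]; per-participant seeds are derived from
#'   `cfg$seed`.
#' @param days Days of free-living wear per participant.
#' @param waking Waking window (hours of day) for the week plan.
#' @param protocol Protocol schedule for the lab session.
#' @return The manifest, invisibly (tibble `file, md5` plus attribute
#'   `seed`); also written as `manifest.json`.
#' @export
write_fixture_study <- function(outdir, n_participants = 20,
                                cfg = sim_config(), days = 7,
                                waking = c(8, 22),
                                protocol = default_protocol()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(paste0("cannot create directory: ", outdir))
  files <- character()
  participants <- list(); logs <- list(); truths <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    pdir <- file.path(outdir, pid)
    dir.create(pdir, showWarnings = FALSE)
    seed_i <- cfg$seed + 1000L * i
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    cfg_i$body_mass <- with_local_seed(seed_i + 13L,
                                       round(rnorm(1, 90.1, 12.5), 1))
    if (cfg_i$body_mass < 40) cfg_i$body_mass <- 40
    plan <- week_plan(days = days, waking = waking, seed = seed_i + 7L)

    # protocol session: scheduled two days after the week ends
    proto_start <- plan$start + days * 86400 + 2 * 86400 + 9 * 3600
    pr <- simulate_accel_pair(protocol, cfg_i, start_time = proto_start)
    br <- simulate_breaths(protocol, cfg_i, start_time = proto_start)
    wk <- simulate_accel_pair(plan, cfg_i)

    paths <- file.path(pdir, c("protocol_test.csv", "protocol_criterion.csv",
                               "protocol_breath.csv", "week_test.csv",
                               "week_criterion.csv", "truth.csv"))
    write_accel_csv(pr$test, paths[1])
    write_accel_csv(pr$criterion, paths[2])
    write_breath_csv(br, paths[3])
    write_accel_csv(wk$test, paths[4])
    write_accel_csv(wk$criterion, paths[5])

    proto_truth <- pr$truth |>
      dplyr::filter(.data$truth_class %in% .ACC_CLASSES) |>
      dplyr::count(.data$truth_class, name = "seconds") |>
      dplyr::transmute(participant = pid, period = "session",
                       class = .data$truth_class,
                       minutes = .data$seconds / 60)
    week_truth <- week_truth_minutes(plan) |>
      dplyr::transmute(participant = pid, period = "week",
                       class = as.character(.data$class),
                       minutes = as.numeric(.data$minutes))
    truth <- dplyr::bind_rows(proto_truth, week_truth)
    readr::write_csv(truth, paths[6], progress = FALSE)
    truths[[i]] <- truth

    participants[[i]] <- tibble::tibble(participant = pid,
                                        body_mass_kg = cfg_i$body_mass)
    logs[[i]] <- dplyr::bind_rows(
      tibble::tibble(participant = pid,
                     date = format(as.Date(plan$sleep$start), "%Y-%m-%d"),
                     sleep_start = plan$sleep$start,
                     sleep_end = plan$sleep$end,
                     nonwear_start = as.POSIXct(NA, tz = "UTC"),
                     nonwear_end = as.POSIXct(NA, tz = "UTC")),
      tibble::tibble(participant = pid,
                     date = format(as.Date(plan$nonwear$start), "%Y-%m-%d"),
                     sleep_start = as.POSIXct(NA, tz = "UTC"),
                     sleep_end = as.POSIXct(NA, tz = "UTC"),
                     nonwear_start = plan$nonwear$start,
                     nonwear_end = plan$nonwear$end)
    )
    files <- c(files, file.path(pid, basename(paths)))
  }
  ptab <- if (length(participants)) dplyr::bind_rows(participants) else
    tibble::tibble(participant = character(), body_mass_kg = numeric())
  ltab <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(participant = character(), date = character(),
                   sleep_start = as.POSIXct(character(), tz = "UTC"),
                   sleep_end = as.POSIXct(character(), tz = "UTC"),
                   nonwear_start = as.POSIXct(character(), tz = "UTC"),
                   nonwear_end = as.POSIXct(character(), tz = "UTC"))
  readr::write_csv(ptab, file.path(outdir, "participants.csv"),
                   progress = FALSE)
  write_log_csv(ltab, file.path(outdir, "log.csv"))
  files <- c(files, "participants.csv", "log.csv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files)))
  )
  jsonlite::write_json(
    list(seed = cfg$seed, n_participants = n_participants, days = days,
         files = manifest),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  attr(manifest, "seed") <- cfg$seed
  invisible(manifest)
}
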