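#' Simulation configuration
#'
#' Parameters of the synthetic study generator: two co-worn wrist devices
#' (a 25 Hz test device and a 100 Hz criterion device) plus breath-by-breath
#' indirect calorimetry.
#'
#' Defaults describe a realistic bench setup: 10 mg per-axis sensor noise
#' while worn, 1 mg electronic noise while the device lies still off the
#' wrist, a 2 mg inter-device bias on the test device, the cohort-average
#' body mass of 90.1 kg, breaths every 2-4 s, 8% coefficient of variation on
#' breath VO2, and a 30 s first-order VO2 onset time constant at activity
#' transitions.
#'
#' @param seed Integer RNG seed; identical configs give identical output.
#' @param fs_test,fs_criterion Sampling rates (Hz) of the two devices.
#' @param noise_sd Per-axis acceleration noise while worn (g).
#' @param offwrist_noise_sd Per-axis noise while off-wrist (g).
#' @param inter_device_bias Additive norm bias of the test device (g).
#' @param body_mass Participant body mass (kg).
#' @param breath_interval Length-2 range (s) of jittered breath spacing.
#' @param vo2_noise_cv Coefficient of variation of breath-level VO2.
#' @param lag_tau First-order VO2 onset time constant (s); 0 disables the
#'   onset lag so VO2 steps instantaneously at block transitions.
#' @return A `wpa_sim_config` list.
#' @export
sim_config <- function(seed = 1L, fs_test = 25, fs_criterion = 100,
                       noise_sd = 0.010, offwrist_noise_sd = 0.001,
                       inter_device_bias = 0.002, body_mass = 90.1,
                       breath_interval = c(2, 4), vo2_noise_cv = 0.08,
                       lag_tau = 30) {
  stopifnot(fs_test > 0, fs_criterion > 0, noise_sd >= 0,
            offwrist_noise_sd >= 0, body_mass > 0,
            length(breath_interval) == 2, all(breath_interval > 0),
            vo2_noise_cv >= 0, lag_tau >= 0)
  structure(list(seed = as.integer(seed), fs_test = fs_test,
                 fs_criterion = fs_criterion, noise_sd = noise_sd,
                 offwrist_noise_sd = offwrist_noise_sd,
                 inter_device_bias = inter_device_bias,
                 body_mass = body_mass, breath_interval = breath_interval,
                 vo2_noise_cv = vo2_noise_cv, lag_tau = lag_tau),
            class = "wpa_sim_config")
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Slowly varying gravity unit vector, one orientation per second.
# Norm is exactly 1 by construction, so orientation never leaks into ENMO.
orientation_per_second <- function(n_sec, t0_off = 0) {
  ph <- runif(2, 0, 2 * pi)
  tt <- t0_off + seq_len(n_sec) - 1
  a <- 0.9 * sin(2 * pi * tt / 913 + ph[1])   # elevation, ~15-min period
  b <- 1.7 * sin(2 * pi * tt / 1471 + ph[2])  # azimuth, ~25-min period
  list(x = cos(a) * cos(b), y = cos(a) * sin(b), z = sin(a))
}

# Synthesize one device stream for a consecutive block table.
# Movement is a half-rectified oscillation of the acceleration norm:
# |a(t)| = 1 + A*sin(2*pi*f*tau) (+ bias), so per-sample ENMO is
# max(A*sin + bias, 0) and the cycle-mean ENMO is A/pi. A = pi*target/1000
# therefore makes the expected per-second ENMO equal target_enmo exactly.
gen_device_stream <- function(blocks, cfg, start_time, fs, bias,
                              dropout_gaps = NULL) {
  dur <- as.integer(round(blocks$duration_s))
  n_sec <- sum(dur)
  n <- n_sec * fs
  idx <- rep(seq_len(nrow(blocks)), times = dur * fs)
  off <- (seq_len(n) - 1) / fs
  blk_start <- rep(cumsum(c(0, head(dur, -1))), times = dur * fs)
  amp <- pi * blocks$target_enmo / 1000
  s <- amp[idx] * sin(2 * pi * blocks$freq_hz[idx] * (off - blk_start))
  nrm <- 1 + s + bias
  ori <- orientation_per_second(n_sec)
  sec <- floor(off) + 1L
  sdv <- ifelse(blocks$intensity_class == "OFF",
                cfg$offwrist_noise_sd, cfg$noise_sd)
  noise_sd <- sdv[idx]
  x <- ori$x[sec] * nrm
  y <- ori$y[sec] * nrm
  z <- ori$z[sec] * nrm
  if (any(noise_sd > 0)) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
    z <- z + rnorm(n, 0, noise_sd)
  }
  ts <- as.numeric(start_time) + off
  if (!is.null(dropout_gaps) && nrow(dropout_gaps)) {
    keep <- rep(TRUE, n)
    for (i in seq_len(nrow(dropout_gaps))) {
      keep <- keep & !(ts >= as.numeric(dropout_gaps$start[i]) &
                         ts < as.numeric(dropout_gaps$end[i]))
    }
    ts <- ts[keep]; x <- x[keep]; y <- y[keep]; z <- z[keep]
  }
  tibble::tibble(
    timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
    x = x, y = y, z = z
  )
}

check_no_overlap <- function(gaps, what = "gap") {
  if (is.null(gaps) || nrow(gaps) < 2) return(invisible(TRUE))
  g <- gaps[order(gaps$start), ]
  if (any(as.numeric(g$start[-1]) < as.numeric(g$end[-nrow(g)]))) {
    abort(paste0("overlapping ", what, " intervals"))
  }
  invisible(TRUE)
}

#' Simulate a pair of co-worn accelerometer streams
#'
#' Generates the test-device and criterion-device raw streams for one
#' activity schedule (or a whole [week_plan()]), together with per-second
#' ground-truth intensity labels. Both streams sample the same underlying
#' motion; the test stream additionally receives the inter-device bias and
#' any device-dropout gaps (its samples are simply absent there).
#'
#' @param schedule A block tibble (e.g. [default_protocol()]) or a
#'   `wpa_week_plan`.
#' @param cfg A [sim_config()].
#' @param start_time Session start (POSIXct, whole minute). Ignored for week
#'   plans, which carry their own clock.
#' @param dropout_gaps Optional tibble with `start`/`end` POSIXct columns of
#'   test-device dropout intervals (week plans carry their own).
#' @return List with tibbles `test`, `criterion` (columns
#'   `timestamp, x, y, z` in g) and `truth` (per-second `truth_class`).
#' @export
simulate_accel_pair <- function(schedule, cfg = sim_config(),
                                start_time = as.POSIXct("2021-03-01 09:00:00",
                                                        tz = "UTC"),
                                dropout_gaps = NULL) {
  if (inherits(schedule, "wpa_week_plan")) {
    days <- simulate_week_days(schedule, cfg)
    return(list(
      test = dplyr::bind_rows(purrr::map(days, "test")),
      criterion = dplyr::bind_rows(purrr::map(days, "criterion")),
      truth = dplyr::bind_rows(purrr::map(days, "truth"))
    ))
  }
  check_no_overlap(dropout_gaps, "dropout")
  with_local_seed(cfg$seed, {
    criterion <- gen_device_stream(schedule, cfg, start_time,
                                   cfg$fs_criterion, bias = 0)
    test <- gen_device_stream(schedule, cfg, start_time, cfg$fs_test,
                              bias = cfg$inter_device_bias, dropout_gaps)
    truth <- protocol_truth_seconds(schedule, start_time)
    list(test = test, criterion = criterion, truth = truth)
  })
}

#' Simulate a breath-by-breath calorimetry stream
#'
#' Breath records are irregularly spaced (jittered interval) and fluctuate
#' around `target_met * 3.5 * body_mass` mL/min for the active block, with a
#' first-order onset lag at block transitions.
#'
#' @inheritParams simulate_accel_pair
#' @return Tibble `timestamp, vo2_ml_min` with attribute `body_mass`.
#' @export
simulate_breaths <- function(schedule, cfg = sim_config(),
                             start_time = as.POSIXct("2021-03-01 09:00:00",
                                                     tz = "UTC")) {
  stopifnot(cfg$body_mass > 0)
  dur <- as.integer(round(schedule$duration_s))
  total <- sum(dur)
  tgt <- schedule$target_met * 3.5 * cfg$body_mass
  t0 <- cumsum(c(0, head(dur, -1)))
  with_local_seed(cfg$seed + 77L, {
    n_max <- ceiling(total / cfg$breath_interval[1]) + 2
    bt <- cumsum(runif(n_max, cfg$breath_interval[1], cfg$breath_interval[2]))
    bt <- bt[bt < total]
    blk <- findInterval(bt, t0)
    v <- tgt[blk]
    if (cfg$lag_tau > 0 && nrow(schedule) > 1) {
      # VO2 at each block entry under the first-order onset lag
      enter <- numeric(nrow(schedule))
      enter[1] <- tgt[1]
      for (b in 2:nrow(schedule)) {
        enter[b] <- tgt[b - 1] +
          (enter[b - 1] - tgt[b - 1]) * exp(-dur[b - 1] / cfg$lag_tau)
      }
      v <- tgt[blk] + (enter[blk] - tgt[blk]) * exp(-(bt - t0[blk]) / cfg$lag_tau)
    }
    if (cfg$vo2_noise_cv > 0) {
      v <- pmax(0, v * (1 + rnorm(length(v), 0, cfg$vo2_noise_cv)))
    }
    out <- tibble::tibble(timestamp = start_time + bt, vo2_ml_min = v)
    attr(out, "body_mass") <- cfg$body_mass
    out
  })
}
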