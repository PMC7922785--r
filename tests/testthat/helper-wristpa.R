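# Brute-force Choi oracle: direct, minute-by-minute implementation of the
# run definition, independent of the rle-based implementation in R/.
choi_oracle <- function(x, window = 90, spike_tol = 2, spike_win = 30) {
  n <- length(x)
  zero <- x == 0
  art <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (!zero[i]) {
      j <- i
      while (j < n && !zero[j + 1]) j <- j + 1
      if (j - i + 1 <= spike_tol) {
        l <- 0; k <- i - 1
        while (k >= 1 && zero[k]) { l <- l + 1; k <- k - 1 }
        r <- 0; k <- j + 1
        while (k <= n && zero[k]) { r <- r + 1; k <- k + 1 }
        if (l >= spike_win && r >= spike_win) art[i:j] <- TRUE
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  cand <- zero | art
  wear <- rep(TRUE, n)
  i <- 1
  while (i <= n) {
    if (cand[i]) {
      j <- i
      while (j < n && cand[j + 1]) j <- j + 1
      if (j - i + 1 >= window) wear[i:j] <- FALSE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  wear
}

# Random minute series alternating zero and active runs, shaped so both
# sub-window and super-window zero runs and short spikes occur.
random_minute_series <- function(max_len = 600) {
  out <- numeric(0)
  while (length(out) < max_len) {
    if (runif(1) < 0.5) {
      out <- c(out, numeric(sample(1:120, 1)))
    } else {
      out <- c(out, sample(1:200, sample(1:40, 1), replace = TRUE))
    }
  }
  out[seq_len(sample(seq_len(max_len), 1))]
}

# Constant-orientation raw stream helper.
flat_stream <- function(xyz, n, fs = 25,
                        t0 = as.POSIXct("2021-03-01 09:00:00", tz = "UTC")) {
  tibble::tibble(timestamp = t0 + (0:(n - 1)) / fs,
                 x = rep(xyz[1], n), y = rep(xyz[2], n), z = rep(xyz[3], n))
}

# Epoch table builder: one intensity class per minute.
epochs_from_classes <- function(classes,
                                t0 = as.POSIXct("2021-03-01 08:00:00",
                                                tz = "UTC")) {
  n <- length(classes)
  tibble::tibble(
    epoch_start = t0 + 60 * (seq_len(n) - 1),
    sed_s = ifelse(classes == "SED", 60, 0),
    lpa_s = ifelse(classes == "LPA", 60, 0),
    mvpa_s = ifelse(classes == "MVPA", 60, 0),
    missing_s = 0,
    mean_enmo_mg = ifelse(classes == "SED", 5,
                          ifelse(classes == "LPA", 70, 200)),
    valid = TRUE
  )
}

noise_free_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, noise_sd = 0, offwrist_noise_sd = 0,
             inter_device_bias = 0, vo2_noise_cv = 0, lag_tau = 0, ...)
}
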