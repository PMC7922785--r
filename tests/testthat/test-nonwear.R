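test_that("choi_nonwear implements the window and spike rules", {
  pad <- rep(5, 10)
  # 90 consecutive zeros bounded by activity -> non-wear
  x <- c(pad, rep(0, 90), pad)
  expect_equal(sum(!choi_nonwear(x)), 90)
  expect_true(all(choi_nonwear(x)[c(1:10, 101:110)]))
  # 89 zeros stay wear
  expect_true(all(choi_nonwear(c(pad, rep(0, 89), pad))))
  # 44 + 2-minute spike + 44 = artifactual, whole 90-block non-wear
  x <- c(pad, rep(0, 44), 7, 7, rep(0, 44), pad)
  expect_equal(sum(!choi_nonwear(x)), 90)
  # 3-minute spike exceeds the tolerance -> all wear
  x <- c(pad, rep(0, 44), 7, 7, 7, rep(0, 44), pad)
  expect_true(all(choi_nonwear(x)))
  # spike with a short flank (< 30 zeros) is real movement
  x <- c(pad, rep(0, 29), 7, rep(0, 70), pad)
  expect_true(all(choi_nonwear(x)[11:40]))
  expect_error(choi_nonwear(c(1, -1, 0)), "non-negative")
})

test_that("choi_nonwear agrees with the brute-force oracle on random series", {
  set.seed(2024)
  for (i in 1:200) {
    x <- random_minute_series(600)
    expect_identical(choi_nonwear(x), choi_oracle(x))
  }
})

test_that("lengthening a zero run never converts non-wear back to wear", {
  set.seed(99)
  for (i in 1:50) {
    x <- random_minute_series(400)
    zi <- which(x == 0)
    if (!length(zi)) next
    base_nonwear <- !choi_nonwear(x)
    # extend one zero run by inserting 30 more zeros at a zero position
    at <- sample(zi, 1)
    y <- append(x, numeric(30), after = at)
    y_nonwear <- !choi_nonwear(y)
    # minutes before the insertion point keep (or gain) non-wear status
    expect_true(all(y_nonwear[seq_len(at)] >= base_nonwear[seq_len(at)]))
    if (at < length(x)) {
      idx_after <- seq(at + 1, length(x))
      expect_true(all(y_nonwear[idx_after + 30] >= base_nonwear[idx_after]))
    }
  }
})

test_that("movement proxy floors stillness and passes activity through", {
  t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")
  ep <- tibble::tibble(epoch_start = t0 + 60 * (0:3),
                       mean_enmo_mg = c(0.4, 120.2, NA, 1.6), valid = TRUE)
  mv <- movement_proxy(ep)
  expect_equal(mv$movement, c(0, 120, 0, 2))
})

test_that("all-still simulated night maps to an all-zero proxy", {
  blk <- activity_block("still", "SED", 120 * 60, 1.0, 0)
  blk$intensity_class <- "OFF"
  sim <- simulate_accel_pair(blk, sim_config(seed = 8))
  ep <- accel_epochs(sim$criterion, fs = 100, calibrate = FALSE)
  expect_true(all(movement_proxy(ep)$movement == 0))
})

test_that("the shared mask combines Choi wear, sleep log and dropout", {
  classes <- c(rep("SED", 120), rep("LPA", 120), rep("MVPA", 60))
  ep_c <- epochs_from_classes(classes)
  ep_t <- ep_c
  # 30-minute test-device dropout -> invalid for both devices
  ep_t$valid[61:90] <- FALSE
  t0 <- ep_c$epoch_start[1]
  log <- tibble::tibble(sleep_start = t0, sleep_end = t0 + 60 * 60)
  mask <- build_wear_mask(ep_t, ep_c, log = log)
  expect_equal(sum(mask$sleep), 60)
  expect_equal(sum(mask$invalid), 30)
  expect_true(all(mask$wear)) # active week, no >= 90-min stillness
  analysis <- mask$wear & !mask$sleep & !mask$invalid
  expect_equal(sum(analysis), 300 - 60 - 30)
  # mask applies identically to both devices in the merge
  merged <- merge_epochs(list(TEST = ep_t, CRITERION = ep_c), mask)
  expect_equal(nrow(merged), 210)
})

test_that("sleep intervals outside the recording span are clipped", {
  ep <- epochs_from_classes(rep("LPA", 60))
  t0 <- ep$epoch_start[1]
  log <- tibble::tibble(sleep_start = t0 - 86400, sleep_end = t0 - 80000)
  expect_warning(mask <- build_wear_mask(ep, ep, log = log), "clipped")
  expect_equal(sum(mask$sleep), 0)
})
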