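test_that("stream sample counts follow duration and sampling rate", {
  p <- default_protocol()[1:2, ]
  sim <- simulate_accel_pair(p, noise_free_cfg())
  dur <- sum(p$duration_s)
  expect_equal(nrow(sim$criterion), ceiling(dur * 100))
  expect_equal(nrow(sim$test), ceiling(dur * 25))
  expect_equal(nrow(sim$truth), dur)
})

test_that("a pure-gravity sedentary block yields near-zero ENMO", {
  blk <- activity_block("still", "SED", 300, 1.0, 0)
  sim <- simulate_accel_pair(blk, noise_free_cfg())
  e <- compute_enmo(sim$criterion, fs = 100)
  expect_true(all(e$enmo_mg <= 1)) # <= 1 mg despite orientation drift
})

test_that("noise-free per-second ENMO sits within 1% of the block target", {
  p <- default_protocol()
  sim <- simulate_accel_pair(p, noise_free_cfg())
  e <- compute_enmo(sim$criterion, fs = 100)
  tgt <- rep(p$target_enmo, p$duration_s)
  active <- tgt > 0
  expect_lt(max(abs(e$enmo_mg[active] - tgt[active]) / tgt[active]), 0.01)
})

test_that("identical sim config reproduces byte-identical streams", {
  p <- default_protocol()[c(1, 6, 11), ]
  cfg <- sim_config(seed = 42)
  s1 <- simulate_accel_pair(p, cfg)
  s2 <- simulate_accel_pair(p, cfg)
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_accel_csv(s1$test, f1); write_accel_csv(s2$test, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("overlapping dropout gaps are rejected", {
  p <- default_protocol()[1:2, ]
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  gaps <- tibble::tibble(start = c(t0 + 60, t0 + 120),
                         end = c(t0 + 180, t0 + 240))
  expect_error(simulate_accel_pair(p, sim_config(), t0, dropout_gaps = gaps),
               "overlap")
})

test_that("breath VO2 reaches the MET-predicted steady state", {
  blk <- activity_block("rest", "SED", 300, 1.0, 5)
  cfg <- noise_free_cfg()
  cfg$body_mass <- 70
  br <- simulate_breaths(blk, cfg)
  expect_true(all(abs(br$vo2_ml_min - 245) < 1e-9)) # 1 MET = 3.5 * 70
  blk3 <- activity_block("walk", "MVPA", 300, 3.0, 180)
  br3 <- simulate_breaths(blk3, cfg)
  expect_true(all(abs(br3$vo2_ml_min - 735) < 1e-9))
  expect_identical(simulate_breaths(blk, cfg), simulate_breaths(blk, cfg))
})

test_that("the onset lag decays first-order towards the new target", {
  sched <- dplyr::bind_rows(activity_block("rest", "SED", 300, 1.0, 5),
                            activity_block("run", "MVPA", 300, 6.0, 300))
  cfg <- noise_free_cfg()
  cfg$lag_tau <- 30
  cfg$body_mass <- 70
  br <- simulate_breaths(sched, cfg)
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  tt <- as.numeric(br$timestamp - t0, units = "secs")
  in2 <- tt > 300
  expected <- 6 * 245 + (245 - 6 * 245) * exp(-(tt[in2] - 300) / 30)
  expect_equal(br$vo2_ml_min[in2], expected, tolerance = 1e-9)
  # near-complete adaptation after several time constants
  late <- tt > 300 + 150
  expect_true(all(abs(br$vo2_ml_min[late] - 1470) < 1470 * 0.01))
})

test_that("fixture studies are complete and checksum-reproducible", {
  cfg <- sim_config(seed = 9, fs_test = 2, fs_criterion = 4)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  m1 <- write_fixture_study(d1, n_participants = 2, cfg = cfg, days = 1,
                            waking = c(9, 13))
  m2 <- write_fixture_study(d2, n_participants = 2, cfg = cfg, days = 1,
                            waking = c(9, 13))
  expect_equal(sort(list.files(file.path(d1, "P01"))),
               sort(c("protocol_test.csv", "protocol_criterion.csv",
                      "protocol_breath.csv", "week_test.csv",
                      "week_criterion.csv", "truth.csv")))
  expect_true(all(c("participants.csv", "log.csv", "manifest.json") %in%
                    list.files(d1)))
  expect_equal(m1$md5, m2$md5) # identical seed, identical bytes
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty fixture study is not an error", {
  d <- file.path(tempdir(), "fx0")
  m <- write_fixture_study(d, n_participants = 0, cfg = sim_config(),
                           days = 1)
  expect_equal(sum(grepl("^P", m$file)), 0)
  unlink(d, recursive = TRUE)
})
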