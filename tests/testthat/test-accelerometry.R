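test_that("ENMO unit vectors map to the defining values", {
  f <- function(xyz) compute_enmo(flat_stream(xyz, 25), fs = 25)$enmo_mg
  expect_equal(f(c(0, 0, 1)), 0)          # unit gravity
  expect_equal(f(c(0, 0, 2)), 1000)       # 2 g norm -> 1000 mg
  expect_equal(f(c(0.6, 0, 0.8)), 0)      # norm exactly 1
  expect_equal(f(c(0, 0, 0.9)), 0)        # negative rounded to zero
})

test_that("ENMO is invariant under axis permutation and sign flips", {
  set.seed(7)
  base <- flat_stream(c(0, 0, 0), 200)
  base$x <- rnorm(200); base$y <- rnorm(200); base$z <- rnorm(200)
  ref <- compute_enmo(base, fs = 25)$enmo_mg
  perm <- base; perm$x <- base$z; perm$z <- base$x
  flip <- base; flip$y <- -base$y
  expect_equal(compute_enmo(perm, fs = 25)$enmo_mg, ref)
  expect_equal(compute_enmo(flip, fs = 25)$enmo_mg, ref)
})

test_that("per-second ENMO matches a naive single-pass oracle", {
  set.seed(11)
  n <- 10000
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  stream <- tibble::tibble(
    timestamp = t0 + (0:(n - 1)) / 25,
    x = rnorm(n, 0, 0.5), y = rnorm(n, 0, 0.5), z = rnorm(n, 0.8, 0.5)
  )
  # oracle: explicit loop, direct per-sample formula, no vectorization
  sums <- numeric(0); cnts <- numeric(0)
  for (i in seq_len(n)) {
    s <- as.character(floor(as.numeric(stream$timestamp[i])))
    e <- max(sqrt(stream$x[i]^2 + stream$y[i]^2 + stream$z[i]^2) - 1, 0)
    sums[s] <- ifelse(is.na(sums[s]), 0, sums[s]) + e
    cnts[s] <- ifelse(is.na(cnts[s]), 0, cnts[s]) + 1
  }
  oracle <- unname(sums / cnts) * 1000
  got <- compute_enmo(stream, fs = 25)
  expect_equal(got$enmo_mg, oracle, tolerance = 1e-9)
  # classified + missing seconds account for the whole span
  cl <- classify_seconds(got)
  expect_equal(sum(!is.na(cl$class)) + sum(is.na(cl$class)), nrow(got))
  expect_equal(nrow(got),
               floor(as.numeric(max(stream$timestamp))) -
                 floor(as.numeric(min(stream$timestamp))) + 1)
})

test_that("seconds below the coverage threshold are missing", {
  stream <- flat_stream(c(0, 0, 1), 75) # 3 s at 25 Hz
  stream <- stream[-(30:47), ]          # second 2 keeps 7/25 samples
  e <- compute_enmo(stream, fs = 25, coverage_min = 0.5)
  expect_true(is.na(e$enmo_mg[2]))
  expect_false(anyNA(e$enmo_mg[-2]))
})

test_that("cut-point classification uses half-open bands, upper class wins", {
  cuts <- cut_points()
  cls <- function(v) {
    as.character(classify_seconds(
      tibble::tibble(second = Sys.time() + seq_along(v), enmo_mg = v,
                     coverage = 1), cuts)$class)
  }
  expect_equal(cls(0), "SED")
  expect_equal(cls(cuts$sed_lpa), "LPA")
  expect_equal(cls(cuts$lpa_mvpa), "MVPA")
  sweep <- cls(seq(0, 300, by = 0.1))
  expect_true(!is.unsorted(match(sweep, c("SED", "LPA", "MVPA"))))
})

test_that("epoch collapsing tallies classes and flags missing seconds", {
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  mk <- function(v) tibble::tibble(second = t0 + seq_along(v) - 1,
                                   enmo_mg = v, coverage = 1)
  ep1 <- collapse_to_epochs(classify_seconds(mk(rep(0, 60))))
  expect_equal(unlist(ep1[1, c("sed_s", "lpa_s", "mvpa_s")], use.names = FALSE),
               c(60, 0, 0))
  ep2 <- collapse_to_epochs(classify_seconds(mk(c(rep(0, 30), rep(200, 30)))))
  expect_equal(unlist(ep2[1, c("sed_s", "lpa_s", "mvpa_s")], use.names = FALSE),
               c(30, 0, 30))
  v <- rep(0, 60); v[21:30] <- NA
  ep3 <- collapse_to_epochs(classify_seconds(mk(v)), missing_tol = 0)
  expect_false(ep3$valid[1])
  expect_equal(ep3$missing_s[1], 10)
  ep4 <- collapse_to_epochs(classify_seconds(mk(v)), missing_tol = 10)
  expect_true(ep4$valid[1])
})

test_that("static calibration recovers a planted gain error", {
  set.seed(42)
  us <- matrix(rnorm(36), ncol = 3)
  us <- us / sqrt(rowSums(us^2))
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  n <- 60 * 25
  stream <- dplyr::bind_rows(lapply(1:12, function(i) {
    tibble::tibble(timestamp = t0 + (i - 1) * 60 + (0:(n - 1)) / 25,
                   x = us[i, 1] + rnorm(n, 0, 0.003),
                   y = us[i, 2] + rnorm(n, 0, 0.003),
                   z = us[i, 3] + rnorm(n, 0, 0.003))
  }))
  recorded <- stream
  recorded$x <- recorded$x * 1.02
  cal <- calibrate_accel(recorded)
  info <- attr(cal, "calibration")
  expect_true(info$calibrated)
  expect_lt(abs(info$gain[1] - 1 / 1.02), 0.002)
  expect_lt(max(abs(info$gain[2:3] - 1)), 0.002)
  # fixed point: an already-calibrated stream changes < 1 mg
  cal2 <- calibrate_accel(stream)
  expect_lt(max(abs(as.matrix(cal2[, 2:4]) - as.matrix(stream[, 2:4]))),
            0.001)
})

test_that("streams without usable static windows are flagged uncalibrated", {
  set.seed(1)
  n <- 15 * 60 * 25
  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  busy <- tibble::tibble(timestamp = t0 + (0:(n - 1)) / 25,
                         x = rnorm(n, 0, 0.3), y = rnorm(n, 0, 0.3),
                         z = rnorm(n, 1, 0.3))
  expect_warning(out <- calibrate_accel(busy), "uncalibrated")
  expect_false(attr(out, "calibration")$calibrated)
  expect_identical(out$x, busy$x)
  short <- busy[1:100, ]
  expect_error(calibrate_accel(short), "10 minutes")
})
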