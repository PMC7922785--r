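#' Collapse breath-by-breath VO2 to minute epochs
#'
#' Emulates the vendor epoch export: each breath's VO2 is held until the
#' next breath (sample-and-hold), but for at most `max_hold` seconds — a
#' silent stretch longer than that (mask off, signal dropout) leaves
#' uncovered time rather than a stale reading. Time-weighted means are
#' taken over 10-s bins, and minutes are the arithmetic mean of their
#' available bins. A bin is available when the held signal covers at least
#' half of it; minutes with fewer than `min_bins` available bins are
#' missing.
#'
#' @param breaths Tibble `timestamp, vo2_ml_min`, timestamps increasing.
#' @param intermediate Intermediate bin length (s).
#' @param final Final epoch length (s).
#' @param min_bins Minimum available bins per final epoch.
#' @param max_hold Longest time (s) a breath value is held.
#' @return Tibble `epoch_start, mean_vo2` on a contiguous minute grid.
#' @export
collapse_breaths <- function(breaths, intermediate = 10, final = 60,
                             min_bins = 3, max_hold = 10) {
  stopifnot(final %% intermediate == 0)
  t <- as.numeric(breaths$timestamp)
  v <- breaths$vo2_ml_min
  if (length(t) == 0) {
    return(tibble::tibble(epoch_start = as.POSIXct(character(), tz = "UTC"),
                          mean_vo2 = numeric()))
  }
  if (is.unsorted(t)) abort("breath timestamps must be increasing")
  bin0 <- floor(t[1] / intermediate) * intermediate
  bin_last <- floor(t[length(t)] / intermediate) * intermediate
  edges <- seq(bin0, bin_last + intermediate, by = intermediate)
  n_bins <- length(edges) - 1
  # piecewise-constant integral of the held signal over each bin; extra
  # breakpoints at t + max_hold keep every segment homogeneous in coverage
  brk <- sort(unique(c(edges, t, t + max_hold)))
  brk <- brk[brk >= edges[1] & brk <= edges[length(edges)]]
  seg_a <- brk[-length(brk)]
  seg_b <- brk[-1]
  idx <- findInterval(seg_a, t)
  seg_v <- ifelse(idx >= 1, v[pmax(idx, 1)], 0) # undefined before 1st breath
  covered <- idx >= 1 & (seg_a - t[pmax(idx, 1)]) < max_hold
  seg_bin <- findInterval(seg_a, edges)
  w <- (seg_b - seg_a) * covered
  int_v <- numeric(n_bins); int_w <- numeric(n_bins)
  ix <- seg_bin >= 1 & seg_bin <= n_bins
  if (any(ix)) {
    sv <- rowsum((w * ifelse(covered, seg_v, 0))[ix], seg_bin[ix])
    sw <- rowsum(w[ix], seg_bin[ix])
    int_v[as.integer(rownames(sv))] <- sv[, 1]
    int_w[as.integer(rownames(sw))] <- sw[, 1]
  }
  bin_mean <- ifelse(int_w > 0, int_v / pmax(int_w, 1e-12), NA_real_)
  bin_ok <- int_w >= intermediate / 2
  bin_mean[!bin_ok] <- NA_real_
  bin_start <- edges[-length(edges)]
  ep <- floor(bin_start / final) * final
  grid <- seq(min(ep), max(ep), by = final)
  gi <- match(ep, grid)
  ok <- as.integer(!is.na(bin_mean))
  n_ok <- integer(length(grid))
  n_ok[sort(unique(gi))] <- rowsum(ok, gi)[, 1]
  s <- numeric(length(grid))
  s[sort(unique(gi))] <- rowsum(ifelse(is.na(bin_mean), 0, bin_mean), gi)[, 1]
  tibble::tibble(
    epoch_start = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    mean_vo2 = ifelse(n_ok >= min_bins, s / pmax(n_ok, 1), NA_real_)
  )
}

#' Convert VO2 to MET
#'
#' `MET = VO2 / (3.5 * body mass)`, with VO2 in mL/min and mass in kg
#' (1 MET = 3.5 mL/kg/min).
#'
#' @param vo2 VO2 in mL/min (vectorized).
#' @param body_mass Body mass in kg (> 0).
#' @return MET values.
#' @export
vo2_to_met <- function(vo2, body_mass) {
  if (!is.numeric(body_mass) || length(body_mass) != 1 || body_mass <= 0) {
    abort("body_mass must be a positive scalar (kg)")
  }
  vo2 / (3.5 * body_mass)
}

#' Classify MET values into intensity classes
#'
#' Continuous half-open bands built from the breakpoints: SED at or below
#' the first, LPA strictly between the first and second, MPA from the
#' second up to (not including) the third, VPA at or above the third. The
#' printed band tables of the MET literature leave gaps (e.g. 1.5-1.6);
#' continuous bands classify every value.
#'
#' @param met MET values (vectorized, >= 0; `NA` passes through).
#' @param breakpoints Numeric length 3, increasing.
#' @return Ordered factor with levels `SED < LPA < MPA < VPA`.
#' @export
classify_met <- function(met, breakpoints = c(1.5, 3.0, 6.0)) {
  stopifnot(length(breakpoints) == 3, all(diff(breakpoints) > 0))
  if (any(met < 0, na.rm = TRUE)) abort("MET values must be non-negative")
  cl <- ifelse(met <= breakpoints[1], "SED",
               ifelse(met < breakpoints[2], "LPA",
                      ifelse(met < breakpoints[3], "MPA", "VPA")))
  factor(cl, levels = .MET_CLASSES, ordered = TRUE)
}

#' Breath stream to MET-classified minute epochs
#'
#' @param breaths Tibble `timestamp, vo2_ml_min`.
#' @param body_mass Body mass (kg); taken from the stream's `body_mass`
#'   attribute if `NULL`.
#' @param config A [study_config()] (MET breakpoints).
#' @return Tibble `epoch_start, mean_vo2, met, met_class, valid`.
#' @export
met_epochs <- function(breaths, body_mass = NULL, config = study_config()) {
  if (is.null(body_mass)) body_mass <- attr(breaths, "body_mass")
  if (is.null(body_mass)) abort("body_mass required")
  collapse_breaths(breaths) |>
    dplyr::mutate(
      met = vo2_to_met(.data$mean_vo2, body_mass),
      met_class = classify_met(.data$met, config$met_breakpoints),
      valid = !is.na(.data$met)
    )
}
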