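#' Build one activity block
#'
#' An activity block is a constant-intensity segment of a simulated session:
#' a label, the intensity category it belongs to, a duration, and the two
#' targets the generator is asked to induce — a metabolic cost in MET and a
#' mean movement intensity in milli-g ENMO.
#'
#' @param label Activity name.
#' @param intensity_class One of `"SED"`, `"LPA"`, `"MVPA"`, `"TRANSIT"`.
#' @param duration_s Block duration in seconds (> 0).
#' @param target_met Target metabolic cost (MET, >= 0.9).
#' @param target_enmo Target mean ENMO (mg, >= 0).
#' @param freq_hz Oscillation frequency of the synthesized movement (Hz);
#'   integer values keep per-second means exact.
#' @return A one-row tibble.
#' @export
activity_block <- function(label, intensity_class, duration_s,
                           target_met, target_enmo, freq_hz = 1) {
  intensity_class <- match.arg(intensity_class,
                               c("SED", "LPA", "MVPA", "TRANSIT"))
  stopifnot(duration_s > 0, target_enmo >= 0, target_met >= 0.9)
  tibble::tibble(
    label = label, intensity_class = intensity_class,
    duration_s = as.numeric(duration_s),
    target_met = target_met, target_enmo = target_enmo,
    freq_hz = freq_hz,
    # class the block is designed to induce in both processing chains;
    # transit breaks are light walking between stations
    truth_class = ifelse(intensity_class == "TRANSIT", "LPA",
                         intensity_class)
  )
}

#' The simulated free-living activity protocol
#'
#' A 62-minute gym protocol of 12 activities in three intensity categories
#' (four sedentary, four light, four moderate-to-vigorous; 5 minutes each)
#' with a 1-minute transit break between categories. Per-block MET and ENMO
#' targets are chosen comfortably inside the class bands of the default
#' cut-points and MET breakpoints, so the induced class always matches the
#' category.
#'
#' @return Tibble of activity blocks in protocol order.
#' @export
#' @examples
#' p <- default_protocol()
#' sum(p$duration_s) / 60 # 62 minutes
default_protocol <- function() {
  dplyr::bind_rows(
    activity_block("resting supine",             "SED", 300, 1.0, 5),
    activity_block("watching TV sitting",        "SED", 300, 1.3, 5),
    activity_block("reading books sitting",      "SED", 300, 1.3, 6),
    activity_block("typing at computer sitting", "SED", 300, 1.4, 8),
    activity_block("transit 1",              "TRANSIT",  60, 2.0, 60),
    activity_block("fidgeting standing",         "LPA", 300, 1.8, 60),
    activity_block("casual walk 1-1.5 mph",      "LPA", 300, 2.0, 70),
    activity_block("housekeeping",               "LPA", 300, 2.5, 80),
    activity_block("exploring and sorting",      "LPA", 300, 2.5, 90),
    activity_block("transit 2",              "TRANSIT",  60, 2.0, 60),
    activity_block("brisk walk 2.5-3.0 mph",    "MVPA", 300, 3.3, 180, 2),
    activity_block("running 3.5-4.0 mph",       "MVPA", 300, 5.0, 250, 2),
    activity_block("running 4.5-5.0 mph",       "MVPA", 300, 8.0, 330, 2),
    activity_block("full-body free play",       "MVPA", 300, 6.5, 400, 2)
  )
}

# Expand a block table into per-second truth labels starting at start_time.
protocol_truth_seconds <- function(blocks, start_time) {
  n <- sum(blocks$duration_s)
  cls <- rep(blocks$truth_class, times = blocks$duration_s)
  lab <- rep(blocks$label, times = blocks$duration_s)
  met <- rep(blocks$target_met, times = blocks$duration_s)
  tibble::tibble(
    second = start_time + seq_len(n) - 1,
    label = lab, truth_class = cls, target_met = met
  )
}
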