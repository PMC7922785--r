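#' Merge epoch streams on the shared analysis set
#'
#' Inner join on `epoch_start` restricted to the analysis set of the mask
#' (`wear & !sleep & !invalid`): a minute appears if and only if every
#' requested source has a valid epoch there. Columns are prefixed with the
#' source name.
#'
#' @param epochs_by_source Named list of epoch tibbles (accelerometer
#'   epochs from [collapse_to_epochs()] or calorimetry epochs from
#'   [met_epochs()]); each must have `epoch_start` and `valid`.
#' @param mask Tibble from [build_wear_mask()], or `NULL` to use every
#'   minute where all sources are valid.
#' @return Wide tibble, one row per analysis minute.
#' @export
merge_epochs <- function(epochs_by_source, mask = NULL) {
  stopifnot(length(epochs_by_source) >= 1,
            !is.null(names(epochs_by_source)),
            all(nzchar(names(epochs_by_source))))
  keep <- NULL
  if (!is.null(mask)) {
    keep <- mask$epoch_start[mask$wear & !mask$sleep & !mask$invalid]
  }
  pieces <- purrr::imap(epochs_by_source, function(ep, nm) {
    ep <- dplyr::filter(ep, .data$valid)
    if (!is.null(keep)) {
      ep <- dplyr::filter(ep, .data$epoch_start %in% keep)
    }
    dplyr::rename_with(ep, function(x) paste(nm, x, sep = "_"),
                       -"epoch_start")
  })
  merged <- purrr::reduce(pieces, function(a, b) {
    dplyr::inner_join(a, b, by = "epoch_start")
  })
  if (nrow(merged) == 0) abort("no valid overlap between epoch sources")
  dplyr::arrange(merged, .data$epoch_start)
}

# Class minutes of a single source within a merged slice.
source_class_minutes <- function(merged, nm) {
  sed_col <- paste0(nm, "_sed_s")
  if (sed_col %in% names(merged)) {
    sed <- sum(merged[[sed_col]]) / 60
    lpa <- sum(merged[[paste0(nm, "_lpa_s")]]) / 60
    mvpa <- sum(merged[[paste0(nm, "_mvpa_s")]]) / 60
  } else {
    cl <- merged[[paste0(nm, "_met_class")]]
    sed <- sum(cl == "SED")
    lpa <- sum(cl == "LPA")
    mvpa <- sum(cl == "MPA" | cl == "VPA") # calorimetry MVPA = MPA + VPA
  }
  tibble::tibble(device = nm, sed_min = sed, lpa_min = lpa, mvpa_min = mvpa,
                 tpa_min = lpa + mvpa, wear_min = nrow(merged))
}

#' Summarize merged epochs into activity minutes
#'
#' Minutes per intensity class for every source in a merged table:
#' accelerometer sources contribute `sum(seconds in class)/60`,
#' calorimetry sources the count of classified minutes (with MVPA = MPA +
#' VPA). `period = "session"` yields one row per source; `period = "day"`
#' one row per source and calendar day.
#'
#' @param merged Tibble from [merge_epochs()].
#' @param period `"session"` or `"day"`.
#' @return Tibble `device, (day,) sed_min, lpa_min, mvpa_min, tpa_min,
#'   wear_min`.
#' @export
summarize_activity <- function(merged, period = c("session", "day")) {
  period <- match.arg(period)
  if (nrow(merged) == 0) abort("merged table is empty")
  nms <- unique(sub("_(sed_s|met_class)$", "",
                    grep("_(sed_s|met_class)$", names(merged), value = TRUE)))
  if (period == "session") {
    out <- purrr::map(nms, function(nm) source_class_minutes(merged, nm))
    return(dplyr::bind_rows(out))
  }
  merged$..day <- as.Date(merged$epoch_start)
  out <- purrr::map(nms, function(nm) {
    merged |>
      dplyr::group_by(day = .data$..day) |>
      dplyr::group_modify(function(df, key) source_class_minutes(df, nm)) |>
      dplyr::ungroup()
  })
  dplyr::bind_rows(out) |>
    dplyr::relocate("device")
}

#' Average per-day summaries into min/day
#'
#' Days must reach `valid_day_min` valid minutes to be included; the
#' default 0 includes every day with any valid time. A participant-device
#' with zero qualifying days is dropped with a warning.
#'
#' @param daily Per-day summary tibble from
#'   `summarize_activity(period = "day")`, optionally with extra grouping
#'   columns (e.g. `participant`).
#' @param valid_day_min Minimum valid minutes per day.
#' @return One row per device (and extra grouping columns) with min/day
#'   averages and `n_days`.
#' @export
daily_average <- function(daily, valid_day_min = 0) {
  keep <- daily$wear_min > 0 & daily$wear_min >= valid_day_min
  if ("participant" %in% names(daily)) {
    lost <- setdiff(unique(daily$participant),
                    unique(daily$participant[keep]))
    if (length(lost)) {
      warn(paste0("participant(s) with zero valid days excluded: ",
                  paste(lost, collapse = ", ")))
    }
  } else if (!any(keep)) {
    warn("no days meet the valid-day rule")
  }
  if (!all(keep)) daily <- daily[keep, ]
  grp <- intersect(c("participant", "device"), names(daily))
  daily |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(dplyr::across(dplyr::ends_with("_min"), mean),
                     n_days = dplyr::n(), .groups = "drop")
}
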