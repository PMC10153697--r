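#' Build a light/dark sampling design
#'
#' Generates the sample metadata for a diel time course: time points at a
#' fixed interval starting one interval after sunrise, with replicate samples
#' at each point. Phase labels follow the marine diel-sampling convention:
#' `L<h>` is `h` hours into the light period, `D<h>` is `h` hours into the
#' dark period, and labels from the second light-dark cycle carry a `2`
#' prefix (`2D12`, `2L3`, ...). `D12` (for a 12 h night) is the sunrise
#' instant and `L12` the sunset instant.
#'
#' @param n_timepoints Number of time points (>= 1; >= 4 for any periodicity
#'   analysis downstream).
#' @param interval Hours between consecutive time points (> 0).
#' @param n_replicates Replicate samples per time point (>= 1).
#' @param sunrise_hour Clock hour of sunrise on day 1, in `[0, 24)`.
#' @param daylight Length of the light period in hours (0 < daylight < 24).
#'
#' @return A tibble with one row per sample: `sample_id`, `clock_hour`,
#'   `phase_label`, `day_index`, `replicate`, `hours_since_start`.
#' @examples
#' make_design(10, 3, 2, sunrise_hour = 6, daylight = 12)
#' @export
make_design <- function(n_timepoints, interval, n_replicates = 1,
                        sunrise_hour = 6, daylight = 12) {
  stopifnot(n_timepoints >= 1, n_replicates >= 1,
            daylight > 0, daylight < 24)
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("`interval` must be a single positive number of hours",
         call. = FALSE)
  }
  # first sample is one interval after the day-1 sunrise
  h_sunrise <- interval + (seq_len(n_timepoints) - 1L) * interval
  tp <- tibble::tibble(
    timepoint = seq_len(n_timepoints),
    hours_since_start = h_sunrise - interval,
    clock_hour = (sunrise_hour + h_sunrise) %% 24,
    phase_label = phase_label(h_sunrise, daylight),
    day_index = cycle_index(h_sunrise)
  )
  out <- tidyr::crossing(tp, replicate = seq_len(n_replicates)) |>
    dplyr::arrange(.data$hours_since_start, .data$replicate) |>
    dplyr::mutate(
      sample_id = paste0(.data$phase_label, "_r", .data$replicate)
    ) |>
    dplyr::select("sample_id", "clock_hour", "phase_label", "day_index",
                  "replicate", "hours_since_start")
  out
}

#' Phase labels from hours past the first sunrise
#'
#' @param hours_since_sunrise Hours elapsed since the day-1 sunrise (>= 0).
#' @param daylight Light-period length in hours.
#' @return Character vector of labels such as `"L3"`, `"D12"`, `"2L6"`.
#' @keywords internal
#' @export
phase_label <- function(hours_since_sunrise, daylight = 12) {
  h <- hours_since_sunrise
  cyc <- cycle_index(h)
  p <- h %% 24
  lab <- ifelse(
    p == 0, paste0("D", fmt_hours(24 - daylight)),
    ifelse(p <= daylight,
           paste0("L", fmt_hours(p)),
           paste0("D", fmt_hours(p - daylight)))
  )
  ifelse(cyc > 1L, paste0(cyc, lab), lab)
}

# light-dark cycle number; the sunrise instant belongs to the new cycle
cycle_index <- function(hours_since_sunrise) {
  as.integer(floor(hours_since_sunrise / 24)) + 1L
}

fmt_hours <- function(x) {
  ifelse(x == round(x), as.character(as.integer(round(x))),
         as.character(x))
}

#' Phase-label arithmetic
#'
#' `parse_phase_label()` splits labels like `"2D12"` into cycle, period and
#' hours. `label_phase_hours()` maps a label to its position on a 24 h clock
#' anchored at sunrise (sunrise = 0/24, so `D12` with a 12 h night maps to 0
#' and `L12` to 12). `collapse_label()` drops the cycle prefix so day-1 and
#' day-2 samples of the same time of day share one label (`2L6` -> `L6`).
#'
#' @param label Character vector of phase labels.
#' @param daylight Light-period length in hours.
#' @return `parse_phase_label()`: a tibble with `cycle`, `period` (`"L"` or
#'   `"D"`) and `hours`; `label_phase_hours()`: numeric hours since sunrise
#'   in `[0, 24)`; `collapse_label()`: character labels.
#' @export
parse_phase_label <- function(label) {
  m <- stringr::str_match(label, "^([0-9]*)([LD])([0-9.]+)$")
  if (anyNA(m[, 1])) {
    bad <- unique(label[is.na(m[, 1])])
    stop("malformed phase label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    label = label,
    cycle = ifelse(m[, 2] == "", 1L, suppressWarnings(as.integer(m[, 2]))),
    period = m[, 3],
    hours = as.numeric(m[, 4])
  )
}

#' @rdname parse_phase_label
#' @export
label_phase_hours <- function(label, daylight = 12) {
  p <- parse_phase_label(label)
  h <- ifelse(p$period == "L", p$hours, daylight + p$hours)
  h %% 24
}

#' @rdname parse_phase_label
#' @export
collapse_label <- function(label) {
  stringr::str_remove(label, "^[0-9]+")
}

#' Restrict a design to a subset of time points
#'
#' Keeps only the samples whose phase labels are in `labels`, preserving the
#' original time order. Used for sensitivity reruns on the time points shared
#' between two studies.
#'
#' @param design A design tibble from [make_design()].
#' @param labels Phase labels to keep (must all be present in the design).
#' @return The subsetted design tibble.
#' @export
subset_timepoints <- function(design, labels) {
  missing <- setdiff(labels, design$phase_label)
  if (length(missing) > 0) {
    stop("labels not in design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  design |>
    dplyr::filter(.data$phase_label %in% labels) |>
    dplyr::arrange(.data$hours_since_start, .data$replicate)
}
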