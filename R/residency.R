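# Detection days, residency index, station-residency runs, occupancy and
# monthly summaries.

#' Reduce retained detections to detection days
#'
#' A detection day is a calendar date (in the reporting timezone) on which a
#' shark was detected at a station at least once; one row per unique
#' (shark, station, date) triple. The first ping time of each triple is kept
#' because same-day multi-station ties in run segmentation are broken by it.
#'
#' @param detections QC-retained detections with `tag_id`, `station_id`,
#'   `timestamp`.
#' @param tags Tag table mapping `tag_id` to `shark_id`.
#' @param tz Reporting timezone; default UTC.
#' @return Tibble with `shark_id`, `station_id`, `date`, `first_time`,
#'   `n_pings`, ordered by shark, date, first ping.
#' @export
to_detection_days <- function(detections, tags, tz = "UTC") {
  assert_columns(detections, c("tag_id", "station_id", "timestamp"),
                 "detections")
  detections %>%
    left_join(select(tags, dplyr::all_of(c("tag_id", "shark_id"))),
              by = "tag_id") %>%
    mutate(date = detection_date(.data$timestamp, tz)) %>%
    group_by(.data$shark_id, .data$station_id, .data$date) %>%
    summarise(first_time = min(.data$timestamp), n_pings = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$shark_id, .data$date, .data$first_time, .data$station_id)
}

#' Residency summaries for every shark
#'
#' The residency index (RI) is the number of distinct detection days divided
#' by the monitoring period, i.e. the proportion of its monitored time a
#' shark spent within acoustic range of the arrays. The monitoring period is
#' counted inclusively, `(last - first) + 1` days, so a shark detected on a
#' single day has RI = 1 rather than an undefined ratio.
#'
#' @param detection_days Output of [to_detection_days()].
#' @return Tibble with one row per shark: `first_detection`,
#'   `last_detection`, `monitoring_days`, `n_detection_days`, `ri`.
#' @export
residency_summary <- function(detection_days) {
  assert_columns(detection_days, c("shark_id", "station_id", "date"),
                 "detection_days")
  if (nrow(detection_days) == 0) {
    return(tibble(shark_id = character(),
                  first_detection = as.Date(character()),
                  last_detection = as.Date(character()),
                  monitoring_days = integer(), n_detection_days = integer(),
                  ri = numeric()))
  }
  detection_days %>%
    group_by(.data$shark_id) %>%
    summarise(
      first_detection = min(.data$date),
      last_detection = max(.data$date),
      n_detection_days = dplyr::n_distinct(.data$date),
      .groups = "drop"
    ) %>%
    mutate(
      monitoring_days =
        as.integer(.data$last_detection - .data$first_detection) + 1L,
      ri = .data$n_detection_days / .data$monitoring_days
    ) %>%
    select(dplyr::all_of(c("shark_id", "first_detection", "last_detection",
                           "monitoring_days", "n_detection_days", "ri")))
}

#' Residency index for a single shark
#'
#' @param detection_days Output of [to_detection_days()].
#' @param shark A `shark_id` present in the data.
#' @return One-row tibble as in [residency_summary()].
#' @export
residency_index <- function(detection_days, shark) {
  out <- residency_summary(filter(detection_days, .data$shark_id == shark))
  if (nrow(out) == 0) {
    stop_sharknet(sprintf("shark '%s' has no detection days", shark),
                  "sharknet_not_found_error")
  }
  out
}

#' Station residency runs
#'
#' Segments a shark's detection days into runs of consecutive days at one
#' station. A run ends when the shark is next detected at another station
#' (`other_station`), when it is absent for over 24 hours (a missing calendar
#' day at that station, `gap_over_24h`) before being re-detected there, or at
#' the end of the record. On a day with detections at several stations, the
#' run at the station with the earliest first ping continues through that
#' day; runs at the other stations start that day.
#'
#' @param detection_days Output of [to_detection_days()].
#' @param shark A `shark_id`; `NULL` (default) computes runs for all sharks.
#' @return Tibble with `shark_id`, `station_id`, `start_date`, `length_days`,
#'   `terminated_by`.
#' @export
station_residency_runs <- function(detection_days, shark = NULL) {
  if (!is.null(shark)) {
    detection_days <- filter(detection_days, .data$shark_id == shark)
  }
  if (nrow(detection_days) == 0) {
    return(tibble(shark_id = character(), station_id = character(),
                  start_date = as.Date(character()),
                  length_days = integer(), terminated_by = character()))
  }
  out <- lapply(split(detection_days, detection_days$shark_id),
                runs_one_shark)
  bind_rows(out)
}

runs_one_shark <- function(dd) {
  dd <- arrange(dd, .data$date, .data$first_time, .data$station_id)
  # earliest-first-ping station of each calendar day (tie-break station_id)
  primary <- dd %>%
    group_by(.data$date) %>%
    slice(1) %>%
    ungroup() %>%
    select(dplyr::all_of(c("date", "station_id"))) %>%
    rename(primary_station = "station_id")
  dd <- left_join(dd, primary, by = "date")
  multi_day <- dd %>% count(.data$date) %>% filter(.data$n > 1) %>%
    pull(.data$date)

  all_days <- sort(unique(dd$date))
  runs <- list()
  for (st in unique(dd$station_id)) {
    days <- sort(unique(dd$date[dd$station_id == st]))
    # break on calendar gaps (absence > 24 h) ...
    brk <- c(TRUE, diff(days) > 1)
    # ... and on multi-station days where this station is not primary
    if (length(multi_day) > 0) {
      not_primary <- days %in% multi_day &
        dd$primary_station[match(days, dd$date)] != st
      brk <- brk | not_primary
    }
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      d <- days[grp == g]
      runs[[length(runs) + 1]] <- tibble(
        shark_id = dd$shark_id[1], station_id = st,
        start_date = d[1], end_date = d[length(d)],
        length_days = length(d)
      )
    }
  }
  runs <- bind_rows(runs) %>% arrange(.data$start_date, .data$station_id)
  # label what terminated each run from the shark's next detection day
  runs$terminated_by <- vapply(seq_len(nrow(runs)), function(i) {
    later <- dd[dd$date > runs$end_date[i], ]
    if (nrow(later) == 0) return("end_of_record")
    nxt <- later[later$date == min(later$date), ]
    if (any(nxt$station_id != runs$station_id[i])) "other_station"
    else "gap_over_24h"
  }, character(1))
  select(runs, -dplyr::all_of("end_date"))
}

#' Mean station residency per station
#'
#' @param runs Output of [station_residency_runs()].
#' @return Tibble with `station_id`, `mean_run_days`, `n_runs`.
#' @export
station_residency <- function(runs) {
  runs %>%
    group_by(.data$station_id) %>%
    summarise(mean_run_days = mean(.data$length_days),
              n_runs = dplyr::n(), .groups = "drop")
}

#' Station occupancy for a group of sharks
#'
#' Occupancy is the group-averaged total number of detection days at a
#' station. Group members with zero detection days at a station contribute
#' zeros; when `receivers` and the sharks' monitoring windows are supplied, a
#' member only enters a station's denominator if that station was active
#' during its monitoring window (a shark cannot score zero at a receiver
#' that was never listening for it).
#'
#' @param detection_days Output of [to_detection_days()].
#' @param group Character vector of `shark_id`s (a life stage, a sex, or
#'   everyone).
#' @param receivers Optional receiver table (one row per deployment) used
#'   with `summary` to restrict denominators to active stations.
#' @param summary Optional [residency_summary()] giving each member's
#'   monitoring window.
#' @param detected_only If `TRUE`, average over only the members detected at
#'   each station (an alternative reading of group-averaged occupancy).
#' @return Tibble with `station_id`, `mean_detection_days`, `n_sharks`.
#' @export
occupancy <- function(detection_days, group, receivers = NULL,
                      summary = NULL, detected_only = FALSE) {
  if (length(group) == 0) {
    stop_sharknet("occupancy requires a non-empty group of sharks",
                  "sharknet_input_error")
  }
  dd <- filter(detection_days, .data$shark_id %in% group)
  stations <- unique(c(dd$station_id,
                       if (!is.null(receivers)) receivers$station_id))
  counts <- dd %>%
    count(.data$shark_id, .data$station_id, name = "days")
  full <- tidyr::expand_grid(shark_id = group, station_id = stations) %>%
    left_join(counts, by = c("shark_id", "station_id")) %>%
    mutate(days = tidyr::replace_na(.data$days, 0L))
  if (!is.null(receivers) && !is.null(summary)) {
    summary <- filter(summary, .data$shark_id %in% group)
    full <- full %>%
      left_join(select(summary, dplyr::all_of(
        c("shark_id", "first_detection", "last_detection"))),
        by = "shark_id") %>%
      filter(mapply(station_active_for, .data$station_id,
                    .data$first_detection, .data$last_detection,
                    MoreArgs = list(receivers = receivers)))
  }
  if (detected_only) full <- filter(full, .data$days > 0)
  full %>%
    group_by(.data$station_id) %>%
    summarise(mean_detection_days = mean(.data$days),
              n_sharks = dplyr::n(), .groups = "drop")
}

#' Monthly detection-day summary
#'
#' Mean number of detection days per shark in each calendar month, optionally
#' split by a grouping of sharks (life stage or sex). Months are
#' month-of-year, pooled across study years, which is how seasonal patterns
#' (e.g. summer emigration) are usually displayed.
#'
#' @param detection_days Output of [to_detection_days()].
#' @param groups Named list mapping a group label to a character vector of
#'   `shark_id`s; default one group `"all"` containing every shark present.
#' @return Tibble with `group`, `month` (1-12), `mean_detection_days`.
#' @export
monthly_summary <- function(detection_days, groups = NULL) {
  if (is.null(groups)) {
    groups <- list(all = unique(detection_days$shark_id))
  }
  day_dates <- detection_days %>%
    distinct(.data$shark_id, .data$date) %>%
    mutate(month = as.integer(format(.data$date, "%m")))
  out <- lapply(names(groups), function(lbl) {
    members <- groups[[lbl]]
    dd <- filter(day_dates, .data$shark_id %in% members)
    per_shark <- tidyr::expand_grid(shark_id = members, month = 1:12) %>%
      left_join(count(dd, .data$shark_id, .data$month, name = "days"),
                by = c("shark_id", "month")) %>%
      mutate(days = tidyr::replace_na(.data$days, 0L))
    per_shark %>%
      group_by(.data$month) %>%
      summarise(mean_detection_days = mean(.data$days), .groups = "drop") %>%
      mutate(group = lbl)
  })
  bind_rows(out) %>%
    select(dplyr::all_of(c("group", "month", "mean_detection_days")))
}
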