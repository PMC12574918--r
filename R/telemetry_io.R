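# Reading/writing receiver, tag and detection tables in export-like CSV
# dialects, plus the two-rule false-detection filter.

vue_header_map <- c(
  "Date and Time (UTC)" = "timestamp",
  "Receiver" = "station_id",
  "Transmitter" = "tag_id"
)

normalise_headers <- function(df) {
  hit <- names(df) %in% names(vue_header_map)
  names(df)[hit] <- unname(vue_header_map[names(df)[hit]])
  df
}

parse_timestamps <- function(x, what = "detections") {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"),
                   optional = TRUE)
  bad <- which(is.na(ts) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    stop_sharknet(
      sprintf("%s: unparseable timestamp(s) at data row(s) %s (e.g. '%s')",
              what, paste(head(bad, 5), collapse = ", "), x[bad[1]]),
      class = "sharknet_parse_error"
    )
  }
  ts
}

#' Read a receiver-station table
#'
#' Expects columns `station_id`, `array`, `latitude`, `longitude`, `depth_m`,
#' `habitat`, `install_date`, `removal_date` (blank for a still-deployed
#' receiver); one row per deployment, so redeployed stations repeat. Habitat
#' must be one of coral reef, deep wall, sand, seagrass.
#'
#' @param path CSV file path.
#' @return A tibble, one row per deployment, `removal_date` `NA` when open.
#' @export
read_receivers <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE))
  assert_columns(df, c("station_id", "array", "latitude", "longitude",
                       "depth_m", "habitat", "install_date", "removal_date"),
                 sprintf("receiver file '%s'", path))
  df$install_date <- as.Date(df$install_date)
  df$removal_date <- as.Date(ifelse(df$removal_date %in% c("", NA),
                                    NA, df$removal_date))
  bad_hab <- setdiff(unique(df$habitat), habitat_classes())
  if (length(bad_hab) > 0) {
    stop_sharknet(sprintf("unknown habitat class(es): %s",
                          paste(bad_hab, collapse = ", ")),
                  "sharknet_schema_error")
  }
  if (any(df$depth_m < 0 | df$depth_m > 1000)) {
    stop_sharknet("receiver depth_m outside [0, 1000]",
                  "sharknet_schema_error")
  }
  validate_deployments(df)
  arrange(df, .data$array, .data$station_id, .data$install_date)
}

validate_deployments <- function(receivers) {
  by_station <- split(receivers, receivers$station_id)
  for (st in by_station) {
    st <- st[order(st$install_date), ]
    removal <- ifelse(is.na(st$removal_date), as.Date("9999-12-31"),
                      st$removal_date)
    if (any(st$install_date >= removal)) {
      stop_sharknet(sprintf("station %s has install_date >= removal_date",
                            st$station_id[1]), "sharknet_schema_error")
    }
    if (nrow(st) > 1 &&
        any(st$install_date[-1] < removal[-nrow(st)])) {
      stop_sharknet(sprintf("station %s has overlapping deployments",
                            st$station_id[1]), "sharknet_schema_error")
    }
  }
  invisible(receivers)
}

#' Read a tag-deployment table
#'
#' Expects columns `shark_id`, `tag_id`, `tagging_datetime`, `tagging_array`,
#' `fl_tagging_cm`, `sex`, `claspers_calcified`, `min_delay_s`,
#' `max_delay_s`.
#'
#' @param path CSV file path.
#' @return A tibble, one row per tagged shark.
#' @export
read_tags <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE))
  assert_columns(df, c("shark_id", "tag_id", "tagging_datetime",
                       "tagging_array", "fl_tagging_cm", "sex",
                       "claspers_calcified", "min_delay_s", "max_delay_s"),
                 sprintf("tag file '%s'", path))
  df$tagging_datetime <- parse_timestamps(df$tagging_datetime, "tags")
  if (any(df$min_delay_s <= 0 | df$max_delay_s <= 0 |
          df$min_delay_s > df$max_delay_s)) {
    stop_sharknet("tag transmission delays must satisfy 0 < min <= max",
                  "sharknet_schema_error")
  }
  if (any(df$fl_tagging_cm < 50 | df$fl_tagging_cm > 400)) {
    stop_sharknet("fl_tagging_cm outside the 50-400 cm plausibility window",
                  "sharknet_schema_error")
  }
  df
}

#' Read a detection table
#'
#' Accepts either the native dialect (`timestamp`, `tag_id`, `station_id`)
#' or VUE-style headers (`Date and Time (UTC)`, `Receiver`, `Transmitter`).
#' Detections whose `tag_id` is not in `tags` are quarantined with a warning
#' (and optionally written to `quarantine_path`), not silently dropped.
#'
#' @param path CSV file path.
#' @param tags Tag table from [read_tags()] used to recognise tag ids.
#' @param quarantine_path Optional CSV path for unknown-tag rows.
#' @return A tibble of detections sorted by timestamp, tag, station, with
#'   `qc_status = "raw"`; quarantined rows attached as
#'   `attr(, "quarantine")`.
#' @export
read_detections <- function(path, tags, quarantine_path = NULL) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE))
  df <- normalise_headers(df)
  assert_columns(df, c("timestamp", "tag_id", "station_id"),
                 sprintf("detection file '%s'", path))
  df <- select(df, dplyr::all_of(c("timestamp", "tag_id", "station_id")))
  df$timestamp <- parse_timestamps(df$timestamp, "detections")
  unknown <- !(df$tag_id %in% tags$tag_id)
  quarantine <- df[unknown, , drop = FALSE]
  if (any(unknown)) {
    warn(sprintf(
      "%d detection(s) from %d unknown tag id(s) quarantined (e.g. %s)",
      sum(unknown), length(unique(quarantine$tag_id)),
      quarantine$tag_id[1]))
    if (!is.null(quarantine_path)) {
      write.csv(quarantine, quarantine_path, row.names = FALSE)
    }
  }
  df <- df[!unknown, , drop = FALSE]
  df <- arrange(df, .data$timestamp, .data$tag_id, .data$station_id)
  df$qc_status <- "raw"
  attr(df, "quarantine") <- quarantine
  df
}

# sequential rule-A scan within one (tag, station) group; returns logical keep
scan_short_interval <- function(times, min_delay) {
  n <- length(times)
  keep <- logical(n)
  keep[1] <- TRUE
  last_kept <- times[1]
  if (n > 1) {
    for (i in 2:n) {
      if (as.numeric(times[i]) - as.numeric(last_kept) < min_delay) {
        keep[i] <- FALSE
      } else {
        keep[i] <- TRUE
        last_kept <- times[i]
      }
    }
  }
  keep
}

#' Filter false detections
#'
#' Applies the two standard telemetry QC rules. Rule A (impossible interval):
#' a detection closer to the previous retained detection of the same tag at
#' the same station than the tag's minimum transmission delay cannot be a
#' genuine ping and is removed. Rule B (isolated detection): a detection with
#' no other detection of the same tag anywhere in the arrays within
#' `isolation_window_h` is removed. Comparing against the previous
#' *retained* detection stops a burst of spurious records from shielding one
#' another, and makes the filter idempotent.
#'
#' @param detections Detection tibble (`timestamp`, `tag_id`, `station_id`).
#' @param tags Tag table supplying `min_delay_s` per tag.
#' @param isolation_window_h Isolation window for Rule B, hours; default 24.
#'   Use `Inf` to disable Rule B.
#' @param rule_a_scope `"station"` (default) compares same-station pairs
#'   only; `"array"` compares all detections of a tag regardless of station.
#' @return A list: `retained`, `removed` (both with `qc_status` filled in)
#'   and `report` (per-tag removal counts per rule).
#' @export
filter_false_detections <- function(detections, tags,
                                    isolation_window_h = 24,
                                    rule_a_scope = c("station", "array")) {
  rule_a_scope <- match.arg(rule_a_scope)
  assert_columns(detections, c("timestamp", "tag_id", "station_id"),
                 "detections")
  missing_delay <- setdiff(unique(detections$tag_id),
                           tags$tag_id[!is.na(tags$min_delay_s)])
  if (length(missing_delay) > 0) {
    stop_sharknet(
      sprintf("no transmission-delay metadata for tag(s): %s",
              paste(missing_delay, collapse = ", ")),
      class = "sharknet_input_error"
    )
  }
  det <- detections %>%
    left_join(select(tags, dplyr::all_of(c("tag_id", "min_delay_s"))),
              by = "tag_id") %>%
    arrange(.data$timestamp, .data$tag_id, .data$station_id) %>%
    mutate(.row = dplyr::row_number())

  # Rule A
  det$qc_status <- "retained"
  grp_cols <- if (rule_a_scope == "station") c("tag_id", "station_id") else
    "tag_id"
  grp <- interaction(det[grp_cols], drop = TRUE)
  for (g in split(seq_len(nrow(det)), grp)) {
    keep <- scan_short_interval(det$timestamp[g], det$min_delay_s[g[1]])
    det$qc_status[g[!keep]] <- "removed_short_interval"
  }

  # Rule B on survivors of Rule A
  if (is.finite(isolation_window_h)) {
    win <- isolation_window_h * 3600
    alive <- det[det$qc_status == "retained", ]
    for (g in split(seq_len(nrow(alive)), alive$tag_id)) {
      t <- as.numeric(alive$timestamp[g])
      n <- length(t)
      gap_prev <- c(Inf, diff(t))
      gap_next <- c(diff(t), Inf)
      iso <- gap_prev > win & gap_next > win
      det$qc_status[alive$.row[g][iso]] <- "removed_isolated"
    }
  }

  retained <- det[det$qc_status == "retained", ]
  removed <- det[det$qc_status != "retained", ]
  report <- det %>%
    group_by(.data$tag_id) %>%
    summarise(
      n_input = dplyr::n(),
      n_retained = sum(.data$qc_status == "retained"),
      n_removed_short_interval =
        sum(.data$qc_status == "removed_short_interval"),
      n_removed_isolated = sum(.data$qc_status == "removed_isolated"),
      .groups = "drop"
    )
  drop_cols <- function(d) select(d, -dplyr::all_of(c(".row", "min_delay_s")))
  list(retained = drop_cols(retained), removed = drop_cols(removed),
       report = report)
}

#' Write detection / receiver / tag tables
#'
#' Writers are bit-stable: fixed column order, ISO-8601 UTC timestamps, no
#' row names.
#'
#' @param x Table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(x, path) {
  x <- x[order(x$timestamp, x$tag_id, x$station_id), ]
  x$timestamp <- format(x$timestamp, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_receivers <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
write_tags <- function(x, path) {
  x$tagging_datetime <- format(x$tagging_datetime, tz = "UTC",
                               format = "%Y-%m-%d %H:%M:%S")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
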