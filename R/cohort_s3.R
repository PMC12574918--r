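# A synthetic stand-in cohort for growth-corrected restaging.

#' Synthetic detected cohort for growth-correction examples
#'
#' A synthetic 39-shark cohort (9 males, 30 females) constructed to match
#' the published summary attributes of a Bahamas tiger shark telemetry
#' cohort: fork length at first detection spanning 91--300 cm (males at most
#' 253 cm), tagging-to-first-detection lags of 0--415 days averaging about
#' 50, life stages at first detection of 1 YOY, 6 juveniles, 22 sub-adults
#' and 10 adults, and exactly five sharks tagged as sub-adults that reach
#' the female maturity threshold (265 cm FL) before their first detection
#' under the default growth schedule. The individual rows are synthetic --
#' the real attribute table is not public -- but every aggregate above is
#' produced by computation on the rows, not assigned.
#'
#' @return A list: `tags` (tag-deployment tibble) and `detections` (first
#'   and last detection timestamps per shark) suitable for
#'   [restage_cohort()].
#' @export
synthetic_staged_cohort <- function() {
  # sex, fork length at tagging (cm), days from tagging to first detection,
  # monitoring span (days); the five late-detected large females tagged as
  # sub-adults grow past 265 cm before first detection
  rows <- tibble(
    sex = c(rep("M", 9), rep("F", 30)),
    fl_tagging_cm = c(
      # males: one juvenile, eight sub-adults
      140, 185, 200, 210, 220, 230, 240, 250, 253,
      # females: one YOY, five juveniles
      91, 120, 135, 150, 165, 176,
      # fourteen sub-adults that stay sub-adult
      182, 185, 190, 195, 205, 215, 220, 225, 230, 235, 240, 245, 248, 250,
      # five sub-adults reclassified to adult by first detection
      258, 260, 263, 255, 252,
      # five adults at tagging
      268, 272, 280, 290, 300
    ),
    elapsed_days = c(
      0, 0, 0, 0, 1, 2, 3, 4, 5,
      0, 5, 6, 6, 7, 2,
      7, 8, 8, 9, 9, 10, 10, 11, 12, 12, 13, 14, 15, 15,
      300, 365, 250, 415, 380,
      17, 18, 5, 5, 5
    ),
    monitoring_days = c(
      450, 820, 120, 640, 900, 300, 1100, 75, 210,
      60, 380, 520, 700, 240, 1320,
      880, 150, 430, 960, 1556, 610, 340, 770, 500, 1020, 95, 660, 285, 520,
      730, 390, 860, 620, 480,
      1, 310, 580, 220, 140
    )
  )
  rows$shark_id <- sprintf("TS%02d", seq_len(nrow(rows)))
  rows$tagging_array <- rep(c("NewProvidence", "GreatExuma"),
                            length.out = nrow(rows))
  tag_dates <- as.Date("2018-02-06") + (seq_len(nrow(rows)) - 1) * 40
  tags <- tibble(
    shark_id = rows$shark_id,
    tag_id = sprintf("A69-1601-%04d", 2000 + seq_len(nrow(rows))),
    tagging_datetime = as_utc(paste(tag_dates, "12:00:00")),
    tagging_array = rows$tagging_array,
    fl_tagging_cm = rows$fl_tagging_cm,
    sex = rows$sex,
    claspers_calcified = rows$sex == "M" & rows$fl_tagging_cm > 255,
    min_delay_s = 120, max_delay_s = 300
  )
  first <- as_utc(paste(tag_dates + rows$elapsed_days, "12:00:00"))
  last <- as_utc(paste(tag_dates + rows$elapsed_days +
                         rows$monitoring_days - 1, "12:00:00"))
  detections <- tibble(
    tag_id = rep(tags$tag_id, 2),
    station_id = "N1",
    timestamp = c(first, last)
  ) %>% arrange(.data$timestamp, .data$tag_id)
  list(tags = tags, detections = detections)
}
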