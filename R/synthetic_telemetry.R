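# Synthetic acoustic-telemetry generator: receiver arrays, shark cohorts,
# ground-truth continuous-time movement trajectories, and detection streams
# with configurable imperfect detection and injected false detections.

#' Simulation configuration
#'
#' Parameters of the synthetic telemetry study. Defaults emulate a two-array
#' Bahamas-style deployment: 18 + 14 stations across New Providence and
#' Great Exuma with coral reef / deep wall / sand / seagrass habitats in
#' 9:6:3:14 proportion, receivers installed on a staggered schedule from
#' February 2018, a cohort of 46 sharks of 91--300 cm fork length tagged
#' 2018--2022 (three-quarters female), and V16-style transmitters.
#'
#' Movement is a continuous-time Markov chain over stations plus an
#' off-array state. While at a station a shark relocates directly to another
#' station at the motility rate (transitions/day, a function of fork length
#' and sex) with distance-decayed target preference, or leaves the array;
#' after an off-array excursion it returns to the station it left, so
#' station-to-station transitions are governed purely by the motility
#' effect. The male effect is linear in fork length; the female effect is a
#' Gaussian bump peaking by default at 237.5 cm (the middle of the published
#' 225--250 cm high-motility band). Off-array excursions lengthen in summer
#' months, thinning summer detection days. Fork length grows along the
#' growth schedule during the track, so life stage can change mid-record.
#'
#' @param seed Integer RNG seed.
#' @param n_stations_per_array Named integer vector, stations per array.
#' @param habitat_proportions Proportions over the four habitat classes.
#' @param deploy_start,deploy_end Receiver installation window.
#' @param late_install_frac Fraction of stations installed after the first
#'   18 months of the window (staggered deployment).
#' @param removal_frac Fraction of stations removed before study end.
#' @param study_end Last simulated day.
#' @param tagging_start,tagging_end Shark tagging window.
#' @param cohort_size Number of tagged sharks.
#' @param fl_range_cm Fork-length range at tagging.
#' @param fl_mean_cm,fl_sd_cm Truncated-normal tagging-length distribution.
#' @param sex_ratio_female Proportion of females.
#' @param prob_never_detected Probability a tagged shark permanently leaves
#'   before ever reaching a receiver (tagged-but-never-detected animals).
#' @param male_rate_min,male_rate_max Male motility rate (moves/day) at the
#'   ends of `fl_range_cm` (linear in FL).
#' @param female_rate_base,female_rate_amplitude,female_peak_fl_cm,female_sd_fl_cm
#'   Female Gaussian motility effect: base + amplitude at the peak.
#' @param off_rate_per_day Rate of leaving the array from a station.
#' @param off_mean_days Mean off-array excursion length (days).
#' @param summer_absence_factor Multiplier on excursion length in
#'   `summer_months`.
#' @param summer_months Months treated as summer.
#' @param distance_decay_km Length scale of the move-target kernel.
#' @param cross_array_prob Probability a move targets the other array.
#' @param detection_prob Per-ping detection probability at a deployed
#'   station.
#' @param ping_delay_s Nominal (min, max) transmission delay, seconds.
#' @param false_detection_rate Expected spurious detections per tag-day.
#' @param growth A [growth_schedule()].
#' @param tz Reporting timezone for derived dates.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_stations_per_array = c(NewProvidence = 18,
                                                GreatExuma = 14),
                       habitat_proportions = c("coral reef" = 9 / 32,
                                               "deep wall" = 6 / 32,
                                               "sand" = 3 / 32,
                                               "seagrass" = 14 / 32),
                       deploy_start = "2018-02-01",
                       deploy_end = "2022-07-31",
                       late_install_frac = 0.25,
                       removal_frac = 0.15,
                       study_end = "2023-06-30",
                       tagging_start = "2018-02-06",
                       tagging_end = "2022-05-30",
                       cohort_size = 46,
                       fl_range_cm = c(91, 300),
                       fl_mean_cm = 215, fl_sd_cm = 45,
                       sex_ratio_female = 0.75,
                       prob_never_detected = 0.15,
                       male_rate_min = 0.1, male_rate_max = 1,
                       female_rate_base = 0.1,
                       female_rate_amplitude = 0.9,
                       female_peak_fl_cm = 237.5,
                       female_sd_fl_cm = 35,
                       off_rate_per_day = 2,
                       off_mean_days = 3,
                       summer_absence_factor = 2,
                       summer_months = 6:9,
                       distance_decay_km = 10,
                       cross_array_prob = 0.002,
                       detection_prob = 0.5,
                       ping_delay_s = c(120, 300),
                       false_detection_rate = 0.05,
                       growth = default_growth_schedule(),
                       tz = "UTC") {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$n_stations_per_array) != 2 ||
      any(cfg$n_stations_per_array < 1)) {
    stop_sharknet("n_stations_per_array must give two positive counts",
                  "sharknet_config_error")
  }
  if (length(cfg$fl_range_cm) != 2 ||
      cfg$fl_range_cm[1] >= cfg$fl_range_cm[2]) {
    stop_sharknet("fl_range_cm must satisfy min < max",
                  "sharknet_config_error")
  }
  for (p in c("sex_ratio_female", "detection_prob", "prob_never_detected",
              "late_install_frac", "removal_frac", "cross_array_prob")) {
    assert_scalar_number(cfg[[p]], p, 0, 1)
  }
  if (length(cfg$ping_delay_s) != 2 || any(cfg$ping_delay_s <= 0) ||
      cfg$ping_delay_s[1] > cfg$ping_delay_s[2]) {
    stop_sharknet("ping_delay_s must satisfy 0 < min <= max",
                  "sharknet_config_error")
  }
  assert_scalar_number(cfg$false_detection_rate, "false_detection_rate", 0)
  assert_scalar_number(cfg$cohort_size, "cohort_size", 1)
  for (p in c("male_rate_min", "male_rate_max", "female_rate_base",
              "female_rate_amplitude", "off_rate_per_day", "off_mean_days",
              "distance_decay_km")) {
    assert_scalar_number(cfg[[p]], p, 0)
  }
  invisible(cfg)
}

# true station-to-station transition rate (moves/day) given FL and sex
motility_rate <- function(fl, sex, cfg) {
  lo <- cfg$fl_range_cm[1]
  hi <- cfg$fl_range_cm[2]
  ifelse(sex == "M",
         cfg$male_rate_min + (cfg$male_rate_max - cfg$male_rate_min) *
           pmin(1, pmax(0, (fl - lo) / (hi - lo))),
         cfg$female_rate_base + cfg$female_rate_amplitude *
           exp(-(fl - cfg$female_peak_fl_cm)^2 /
                 (2 * cfg$female_sd_fl_cm^2)))
}

array_centres <- function() {
  tibble(array = c("NewProvidence", "GreatExuma"),
         lat = c(25.03, 23.50), lon = c(-77.40, -75.80))
}

#' Simulate a receiver array
#'
#' Generates station positions, habitats, depths and staggered deployment
#' windows for the configured arrays. The first station of each array is
#' installed on day one and never removed, so each array has at least one
#' active station on every simulated day.
#'
#' @param config A [sim_config()].
#' @return Receiver tibble (one row per deployment) in the dialect
#'   [read_receivers()] produces.
#' @export
simulate_array <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  centres <- array_centres()
  arrays <- names(config$n_stations_per_array)
  if (is.null(arrays)) arrays <- centres$array
  prefixes <- c("N", "E")
  out <- list()
  for (i in seq_along(arrays)) {
    n <- config$n_stations_per_array[i]
    ctr <- centres[match(arrays[i], centres$array), ]
    if (nrow(ctr) == 0 || is.na(ctr$lat[1])) ctr <- centres[i, ]
    hab_n <- floor(config$habitat_proportions * n)
    rem <- n - sum(hab_n)
    if (rem > 0) {
      top_up <- order(config$habitat_proportions * n - hab_n,
                      decreasing = TRUE)[seq_len(rem)]
      hab_n[top_up] <- hab_n[top_up] + 1
    }
    habitat <- sample(rep(names(hab_n), hab_n))
    depth <- round(ifelse(
      habitat == "deep wall", runif(n, 60, 207),
      ifelse(habitat == "coral reef", runif(n, 5, 30),
             ifelse(habitat == "sand", runif(n, 3, 20), runif(n, 2, 12)))))
    d0 <- as.Date(config$deploy_start)
    d1 <- as.Date(config$deploy_end)
    early_span <- min(540, as.integer(d1 - d0))
    late <- runif(n) < config$late_install_frac
    install <- d0 + ifelse(late,
                           sample.int(max(1, as.integer(d1 - d0)), n,
                                      replace = TRUE),
                           sample.int(max(1, early_span), n, replace = TRUE))
    install[1] <- d0
    removed <- runif(n) < config$removal_frac
    removed[1] <- FALSE
    removal <- as.Date(rep(NA, n))
    span <- as.integer(as.Date(config$study_end) - install)
    pick <- which(removed & span > 400)
    removal[pick] <- install[pick] + 365 +
      vapply(span[pick] - 400, function(s) sample.int(max(1, s), 1),
             integer(1))
    out[[i]] <- tibble(
      station_id = sprintf("%s%d", prefixes[i], seq_len(n)),
      array = arrays[i],
      latitude = round(ctr$lat[1] + runif(n, -0.15, 0.15), 5),
      longitude = round(ctr$lon[1] + runif(n, -0.15, 0.15), 5),
      depth_m = depth,
      habitat = habitat,
      install_date = install,
      removal_date = removal
    )
  }
  bind_rows(out)
}

# distance-decayed move-target weight matrix between stations
move_kernel <- function(stations, cfg) {
  st <- distinct(stations, .data$station_id, .data$array, .data$latitude,
                 .data$longitude)
  n <- nrow(st)
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(st$latitude[i], st$longitude[i],
                 st$latitude[j], st$longitude[j]))
  w <- exp(-d / cfg$distance_decay_km)
  same <- outer(st$array, st$array, "==")
  w[!same] <- cfg$cross_array_prob
  diag(w) <- 0
  rownames(w) <- colnames(w) <- st$station_id
  list(stations = st, weights = w)
}

# month of a fractional day offset from an origin date
month_of <- function(origin, day_offset) {
  as.integer(format(origin + floor(day_offset), "%m"))
}

simulate_track <- function(shark, stations, kernel, cfg, study_end_day) {
  # event-by-event CTMC: states are stations plus "off"; times in days
  # since tagging
  st <- kernel$stations
  visits <- list()
  t <- 0
  fl <- shark$fl_tagging_cm
  fl_t <- 0
  home <- which(st$array == shark$tagging_array)
  if (length(home) == 0) home <- seq_len(nrow(st))
  cur <- sample(home, 1)
  origin <- as.Date(shark$tagging_datetime)
  n_moves <- 0
  while (t < study_end_day) {
    # grow fork length to the current event time
    dt_days <- t - fl_t
    if (dt_days > 0) {
      fl <- fl + growth_rate_at(fl, cfg$growth) * dt_days / 365.25
      fl_t <- t
    }
    lambda <- motility_rate(fl, shark$sex, cfg)
    total <- lambda + cfg$off_rate_per_day
    stay <- rexp(1, max(total, 1e-9))
    leave_t <- min(t + stay, study_end_day)
    visits[[length(visits) + 1]] <-
      list(station = st$station_id[cur], enter = t, exit = leave_t)
    if (leave_t >= study_end_day) break
    t <- leave_t
    if (runif(1) < lambda / total && nrow(st) > 1) {
      # direct relocation to another station
      w <- kernel$weights[cur, ]
      cur <- sample.int(nrow(st), 1, prob = w)
      n_moves <- n_moves + 1
    } else {
      # off-array excursion; longer in summer; returns to the same station
      fac <- if (month_of(origin, t) %in% cfg$summer_months)
        cfg$summer_absence_factor else 1
      t <- t + rexp(1, 1 / (cfg$off_mean_days * fac))
    }
  }
  vis <- bind_rows(lapply(visits, as_tibble))
  tibble(
    shark_id = shark$shark_id,
    station_id = vis$station,
    enter = as_utc(shark$tagging_datetime) + vis$enter * 86400,
    exit = as_utc(shark$tagging_datetime) + vis$exit * 86400
  )
}

#' Simulate a tagged cohort and its true movement tracks
#'
#' Draws a cohort (sex, fork length at tagging, tagging date and array) and
#' simulates each shark's continuous-time trajectory over the stations from
#' tagging to study end. The returned truth records carry the exact station
#' visit intervals and per-shark true transition counts, against which the
#' detection-based pipeline can be validated.
#'
#' @param config A [sim_config()].
#' @param stations Receiver tibble from [simulate_array()].
#' @return A list: `tags` (tag-deployment tibble) and `truth` (a list with
#'   `visits`: shark/station/enter/exit intervals, and `summary`: per-shark
#'   true transition counts and rates).
#' @export
simulate_cohort_and_tracks <- function(config, stations) {
  validate_sim_config(config)
  if (nrow(stations) < 2) {
    stop_sharknet("movement simulation needs at least two stations",
                  "sharknet_config_error")
  }
  set.seed(config$seed + 1L)
  n <- config$cohort_size
  t0 <- as.Date(config$tagging_start)
  t1 <- as.Date(config$tagging_end)
  arrays <- unique(stations$array)
  fl <- rnorm(n, config$fl_mean_cm, config$fl_sd_cm)
  fl <- pmin(pmax(fl, config$fl_range_cm[1]), config$fl_range_cm[2])
  tags <- tibble(
    shark_id = sprintf("SH%02d", seq_len(n)),
    tag_id = sprintf("A69-1601-%04d", 1000 + seq_len(n)),
    tagging_datetime = as_utc(paste(
      t0 + sample.int(max(1, as.integer(t1 - t0)), n, replace = TRUE),
      "12:00:00")),
    tagging_array = sample(arrays, n, replace = TRUE),
    fl_tagging_cm = round(fl),
    sex = ifelse(runif(n) < config$sex_ratio_female, "F", "M"),
    min_delay_s = config$ping_delay_s[1],
    max_delay_s = config$ping_delay_s[2]
  )
  tags$claspers_calcified <- tags$sex == "M" &
    tags$fl_tagging_cm > life_stage_scheme()$adult_min_fl_male

  kernel <- move_kernel(stations, config)
  study_end <- as.Date(config$study_end)
  gone <- runif(n) < config$prob_never_detected
  visits <- list()
  for (i in seq_len(n)) {
    if (gone[i]) next
    horizon <- as.numeric(study_end - as.Date(tags$tagging_datetime[i]))
    if (horizon <= 0) next
    visits[[length(visits) + 1]] <-
      simulate_track(tags[i, ], stations, kernel, config, horizon)
  }
  visits <- if (length(visits) > 0) bind_rows(visits) else
    tibble(shark_id = character(), station_id = character(),
           enter = as_utc(character()), exit = as_utc(character()))
  truth_summary <- visits %>%
    group_by(.data$shark_id) %>%
    summarise(
      n_visits = dplyr::n(),
      n_transitions = sum(.data$station_id !=
                            dplyr::lag(.data$station_id),
                          na.rm = TRUE),
      n_stations_visited = dplyr::n_distinct(.data$station_id),
      .groups = "drop"
    ) %>%
    left_join(select(tags, dplyr::all_of(c("shark_id", "sex",
                                           "fl_tagging_cm"))),
              by = "shark_id") %>%
    mutate(true_rate_at_tagging =
             motility_rate(.data$fl_tagging_cm, .data$sex, config))
  list(tags = tags,
       truth = list(visits = visits, summary = truth_summary,
                    never_detected = tags$shark_id[gone]))
}

# deployment intervals per station as a lookup list
deployment_lookup <- function(stations) {
  split(stations[c("install_date", "removal_date")], stations$station_id)
}

#' Emit a detection stream from truth tracks
#'
#' For every station visit, transmitter pings at uniform-random delays are
#' heard with probability `detection_prob` while the station is within a
#' deployment interval. False detections are injected in the two classes the
#' QC filter targets: impossible short-interval duplicates (a copy of a true
#' detection offset by less than the minimum transmission delay) and
#' isolated singletons at random stations and times. A truth flag and class
#' label are retained for testing only.
#'
#' @param truth Truth list from [simulate_cohort_and_tracks()].
#' @param stations Receiver tibble.
#' @param tags Tag tibble (transmission delays and tag ids).
#' @param config A [sim_config()].
#' @return Detection tibble sorted by timestamp with `timestamp`, `tag_id`,
#'   `station_id`, `is_false`, `false_class`.
#' @export
emit_detections <- function(truth, stations, tags, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  visits <- truth$visits
  if (nrow(visits) == 0) {
    stop_sharknet("truth records contain no station visits",
                  "sharknet_input_error")
  }
  dmin <- config$ping_delay_s[1]
  dmax <- config$ping_delay_s[2]
  tag_of <- setNames(tags$tag_id, tags$shark_id)
  dep <- deployment_lookup(stations)

  ping_rows <- vector("list", nrow(visits))
  for (i in seq_len(nrow(visits))) {
    dur <- as.numeric(visits$exit[i]) - as.numeric(visits$enter[i])
    if (dur <= 0) next
    n_max <- ceiling(dur / dmin) + 1
    if (n_max > 1e6) n_max <- 1e6
    # first ping lands inside the visit (delay clock mid-cycle on arrival)
    delays <- c(runif(1, 0, min(dmax, dur)), runif(n_max - 1, dmin, dmax))
    t <- as.numeric(visits$enter[i]) + cumsum(delays)
    t <- t[t <= as.numeric(visits$exit[i])]
    if (length(t) == 0) next
    ping_rows[[i]] <- tibble(
      timestamp_num = t,
      shark_id = visits$shark_id[i],
      station_id = visits$station_id[i]
    )
  }
  pings <- bind_rows(ping_rows)
  det <- tibble()
  if (nrow(pings) > 0) {
    heard <- runif(nrow(pings)) < config$detection_prob
    pings <- pings[heard, , drop = FALSE]
    # keep only pings inside a deployment interval of the station
    keep <- logical(nrow(pings))
    d <- as.Date(as.POSIXct(pings$timestamp_num, origin = "1970-01-01",
                            tz = "UTC"))
    for (st in unique(pings$station_id)) {
      idx <- pings$station_id == st
      ivals <- dep[[st]]
      if (is.null(ivals)) next
      removal <- ivals$removal_date
      removal[is.na(removal)] <- as.Date("9999-12-31")
      ok <- rep(FALSE, sum(idx))
      for (k in seq_len(nrow(ivals))) {
        ok <- ok | (d[idx] >= ivals$install_date[k] &
                      d[idx] <= removal[k])
      }
      keep[idx] <- ok
    }
    pings <- pings[keep, , drop = FALSE]
    det <- tibble(
      timestamp = as.POSIXct(pings$timestamp_num, origin = "1970-01-01",
                             tz = "UTC"),
      tag_id = unname(tag_of[pings$shark_id]),
      station_id = pings$station_id,
      is_false = FALSE, false_class = "none"
    )
  }

  # injected false detections
  if (config$false_detection_rate > 0) {
    fd <- list()
    all_stations <- unique(stations$station_id)
    study_end <- as_utc(paste(config$study_end, "00:00:00"))
    for (sh in unique(visits$shark_id)) {
      tg <- tag_of[[sh]]
      t_tag <- min(visits$enter[visits$shark_id == sh])
      days <- as.numeric(study_end - t_tag, units = "days")
      n_false <- rpois(1, config$false_detection_rate * max(days, 0))
      if (n_false == 0) next
      n_short <- rbinom(1, n_false, 0.5)
      mine <- det[det$tag_id == tg, , drop = FALSE]
      if (n_short > 0 && nrow(mine) > 0) {
        src <- mine[sample.int(nrow(mine), n_short, replace = TRUE), ]
        fd[[length(fd) + 1]] <- tibble(
          timestamp = src$timestamp + runif(n_short, 0.05, 0.45) * dmin,
          tag_id = tg, station_id = src$station_id,
          is_false = TRUE, false_class = "short_interval"
        )
      }
      n_iso <- n_false - if (nrow(mine) > 0) n_short else 0
      if (n_iso > 0) {
        fd[[length(fd) + 1]] <- tibble(
          timestamp = t_tag + runif(n_iso, 0, max(days, 1) * 86400),
          tag_id = tg,
          station_id = sample(all_stations, n_iso, replace = TRUE),
          is_false = TRUE, false_class = "isolated"
        )
      }
    }
    det <- bind_rows(det, bind_rows(fd))
  }
  arrange(det, .data$timestamp, .data$tag_id, .data$station_id)
}

#' Run the full synthetic telemetry generator
#'
#' Convenience wrapper: array, cohort, tracks, detections.
#'
#' @param config A [sim_config()].
#' @return A list: `stations`, `tags`, `truth`, `detections`.
#' @export
simulate_telemetry <- function(config = sim_config()) {
  stations <- simulate_array(config)
  ct <- simulate_cohort_and_tracks(config, stations)
  detections <- emit_detections(ct$truth, stations, ct$tags, config)
  list(stations = stations, tags = ct$tags, truth = ct$truth,
       detections = detections)
}

#' Write a simulated data set as CSV files
#'
#' Emits the same dialects the readers consume: `receivers.csv`,
#' `tags.csv`, `detections.csv` plus `truth_visits.csv`.
#'
#' @param sim Output of [simulate_telemetry()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_receivers(sim$stations, file.path(dir, "receivers.csv"))
  write_tags(sim$tags, file.path(dir, "tags.csv"))
  write_detections(
    select(sim$detections,
           dplyr::all_of(c("timestamp", "tag_id", "station_id"))),
    file.path(dir, "detections.csv"))
  tv <- sim$truth$visits
  tv$enter <- format(tv$enter, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  tv$exit <- format(tv$exit, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  write.csv(tv, file.path(dir, "truth_visits.csv"), row.names = FALSE)
  invisible(dir)
}
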