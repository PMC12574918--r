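test_that("simulated arrays honour the configured geometry", {
  cfg <- sim_config(seed = 4)
  st <- simulate_array(cfg)
  expect_equal(nrow(st), 32)
  expect_equal(sum(st$array == "NewProvidence"), 18)
  expect_equal(sum(st$array == "GreatExuma"), 14)
  expect_false(any(duplicated(st$station_id)))
  expect_true(all(st$habitat %in% c("coral reef", "deep wall", "sand",
                                    "seagrass")))
  expect_true(all(st$depth_m >= 2 & st$depth_m <= 207))
  # the anchor station of each array spans the whole study
  expect_true(all(is.na(st$removal_date[st$station_id %in% c("N1", "E1")])))
  # degenerate two-station config still simulates
  st2 <- simulate_array(sim_config(
    seed = 4, n_stations_per_array = c(A = 1, B = 1)))
  expect_equal(nrow(st2), 2)
  # determinism: same seed, identical table
  expect_identical(simulate_array(cfg), simulate_array(cfg))
  # invalid configuration errors name the offending field
  expect_error(sim_config(detection_prob = 1.4), "detection_prob",
               class = "sharknet_config_error")
  expect_error(sim_config(ping_delay_s = c(300, 100)), "ping_delay_s",
               class = "sharknet_config_error")
  expect_error(sim_config(fl_range_cm = c(300, 91)), "fl_range_cm",
               class = "sharknet_config_error")
})

test_that("zero motility pins every shark to a single station", {
  cfg <- small_sim_config(seed = 6, n_sharks = 5,
                          male_rate_min = 0, male_rate_max = 0,
                          female_rate_base = 0, female_rate_amplitude = 0)
  st <- simulate_array(cfg)
  ct <- simulate_cohort_and_tracks(cfg, st)
  per_shark <- tapply(ct$truth$visits$station_id, ct$truth$visits$shark_id,
                      function(x) length(unique(x)))
  expect_true(all(per_shark == 1))
  expect_true(all(ct$truth$summary$n_transitions == 0))
})

test_that("male transition counts increase with fork length", {
  for (sd in c(101, 102, 103)) {
    cfg <- small_sim_config(seed = sd, n_sharks = 30,
                            sex_ratio_female = 0,
                            fl_mean_cm = 200, fl_sd_cm = 70)
    st <- simulate_array(cfg)
    ct <- simulate_cohort_and_tracks(cfg, st)
    s <- ct$truth$summary
    expect_gt(cor(s$fl_tagging_cm, s$n_transitions, method = "spearman"), 0)
  }
})

test_that("trajectories are time-ordered and reproducible", {
  cfg <- small_sim_config(seed = 13, n_sharks = 6)
  st <- simulate_array(cfg)
  ct <- simulate_cohort_and_tracks(cfg, st)
  v <- ct$truth$visits
  for (sh in unique(v$shark_id)) {
    mine <- v[v$shark_id == sh, ]
    expect_true(all(diff(as.numeric(mine$enter)) > 0))
    expect_true(all(mine$exit >= mine$enter))
  }
  # same seed: byte-identical truth; different seed: something differs
  ct2 <- simulate_cohort_and_tracks(cfg, st)
  expect_identical(ct$truth$visits, ct2$truth$visits)
  cfg2 <- small_sim_config(seed = 14, n_sharks = 6)
  ct3 <- simulate_cohort_and_tracks(cfg2, simulate_array(cfg2))
  expect_false(identical(ct$truth$visits, ct3$truth$visits))
  # movement with fewer than two stations is a configuration error
  expect_error(simulate_cohort_and_tracks(cfg, st[0, ]),
               class = "sharknet_config_error")
})

test_that("perfect detection reproduces the truth; zero detection leaves only noise", {
  cfg <- sim_config(seed = 23, cohort_size = 6,
                    n_stations_per_array = c(NewProvidence = 5,
                                             GreatExuma = 4),
                    deploy_start = "2018-01-01", deploy_end = "2018-01-02",
                    late_install_frac = 0, removal_frac = 0,
                    tagging_start = "2018-02-06",
                    tagging_end = "2018-03-15",
                    study_end = "2018-05-01", prob_never_detected = 0,
                    detection_prob = 1, false_detection_rate = 0,
                    off_rate_per_day = 0.2,
                    male_rate_min = 0.05, male_rate_max = 0.3,
                    female_rate_base = 0.05,
                    female_rate_amplitude = 0.25,
                    ping_delay_s = c(60, 120))
  sim <- simulate_telemetry(cfg)
  expect_true(all(!sim$detections$is_false))
  # detections never precede tagging
  tag_time <- stats::setNames(sim$tags$tagging_datetime, sim$tags$tag_id)
  expect_true(all(sim$detections$timestamp >=
                    tag_time[sim$detections$tag_id]))
  # every detection lies inside a deployment window of its station
  inst <- stats::setNames(sim$stations$install_date,
                          sim$stations$station_id)
  expect_true(all(as.Date(sim$detections$timestamp) >=
                    inst[sim$detections$station_id]))
  # the pipeline reconstructs the per-shark visited set and movement count
  qc <- filter_false_detections(
    dplyr::select(sim$detections, timestamp, tag_id, station_id),
    sim$tags, isolation_window_h = Inf)
  expect_equal(nrow(qc$removed), 0)
  dd <- to_detection_days(qc$retained, sim$tags)
  rs <- residency_summary(dd)
  total_moves <- 0
  for (i in seq_len(nrow(rs))) {
    sh <- rs$shark_id[i]
    act <- dplyr::distinct(sim$stations, station_id, array)
    nets <- build_network(qc$retained, sim$tags, sh, act)
    visited <- unique(unlist(lapply(nets$networks, function(x) x$visited)))
    truth_visited <- unique(
      sim$truth$visits$station_id[sim$truth$visits$shark_id == sh])
    expect_setequal(visited, truth_visited)
    total_moves <- total_moves + sum(vapply(nets$networks,
                                            function(x) x$n_movements,
                                            numeric(1))) +
      nrow(nets$inter_array)
  }
  expect_equal(total_moves, sum(sim$truth$summary$n_transitions))

  # with detection_prob 0 only injected false detections remain
  cfg0 <- small_sim_config(seed = 23, n_sharks = 3, detection_prob = 0,
                           false_detection_rate = 0.2)
  sim0 <- simulate_telemetry(cfg0)
  expect_true(all(sim0$detections$is_false))
})

test_that("injected short-interval duplicates are always caught by the filter", {
  cfg <- small_sim_config(seed = 29, n_sharks = 5,
                          false_detection_rate = 0.5)
  sim <- simulate_telemetry(cfg)
  qc <- filter_false_detections(
    dplyr::select(sim$detections, timestamp, tag_id, station_id), sim$tags)
  injected <- sim$detections[sim$detections$false_class == "short_interval", ]
  expect_gt(nrow(injected), 0)
  removed <- qc$removed[qc$removed$qc_status == "removed_short_interval", ]
  key <- function(d) paste(format(d$timestamp, "%Y%m%d%H%M%OS6"), d$tag_id,
                           d$station_id)
  expect_true(all(key(injected) %in% key(removed)))
})

test_that("the detection stream is seed-deterministic and seed-sensitive", {
  cfg <- small_sim_config(seed = 37, n_sharks = 5)
  expect_identical(simulate_telemetry(cfg)$detections,
                   simulate_telemetry(cfg)$detections)
  other <- simulate_telemetry(small_sim_config(seed = 38, n_sharks = 5))
  expect_false(identical(simulate_telemetry(cfg)$detections,
                         other$detections))
})
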