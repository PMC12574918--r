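test_that("receiver/tag/detection CSVs round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 3)
  stations <- simulate_array(cfg)
  expect_equal(nrow(stations), 32)
  expect_equal(sort(as.integer(table(stations$habitat)[
    c("coral reef", "deep wall", "sand", "seagrass")])), sort(c(9, 6, 3, 14)))
  write_receivers(stations, file.path(dir, "r.csv"))
  back <- read_receivers(file.path(dir, "r.csv"))
  expect_equal(nrow(back), 32)
  expect_equal(sort(back$station_id), sort(stations$station_id))

  tags <- tiny_tags(c("S1", "S2"))
  write_tags(tags, file.path(dir, "t.csv"))
  tags2 <- read_tags(file.path(dir, "t.csv"))
  expect_equal(tags2$tag_id, tags$tag_id)
  expect_equal(tags2$tagging_datetime, tags$tagging_datetime)

  det <- det_at(c(0, 100, 200), tag = "TS1")
  write_detections(det, file.path(dir, "d.csv"))
  det2 <- read_detections(file.path(dir, "d.csv"), tags)
  expect_equal(nrow(det2), 3)
  expect_equal(det2$timestamp, det$timestamp)
  expect_true(all(det2$qc_status == "raw"))
})

test_that("reader errors and quarantine behave as documented", {
  dir <- withr::local_tempdir()
  tags <- tiny_tags("S1")
  # empty detections file with a valid header parses to an empty table
  writeLines("timestamp,tag_id,station_id", file.path(dir, "empty.csv"))
  expect_equal(nrow(read_detections(file.path(dir, "empty.csv"), tags)), 0)
  # VUE-style headers are accepted
  writeLines(c("Date and Time (UTC),Receiver,Transmitter",
               "2018-03-01 00:00:00,N1,TS1"), file.path(dir, "vue.csv"))
  vue <- read_detections(file.path(dir, "vue.csv"), tags)
  expect_equal(vue$station_id, "N1")
  # unknown tag ids are quarantined with a warning, not kept
  writeLines(c("timestamp,tag_id,station_id",
               "2018-03-01 00:00:00,TS1,N1",
               "2018-03-01 00:01:00,GHOST,N1"), file.path(dir, "mix.csv"))
  expect_warning(mix <- read_detections(file.path(dir, "mix.csv"), tags,
                                        file.path(dir, "q.csv")),
                 "quarantined")
  expect_equal(nrow(mix), 1)
  expect_equal(nrow(attr(mix, "quarantine")), 1)
  expect_true(file.exists(file.path(dir, "q.csv")))
  # missing column and unparseable timestamp raise named errors
  writeLines("timestamp,tag_id", file.path(dir, "short.csv"))
  expect_error(read_detections(file.path(dir, "short.csv"), tags),
               "station_id", class = "sharknet_schema_error")
  writeLines(c("timestamp,tag_id,station_id", "not-a-time,TS1,N1"),
             file.path(dir, "bad.csv"))
  expect_error(read_detections(file.path(dir, "bad.csv"), tags),
               "row", class = "sharknet_parse_error")
})

test_that("rule A removes impossible short intervals against retained pings", {
  tags <- tiny_tags("S1", min_delay = 60)
  # 0 and 30 s at one station: second is impossible
  out <- filter_false_detections(det_at(c(0, 30)), tags,
                                 isolation_window_h = Inf)
  expect_equal(nrow(out$retained), 1)
  expect_equal(out$removed$qc_status, "removed_short_interval")
  # a burst cannot shield itself: 0, 30, 70 keeps 0 and 70
  out <- filter_false_detections(det_at(c(0, 30, 70)), tags,
                                 isolation_window_h = Inf)
  expect_equal(as.numeric(out$retained$timestamp) -
                 as.numeric(out$retained$timestamp[1]), c(0, 70))
  # two detections an hour apart are both genuine
  out <- filter_false_detections(det_at(c(0, 3600)), tags)
  expect_equal(nrow(out$retained), 2)
})

test_that("rule B removes detections isolated beyond the window", {
  tags <- tiny_tags("S1", min_delay = 60)
  d <- dplyr::bind_rows(
    det_at(c(0, 3600)),
    det_at(50 * 3600, station = "N2"))  # lone ping 50 h later
  out <- filter_false_detections(d, tags)
  expect_equal(out$removed$qc_status, "removed_isolated")
  expect_equal(out$removed$station_id, "N2")
  # window is configurable; Inf disables rule B
  out <- filter_false_detections(d, tags, isolation_window_h = Inf)
  expect_equal(nrow(out$retained), 3)
  # a shark without delay metadata is an error listing the tag
  expect_error(filter_false_detections(det_at(0, tag = "NOPE"), tags),
               "NOPE", class = "sharknet_input_error")
})

test_that("the filter matches a brute-force oracle and is idempotent", {
  tags <- tiny_tags("S1", min_delay = 90)
  set.seed(21)
  for (case in 1:50) {
    n <- sample(3:14, 1)
    # mix of plausible gaps, impossible bursts, and far-flung strays
    offs <- sort(c(cumsum(runif(n, 10, 7200)),
                   if (runif(1) < 0.5) 90 * 3600 + runif(1, 0, 3600)))
    d <- det_at(offs, station = sample(c("N1", "N2"), length(offs),
                                       replace = TRUE))
    got <- filter_false_detections(d, tags)
    want <- brute_filter(d, 90)
    got_all <- dplyr::arrange(dplyr::bind_rows(got$retained, got$removed),
                              timestamp, station_id)
    want <- dplyr::arrange(want, timestamp, station_id)
    expect_equal(got_all$qc_status, want$status)
    # removal counts partition the input
    expect_equal(nrow(got$retained) + nrow(got$removed), nrow(d))
    expect_equal(sum(got$report$n_removed_short_interval) +
                   sum(got$report$n_removed_isolated), nrow(got$removed))
    # idempotence on the retained set
    again <- filter_false_detections(got$retained, tags)
    expect_equal(nrow(again$removed), 0)
    # no retained same-station pair is closer than the minimum delay
    for (st in unique(got$retained$station_id)) {
      tt <- sort(as.numeric(got$retained$timestamp[
        got$retained$station_id == st]))
      if (length(tt) > 1) expect_true(all(diff(tt) >= 90))
    }
  }
})
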