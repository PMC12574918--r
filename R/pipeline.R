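# End-to-end orchestration: simulate (or read) -> QC -> residency ->
# growth staging -> networks/motility -> model selection.

#' Pipeline run configuration
#'
#' Either a `simulate` block (a [sim_config()]) or input CSV paths
#' (`receivers`, `tags`, `detections`). Everything is a plain list so a
#' run's configuration can be archived as YAML next to its outputs.
#'
#' @param simulate A [sim_config()], or `NULL` to read CSVs.
#' @param receivers,tags,detections Input CSV paths (data mode).
#' @param tz Reporting timezone.
#' @param isolation_window_h Rule-B isolation window, hours.
#' @param directed Directed edge-density convention.
#' @param null_reps Random-network null replicates per shark (0 skips the
#'   null tests).
#' @param seed Seed for the null-model draws (and the simulator, which uses
#'   its own `seed` field when `simulate` is given).
#' @param growth A [growth_schedule()].
#' @param scheme A [life_stage_scheme()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = sim_config(), receivers = NULL,
                       tags = NULL, detections = NULL, tz = "UTC",
                       isolation_window_h = 24, directed = TRUE,
                       null_reps = 0, seed = 1,
                       growth = default_growth_schedule(),
                       scheme = life_stage_scheme()) {
  if (is.null(simulate) &&
      (is.null(receivers) || is.null(tags) || is.null(detections))) {
    stop_sharknet(
      "run_config needs either a simulate block or receiver/tag/detection paths",
      "sharknet_config_error")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Per-shark motility records
#'
#' Builds each detected shark's movement network over the stations active in
#' its monitoring window and reduces it to a motility record (node and edge
#' density) for its primary array -- the array holding most of its detection
#' days. Appearances in the other array are left to the inter-array
#' connectivity tally, mirroring the treatment of the two arrays as separate
#' networks.
#'
#' @param detections QC-retained detections.
#' @param tags Tag table.
#' @param receivers Receiver table.
#' @param staged Staged cohort from [restage_cohort()] (supplies fork length
#'   at first detection and sex).
#' @param tz Reporting timezone.
#' @param directed Edge-density convention.
#' @return A list: `records` (motility tibble with `fl_first_detection_cm`,
#'   `sex`, `island`), `networks` (named list of `shark_networks`),
#'   `inter_array` (row-bound array-spanning transitions).
#' @export
motility_table <- function(detections, tags, receivers, staged,
                           tz = "UTC", directed = TRUE) {
  dd <- to_detection_days(detections, tags, tz)
  summ <- residency_summary(dd)
  records <- list()
  networks <- list()
  inter <- list()
  for (i in seq_len(nrow(summ))) {
    sh <- summ$shark_id[i]
    act <- active_stations(summ$first_detection[i], summ$last_detection[i],
                           receivers)
    nets <- build_network(detections, tags, sh, act)
    networks[[sh]] <- nets
    if (nrow(nets$inter_array) > 0) {
      inter[[sh]] <- mutate(nets$inter_array, shark_id = sh)
    }
    days_by_array <- dd %>%
      filter(.data$shark_id == sh) %>%
      left_join(distinct(receivers, .data$station_id, .data$array),
                by = "station_id") %>%
      count(.data$array, sort = TRUE)
    primary <- days_by_array$array[1]
    if (is.na(primary) || !primary %in% names(nets$networks)) next
    records[[sh]] <- motility(nets$networks[[primary]], directed = directed)
  }
  records <- bind_rows(records) %>%
    left_join(select(staged, dplyr::all_of(
      c("shark_id", "sex", "fl_first_detection_cm",
        "stage_first_detection"))),
      by = "shark_id") %>%
    mutate(island = .data$array)
  list(records = records, networks = networks,
       inter_array = bind_rows(inter))
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) telemetry tables, filter false detections, compute
#' residency statistics, growth-correct life stages, build per-shark
#' movement networks with motility metrics (optionally tested against
#' random-network nulls), and fit/select the candidate motility GAMs. With a
#' fixed configuration and seed the numeric outputs are identical across
#' runs.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, stage outputs are
#'   written as CSVs together with the archived configuration and a
#'   manifest.
#' @return A list of stage results: `data`, `qc`, `detection_days`,
#'   `residency`, `runs`, `staging`, `motility`, `movers`, `null_tests`,
#'   `model_table`, `selected_model`, `fits`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    sim <- simulate_telemetry(config$simulate)
    receivers <- sim$stations
    tags <- sim$tags
    detections <- select(sim$detections, dplyr::all_of(
      c("timestamp", "tag_id", "station_id")))
    truth <- sim$truth
  } else {
    for (f in c("receivers", "tags", "detections")) {
      if (!file.exists(config[[f]])) {
        stop_sharknet(sprintf("input file for '%s' not found: %s", f,
                              config[[f]]), "sharknet_schema_error")
      }
    }
    receivers <- read_receivers(config$receivers)
    tags <- read_tags(config$tags)
    detections <- read_detections(config$detections, tags)
    truth <- NULL
  }

  qc <- filter_false_detections(detections, tags,
                                isolation_window_h =
                                  config$isolation_window_h)
  dd <- to_detection_days(qc$retained, tags, config$tz)
  resid <- residency_summary(dd)
  runs <- station_residency_runs(dd)
  staging <- restage_cohort(tags, qc$retained, config$growth,
                            config$scheme, config$tz)
  mot <- motility_table(qc$retained, tags, receivers, staging$staged,
                        config$tz, config$directed)
  movers <- tally_movers(mot$records, mot$inter_array)

  null_tests <- NULL
  if (config$null_reps > 0) {
    set.seed(config$seed)
    null_tests <- bind_rows(lapply(names(mot$networks), function(sh) {
      nets <- mot$networks[[sh]]
      bind_rows(lapply(nets$networks, function(nw) {
        if (nrow(nw$edges) == 0 || length(nw$nodes) < 2) return(NULL)
        nm <- node_metrics(nw)
        null <- random_network_null(length(nw$nodes),
                                    nrow(distinct(nw$edges, .data$from,
                                                  .data$to)),
                                    reps = config$null_reps)
        mutate(compare_to_null(nm$betweenness, null, "betweenness"),
               shark_id = sh, array = nw$array)
      }))
    }))
  }

  model_table <- NULL
  selected <- NULL
  fits <- NULL
  rec <- mot$records[!is.na(mot$records$fl_first_detection_cm), ]
  if (nrow(rec) >= 10 && length(unique(rec$sex)) >= 1) {
    fits <- tryCatch(fit_candidates(rec), error = function(e) NULL)
    if (!is.null(fits)) {
      model_table <- model_selection_table(fits)
      selected <- select_model(model_table)
    }
  }

  out <- list(
    data = list(receivers = receivers, tags = tags,
                detections = detections, truth = truth),
    qc = qc, detection_days = dd, residency = resid, runs = runs,
    staging = staging, motility = mot, movers = movers,
    null_tests = null_tests, model_table = model_table,
    selected_model = selected, fits = fits
  )
  if (!is.null(outdir)) write_pipeline_outputs(out, config, outdir)
  out
}

write_pipeline_outputs <- function(out, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0) {
      write.csv(x, file.path(outdir, name), row.names = FALSE)
    }
  }
  wr(out$qc$report, "qc_report.csv")
  wr(out$detection_days, "detection_days.csv")
  wr(out$residency, "residency_summary.csv")
  wr(out$runs, "station_runs.csv")
  wr(out$staging$staged, "staged_cohort.csv")
  wr(out$staging$reclassified, "reclassified.csv")
  wr(out$motility$records, "motility.csv")
  wr(out$model_table, "model_selection.csv")
  wr(out$null_tests, "null_tests.csv")
  cfg <- config
  cfg$growth <- as.data.frame(cfg$growth)
  cfg$scheme <- unclass(cfg$scheme)
  if (!is.null(cfg$simulate)) {
    cfg$simulate$growth <- as.data.frame(cfg$simulate$growth)
    cfg$simulate <- unclass(cfg$simulate)
  }
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (inherits(x, "Date")) as.character(x) else x),
    file.path(outdir, "run_config.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("sharknet")),
    created = format(Sys.time(), tz = "UTC"),
    files = list.files(outdir)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
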