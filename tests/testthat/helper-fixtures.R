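# Shared fixtures and independent brute-force oracles.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# a small two-array receiver table, deployed throughout unless overridden
tiny_receivers <- function(n1 = 4, n2 = 3,
                           install = "2018-02-01", removal = NA) {
  tibble::tibble(
    station_id = c(sprintf("N%d", seq_len(n1)), sprintf("E%d", seq_len(n2))),
    array = c(rep("NewProvidence", n1), rep("GreatExuma", n2)),
    latitude = c(25.0 + seq_len(n1) / 100, 23.5 + seq_len(n2) / 100),
    longitude = c(-77.4 + seq_len(n1) / 100, -75.8 + seq_len(n2) / 100),
    depth_m = 10,
    habitat = "seagrass",
    install_date = as.Date(install),
    removal_date = as.Date(removal)
  )
}

tiny_tags <- function(ids = "SH1", sex = "F", fl = 200,
                      tagged = "2018-02-06 12:00:00",
                      min_delay = 60, max_delay = 180) {
  n <- length(ids)
  tibble::tibble(
    shark_id = ids,
    tag_id = paste0("T", ids),
    tagging_datetime = utc(rep_len(tagged, n)),
    tagging_array = "NewProvidence",
    fl_tagging_cm = rep_len(fl, n),
    sex = rep_len(sex, n),
    claspers_calcified = FALSE,
    min_delay_s = rep_len(min_delay, n),
    max_delay_s = rep_len(max_delay, n)
  )
}

# quick detection builder: times as seconds offset from an origin
det_at <- function(offsets_s, station = "N1", tag = "TS1",
                   origin = "2018-03-01 00:00:00") {
  tibble::tibble(
    timestamp = utc(origin) + offsets_s,
    tag_id = tag,
    station_id = rep_len(station, length(offsets_s))
  )
}

# detection-day builder from (station, date) pairs
dd_of <- function(stations, dates, shark = "SH1") {
  tibble::tibble(
    shark_id = shark, station_id = stations, date = as.Date(dates),
    first_time = utc(paste(as.Date(dates), "08:00:00")) +
      seq_along(stations),  # preserves input order as ping order
    n_pings = 1L
  )
}

# --- independent oracles -------------------------------------------------

# betweenness by explicit all-pairs shortest-path enumeration (BFS + DFS
# path counting), written independently of igraph
brute_betweenness <- function(nodes, edges) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    edges$to[edges$from == v])
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  all_shortest_paths <- function(s, t) {
    # BFS distances from s
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1; q <- c(q, w)
      }
    }
    if (is.infinite(dist[t])) return(list())
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (w in adj[[v]]) if (dist[w] == dist[v] + 1 && dist[w] <= dist[t])
        walk(c(path, w))
    }
    walk(s)
    paths
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_shortest_paths(s, t)
    if (length(paths) == 0) next
    for (p in paths) {
      inner <- p[-c(1, length(p))]
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw
}

# signed-rank p by direct 2^n enumeration, independent implementation
brute_signed_rank_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    vs[mask + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(vs >= v_obs - 1e-9), mean(vs <= v_obs + 1e-9)))
}

# QC filter oracle: literal sequential definition, one pass per rule
brute_filter <- function(detections, min_delay, window_h = 24) {
  d <- detections[order(detections$timestamp, detections$tag_id,
                        detections$station_id), ]
  d$status <- "retained"
  for (tg in unique(d$tag_id)) {
    for (st in unique(d$station_id[d$tag_id == tg])) {
      idx <- which(d$tag_id == tg & d$station_id == st)
      last_kept <- -Inf
      for (i in idx) {
        t <- as.numeric(d$timestamp[i])
        if (t - last_kept < min_delay) d$status[i] <- "removed_short_interval"
        else last_kept <- t
      }
    }
  }
  for (tg in unique(d$tag_id)) {
    idx <- which(d$tag_id == tg & d$status == "retained")
    for (i in idx) {
      others <- setdiff(idx, i)
      gaps <- abs(as.numeric(d$timestamp[others]) - as.numeric(d$timestamp[i]))
      if (length(others) == 0 || min(gaps) > window_h * 3600) {
        d$status[i] <- "removed_isolated"
      }
    }
  }
  d
}

# distinct ordered/unordered pair enumeration for density oracles
brute_densities <- function(seq_stations, active, directed = TRUE) {
  n <- length(active)
  moves <- cbind(seq_stations[-length(seq_stations)], seq_stations[-1])
  moves <- moves[moves[, 1] != moves[, 2], , drop = FALSE]
  moves <- moves[moves[, 1] %in% active & moves[, 2] %in% active, ,
                 drop = FALSE]
  pairs <- if (directed) unique(paste(moves[, 1], moves[, 2])) else
    unique(paste(pmin(moves[, 1], moves[, 2]),
                 pmax(moves[, 1], moves[, 2])))
  denom <- if (directed) n * (n - 1) else n * (n - 1) / 2
  list(
    node_density = length(intersect(unique(seq_stations), active)) / n,
    edge_density = if (denom > 0) length(pairs) / denom else 0
  )
}

# a fast small simulation shared by heavier tests
small_sim_config <- function(seed = 11, n_sharks = 8,
                             study_end = "2018-09-01",
                             detection_prob = 0.5, ...) {
  sim_config(seed = seed, cohort_size = n_sharks,
             n_stations_per_array = c(NewProvidence = 5, GreatExuma = 4),
             study_end = study_end, tagging_start = "2018-02-06",
             tagging_end = "2018-03-15", deploy_end = "2018-03-01",
             late_install_frac = 0, removal_frac = 0,
             prob_never_detected = 0, detection_prob = detection_prob,
             ping_delay_s = c(300, 600), ...)
}
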