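# Per-individual movement networks over active stations: construction,
# node metrics, motility (node/edge density), and random-network null tests.

# is a station active (any deployment overlapping [first, last] by >= 1 day)?
station_active_for <- function(station_id, first, last, receivers) {
  dep <- receivers[receivers$station_id == station_id, , drop = FALSE]
  if (nrow(dep) == 0) return(FALSE)
  removal <- dep$removal_date
  removal[is.na(removal)] <- as.Date("9999-12-31")
  any(dep$install_date <= last & removal >= first)
}

#' Stations active during a shark's monitoring window
#'
#' Receivers come and go over a multi-year study; a shark can only be
#' detected at stations that were listening while it was monitored. A station
#' is active for a shark if any of its deployment intervals overlaps the
#' shark's first-to-last-detection window by at least one day. Motility
#' denominators use these active sets.
#'
#' @param first_detection,last_detection The shark's monitoring window
#'   (dates).
#' @param receivers Receiver table, one row per deployment (`station_id`,
#'   `array`, `install_date`, `removal_date`).
#' @return Tibble of active stations with `station_id` and `array`.
#' @export
active_stations <- function(first_detection, last_detection, receivers) {
  first_detection <- as.Date(first_detection)
  last_detection <- as.Date(last_detection)
  stations <- distinct(receivers, .data$station_id, .data$array)
  act <- vapply(stations$station_id, station_active_for, logical(1),
                first = first_detection, last = last_detection,
                receivers = receivers)
  stations[act, , drop = FALSE]
}

#' Build per-array movement networks for one shark
#'
#' Receivers are nodes and movements -- subsequent detections of the shark at
#' different receiver locations -- are directed edges weighted by the number
#' of movements. Consecutive detections at the same station are residence,
#' not movement, and add nothing. Transitions that span the two arrays are
#' tallied separately as inter-array links and belong to neither array
#' network, so each array is analysed as its own network.
#'
#' @param detections QC-retained detections of the cohort (`tag_id`,
#'   `station_id`, `timestamp`).
#' @param tags Tag table mapping `tag_id` to `shark_id`.
#' @param shark The `shark_id` to build networks for.
#' @param active Active-station tibble from [active_stations()]
#'   (`station_id`, `array`).
#' @return An object of class `shark_networks`: a list with `owner`,
#'   `networks` (one `movement_network` per array: `nodes`, `visited`,
#'   `edges` tibble `from`/`to`/`n`, `n_movements`, `outside_active`), and
#'   `inter_array` (tibble of array-spanning transitions).
#' @export
build_network <- function(detections, tags, shark, active) {
  det <- detections %>%
    left_join(select(tags, dplyr::all_of(c("tag_id", "shark_id"))),
              by = "tag_id") %>%
    filter(.data$shark_id == shark) %>%
    arrange(.data$timestamp)
  if (nrow(det) == 0) {
    stop_sharknet(sprintf("shark '%s' has no retained detections", shark),
                  "sharknet_not_found_error")
  }
  station_array <- setNames(active$array, active$station_id)
  arr <- station_array[det$station_id]
  outside <- unique(det$station_id[is.na(arr)])
  if (length(outside) > 0) {
    warn(sprintf(
      "shark %s detected at %d station(s) outside its active set: %s",
      shark, length(outside), paste(outside, collapse = ", ")))
  }

  s_from <- det$station_id[-nrow(det)]
  s_to <- det$station_id[-1]
  a_from <- arr[-nrow(det)]
  a_to <- arr[-1]
  move <- s_from != s_to
  same_array <- !is.na(a_from) & !is.na(a_to) & a_from == a_to

  inter <- tibble(from = s_from, to = s_to,
                  from_array = unname(a_from), to_array = unname(a_to))[
    move & !is.na(a_from) & !is.na(a_to) & a_from != a_to, , drop = FALSE]

  networks <- lapply(sort(unique(active$array)), function(ar) {
    nodes <- active$station_id[active$array == ar]
    sel <- move & same_array & a_from == ar
    edges <- tibble(from = s_from[sel], to = s_to[sel]) %>%
      count(.data$from, .data$to, name = "n") %>%
      arrange(.data$from, .data$to)
    visited <- unique(det$station_id[!is.na(arr) & arr == ar])
    structure(list(
      owner = shark, array = ar, nodes = nodes, visited = visited,
      edges = edges, n_movements = sum(edges$n),
      outside_active = outside
    ), class = "movement_network")
  })
  names(networks) <- sort(unique(active$array))
  structure(list(owner = shark, networks = networks, inter_array = inter),
            class = "shark_networks")
}

#' @export
print.movement_network <- function(x, ...) {
  cat(sprintf(
    "<movement_network> owner %s, array %s: %d active stations, %d visited, %d distinct edges, %d movements\n",
    x$owner, x$array, length(x$nodes), length(x$visited), nrow(x$edges),
    x$n_movements))
  invisible(x)
}

# igraph representation over the active node set (distinct edges, unweighted)
network_igraph <- function(network) {
  edges <- network$edges %>%
    filter(.data$from %in% network$nodes, .data$to %in% network$nodes)
  igraph::graph_from_data_frame(
    edges[c("from", "to")], directed = TRUE,
    vertices = data.frame(name = network$nodes))
}

#' Per-station network metrics
#'
#' Connectivity is the centrality degree: the number of distinct stations a
#' node exchanges movements with (in or out, each neighbour counted once).
#' Betweenness counts how often a station lies on shortest paths between
#' pairs of other stations in the directed, unweighted network (Brandes
#' counting with fractional credit for tied shortest paths; unnormalized).
#' Occupancy and station residency are joined in when residency inputs are
#' supplied.
#'
#' @param network A `movement_network`.
#' @param detection_days Optional [to_detection_days()] output (occupancy).
#' @param runs Optional [station_residency_runs()] output (mean run length).
#' @return Tibble with one row per active station: `station_id`,
#'   `connectivity`, `betweenness`, and optionally `occupancy_days`,
#'   `station_residency_days`.
#' @export
node_metrics <- function(network, detection_days = NULL, runs = NULL) {
  g <- network_igraph(network)
  und <- igraph::as_undirected(g, mode = "collapse")
  out <- tibble(
    station_id = network$nodes,
    connectivity = as.integer(igraph::degree(und)[network$nodes]),
    betweenness = as.numeric(
      igraph::betweenness(g, directed = TRUE, weights = NULL)[network$nodes])
  )
  if (!is.null(detection_days)) {
    occ <- detection_days %>%
      filter(.data$shark_id == network$owner) %>%
      count(.data$station_id, name = "occupancy_days")
    out <- left_join(out, occ, by = "station_id") %>%
      mutate(occupancy_days =
               tidyr::replace_na(.data$occupancy_days, 0L))
  }
  if (!is.null(runs)) {
    sr <- runs %>%
      filter(.data$shark_id == network$owner) %>%
      group_by(.data$station_id) %>%
      summarise(station_residency_days = mean(.data$length_days),
                .groups = "drop")
    out <- left_join(out, sr, by = "station_id")
  }
  out
}

#' Motility: node and edge density of an individual network
#'
#' Node density is the fraction of active stations at which the shark was
#' detected (0 = detected nowhere, 1 = detected at every active station).
#' Edge density is the fraction of possible station-to-station movements the
#' shark realized: distinct ordered station pairs with at least one movement
#' over `n_active * (n_active - 1)` under the directed convention (the
#' default), or distinct unordered pairs over `n_active * (n_active - 1) / 2`
#' undirected. Together they measure motility on a 0-1 scale. Movement
#' counts (edge weights) are kept for display but do not enter the density.
#'
#' @param network A `movement_network`.
#' @param directed Use the directed ordered-pair convention (default TRUE).
#' @return One-row tibble: `shark_id`, `array`, `n_active`, `n_visited`,
#'   `node_density`, `n_distinct_edges`, `edge_density`, `n_movements`,
#'   `edge_density_defined`.
#' @export
motility <- function(network, directed = TRUE) {
  n_active <- length(network$nodes)
  if (n_active < 1) {
    stop_sharknet("motility needs at least one active station",
                  "sharknet_input_error")
  }
  edges <- network$edges %>%
    filter(.data$from %in% network$nodes, .data$to %in% network$nodes)
  if (directed) {
    n_distinct_edges <- nrow(distinct(edges, .data$from, .data$to))
    denom <- n_active * (n_active - 1)
  } else {
    pairs <- tibble(a = pmin(edges$from, edges$to),
                    b = pmax(edges$from, edges$to))
    n_distinct_edges <- nrow(distinct(pairs))
    denom <- n_active * (n_active - 1) / 2
  }
  defined <- denom > 0
  tibble(
    shark_id = network$owner, array = network$array,
    n_active = n_active,
    n_visited = length(intersect(network$visited, network$nodes)),
    node_density = length(intersect(network$visited, network$nodes)) /
      n_active,
    n_distinct_edges = n_distinct_edges,
    edge_density = if (defined) n_distinct_edges / denom else 0,
    n_movements = network$n_movements,
    edge_density_defined = defined
  )
}

#' Aggregate member networks into a group network
#'
#' A life-stage or sex group network is the edge-count sum of its member
#' networks over the union of their active stations.
#'
#' @param networks List of `movement_network`s from the same array.
#' @param label Group label for the owner field.
#' @return A `movement_network` owned by `label`.
#' @export
group_network <- function(networks, label = "group") {
  stopifnot(length(networks) > 0)
  arrays <- unique(vapply(networks, function(x) x$array, character(1)))
  if (length(arrays) != 1) {
    stop_sharknet("group_network members must come from one array",
                  "sharknet_input_error")
  }
  edges <- bind_rows(lapply(networks, function(x) x$edges)) %>%
    group_by(.data$from, .data$to) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    arrange(.data$from, .data$to)
  structure(list(
    owner = label, array = arrays,
    nodes = sort(unique(unlist(lapply(networks, function(x) x$nodes)))),
    visited = sort(unique(unlist(lapply(networks, function(x) x$visited)))),
    edges = edges, n_movements = sum(edges$n),
    outside_active = character()
  ), class = "movement_network")
}

#' Tally movers and inter-array connectivity
#'
#' Counts, per array, the sharks that made at least one within-array
#' movement, the sharks (if any) that moved within both arrays, the total
#' number of distinct movers, and the sharks with connective (array-spanning)
#' transitions.
#'
#' @param motility_records Row-bound [motility()] records for the cohort.
#' @param inter_array Optional row-bound inter-array transition tibbles from
#'   [build_network()], with a `shark_id` column.
#' @return A list: `per_array` (tibble of array, n_movers, n_movements),
#'   `movers_within_both`, `total_movers`, `connective_sharks`.
#' @export
tally_movers <- function(motility_records, inter_array = NULL) {
  movers <- filter(motility_records, .data$n_distinct_edges > 0)
  per_array <- movers %>%
    group_by(.data$array) %>%
    summarise(n_movers = dplyr::n_distinct(.data$shark_id),
              n_movements = sum(.data$n_movements), .groups = "drop")
  by_shark <- movers %>% count(.data$shark_id)
  list(
    per_array = per_array,
    movers_within_both = sum(by_shark$n > 1),
    total_movers = nrow(by_shark),
    connective_sharks = if (is.null(inter_array)) character() else
      sort(unique(inter_array$shark_id))
  )
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether paired differences `x - mu` are symmetric about zero. Zero
#' differences are dropped; absolute differences are ranked with average
#' ranks for ties. For n <= 12 the two-sided p-value is exact, from full
#' enumeration of the 2^n equally likely sign assignments of the observed
#' ranks; for larger n a normal approximation with continuity correction and
#' tie-corrected variance is used. If every difference is zero the test is
#' degenerate and returns p = 1 with a flag rather than failing.
#'
#' @param x Numeric sample.
#' @param mu Null location; default 0.
#' @return A list: `statistic` (V, sum of positive ranks), `p_value`, `n`
#'   (non-zero differences), `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, mu = 0) {
  d <- x - mu
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate",
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12) {
    # exact: enumerate all sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    dist <- as.vector(signs %*% r)
    p_ge <- mean(dist >= v - 1e-9)
    p_le <- mean(dist <= v + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu_v - sign(v - mu_v) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method,
       degenerate = FALSE)
}

#' Random-network null distributions
#'
#' Draws directed Erdos-Renyi G(n, m) graphs matching the observed node and
#' edge counts and computes the same per-node metrics as [node_metrics()],
#' giving the null distribution an individual's observed network is tested
#' against.
#'
#' @param n_nodes,n_edges Observed node and distinct-edge counts.
#' @param reps Number of random graphs (>= 100).
#' @param seed Optional RNG seed.
#' @return A list of `reps x n_nodes` matrices: `betweenness`, `degree`
#'   (distinct-neighbour connectivity), plus `n_nodes`, `n_edges`.
#' @export
random_network_null <- function(n_nodes, n_edges, reps = 1000, seed = NULL) {
  assert_scalar_number(n_nodes, "n_nodes", lower = 1)
  assert_scalar_number(n_edges, "n_edges", lower = 0,
                       upper = n_nodes * (n_nodes - 1))
  assert_scalar_number(reps, "reps", lower = 100)
  if (!is.null(seed)) set.seed(seed)
  btw <- matrix(0, nrow = reps, ncol = n_nodes)
  deg <- matrix(0, nrow = reps, ncol = n_nodes)
  for (i in seq_len(reps)) {
    g <- igraph::sample_gnm(n_nodes, n_edges, directed = TRUE)
    btw[i, ] <- igraph::betweenness(g, directed = TRUE)
    deg[i, ] <- igraph::degree(igraph::as_undirected(g, mode = "collapse"))
  }
  list(betweenness = btw, degree = deg, n_nodes = n_nodes,
       n_edges = n_edges)
}

#' Compare observed node metrics against a random-network null
#'
#' One-sample Wilcoxon signed-rank test of the observed per-node metric
#' values against the null mean of that metric under G(n, m).
#'
#' @param observed Numeric vector of per-node metric values (e.g. the
#'   `betweenness` column of [node_metrics()]).
#' @param null Output of [random_network_null()].
#' @param metric `"betweenness"` or `"degree"`.
#' @return A one-row tibble: `metric`, `null_mean`, `statistic`, `p_value`,
#'   `n`, `degenerate`.
#' @export
compare_to_null <- function(observed, null,
                            metric = c("betweenness", "degree")) {
  metric <- match.arg(metric)
  null_mean <- mean(null[[metric]])
  w <- wilcoxon_signed_rank(observed, mu = null_mean)
  tibble(metric = metric, null_mean = null_mean,
         statistic = w$statistic, p_value = w$p_value, n = w$n,
         degenerate = w$degenerate)
}
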