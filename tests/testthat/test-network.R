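test_that("active stations are those whose deployments overlap monitoring", {
  rec <- tiny_receivers(3, 1)
  rec$removal_date[1] <- as.Date("2018-03-01")   # removed before window
  rec$install_date[2] <- as.Date("2018-06-01")   # installed mid-window
  act <- active_stations("2018-05-01", "2018-06-01", rec)
  expect_false("N1" %in% act$station_id)
  expect_true(all(c("N2", "N3", "E1") %in% act$station_id))
  # a single day of overlap suffices
  rec$removal_date[1] <- as.Date("2018-05-01")
  expect_true("N1" %in%
                active_stations("2018-05-01", "2018-06-01", rec)$station_id)
})

test_that("movement edges count subsequent detections at different stations", {
  rec <- tiny_receivers(4, 2)
  tags <- tiny_tags("S1")
  d <- det_at(0:4 * 3600, station = c("N1", "N1", "N2", "N1", "N3"))
  act <- active_stations("2018-03-01", "2018-03-02", rec)
  nets <- build_network(d, tags, "S1", act)
  np <- nets$networks$NewProvidence
  expect_equal(np$n_movements, 3)
  got <- dplyr::arrange(np$edges, from, to)
  expect_equal(got$from, c("N1", "N1", "N2"))
  expect_equal(got$to, c("N2", "N3", "N1"))
  expect_equal(got$n, c(1L, 1L, 1L))
  # a single-station shark has no edges
  one <- build_network(det_at(c(0, 60)), tags, "S1", act)
  expect_equal(nrow(one$networks$NewProvidence$edges), 0)
  # transitions spanning arrays are inter-array links, not edges
  d <- det_at(0:2 * 3600, station = c("N1", "E1", "E2"))
  nets <- build_network(d, tags, "S1", act)
  expect_equal(nrow(nets$inter_array), 1)
  expect_equal(nets$networks$NewProvidence$n_movements, 0)
  expect_equal(nets$networks$GreatExuma$n_movements, 1)
  # a visit outside the active set warns and is flagged
  act2 <- act[act$station_id != "N3", ]
  expect_warning(out <- build_network(det_at(c(0, 60),
                                             station = c("N1", "N3")),
                                      tags, "S1", act2),
                 "outside")
  expect_true("N3" %in% out$networks$NewProvidence$outside_active)
})

make_net <- function(nodes, from, to, owner = "x", array = "A") {
  structure(list(
    owner = owner, array = array, nodes = nodes,
    visited = unique(c(from, to)),
    edges = dplyr::count(tibble::tibble(from = from, to = to), from, to,
                         name = "n"),
    n_movements = length(from), outside_active = character()),
    class = "movement_network")
}

test_that("betweenness and connectivity match hand-enumerated graphs", {
  # directed path A -> B -> C: only B bridges
  nm <- node_metrics(make_net(c("A", "B", "C"), c("A", "B"), c("B", "C")))
  expect_equal(nm$betweenness[nm$station_id == "B"], 1)
  expect_equal(sum(nm$betweenness), 1)
  # complete directed graph: nobody bridges
  nodes <- c("A", "B", "C", "D")
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  nm <- node_metrics(make_net(nodes, pairs$from, pairs$to))
  expect_true(all(nm$betweenness == 0))
  expect_true(all(nm$connectivity == 3))
  # star with bidirected spokes: centre carries all 12 ordered leaf pairs
  leaves <- paste0("L", 1:4)
  nm <- node_metrics(make_net(c("C0", leaves),
                              c(rep("C0", 4), leaves),
                              c(leaves, rep("C0", 4))))
  expect_equal(nm$betweenness[nm$station_id == "C0"], 12)
})

test_that("betweenness equals brute-force path enumeration on random graphs", {
  set.seed(77)
  for (case in 1:50) {
    n <- sample(3:8, 1)
    nodes <- paste0("V", seq_len(n))
    m <- sample.int(n * (n - 1), 1)
    pairs <- expand.grid(from = nodes, to = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    pick <- pairs[sample.int(nrow(pairs), m), ]
    nm <- node_metrics(make_net(nodes, pick$from, pick$to))
    oracle <- brute_betweenness(nodes, pick)
    expect_equal(nm$betweenness, unname(oracle[nm$station_id]),
                 tolerance = 1e-9)
  }
})

test_that("motility densities match ordered-pair enumeration", {
  # all 12 ordered pairs of 4 active stations: edge density 1
  nodes <- paste0("S", 1:4)
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- motility(make_net(nodes, pairs$from, pairs$to))
  expect_equal(m$edge_density, 1)
  expect_equal(m$node_density, 1)
  # no movements at all
  net0 <- make_net(nodes, character(), character())
  net0$visited <- "S1"
  expect_equal(motility(net0)$edge_density, 0)
  # 5 active stations, 3 distinct ordered pairs: 3/20
  m <- motility(make_net(paste0("S", 1:5), c("S1", "S2", "S1"),
                         c("S2", "S1", "S3")))
  expect_equal(m$edge_density, 0.15)
  # undirected convention halves the denominator and merges the pair
  m <- motility(make_net(paste0("S", 1:5), c("S1", "S2", "S1"),
                         c("S2", "S1", "S3")), directed = FALSE)
  expect_equal(m$edge_density, 2 / 10)
  expect_error(motility(make_net(character(), character(), character())),
               class = "sharknet_input_error")
})

test_that("densities match the enumeration oracle on random sequences and never rise under sub-sampling", {
  rec <- tiny_receivers(5, 0)
  tags <- tiny_tags("S1")
  act <- active_stations("2018-03-01", "2018-03-03", rec)
  set.seed(15)
  for (case in 1:20) {
    seq_st <- sample(paste0("N", 1:5), 40, replace = TRUE)
    d <- det_at(seq_len(40) * 600, station = seq_st)
    net <- build_network(d, tags, "S1", act)$networks$NewProvidence
    m <- motility(net)
    oracle <- brute_densities(seq_st, act$station_id)
    expect_equal(m$node_density, oracle$node_density)
    expect_equal(m$edge_density, oracle$edge_density)
    # dropping detections can only shrink the densities
    keep <- sort(sample.int(40, 25))
    net2 <- build_network(d[keep, ], tags, "S1", act)$networks$NewProvidence
    m2 <- motility(net2)
    expect_lte(m2$node_density, m$node_density)
    expect_lte(m2$edge_density, m$edge_density)
  }
})

test_that("group networks are the edge-count sum of member networks", {
  rec <- tiny_receivers(4, 0)
  tags <- tiny_tags(c("S1", "S2"))
  act <- active_stations("2018-03-01", "2018-03-02", rec)
  n1 <- build_network(det_at(0:3 * 600, station = c("N1", "N2", "N1", "N3"),
                             tag = "TS1"),
                      tags, "S1", act)$networks$NewProvidence
  n2 <- build_network(det_at(0:2 * 600, station = c("N2", "N1", "N2"),
                             tag = "TS2"),
                      tags, "S2", act)$networks$NewProvidence
  grp <- group_network(list(n1, n2), "both")
  expect_equal(grp$n_movements, n1$n_movements + n2$n_movements)
  both <- dplyr::bind_rows(n1$edges, n2$edges) %>%
    dplyr::count(from, to, wt = n, name = "n") %>%
    dplyr::arrange(from, to)
  expect_equal(as.data.frame(grp$edges), as.data.frame(both))
  expect_setequal(grp$nodes, union(n1$nodes, n2$nodes))
})

test_that("the signed-rank test matches enumeration, wilcox.test and handles degeneracy", {
  set.seed(8)
  # exact region: against a brute-force 2^n oracle, ties included
  for (case in 1:20) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n, 0.3), 1)
    x <- x[x != 0]
    if (length(x) < 2) next
    got <- wilcoxon_signed_rank(x)
    expect_equal(got$p_value, brute_signed_rank_p(x), tolerance = 1e-12)
  }
  # tie-free samples agree with the reference implementation in stats
  for (case in 1:10) {
    x <- rnorm(10, 0.4)
    expect_equal(wilcoxon_signed_rank(x)$p_value,
                 stats::wilcox.test(x, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample normal approximation tracks the reference
  x <- rnorm(40, 0.2)
  expect_equal(wilcoxon_signed_rank(x)$p_value,
               stats::wilcox.test(x, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # all-zero differences: degenerate, p = 1, flagged
  w <- wilcoxon_signed_rank(rep(2, 6), mu = 2)
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)
})

test_that("null-model comparisons are calibrated when the observed graph is itself random", {
  set.seed(12)
  ps <- replicate(200, {
    g <- igraph::sample_gnm(8, 16, directed = TRUE)
    obs <- as.numeric(igraph::betweenness(g, directed = TRUE))
    null <- random_network_null(8, 16, reps = 150)
    compare_to_null(obs, null, "betweenness")$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # degenerate observed vector flags rather than fails
  null <- random_network_null(4, 3, reps = 100, seed = 2)
  out <- compare_to_null(rep(mean(null$betweenness), 4), null)
  expect_true(out$degenerate)
  # invalid edge counts are configuration errors naming the field
  expect_error(random_network_null(3, 7, reps = 100),
               "n_edges", class = "sharknet_config_error")
})
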