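test_that("toy-network panel values match hand computation", {
  net <- toy_network()
  ds <- degree_stats(net)
  expect_equal(unname(ds$k[match("Kan", net$vertices)]), 3L)
  expect_equal(ds$k_mean, 8 / 5)
  expect_equal(ds$k_max, 3L)

  expect_equal(geodesic_distance(net, "Ta", "Zai"), 2)
  expect_equal(geodesic_distance(net, "Shu", "Xuexiao"), 3)
  pl <- average_path_length(net)
  expect_equal(pl$L, 18 / 10)
  expect_equal(pl$component_count, 1L)

  expect_equal(clustering(net)$C, 0)
  dc <- density_centralization(net)
  expect_equal(dc$ND, 0.4)
  expect_equal(dc$NC, (5 / 4) * (3 / 4 - 0.4))
})

test_that("closed-form cases: single edge, path, triangle, K4", {
  ab <- mk_network("A", "B")
  expect_equal(degree_stats(ab)$k_mean, 1)

  path3 <- mk_network(c("A", "B"), c("B", "C"))
  expect_equal(average_path_length(path3)$L, 4 / 3)

  tri <- mk_network(c("A", "B", "C"), c("B", "C", "A"))
  expect_equal(clustering(tri)$C, 1)

  # triangle plus pendant: C = (1 + 1 + 1/3 + 0) / 4
  trip <- mk_network(c("A", "B", "C", "D"), c("B", "C", "A", "A"))
  expect_equal(clustering(trip)$C, (1 + 1 + 1 / 3 + 0) / 4)

  k4 <- mk_network(c("A", "A", "A", "B", "B", "C"),
                   c("B", "C", "D", "C", "D", "D"))
  dc <- density_centralization(k4)
  expect_equal(dc$ND, 1)
  expect_equal(dc$NC, 0)
})

test_that("panel matches the brute-force oracle on random small graphs", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(4:20, 1)
    net <- random_small_network(n, runif(1, 0.1, 0.5))
    expect_equal(unname(degree_stats(net)$k), unname(oracle_degrees(net)))
    expect_equal(clustering(net)$C, oracle_clustering(net),
                 tolerance = 1e-12)
    expect_equal(average_path_length(net)$L, oracle_L_reachable(net),
                 tolerance = 1e-12)
    expect_equal(density_centralization(net)$ND, oracle_density(net),
                 tolerance = 1e-12)
    expect_equal(density_centralization(net)$NC,
                 oracle_centralization(net), tolerance = 1e-12)
  }
})

test_that("distance matrix equals the Floyd-Warshall oracle", {
  set.seed(33)
  net <- random_small_network(12, 0.2)
  got <- average_path_length(net, keep_distances = TRUE)$distances
  expect_equal(unname(got), unname(oracle_distances(net)))
})

test_that("handshake and edge-monotonicity properties hold", {
  set.seed(99)
  for (rep in 1:15) {
    net <- random_small_network(sample(5:25, 1), runif(1, 0.15, 0.5))
    expect_equal(sum(degree_stats(net)$k), 2 * net$M)

    # add one absent edge (if any): ND never decreases, L never increases
    a <- oracle_adjacency(net)
    absent <- which(!a & upper.tri(a), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    net2 <- net
    net2$edges <- rbind(net2$edges,
                        data.frame(i = min(pick), j = max(pick), weight = 1L))
    net2$M <- net2$M + 1L
    expect_gte(density_centralization(net2)$ND,
               density_centralization(net)$ND)
    d1 <- average_path_length(net, keep_distances = TRUE)$distances
    d2 <- average_path_length(net2, keep_distances = TRUE)$distances
    same <- is.finite(d1)  # compare on the originally reachable pair set
    expect_lte(mean(d2[same]), mean(d1[same]))
  }
})

test_that("exact and approximate centralization agree to O(1/N)", {
  for (seed in 1:3) {
    set.seed(seed)
    net <- generate_gnm(600, 1800, seed = seed)
    ex <- density_centralization(net, "exact")$NC
    ap <- density_centralization(net, "approximate")$NC
    expect_lt(abs(ex - ap), 0.01)
  }
})

test_that("disconnected networks: reachable default, all_pairs errors, largest component", {
  # two components: path A-B-C and edge X-Y
  net <- mk_network(c("A", "B", "X"), c("B", "C", "Y"))
  pl <- average_path_length(net)
  expect_equal(pl$component_count, 2L)
  expect_equal(pl$unreachable_pairs, 6)
  expect_equal(pl$L, (1 + 1 + 2 + 1) / 4)       # reachable pairs only
  expect_equal(pl$largest_component_fraction, 3 / 5)
  expect_error(average_path_length(net, mode = "all_pairs"), "disconnected",
               class = "syntnet_validation_error")
  expect_equal(average_path_length(net, mode = "largest_component")$L, 4 / 3)
})

test_that("metric rows assemble and serialize with 3-decimal rounding", {
  net <- toy_network()
  row <- compute_metrics_row(net, corpus_meta("written", 1, "TOY"),
                             token_count = 8L)
  expect_equal(row$N, 5L)
  expect_equal(row$C, 0)
  expect_equal(row$ND, 0.4)
  expect_true(is.na(row$gamma_prime))
  row2 <- compute_metrics_row(net, corpus_meta("written", 1, "TOY"),
                              token_count = 8L)
  expect_identical(row, row2)

  p <- tempfile(fileext = ".tsv")
  row$L <- 1.8125   # binary-exact half case: rounds to even -> 1.812
  write_metrics_table(row, p)
  back <- read_metrics_table(p)
  expect_equal(back$L, 1.812)
  expect_equal(back$level, "1")
})
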