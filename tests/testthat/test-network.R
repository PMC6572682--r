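test_that("ring lattice has the prescribed degrees and edge count", {
  tiny <- build_ring_lattice(4, 2)
  expect_equal(nrow(tiny$edges), 4)
  g <- as_igraph(tiny)
  expect_true(all(igraph::degree(g) == 2))
  expect_equal(igraph::components(g)$no, 1)  # a single cycle

  big <- build_ring_lattice(10000, 6)
  expect_equal(nrow(big$edges), 30000)
  degs <- tabulate(c(big$edges[, 1], big$edges[, 2]) + 1L, nbins = 10000)
  expect_true(all(degs == 6))

  expect_error(build_ring_lattice(10, 3), "even")
  expect_error(build_ring_lattice(4, 4), "smaller than n")
})

test_that("lattice clustering matches the closed form 3(k-2)/(4(k-1))", {
  net <- build_ring_lattice(20, 4)
  g <- as_igraph(net)
  expect_equal(igraph::transitivity(g, type = "localaverage"), 0.5,
               tolerance = 1e-12)
  # second check by exhaustive triangle count via the global coefficient
  expect_equal(igraph::transitivity(g, type = "global"),
               3 * (4 - 2) / (4 * (4 - 1)), tolerance = 1e-12)
})

test_that("rewiring conserves edges and keeps the graph simple", {
  lat <- build_ring_lattice(500, 6)
  expect_identical(rewire(lat, 0)$edges, lat$edges)

  for (beta in c(0.1, 0.5, 1)) {
    set.seed(100 + beta * 10)
    rw <- rewire(lat, beta)
    expect_equal(nrow(rw$edges), nrow(lat$edges))
    expect_true(all(rw$edges[, 1] != rw$edges[, 2]))  # no self-loops
    key <- paste(pmin(rw$edges[, 1], rw$edges[, 2]),
                 pmax(rw$edges[, 1], rw$edges[, 2]))
    expect_equal(anyDuplicated(key), 0)  # no duplicate edges
  }
})

test_that("fully rewired lattice behaves like a random graph", {
  set.seed(11)
  rw <- rewire(build_ring_lattice(1000, 6), 1)
  g <- as_igraph(rw)
  set.seed(12)
  er <- igraph::sample_gnm(1000, 3000)
  # BFS-based mean shortest path oracle for both
  expect_lt(abs(igraph::mean_distance(g) / igraph::mean_distance(er) - 1),
            0.2)
})

test_that("small rewiring keeps high clustering with short paths", {
  n <- 2000; k <- 6
  set.seed(21)
  sw <- build_small_world(n, k, beta = 0.1)
  g <- as_igraph(sw)
  set.seed(22)
  er <- igraph::sample_gnm(n, n * k / 2)
  cc_sw <- igraph::transitivity(g, type = "localaverage")
  cc_er <- igraph::transitivity(er, type = "localaverage")
  expect_gte(cc_sw, 5 * cc_er)
  # path length close to the random-graph value, far below the lattice's
  expect_lt(igraph::mean_distance(g), 2 * igraph::mean_distance(er))
  expect_lt(igraph::mean_distance(g),
            igraph::mean_distance(as_igraph(build_ring_lattice(n, k))) / 5)
})

test_that("signal counts follow the neighborhood states", {
  # isolated nodes receive nothing
  net0 <- empty_network(3)
  s <- count_signals(c(TRUE, FALSE, TRUE), rep(TRUE, 3), net0)
  expect_identical(s$positive, integer(3))
  expect_identical(s$negative, integer(3))

  # 4-cycle with alternating states: hand enumeration — on the cycle
  # 0-1-2-3-0 both neighbors of every node carry the opposite state, so
  # healthy nodes receive (0, 2) and unhealthy nodes (2, 0)
  cyc <- build_ring_lattice(4, 2)
  s <- count_signals(c(TRUE, FALSE, TRUE, FALSE), rep(TRUE, 4), cyc)
  expect_identical(s$positive, c(0L, 2L, 0L, 2L))
  expect_identical(s$negative, c(2L, 0L, 2L, 0L))

  # uniformly healthy neighborhoods
  ring <- build_ring_lattice(50, 6)
  s <- count_signals(rep(TRUE, 50), rep(TRUE, 50), ring)
  expect_identical(s$positive, rep(6L, 50))
  expect_identical(s$negative, rep(0L, 50))
})

test_that("dead agents neither send nor receive signals", {
  cyc <- build_ring_lattice(4, 2)
  alive <- c(TRUE, FALSE, TRUE, TRUE)
  s <- count_signals(c(TRUE, TRUE, FALSE, FALSE), alive, cyc)
  expect_identical(s$positive[2], 0L)
  expect_identical(s$negative[2], 0L)
  # node 0's neighbors are 1 (dead) and 3 (alive, unhealthy)
  expect_identical(s$positive[1], 0L)
  expect_identical(s$negative[1], 1L)
})

test_that("total signals equal twice the edges among living agents", {
  set.seed(31)
  net <- build_small_world(300, 6, 0.2)
  for (seed in 1:5) {
    set.seed(seed)
    healthy <- stats::runif(300) < 0.4
    alive <- stats::runif(300) < 0.9
    s <- count_signals(healthy, alive, net)
    living_edges <- sum(alive[net$edges[, 1] + 1] & alive[net$edges[, 2] + 1])
    expect_equal(sum(s$positive) + sum(s$negative), 2 * living_edges)
  }
})

test_that("edge lists round-trip through the text format", {
  set.seed(41)
  net <- build_small_world(60, 4, 0.3)
  path <- withr::local_tempfile(fileext = ".edges")
  write_edgelist(net, path)
  back <- read_edgelist(path, n_nodes = 60)
  expect_identical(back$edges, net$edges)
})
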