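test_that("generated spirals have the stated polar geometry", {
  sp <- generate_spiral(center = c(0, 0), spacing_px = 10, turns = 1, n_points = 5)
  expect_equal(nrow(sp), 5)
  expect_equal(sqrt(sp$x[5]^2 + sp$y[5]^2), 10, tolerance = 1e-12)
  expect_equal(c(sp$x[1], sp$y[1]), c(0, 0))

  cw <- generate_spiral(c(50, 50), 20, 2, "cw", 64)
  ccw <- generate_spiral(c(50, 50), 20, 2, "ccw", 64)
  expect_equal(ccw$x, 100 - cw$x, tolerance = 1e-12)  # mirror about x = 50
  expect_equal(ccw$y, cw$y)

  arc <- cumsum(c(0, sqrt(diff(cw$x)^2 + diff(cw$y)^2)))
  expect_true(all(diff(arc) > 0))

  expect_error(generate_spiral(spacing_px = -1), class = "cogscreen_domain_error")
  expect_error(generate_spiral(turns = 0), class = "cogscreen_domain_error")
})

test_that("discrete Frechet matches hand examples", {
  a <- rbind(c(0, 0), c(1, 0))
  expect_equal(discrete_frechet(a, a), 0)
  expect_equal(discrete_frechet(a, rbind(c(0, 1), c(1, 1))), 1)
  expect_equal(discrete_frechet(rbind(c(0, 0), c(4, 0)),
                                rbind(c(0, 0), c(2, 3), c(4, 0))), sqrt(13))
  expect_error(discrete_frechet(a, matrix(numeric(0), 0, 2)),
               class = "cogscreen_domain_error")
})

test_that("discrete Frechet agrees with the brute-force coupling oracle and is a metric", {
  set.seed(11)
  for (rep in 1:40) {
    a <- random_curve(sample(2:7, 1))
    b <- random_curve(sample(2:7, 1))
    expect_equal(discrete_frechet(a, b), brute_frechet(a, b), tolerance = 1e-12)
    expect_equal(discrete_frechet(a, b), discrete_frechet(b, a))
  }
  # triangle inequality and identity on random triples
  for (rep in 1:15) {
    a <- random_curve(4); b <- random_curve(5); c <- random_curve(6)
    expect_lte(discrete_frechet(a, c),
               discrete_frechet(a, b) + discrete_frechet(b, c) + 1e-12)
    expect_equal(discrete_frechet(a, a), 0)
  }
  # constant offset: distance equals |v|
  a <- random_curve(6)
  v <- c(3, -4)
  expect_equal(discrete_frechet(a, sweep(a, 2, -v)), 5, tolerance = 1e-12)
})

test_that("percentage match counts drawn points within the radius", {
  ref <- curve2d(0:10, rep(0, 11))
  expect_equal(percentage_match(ref, ref, 1), 1)
  far <- curve2d(0:10, rep(50, 11))
  expect_equal(percentage_match(far, ref, 1), 0)
  drawn <- curve2d(c(0, 1, 2, 3), c(0.5, 0.5, 0.5, 30))
  expect_equal(percentage_match(drawn, ref, 1), 0.75)
  # invariant to reordering of drawn points, monotone in radius
  perm <- drawn[c(3, 1, 4, 2), ]
  expect_equal(percentage_match(perm, ref, 1), 0.75)
  expect_gte(percentage_match(drawn, ref, 40), percentage_match(drawn, ref, 1))
  expect_error(percentage_match(drawn, ref, 0), class = "cogscreen_domain_error")
})

test_that("parallel angles follow the arctangent slope formula", {
  expect_equal(parallel_angle(2, 2), 0)
  expect_equal(parallel_angle(0, 1), 45)
  expect_equal(parallel_angle(1, -1), 90)
  expect_equal(parallel_angle(Inf, Inf), 0)
  expect_equal(parallel_angle(Inf, 0), 90)
  expect_equal(parallel_angle(Inf, 1), 45)
})

test_that("parallel-pair scoring applies the tolerance and match fraction", {
  s <- function(m) list(slope = m, vertical = FALSE)
  slopes <- lapply(c(1, 1.0001, 5, -5, 0.2, 0.21, 2, 2.05, 3, 10), s)
  all_par <- parallel_pairs_score(slopes, list(c(1, 2), c(5, 6), c(7, 8)))
  expect_equal(all_par$fraction, 1)
  expect_true(all_par$pass)

  none <- parallel_pairs_score(lapply(c(0, 5), s), rep(list(c(1, 2)), 9))
  expect_equal(none$fraction, 0)
  expect_false(none$pass)

  mixed_slopes <- lapply(c(1, 1.01, 0.5, 0.51, 2, 2.01, 3, 3.01, 4, 4.01,
                           0, 10, -1, 1, 0, 20, 0, 30), s)
  pairs <- lapply(seq(1, 17, by = 2), function(i) c(i, i + 1))
  mixed <- parallel_pairs_score(mixed_slopes, pairs)
  expect_equal(mixed$fraction, 5 / 9, tolerance = 1e-12)
  expect_true(mixed$pass)
  expect_error(parallel_pairs_score(slopes, list()), class = "cogscreen_domain_error")
})

test_that("total-least-squares slope fit handles steep and flat strokes", {
  flat <- fit_line_slope(curve2d(0:10, 0.5 * (0:10) + rnorm(11, 0, 1e-9)))
  expect_equal(flat$slope, 0.5, tolerance = 1e-6)
  steep <- fit_line_slope(curve2d(rep(2, 10) + rnorm(10, 0, 1e-12), 1:10))
  expect_true(steep$vertical)
})

test_that("stroke-node resolution returns distinct ids in first-touch order", {
  lay <- graph_layout(data.frame(node_id = c("a", "b", "c"),
                                 x_px = c(0, 100, 200), y_px = c(0, 0, 0)),
                      node_radius_px = 10)
  straight <- curve2d(seq(0, 100, by = 5), rep(0, 21))
  expect_identical(resolve_stroke_nodes(straight, lay), c("a", "b"))
  far <- curve2d(seq(0, 100, by = 5), rep(500, 21))
  expect_identical(resolve_stroke_nodes(far, lay), character(0))
  grazing <- curve2d(seq(200, 0, by = -5), rep(8, 41))
  expect_identical(resolve_stroke_nodes(grazing, lay), c("c", "b", "a"))
})

test_that("the Hungarian solver matches permutation enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    sim <- matrix(runif(n * n), n)
    expect_equal(cogscreen:::assignment_max(sim), brute_assignment_max(sim),
                 tolerance = 1e-12)
  }
  # rectangular
  sim <- matrix(runif(12), 3, 4)
  expect_equal(cogscreen:::assignment_max(sim), brute_assignment_max(sim),
               tolerance = 1e-12)
})

make_graph <- function(ids, edges) {
  graph_layout(data.frame(node_id = ids, x_px = seq_along(ids), y_px = 0), edges)
}

test_that("neighbor matching is 1 for isomorphic graphs and label-invariant", {
  g <- make_graph(c("a", "b", "c", "d"),
                  rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_equal(neighbor_matching_similarity(g, g), 1)
  relabeled <- make_graph(c("w", "x", "y", "z"),
                          rbind(c("x", "w"), c("y", "x"), c("z", "y"), c("w", "z")))
  expect_equal(neighbor_matching_similarity(g, relabeled), 1)
  expect_equal(neighbor_matching_similarity(g, relabeled),
               neighbor_matching_similarity(relabeled, g))
  empty <- graph_layout(tibble::tibble(node_id = character(0),
                                       x_px = numeric(0), y_px = numeric(0)))
  expect_error(neighbor_matching_similarity(g, empty),
               class = "cogscreen_domain_error")
})

test_that("neighbor matching agrees with the independent fixed-point oracle", {
  path3 <- make_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  cyc3 <- make_graph(c("x", "y", "z"), rbind(c("x", "y"), c("y", "z"), c("z", "x")))
  adj_p <- matrix(0, 3, 3); adj_p[1, 2] <- adj_p[2, 1] <- adj_p[2, 3] <- adj_p[3, 2] <- 1
  adj_c <- matrix(1, 3, 3) - diag(3)
  expected <- oracle_neighbor_matching(adj_p, adj_c)
  got <- neighbor_matching_similarity(path3, cyc3, eps = 1e-6)
  expect_equal(got, expected, tolerance = 1e-3)
  # star vs path, 4 nodes
  star <- make_graph(c("h", "l1", "l2", "l3"),
                     rbind(c("h", "l1"), c("h", "l2"), c("h", "l3")))
  path4 <- make_graph(c("a", "b", "c", "d"),
                      rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  adj_s <- matrix(0, 4, 4); adj_s[1, 2:4] <- adj_s[2:4, 1] <- 1
  adj_p4 <- matrix(0, 4, 4)
  adj_p4[1, 2] <- adj_p4[2, 1] <- adj_p4[2, 3] <- adj_p4[3, 2] <- 1
  adj_p4[3, 4] <- adj_p4[4, 3] <- 1
  expect_equal(neighbor_matching_similarity(star, path4, eps = 1e-6),
               oracle_neighbor_matching(adj_s, adj_p4), tolerance = 1e-3)
})

test_that("point-in-polygon classifies a concave polygon correctly", {
  # L-shaped polygon
  px <- c(0, 4, 4, 2, 2, 0); py <- c(0, 0, 2, 2, 4, 4)
  inside <- cogscreen:::point_in_polygon(c(1, 3, 3, 1), c(1, 1, 3, 3), px, py)
  expect_identical(inside, c(TRUE, TRUE, FALSE, TRUE))
})
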