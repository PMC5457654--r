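test_that("euclidean distance matches the planar formula", {
  expect_equal(euclidean_distance(0, 0, 3, 4), 5)
  expect_equal(euclidean_distance(7, 2, 7, 2), 0)
  expect_equal(euclidean_distance(1, 1, 4, 5), 5)
  expect_error(euclidean_distance(NA, 0, 1, 1), class = "pedsda_domain_error")
  withr::with_seed(1, {
    p <- matrix(runif(40, -50, 50), ncol = 4)
    expect_equal(euclidean_distance(p[, 1], p[, 2], p[, 3], p[, 4]),
                 euclidean_distance(p[, 3], p[, 4], p[, 1], p[, 2]))
  })
})

test_that("network constructor enforces its invariants", {
  nodes <- tibble::tibble(node_id = c("a", "b"), x = c(0, 100), y = c(0, 0))
  expect_error(road_network(nodes, tibble::tibble(from = "a", to = "z", length_m = 1)),
               "z", class = "pedsda_domain_error")
  expect_error(road_network(nodes, tibble::tibble(from = "a", to = "b", length_m = -5)),
               class = "pedsda_domain_error")
  expect_error(road_network(nodes, tibble::tibble(from = "a", to = "b", length_m = 0)),
               class = "pedsda_domain_error")
  # a road shorter than its chord is geometrically impossible
  expect_error(road_network(nodes, tibble::tibble(from = "a", to = "b", length_m = 50)),
               "chord", class = "pedsda_domain_error")
  expect_s3_class(road_network(nodes, tibble::tibble(from = "a", to = "b", length_m = 120)),
                  "road_network")
})

test_that("snapping picks the nearest node with lexicographic ties", {
  net <- make_square_network()
  expect_equal(snap_to_network(0, 0, net), "a")
  expect_equal(snap_to_network(0.5, 0, net), "a")  # equidistant a/b -> a
  withr::with_seed(42, {
    for (k in 1:20) {
      px <- runif(1, -0.5, 1.5); py <- runif(1, -0.5, 1.5)
      d2 <- (net$nodes$x - px)^2 + (net$nodes$y - py)^2
      expect_equal(snap_to_network(px, py, net),
                   net$nodes$node_id[which.min(d2)])
    }
  })
})

test_that("network distance is zero at origin, exact on the unit square, errors on unknown nodes", {
  net <- make_square_network()
  expect_equal(network_distance(net, "a", "a"), 0)
  expect_equal(network_distance(net, "a", "d"), 2)
  expect_error(network_distance(net, "a", "zz"), class = "pedsda_domain_error")
})

test_that("disconnected pairs return the unreachable marker, never an error", {
  net <- road_network(
    tibble::tibble(node_id = c("a", "b", "c", "d"),
                   x = c(0, 1, 10, 11), y = c(0, 0, 0, 0)),
    tibble::tibble(from = c("a", "c"), to = c("b", "d"), length_m = c(1, 1))
  )
  expect_equal(network_distance(net, "a", "b"), 1)
  expect_identical(network_distance(net, "a", "c"), Inf)
})

test_that("network distance agrees with exhaustive path enumeration on random graphs", {
  withr::with_seed(7, {
    for (k in 1:25) {
      net <- random_road_network(sample(4:8, 1), n_extra = sample(0:3, 1))
      pair <- sample(net$nodes$node_id, 2)
      expect_equal(network_distance(net, pair[1], pair[2]),
                   oracle_shortest_path(net$edges, pair[1], pair[2]),
                   tolerance = 1e-10)
    }
  })
})

test_that("network distance is symmetric and satisfies the triangle inequality", {
  withr::with_seed(11, {
    net <- random_road_network(8, n_extra = 4)
    ids <- net$nodes$node_id
    D <- outer(ids, ids, function(o, d) network_distance(net, o, d))
    expect_equal(D, t(D))
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
    }
    # network distance dominates the chord between the endpoints
    chord <- outer(seq_along(ids), seq_along(ids), function(i, j) {
      euclidean_distance(net$nodes$x[i], net$nodes$y[i],
                         net$nodes$x[j], net$nodes$y[j])
    })
    expect_true(all(D >= chord - 1e-9))
  })
})

test_that("annotate_distances adds both distances and flags disconnection", {
  net <- make_square_network()
  reg <- make_mini_registry() |>
    dplyr::mutate(residence_x = c(0, 0, 1), residence_y = c(0, 0, 1),
                  injury_x = c(0, 1, 1), injury_y = c(0, 1, 1))
  ann <- annotate_distances(reg, net)
  expect_equal(ann$euclidean_m, c(0, sqrt(2), 0))
  expect_equal(ann$network_distance_m, c(0, 2, 0))
  expect_false(any(ann$unreachable))

  split_net <- road_network(
    tibble::tibble(node_id = c("a", "b", "c", "d"),
                   x = c(0, 1, 10, 11), y = c(0, 0, 0, 0)),
    tibble::tibble(from = c("a", "c"), to = c("b", "d"), length_m = c(1, 1))
  )
  reg2 <- dplyr::mutate(reg, residence_x = c(0, 0, 0), residence_y = 0,
                        injury_x = c(1, 10, 0), injury_y = 0)
  expect_message(ann2 <- annotate_distances(reg2, split_net), "disconnected")
  expect_equal(ann2$unreachable, c(FALSE, TRUE, FALSE))
  expect_true(is.na(ann2$network_distance_m[2]))
  expect_equal(attr(ann2, "n_unreachable"), 1L)
})

test_that("GeoJSON line strings load with shared vertices merged", {
  gj <- jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", properties = NULL,
           geometry = list(type = "LineString",
                           coordinates = list(c(0, 0), c(100, 0), c(200, 0)))),
      list(type = "Feature", properties = NULL,
           geometry = list(type = "LineString",
                           coordinates = list(c(100, 0), c(100, 150))))
    )
  ), auto_unbox = TRUE)
  p <- withr::local_tempfile(fileext = ".geojson")
  writeLines(gj, p)
  net <- read_network_geojson(p)
  expect_equal(nrow(net$nodes), 4)  # the (100, 0) junction is shared
  expect_equal(nrow(net$edges), 3)
  a <- snap_to_network(0, 0, net)
  b <- snap_to_network(100, 150, net)
  expect_equal(network_distance(net, a, b), 250)
})
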