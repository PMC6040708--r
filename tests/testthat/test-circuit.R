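test_that("series and parallel resistor laws hold exactly", {
  chain <- conductance_graph(
    tibble::tibble(from = c(1, 2), to = c(2, 3), conductance = c(1, 1)), 3
  )
  expect_equal(effective_resistance(chain, 1, 3)$resistance_ohm, 2,
               tolerance = 1e-10)
  par2 <- conductance_graph(
    tibble::tibble(from = c(1, 1), to = c(2, 2), conductance = c(1, 1)), 2
  )
  expect_equal(effective_resistance(par2, 1, 2)$resistance_ohm, 0.5,
               tolerance = 1e-10)
  # mixed: two parallel branches of two 1-S edges each -> R = 1
  g <- conductance_graph(
    tibble::tibble(from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
                   conductance = 1), 4
  )
  expect_equal(effective_resistance(g, 1, 4)$resistance_ohm, 1,
               tolerance = 1e-10)
})

test_that("raster edges use mean cell conductance with the diagonal factor", {
  v <- matrix(Inf, 2, 2)
  v[1, 1] <- 0.01
  v[1, 2] <- 0.01
  g <- raster_to_graph(resistance_raster(v), 4)
  expect_equal(g$n_edges, 1)
  expect_equal(effective_resistance(g, 1, 2)$resistance_ohm, 1 / 100,
               tolerance = 1e-12)

  v[1, 2] <- 0.02 # mean of 100 and 50 S
  g2 <- raster_to_graph(resistance_raster(v), 4)
  expect_equal(effective_resistance(g2, 1, 2)$resistance_ohm, 1 / 75,
               tolerance = 1e-12)

  vd <- matrix(Inf, 2, 2)
  vd[1, 1] <- 0.01
  vd[2, 2] <- 0.01 # diagonal neighbours only
  g4 <- raster_to_graph(resistance_raster(vd), 4)
  expect_equal(max(g4$comp), 2) # not adjacent under 4-neighbourhood
  g8 <- raster_to_graph(resistance_raster(vd), 8)
  expect_equal(effective_resistance(g8, 1, 2)$resistance_ohm,
               sqrt(2) / 100, tolerance = 1e-12)
})

test_that("solver agrees with the dense pseudo-inverse oracle on a 3x3 grid", {
  v <- matrix(0.01, 3, 3)
  g <- raster_to_graph(resistance_raster(v), 4)
  corner_a <- g$nodes$node[g$nodes$row == 1 & g$nodes$col == 1]
  corner_b <- g$nodes$node[g$nodes$row == 3 & g$nodes$col == 3]
  got <- effective_resistance(g, corner_a, corner_b)$resistance_ohm
  edges <- tibble::tibble(
    from = g$L@i + 1L, to = rep(seq_len(g$n), diff(g$L@p)),
    conductance = -g$L@x
  )
  edges <- edges[edges$from < edges$to, ]
  oracle <- dense_resistance_oracle(edges, g$n, corner_a, corner_b)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("effective resistance is a metric and matches the oracle on random graphs", {
  withr::with_seed(101, {
    for (trial in 1:25) {
      n <- sample(4:30, 1)
      edges <- random_connected_graph(n)
      g <- conductance_graph(edges, n)
      nodes <- sample(n, 3)
      r <- outer(nodes, nodes, Vectorize(function(a, b) {
        if (a == b) 0 else effective_resistance(g, a, b)$resistance_ohm
      }))
      # symmetry, non-negativity, triangle inequality
      expect_equal(r, t(r), tolerance = 1e-9)
      expect_true(all(r >= 0))
      expect_lte(r[1, 3], r[1, 2] + r[2, 3] + 1e-9)
      # oracle agreement on one pair
      oracle <- dense_resistance_oracle(edges, n, nodes[1], nodes[2])
      expect_equal(r[1, 2], oracle, tolerance = 1e-8)
    }
  })
})

test_that("scaling all resistances by k scales every effective resistance by k", {
  withr::with_seed(7, {
    edges <- random_connected_graph(12)
    g1 <- conductance_graph(edges, 12)
    k <- 3.7
    edges2 <- edges
    edges2$conductance <- edges$conductance / k # resistance x k
    g2 <- conductance_graph(edges2, 12)
    for (pair in list(c(1, 5), c(2, 9))) {
      expect_equal(
        effective_resistance(g2, pair[1], pair[2])$resistance_ohm,
        k * effective_resistance(g1, pair[1], pair[2])$resistance_ohm,
        tolerance = 1e-9
      )
    }
  })
})

test_that("disconnected node pairs are flagged, not given numbers", {
  g <- conductance_graph(
    tibble::tibble(from = c(1, 3), to = c(2, 4), conductance = 1), 4
  )
  er <- effective_resistance(g, 1, 3)
  expect_false(er$connected)
  expect_true(is.na(er$resistance_ohm))
  expect_equal(effective_resistance(g, 2, 2)$resistance_ohm, 0)
})

test_that("pairwise resistance over a raster matches single-pair solves", {
  seg <- tibble::tibble(
    x1 = c(0, 0, 40), y1 = c(10, 10, 10), x2 = c(40, 0, 40),
    y2 = c(10, 40, 40), width_m = 2
  )
  r <- rasterize_lle(seg, extent = c(-5, 50, -5, 50))
  plots <- tibble::tibble(
    plot = c("p1", "p2", "p3"), area = 1,
    x = c(1, 20, 39), y = c(10, 10, 35)
  )
  pw <- pairwise_resistance(r, plots)
  expect_equal(nrow(pw), 3)
  g <- raster_to_graph(r)
  for (i in seq_len(3)) {
    na <- corrscape:::snap_plot_node(g, r, plots$x[match(pw$plot_a[i], plots$plot)],
                                     plots$y[match(pw$plot_a[i], plots$plot)], 5,
                                     pw$plot_a[i])
    nb <- corrscape:::snap_plot_node(g, r, plots$x[match(pw$plot_b[i], plots$plot)],
                                     plots$y[match(pw$plot_b[i], plots$plot)], 5,
                                     pw$plot_b[i])
    expect_equal(pw$resistance_ohm[i],
                 effective_resistance(g, na, nb)$resistance_ohm,
                 tolerance = 1e-8)
  }
})

test_that("an added parallel path strictly lowers effective resistance", {
  base <- tibble::tibble(x1 = 0, y1 = 10, x2 = 60, y2 = 10, width_m = 2)
  # detour: up at x=0, across at y=30, down at x=60
  extra <- tibble::tibble(
    x1 = c(0, 0, 60), y1 = c(10, 30, 10), x2 = c(0, 60, 60),
    y2 = c(30, 30, 30), width_m = 2
  )
  plots <- tibble::tibble(plot = c("a", "b"), area = 1, x = c(1, 59), y = 10)
  r1 <- rasterize_lle(base, extent = c(-5, 65, -5, 45))
  r2 <- rasterize_lle(rbind(base, extra), extent = c(-5, 65, -5, 45))
  p1 <- pairwise_resistance(r1, plots)
  p2 <- pairwise_resistance(r2, plots)
  expect_lt(p2$resistance_ohm, p1$resistance_ohm)
})

test_that("plots far from any conductive cell fail by name", {
  seg <- tibble::tibble(x1 = 0, y1 = 10, x2 = 40, y2 = 10, width_m = 2)
  r <- rasterize_lle(seg, extent = c(-5, 45, -5, 45))
  plots <- tibble::tibble(plot = c("ok", "lost"), area = 1,
                          x = c(5, 20), y = c(10, 40))
  expect_error(pairwise_resistance(r, plots), "lost")
})
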