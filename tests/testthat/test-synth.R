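test_that("landscape generation is reproducible and honours plot constraints", {
  cfg <- scaled_landscape_config(seed = 42)
  land1 <- generate_landscape(cfg)
  land2 <- generate_landscape(cfg)
  expect_identical(land1$segments, land2$segments)
  expect_identical(land1$plots, land2$plots)

  expect_equal(length(unique(land1$plots$area)), cfg$n_areas)
  counts <- table(land1$plots$area)
  expect_true(all(counts >= cfg$plots_per_area[1] & counts <= cfg$plots_per_area[2]))

  # pairwise spacing within areas
  for (a in unique(land1$plots$area)) {
    pl <- land1$plots[land1$plots$area == a, ]
    if (nrow(pl) < 2) next
    dmin <- min(dist(cbind(pl$x, pl$y)))
    expect_gte(dmin, cfg$min_plot_spacing_m)
  }
  # every plot sits on an element of >= 2 m width (on the rasterised grid)
  a <- unique(land1$plots$area)[1]
  seg <- land1$segments[land1$segments$area == a, ]
  pl <- land1$plots[land1$plots$area == a, ]
  r <- rasterize_lle(seg, extent = c(-20, 520, -20, 520))
  g <- raster_to_graph(r)
  for (i in seq_len(nrow(pl))) {
    d2 <- (g$nodes$x - pl$x[i])^2 + (g$nodes$y - pl$y[i])^2
    expect_lt(sqrt(min(d2)), 1) # nearest element cell centre within one cell
  }
})

test_that("generated LLE density matches the configured target", {
  cfg <- landscape_config(
    area_side_m = 500, n_areas = 2, lle_density_range = c(0.05, 0.05),
    min_plot_spacing_m = 50, buffer_m = 100, gap_rate = 0, seed = 9
  )
  land <- generate_landscape(cfg)
  for (a in 1:2) {
    seg <- land$segments[land$segments$area == a, ]
    r <- rasterize_lle(seg, extent = c(0, 500, 0, 500))
    dens <- mean(is.finite(r$values))
    expect_lt(abs(dens - 0.05), 0.01)
  }
})

test_that("without gaps each area rasterises to a single connected component", {
  cfg <- landscape_config(
    area_side_m = 500, n_areas = 2, gap_rate = 0,
    min_plot_spacing_m = 50, buffer_m = 100, seed = 4
  )
  land <- generate_landscape(cfg)
  for (a in 1:2) {
    seg <- land$segments[land$segments$area == a, ]
    r <- rasterize_lle(seg, extent = c(-60, 560, -60, 560))
    g <- raster_to_graph(r)
    expect_equal(max(g$comp), 1)
  }
})

test_that("infeasible plot placement fails naming the area", {
  cfg <- landscape_config(
    area_side_m = 200, n_areas = 1, min_plot_spacing_m = 190,
    plots_per_area = c(8, 8), buffer_m = 50, seed = 2
  )
  expect_error(generate_landscape(cfg), "area 1")
})

test_that("community simulation: initial draw, monotone growth, corridor limit", {
  land <- generate_landscape(
    landscape_config(area_side_m = 400, n_areas = 2, min_plot_spacing_m = 40,
                     buffer_m = 100, seed = 6)
  )
  lr <- landscape_resistance(land)

  cc0 <- community_config(n_generations = 0, seed = 11)
  rel0 <- simulate_communities(land$plots, cc0, lr$resistance)
  # generation zero equals the seeded Bernoulli draw
  occ_expect <- withr::with_seed(cc0$seed, {
    matrix(runif(nrow(land$plots) * nrow(cc0$species_pool)) < cc0$initial_occupancy,
           nrow(land$plots), nrow(cc0$species_pool))
  })
  expect_identical(unname(as.matrix(rel0[, -1]) == 1), occ_expect)
  expect_equal(mean(as.matrix(rel0[, -1])), cc0$initial_occupancy, tolerance = 0.1)

  # same seed, more generations: occupancy only grows
  ccN <- community_config(n_generations = 8, seed = 11)
  relN <- simulate_communities(land$plots, ccN, lr$resistance)
  expect_true(all(as.matrix(relN[, -1]) >= as.matrix(rel0[, -1])))

  # infinite corridor decay scale: corridor species fill every plot of a
  # connected area that contained at least one initial occurrence
  ccInf <- community_config(n_generations = 3, seed = 11,
                            lambda_corridor_m = 1e12, lambda_matrix_m = 1)
  relInf <- simulate_communities(land$plots, ccInf, lr$resistance)
  corr_sp <- ccInf$species_pool$species[
    ccInf$group_channel[ccInf$species_pool$dispersal_class] == "corridor"
  ]
  conn <- all(lr$resistance$connected)
  expect_true(conn) # this landscape is fully connected per area
  for (a in unique(land$plots$area)) {
    in_area <- land$plots$plot[land$plots$area == a]
    m0 <- as.matrix(rel0[match(in_area, rel0$plot), corr_sp])
    mI <- as.matrix(relInf[match(in_area, relInf$plot), corr_sp])
    seeded <- colSums(m0) > 0
    expect_true(all(colSums(mI)[seeded] == length(in_area)))
  }
})

test_that("matrix-channel species ignore Euclidean neighbours when their kernel vanishes", {
  land <- generate_landscape(
    landscape_config(area_side_m = 400, n_areas = 2, min_plot_spacing_m = 40,
                     buffer_m = 100, seed = 6)
  )
  lr <- landscape_resistance(land)
  cc <- community_config(n_generations = 6, seed = 3, lambda_matrix_m = 1e-9)
  rel <- simulate_communities(land$plots, cc, lr$resistance)
  cc0 <- community_config(n_generations = 0, seed = 3)
  rel0 <- simulate_communities(land$plots, cc0, lr$resistance)
  long_sp <- cc$species_pool$species[
    cc$group_channel[cc$species_pool$dispersal_class] == "matrix"
  ]
  # no colonisation at all for matrix-channel species: occupancy unchanged,
  # hence no dependence of their similarity on any distance
  expect_identical(rel[, long_sp], rel0[, long_sp])
})

test_that("species with an unmapped dispersal channel are rejected", {
  pool <- default_species_pool()
  expect_error(
    community_config(species_pool = pool,
                     group_channel = c(short = "corridor", medium = "corridor")),
    "long"
  )
})

test_that("segment and classification CSV round trips are identical", {
  land <- generate_landscape(
    landscape_config(area_side_m = 300, n_areas = 1, min_plot_spacing_m = 30,
                     buffer_m = 50, seed = 8)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_lle_segments(land$segments, f)
  back <- read_lle_segments(f)
  expect_equal(as.data.frame(back), as.data.frame(land$segments))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_species_classification(default_species_pool(), f2)
  expect_equal(as.data.frame(read_species_classification(f2)),
               as.data.frame(default_species_pool()))
})
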