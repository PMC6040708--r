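#' Per-area resistance rasters and pairwise resistance for a landscape
#'
#' Rasterises each study area's elements onto its own grid (the area square
#' plus the configured frame on all sides), applies the gap buffer, and
#' computes the effective resistance between all plot pairs of the area.
#'
#' @param landscape A `cs_landscape` from [generate_landscape()].
#' @param r_lle,r_buffer,buffer_dist_m Resistance parameterisation: element
#'   and gap-buffer cell resistance and the buffer distance.
#' @param neighborhood Cell neighbourhood for the conductance graph.
#' @param keep_rasters Return the per-area rasters (memory-heavy for large
#'   frames).
#' @return List with `resistance` (pair tibble across all areas) and, if
#'   requested, `rasters` (named list of [resistance_raster()]).
#' @export
landscape_resistance <- function(landscape, r_lle = 0.01, r_buffer = 0.02,
                                 buffer_dist_m = 5, neighborhood = 8,
                                 keep_rasters = FALSE) {
  stopifnot(inherits(landscape, "cs_landscape"))
  cfg <- landscape$config
  extent <- c(-cfg$buffer_m, cfg$area_side_m + cfg$buffer_m,
              -cfg$buffer_m, cfg$area_side_m + cfg$buffer_m)
  areas <- sort(unique(landscape$plots$area))
  rasters <- list()
  res <- purrr::map(areas, function(a) {
    seg <- filter(landscape$segments, .data$area == a)
    pl <- filter(landscape$plots, .data$area == a)
    r <- rasterize_lle(seg, cell_m = cfg$cell_m, extent = extent, r_lle = r_lle)
    r <- apply_gap_buffers(r, buffer_m = buffer_dist_m,
                           r_lle = r_lle, r_buffer = r_buffer)
    if (keep_rasters) rasters[[as.character(a)]] <<- r
    pairwise_resistance(r, pl, neighborhood = neighborhood)
  })
  out <- list(resistance = purrr::list_rbind(res))
  if (keep_rasters) out$rasters <- rasters
  out
}

#' Run the full synthetic corridor-dispersal pipeline
#'
#' Chains all stages on generated data: landscape generation, resistance
#' rasterisation and circuit-theory pairwise resistance, community
#' simulation, and assembly of the plot-pair table with group-wise Jaccard
#' similarities. The result feeds directly into
#' [compare_isolation_models()] and [table2_report()].
#'
#' @param lconf A [landscape_config()].
#' @param cconf A [community_config()]; its seed is re-derived from the
#'   landscape seed unless the configuration was built with an explicit one.
#' @param ... Passed to [landscape_resistance()].
#' @return A `cs_run` list: `landscape`, `resistance`, `releves`,
#'   `pair_table`, `classification`.
#' @export
#' @examples
#' \donttest{
#' lconf <- landscape_config(area_side_m = 300, n_areas = 3,
#'                           min_plot_spacing_m = 50, buffer_m = 100, seed = 3)
#' run <- run_pipeline(lconf, community_config(seed = 3))
#' head(run$pair_table)
#' }
run_pipeline <- function(lconf, cconf = community_config(seed = lconf$seed), ...) {
  landscape <- generate_landscape(lconf)
  lr <- landscape_resistance(landscape, ...)
  releves <- simulate_communities(landscape$plots, cconf, lr$resistance)
  pair_table <- build_pair_table(releves, cconf$species_pool,
                                 landscape$plots, lr$resistance)
  structure(
    list(landscape = landscape, resistance = lr$resistance,
         releves = releves, pair_table = pair_table,
         classification = cconf$species_pool),
    class = "cs_run"
  )
}

#' @export
print.cs_run <- function(x, ...) {
  cat(sprintf(
    "<cs_run> %d plots, %d pairs (%d connected), %d species\n",
    nrow(x$landscape$plots),
    nrow(distinct(x$pair_table, .data$plot_a, .data$plot_b)),
    sum(distinct(x$pair_table, .data$plot_a, .data$plot_b,
                 .keep_all = TRUE)$connected),
    nrow(x$classification)
  ))
  invisible(x)
}
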