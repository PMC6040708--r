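#' Default synthetic species pool
#'
#' A fixed pool of 106 pseudo-species spread over the phytosociological groups
#' and terrestrial dispersal-distance classes the analysis distinguishes.
#' Group sizes lean towards grassland communities (meadows and pastures) as in
#' mesic agricultural landscapes; species of aquatic communities, fens and
#' bogs, and part of the wet-grassland species carry the aquatic-dispersal
#' flag, which overlaps the terrestrial classes.
#'
#' @return Tibble with columns `species`, `group`, `dispersal_class`
#'   (`short`, `medium`, `long`) and `aquatic` (0/1).
#' @export
#' @examples
#' dplyr::count(default_species_pool(), group, dispersal_class)
default_species_pool <- function() {
  counts <- tibble::tribble(
    ~group,                 ~short, ~medium, ~long,
    "meadows-pastures",         12,      10,     6,
    "tall-herb",                 4,       8,     4,
    "weeds-trackside",           3,       5,     8,
    "wet-grassland",             4,       4,     2,
    "aquatic-fens-bogs",         4,       2,     1,
    "poor-grassland-heath",      2,       2,     1,
    "none",                      6,       8,    10
  )
  long <- tidyr::pivot_longer(counts, -"group", names_to = "dispersal_class",
                              values_to = "n")
  pool <- tidyr::uncount(long, weights = .data$n)
  pool$species <- sprintf("sp%03d", seq_len(nrow(pool)))
  pool$aquatic <- as.integer(
    pool$group == "aquatic-fens-bogs" |
      (pool$group == "wet-grassland" & pool$dispersal_class == "short")
  )
  pool[, c("species", "group", "dispersal_class", "aquatic")]
}

#' Configuration for the synthetic community simulator
#'
#' The simulator seeds each plot with a sparse random community and then lets
#' species spread between plots of the same study area with a
#' distance-decaying per-generation colonisation kernel. Which isolation
#' measure drives a species is set per dispersal class: corridor-channel
#' species (short and medium terrestrial dispersal by default) respond to
#' resistance distance along the element network, matrix-channel species
#' (long-distance dispersal) to Euclidean distance, and `both` takes the more
#' permissive of the two.
#'
#' @param species_pool Species classification tibble (see
#'   [default_species_pool()]).
#' @param initial_occupancy Probability that a species is present in a plot at
#'   generation zero.
#' @param n_generations Number of colonisation generations.
#' @param lambda_corridor_m Decay scale (m) of the corridor-channel kernel,
#'   applied to the metre-equivalent of resistance distance. The default
#'   (`NULL`) self-calibrates at simulation time to a fifth of the median
#'   pairwise corridor distance, so the kernel spans the isolation range of
#'   the landscape at any problem size.
#' @param lambda_matrix_m Decay scale (m) of the matrix-channel kernel,
#'   applied to Euclidean distance; `NULL` self-calibrates like the corridor
#'   scale.
#' @param group_channel Named character vector mapping dispersal classes to
#'   channels (`corridor`, `matrix`, `both`).
#' @param resistance_scale_m_per_ohm Conversion from effective resistance
#'   (ohm) to a metre-equivalent corridor length, so that the corridor and
#'   matrix kernels operate on commensurate scales. One ohm of effective
#'   resistance corresponds to roughly 8 km of typical corridor
#'   cross-section (about 3.5 m of element at conductivity 100 plus 10 m of
#'   flanking buffer at 50, times the path multiplicity of a connected
#'   network); under default densities this maps the median pairwise
#'   resistance onto the median Euclidean plot separation.
#' @param seed Integer seed.
#'
#' @return A `cs_community_config` list.
#' @export
community_config <- function(species_pool = default_species_pool(),
                             initial_occupancy = 0.15,
                             n_generations = 8,
                             lambda_corridor_m = NULL,
                             lambda_matrix_m = NULL,
                             group_channel = c(short = "corridor",
                                               medium = "corridor",
                                               long = "matrix"),
                             resistance_scale_m_per_ohm = 8000,
                             seed = 1) {
  stopifnot(is.data.frame(species_pool))
  need <- c("species", "group", "dispersal_class")
  if (!all(need %in% names(species_pool))) {
    abort("`species_pool` needs columns species, group, dispersal_class.")
  }
  if (anyDuplicated(species_pool$species)) {
    abort("every species must map to exactly one group and dispersal class")
  }
  if (initial_occupancy < 0 || initial_occupancy > 1) {
    abort("`initial_occupancy` must be a probability.")
  }
  for (lam in list(lambda_corridor_m, lambda_matrix_m)) {
    if (!is.null(lam) && lam <= 0) abort("decay scales must be > 0")
  }
  if (!all(group_channel %in% c("corridor", "matrix", "both"))) {
    abort("`group_channel` values must be corridor, matrix or both")
  }
  missing_cls <- setdiff(unique(species_pool$dispersal_class), names(group_channel))
  if (length(missing_cls) > 0) {
    abort(paste0("no channel mapped for dispersal class: ",
                 paste(missing_cls, collapse = ", ")))
  }
  if (!"aquatic" %in% names(species_pool)) species_pool$aquatic <- 0L
  structure(
    list(
      species_pool = as_tibble(species_pool),
      initial_occupancy = initial_occupancy,
      n_generations = as.integer(n_generations),
      lambda_corridor_m = lambda_corridor_m,
      lambda_matrix_m = lambda_matrix_m,
      group_channel = group_channel,
      resistance_scale_m_per_ohm = resistance_scale_m_per_ohm,
      seed = as.integer(seed)
    ),
    class = "cs_community_config"
  )
}

#' Simulate plant communities spreading along corridors
#'
#' Starting from independent Bernoulli occupancies, each species colonises
#' unoccupied plots of the same study area from every occupied plot with
#' per-generation probability `exp(-d / lambda)`, where `d` is the
#' metre-equivalent resistance distance for corridor-channel species, the
#' Euclidean distance for matrix-channel species, and the channel-wise maximum
#' of the two probabilities for `both`. Colonisation attempts from different
#' source plots are independent. No extinction is modelled, so occupancy is
#' monotone non-decreasing over generations.
#'
#' @param plots Plot metadata tibble (`plot`, `area`, `x`, `y`, ...).
#' @param cconf A [community_config()] object.
#' @param resist_pairs Pairwise resistance tibble with columns `plot_a`,
#'   `plot_b`, `resistance_ohm` and logical `connected`, e.g. from
#'   [pairwise_resistance()]. Disconnected pairs never exchange
#'   corridor-channel colonists.
#'
#' @return Wide presence/absence tibble: first column `plot`, one 0/1 column
#'   per species.
#' @export
simulate_communities <- function(plots, cconf, resist_pairs) {
  stopifnot(inherits(cconf, "cs_community_config"))
  pool <- cconf$species_pool
  channel <- unname(cconf$group_channel[pool$dispersal_class])
  if (anyNA(channel)) abort("species with unknown dispersal channel")

  np <- nrow(plots)
  ns <- nrow(pool)
  d_eucl <- as.matrix(stats::dist(cbind(plots$x, plots$y)))
  # cross-area colonisation is off: infinite distance outside the study area
  same_area <- outer(plots$area, plots$area, `==`)
  d_eucl[!same_area] <- Inf

  d_corr <- matrix(Inf, np, np)
  ia <- match(resist_pairs$plot_a, plots$plot)
  ib <- match(resist_pairs$plot_b, plots$plot)
  ok <- !is.na(ia) & !is.na(ib) & resist_pairs$connected
  dval <- resist_pairs$resistance_ohm[ok] * cconf$resistance_scale_m_per_ohm
  d_corr[cbind(ia[ok], ib[ok])] <- dval
  d_corr[cbind(ib[ok], ia[ok])] <- dval
  diag(d_corr) <- 0

  lam_c <- cconf$lambda_corridor_m %||%
    (stats::median(d_corr[is.finite(d_corr) & d_corr > 0]) / 5)
  lam_m <- cconf$lambda_matrix_m %||%
    (stats::median(d_eucl[is.finite(d_eucl) & d_eucl > 0]) / 5)
  p_corr <- exp(-d_corr / lam_c)
  p_eucl <- exp(-d_eucl / lam_m)
  diag(p_corr) <- 0
  diag(p_eucl) <- 0

  occ <- withr::with_seed(cconf$seed, {
    occ <- matrix(runif(np * ns) < cconf$initial_occupancy, np, ns)
    for (gen in seq_len(cconf$n_generations)) {
      for (s in seq_len(ns)) {
        src <- occ[, s]
        if (!any(src) || all(src)) next
        p_pair <- switch(channel[s],
          corridor = p_corr,
          matrix = p_eucl,
          both = pmax(p_corr, p_eucl)
        )
        # independent attempts from every occupied source plot
        miss <- 1 - p_pair[src, !src, drop = FALSE]
        p_col <- 1 - apply(miss, 2, prod)
        occ[!src, s][runif(length(p_col)) < p_col] <- TRUE
      }
    }
    occ
  })

  out <- as_tibble(matrix(as.integer(occ), np, ns,
                          dimnames = list(NULL, pool$species)))
  dplyr::bind_cols(tibble(plot = plots$plot), out)
}

#' Write or read a relevé presence/absence matrix as CSV
#'
#' @param releves Wide tibble, first column `plot`, one 0/1 column per species.
#' @param path File path.
#' @return `read_releves()` returns the relevé tibble.
#' @export
write_releves <- function(releves, path) {
  readr::write_csv(releves, path)
  invisible(path)
}

#' @rdname write_releves
#' @export
read_releves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write or read a species classification table as CSV
#'
#' Columns `species`, `group`, `dispersal_class`, `aquatic` (0/1).
#'
#' @param classification Species classification tibble.
#' @param path File path.
#' @return `read_species_classification()` returns the classification tibble.
#' @export
write_species_classification <- function(classification, path) {
  readr::write_csv(classification, path)
  invisible(path)
}

#' @rdname write_species_classification
#' @export
read_species_classification <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species = readr::col_character(),
                    group = readr::col_character(),
                    dispersal_class = readr::col_character(),
                    aquatic = readr::col_integer()
                  ))
}
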