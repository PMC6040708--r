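#' Jaccard similarity of two species sets
#'
#' `J = c / S`, where `c` is the number of species common to both plots and
#' `S` the total (union) number of species of the pair. A pair with an empty
#' union (`S = 0`) has no defined similarity and is marked `NA`.
#'
#' @param species_a,species_b Character vectors of species present in each
#'   plot.
#' @return One-row tibble with `c`, `S`, `J`.
#' @export
#' @examples
#' jaccard(c("x", "y", "z"), c("y", "z", "w")) # c = 2, S = 4, J = 0.5
jaccard <- function(species_a, species_b) {
  species_a <- unique(species_a)
  species_b <- unique(species_b)
  c_ <- length(intersect(species_a, species_b))
  s_ <- length(union(species_a, species_b))
  tibble(c = c_, S = s_, J = if (s_ == 0) NA_real_ else c_ / s_)
}

# the species-set definitions used throughout: "all", one per
# phytosociological group, one per dispersal class, and the aquatic overlap
species_set_members <- function(classification) {
  sets <- list(all = classification$species)
  for (g in sort(unique(classification$group))) {
    if (g == "none") next
    sets[[paste0("group:", g)]] <-
      classification$species[classification$group == g]
  }
  for (d in intersect(c("short", "medium", "long"),
                      unique(classification$dispersal_class))) {
    sets[[paste0("dispersal:", d)]] <-
      classification$species[classification$dispersal_class == d]
  }
  if ("aquatic" %in% names(classification) && any(classification$aquatic == 1)) {
    sets[["aquatic-dispersal"]] <-
      classification$species[classification$aquatic == 1]
  }
  sets
}

#' Build the within-area plot-pair table
#'
#' The central observation table of the analysis: one row per unordered
#' within-area plot pair and species set, carrying the pair's LLE-type
#' combination, Euclidean distance, effective resistance, and the Jaccard
#' components `c` (shared species), `S` (union size) and `J = c/S` computed
#' over the species of that set. Species sets are: all recorded species
#' (classified or not), each phytosociological group, each dispersal-distance
#' class, and the aquatic-dispersal overlap class. Pairs whose union is empty
#' for a set keep the row with `J = NA` so they can be dropped per model, not
#' globally; pairs disconnected on the resistance raster keep `resistance_ohm
#' = NA` with `connected = FALSE`.
#'
#' @param releves Wide presence/absence tibble (first column `plot`).
#' @param classification Species classification tibble (`species`, `group`,
#'   `dispersal_class`, `aquatic`). Species present in the relevés but absent
#'   here only enter the `all` set.
#' @param plots Plot metadata (`plot`, `area`, `lle_type`, `x`, `y`).
#' @param resistance Pair resistance tibble from [pairwise_resistance()]
#'   (may cover several areas row-bound together).
#' @return Long tibble: `area`, `plot_a`, `plot_b`, `lle_combo`, `euclid_m`,
#'   `resistance_ohm`, `connected`, `species_set`, `c`, `S`, `J`.
#' @export
build_pair_table <- function(releves, classification, plots, resistance) {
  sp_cols <- setdiff(names(releves), "plot")
  missing_plots <- setdiff(releves$plot, plots$plot)
  if (length(missing_plots) > 0) {
    abort(paste0("plots in releves without coordinates: ",
                 paste(missing_plots, collapse = ", ")))
  }
  pres <- as.matrix(releves[, sp_cols]) > 0
  rownames(pres) <- releves$plot

  sets <- species_set_members(classification)
  set_idx <- purrr::map(sets, ~ which(sp_cols %in% .x))
  set_idx$all <- seq_along(sp_cols) # "all" includes unclassified species

  pair_rows <- plots |>
    split(plots$area) |>
    purrr::map(function(d) {
      if (nrow(d) < 2) return(NULL)
      pr <- t(combn(nrow(d), 2))
      tibble(area = d$area[1], plot_a = d$plot[pr[, 1]], plot_b = d$plot[pr[, 2]])
    }) |>
    purrr::list_rbind()

  meta <- plots |> select("plot", "lle_type", "x", "y")
  pair_rows <- pair_rows |>
    left_join(rename(meta, plot_a = "plot", type_a = "lle_type",
                     xa = "x", ya = "y"), by = "plot_a") |>
    left_join(rename(meta, plot_b = "plot", type_b = "lle_type",
                     xb = "x", yb = "y"), by = "plot_b") |>
    mutate(
      lle_combo = factor(lle_combo_label(.data$type_a, .data$type_b),
                         levels = lle_combo_levels),
      euclid_m = sqrt((.data$xa - .data$xb)^2 + (.data$ya - .data$yb)^2)
    ) |>
    select("area", "plot_a", "plot_b", "lle_combo", "euclid_m")

  res_key <- resistance |>
    mutate(
      key = paste(pmin(.data$plot_a, .data$plot_b),
                  pmax(.data$plot_a, .data$plot_b))
    ) |>
    select("key", "resistance_ohm", "connected")
  pair_rows <- pair_rows |>
    mutate(key = paste(pmin(.data$plot_a, .data$plot_b),
                       pmax(.data$plot_a, .data$plot_b))) |>
    left_join(res_key, by = "key") |>
    select(-"key") |>
    mutate(connected = dplyr::coalesce(.data$connected, FALSE))

  per_set <- purrr::imap(set_idx, function(idx, set_name) {
    pa <- pres[pair_rows$plot_a, idx, drop = FALSE]
    pb <- pres[pair_rows$plot_b, idx, drop = FALSE]
    c_ <- rowSums(pa & pb)
    s_ <- rowSums(pa | pb)
    tibble(
      pair_row = seq_len(nrow(pair_rows)),
      species_set = set_name,
      c = as.integer(c_),
      S = as.integer(s_),
      J = unname(ifelse(s_ == 0, NA_real_, c_ / s_))
    )
  })
  out <- purrr::list_rbind(per_set)
  out <- dplyr::bind_cols(pair_rows[out$pair_row, ], out[, -1])
  arrange(out, .data$species_set, .data$area, .data$plot_a, .data$plot_b)
}

#' Choose the response coding for a species set
#'
#' Jaccard similarity enters the models as binomial proportion data
#' (successes `c` of `S` trials) by default. Sets with many empty pairs are
#' instead coded as binary presence of any shared species (`0` if `J = 0`,
#' `1` if `J > 0`); the switch is automatic when the fraction of zero-`J`
#' rows (among defined rows) exceeds `zero_threshold`.
#'
#' @param pair_table Output of [build_pair_table()].
#' @param species_set Name of the species set.
#' @param zero_threshold Zero fraction above which binary coding is chosen.
#' @return `"proportion"` or `"binary"`.
#' @export
code_response <- function(pair_table, species_set, zero_threshold = 0.5) {
  j <- pair_table$J[pair_table$species_set == species_set]
  j <- j[!is.na(j)]
  if (length(j) == 0) return("binary")
  if (mean(j == 0) > zero_threshold) "binary" else "proportion"
}

#' z-transform with stored back-transformation
#'
#' Centres and scales to sample standard deviation one (n - 1 denominator),
#' keeping the parameters as attributes so model predictions can be made at
#' values on the original data scale.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Numeric vector with attributes `center` and `scale`.
#' @seealso [z_back()]
#' @export
#' @examples
#' z_transform(c(1, 2, 3))
z_transform <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2 || sd(values[ok]) == 0) {
    abort("z_transform needs >= 2 distinct finite values")
  }
  ctr <- mean(values[ok])
  scl <- sd(values[ok])
  structure((values - ctr) / scl, center = ctr, scale = scl)
}

#' @rdname z_transform
#' @param z A vector produced by [z_transform()].
#' @export
z_back <- function(z) {
  as.numeric(z) * attr(z, "scale") + attr(z, "center")
}

#' Correlation between resistance and Euclidean distance
#'
#' Pearson correlation over the connected within-area plot pairs, with the
#' two-tailed test. A moderate correlation is expected: resistance distance
#' grows with separation but also reflects the number and quality of
#' connecting elements.
#'
#' @param pair_table Output of [build_pair_table()].
#' @return One-row tibble `r`, `p`, `n`.
#' @export
correlation_check <- function(pair_table) {
  pairs <- pair_table |>
    distinct(.data$area, .data$plot_a, .data$plot_b, .keep_all = TRUE) |>
    filter(.data$connected)
  if (nrow(pairs) < 3) abort("need >= 3 connected pairs")
  ct <- cor.test(pairs$resistance_ohm, pairs$euclid_m, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Plot group-wise distance decay of similarity
#'
#' Jaccard similarity against an isolation measure, faceted by LLE-type
#' combination, with a binomial-GLM smoother per panel.
#'
#' @param pair_table Output of [build_pair_table()].
#' @param species_set Species set to show.
#' @param measure `"resistance"` or `"euclidean"`.
#' @return A ggplot object.
#' @export
plot_distance_decay <- function(pair_table, species_set = "all",
                                measure = c("resistance", "euclidean")) {
  measure <- match.arg(measure)
  df <- pair_table |>
    filter(.data$species_set == !!species_set, !is.na(.data$J))
  if (measure == "resistance") df <- filter(df, .data$connected)
  df$iso <- if (measure == "resistance") df$resistance_ohm else df$euclid_m
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iso, y = .data$J)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "glm", formula = y ~ x,
                         method.args = list(family = stats::quasibinomial()),
                         se = FALSE, colour = "steelblue") +
    ggplot2::facet_wrap(~lle_combo) +
    ggplot2::labs(
      x = if (measure == "resistance") "resistance distance (ohm)"
          else "Euclidean distance (m)",
      y = "Jaccard similarity",
      title = paste0("Distance decay: ", species_set)
    ) +
    ggplot2::theme_minimal()
}
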