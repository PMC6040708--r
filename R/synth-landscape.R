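#' Configuration for the synthetic landscape generator
#'
#' Defines the sampling frame the generator emulates: square study areas with a
#' network of linear landscape elements (LLE) laid along the boundaries of a
#' random rectangular field mosaic, and vegetation plots placed on the
#' elements. Defaults follow the study design the analysis targets: eight
#' 1-km-square areas, LLE areal density between 2.5 and 10 per cent, element
#' widths of 2 to 5 m, 5 to 8 plots per area at a minimum spacing of 100 m,
#' and a 500-m frame around each area so that effective resistance is not
#' biased at the boundary.
#'
#' @param area_side_m Side length of each square study area in metres.
#' @param cell_m Raster cell size in metres.
#' @param n_areas Number of study areas.
#' @param lle_density_range Length-2 numeric, range of the LLE areal fraction
#'   of a study area from which each area's target density is drawn.
#' @param margin_width_range_m Length-2 numeric, element width range in metres.
#' @param ditch_fraction Probability that a selected element is a ditch rather
#'   than a field margin.
#' @param gap_rate Expected number of gaps per km of generated LLE.
#' @param gap_length_range_m Length-2 numeric, gap length range in metres.
#'   The default mixes gaps below and above the 10-m threshold that the
#'   5-m gap buffer can close.
#' @param plots_per_area Length-2 integer, inclusive range of plots per area.
#' @param min_plot_spacing_m Minimum distance between plots of one area.
#' @param buffer_m Width of the frame around each study area that the
#'   resistance raster must cover.
#' @param seed Integer run seed; all per-area and per-stage randomness is
#'   derived from it deterministically.
#'
#' @return A `cs_landscape_config` list.
#' @export
#' @examples
#' cfg <- landscape_config(n_areas = 2, seed = 42)
landscape_config <- function(area_side_m = 1000,
                             cell_m = 1,
                             n_areas = 8,
                             lle_density_range = c(0.025, 0.10),
                             margin_width_range_m = c(2, 5),
                             ditch_fraction = 0.4,
                             gap_rate = 1,
                             gap_length_range_m = c(4, 15),
                             plots_per_area = c(5, 8),
                             min_plot_spacing_m = 100,
                             buffer_m = 500,
                             seed = 1) {
  stopifnot(
    area_side_m > 0, cell_m > 0, n_areas >= 1,
    length(lle_density_range) == 2, length(margin_width_range_m) == 2,
    length(gap_length_range_m) == 2, length(plots_per_area) == 2
  )
  if (any(lle_density_range <= 0) || any(lle_density_range >= 1)) {
    abort("`lle_density_range` must lie strictly within (0, 1).")
  }
  if (min_plot_spacing_m < 0) abort("`min_plot_spacing_m` must be >= 0.")
  if (plots_per_area[1] < 1 || plots_per_area[2] > 20) {
    abort("`plots_per_area` must lie within [1, 20].")
  }
  if (ditch_fraction < 0 || ditch_fraction > 1) {
    abort("`ditch_fraction` must be a probability.")
  }
  if (gap_rate < 0) abort("`gap_rate` must be >= 0.")
  structure(
    list(
      area_side_m = area_side_m, cell_m = cell_m, n_areas = n_areas,
      lle_density_range = sort(lle_density_range),
      margin_width_range_m = sort(margin_width_range_m),
      ditch_fraction = ditch_fraction,
      gap_rate = gap_rate,
      gap_length_range_m = sort(gap_length_range_m),
      plots_per_area = sort(as.integer(plots_per_area)),
      min_plot_spacing_m = min_plot_spacing_m,
      buffer_m = buffer_m,
      seed = as.integer(seed)
    ),
    class = "cs_landscape_config"
  )
}

#' Generate a synthetic landscape of linear elements and vegetation plots
#'
#' For each study area, draws a rectangular field mosaic (Poisson-spaced
#' vertical and horizontal boundary lines), grows a connected subset of the
#' boundary segments until the target LLE areal density is reached, assigns
#' widths and element types (margin or ditch), deletes gap intervals at the
#' configured rate, and finally places vegetation plots on elements at least
#' 2 m wide while honouring the minimum plot spacing. Lines overhang the
#' study-area boundary so the element network extends into the surrounding
#' frame.
#'
#' @param config A [landscape_config()] object.
#'
#' @return A `cs_landscape` list with elements
#'   \describe{
#'     \item{segments}{tibble of LLE centrelines: `area`, `seg_id`, `x1`,
#'       `y1`, `x2`, `y2`, `width_m`, `lle_type`.}
#'     \item{plots}{tibble of plot metadata: `plot`, `area`, `lle_type`,
#'       `x`, `y`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' land <- generate_landscape(landscape_config(n_areas = 1, area_side_m = 400,
#'   min_plot_spacing_m = 40, seed = 7))
#' nrow(land$plots)
generate_landscape <- function(config) {
  stopifnot(inherits(config, "cs_landscape_config"))
  areas <- purrr::map(seq_len(config$n_areas), function(a) {
    # plot placement can fail on an unlucky sparse mosaic; retry the area a
    # bounded, deterministic number of times before reporting infeasibility
    for (attempt in 1:3) {
      out <- tryCatch(
        withr::with_seed(child_seed(config$seed, a * 101 + attempt),
                         generate_area(config, a)),
        error = function(e) e
      )
      if (!inherits(out, "error")) return(out)
    }
    stop(out)
  })
  structure(
    list(
      segments = purrr::list_rbind(purrr::map(areas, "segments")),
      plots = purrr::list_rbind(purrr::map(areas, "plots")),
      config = config
    ),
    class = "cs_landscape"
  )
}

# one study area; called inside a seeded context
generate_area <- function(config, area_id) {
  side <- config$area_side_m
  overhang <- min(50, config$buffer_m)
  lo <- -overhang
  hi <- side + overhang

  target_density <- runif(1, config$lle_density_range[1], config$lle_density_range[2])
  wbar <- mean(config$margin_width_range_m)
  spacing <- wbar / target_density # gives ~2x the needed boundary length

  xs <- poisson_positions(lo, hi, spacing)
  ys <- poisson_positions(lo, hi, spacing)

  seg <- mosaic_segments(xs, ys, lo, hi)
  seg$width_m <- runif(nrow(seg), config$margin_width_range_m[1],
                       config$margin_width_range_m[2])

  sel <- grow_connected(seg, target_area = target_density * side^2, side = side)
  if (attr(sel, "achieved_area") < 0.8 * target_density * side^2) {
    warn(sprintf(
      "area %d: boundary mosaic exhausted at LLE density %.3f (target %.3f)",
      area_id, attr(sel, "achieved_area") / side^2, target_density
    ))
  }
  attr(sel, "achieved_area") <- NULL
  sel$lle_type <- ifelse(runif(nrow(sel)) < config$ditch_fraction, "ditch", "margin")

  sel <- insert_gaps(sel, config)
  sel$area <- area_id
  sel$seg_id <- seq_len(nrow(sel))

  plots <- place_plots(sel, config, area_id, side)

  list(
    segments = as_tibble(sel[, c("area", "seg_id", "x1", "y1", "x2", "y2",
                                 "width_m", "lle_type")]),
    plots = plots
  )
}

# Poisson process positions on [lo, hi] with mean spacing; guarantees >= 2
poisson_positions <- function(lo, hi, spacing) {
  n_max <- ceiling((hi - lo) / spacing * 4) + 10
  pos <- lo + cumsum(rexp(n_max, rate = 1 / spacing))
  pos <- pos[pos < hi]
  if (length(pos) < 2) pos <- seq(lo + spacing / 2, hi, by = spacing)[1:2]
  pos
}

# split full-span vertical/horizontal lines into inter-crossing segments
mosaic_segments <- function(xs, ys, lo, hi) {
  ybreaks <- sort(unique(c(lo, ys, hi)))
  xbreaks <- sort(unique(c(lo, xs, hi)))
  vert <- purrr::list_rbind(purrr::map(xs, function(x) {
    tibble(x1 = x, y1 = head(ybreaks, -1), x2 = x, y2 = ybreaks[-1])
  }))
  horiz <- purrr::list_rbind(purrr::map(ys, function(y) {
    tibble(x1 = head(xbreaks, -1), y1 = y, x2 = xbreaks[-1], y2 = y)
  }))
  seg <- bind_rows(vert, horiz)
  seg$len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  seg[seg$len > 0.5, , drop = FALSE]
}

# parametric clip of segments to the core square [0, side]^2: returns the
# t-interval of the centreline inside the core (NA if it misses the core)
clip_to_core <- function(seg, side) {
  n <- nrow(seg)
  t0 <- rep(0, n)
  t1 <- rep(1, n)
  for (dim in list(c("x1", "x2"), c("y1", "y2"))) {
    p1 <- seg[[dim[1]]]
    p2 <- seg[[dim[2]]]
    d <- p2 - p1
    flat <- abs(d) < 1e-12
    # slab [0, side] in this dimension
    ta <- ifelse(flat, ifelse(p1 >= 0 & p1 <= side, 0, NA_real_), (0 - p1) / d)
    tb <- ifelse(flat, ifelse(p1 >= 0 & p1 <= side, 1, NA_real_), (side - p1) / d)
    lohi <- cbind(pmin(ta, tb), pmax(ta, tb))
    t0 <- pmax(t0, lohi[, 1])
    t1 <- pmin(t1, lohi[, 2])
  }
  bad <- is.na(t0) | is.na(t1) | t0 >= t1
  t0[bad] <- NA_real_
  t1[bad] <- NA_real_
  list(t0 = t0, t1 = t1)
}

# length of each segment's centreline inside the core square
core_length <- function(seg, side) {
  cl <- clip_to_core(seg, side)
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  out <- (cl$t1 - cl$t0) * len
  ifelse(is.na(out), 0, out)
}

# grow a connected subgraph of mosaic segments until the target LLE area
# (within the core square) is reached
grow_connected <- function(seg, target_area, side) {
  nkey <- function(x, y) paste(round(x, 6), round(y, 6))
  k1 <- nkey(seg$x1, seg$y1)
  k2 <- nkey(seg$x2, seg$y2)
  seg$core_len <- core_length(seg, side)
  seg$core_area <- seg$core_len * seg$width_m

  n_seg <- nrow(seg)
  selected <- logical(n_seg)
  # start near the centre so growth reaches the core first
  mid_x <- (seg$x1 + seg$x2) / 2
  mid_y <- (seg$y1 + seg$y2) / 2
  d_centre <- (mid_x - side / 2)^2 + (mid_y - side / 2)^2
  start <- which.min(d_centre)
  selected[start] <- TRUE
  nodes <- new.env(parent = emptyenv())
  assign(k1[start], TRUE, envir = nodes)
  assign(k2[start], TRUE, envir = nodes)
  area_acc <- seg$core_area[start]

  # incidence: segments per node key
  by_node <- split(rep(seq_len(n_seg), 2L), c(k1, k2))

  frontier <- setdiff(unlist(by_node[c(k1[start], k2[start])], use.names = FALSE), start)
  while (area_acc < target_area && length(frontier) > 0) {
    pick <- frontier[sample.int(length(frontier), 1)]
    frontier <- frontier[frontier != pick]
    if (selected[pick]) next
    selected[pick] <- TRUE
    area_acc <- area_acc + seg$core_area[pick]
    for (k in c(k1[pick], k2[pick])) {
      if (!isTRUE(get0(k, envir = nodes))) {
        assign(k, TRUE, envir = nodes)
        inc <- by_node[[k]]
        frontier <- c(frontier, inc[!selected[inc]])
      }
    }
  }
  out <- seg[selected, c("x1", "y1", "x2", "y2", "width_m"), drop = FALSE]
  attr(out, "achieved_area") <- area_acc
  out
}

# delete gap intervals from selected segments at gap_rate per km
insert_gaps <- function(sel, config) {
  if (config$gap_rate <= 0 || nrow(sel) == 0) return(sel)
  total_km <- sum(sqrt((sel$x2 - sel$x1)^2 + (sel$y2 - sel$y1)^2)) / 1000
  n_gaps <- rpois(1, config$gap_rate * total_km)
  for (g in seq_len(n_gaps)) {
    len <- sqrt((sel$x2 - sel$x1)^2 + (sel$y2 - sel$y1)^2)
    i <- sample.int(nrow(sel), 1, prob = len)
    glen <- runif(1, config$gap_length_range_m[1], config$gap_length_range_m[2])
    if (glen >= len[i] - 2) { # segment too short: remove it entirely
      sel <- sel[-i, , drop = FALSE]
      next
    }
    t0 <- runif(1, 0, len[i] - glen) / len[i]
    t1 <- t0 + glen / len[i]
    s <- sel[i, ]
    dx <- s$x2 - s$x1
    dy <- s$y2 - s$y1
    left <- s
    left$x2 <- s$x1 + t0 * dx
    left$y2 <- s$y1 + t0 * dy
    right <- s
    right$x1 <- s$x1 + t1 * dx
    right$y1 <- s$y1 + t1 * dy
    pieces <- rbind(left, right)
    plen <- sqrt((pieces$x2 - pieces$x1)^2 + (pieces$y2 - pieces$y1)^2)
    sel <- rbind(sel[-i, , drop = FALSE], pieces[plen >= 1, , drop = FALSE])
  }
  sel
}

# place plots on >= 2 m wide elements inside the core, honouring spacing
place_plots <- function(sel, config, area_id, side) {
  n_range <- seq(config$plots_per_area[1], config$plots_per_area[2])
  n_target <- if (length(n_range) == 1) n_range else sample(n_range, 1)
  cand <- sel
  cand$core_len <- core_length(cand, side)
  cand <- cand[cand$width_m >= 2 & cand$core_len > 1, , drop = FALSE]
  if (nrow(cand) == 0) {
    abort(sprintf("area %d: no element of >= 2 m width to place plots on", area_id))
  }
  xs <- numeric(0)
  ys <- numeric(0)
  types <- character(0)
  tries <- 0L
  while (length(xs) < n_target && tries < 5000L) {
    tries <- tries + 1L
    i <- sample.int(nrow(cand), 1, prob = cand$core_len)
    s <- cand[i, ]
    # uniform position on the part of the centreline inside the core
    cl <- clip_to_core(s, side)
    t <- runif(1, cl$t0, cl$t1)
    px <- s$x1 + t * (s$x2 - s$x1)
    py <- s$y1 + t * (s$y2 - s$y1)
    if (length(xs) > 0 &&
        min(sqrt((xs - px)^2 + (ys - py)^2)) < config$min_plot_spacing_m) {
      next
    }
    xs <- c(xs, px)
    ys <- c(ys, py)
    types <- c(types, s$lle_type)
  }
  if (length(xs) < n_target) {
    abort(sprintf(
      "area %d: could only place %d of %d plots at %g m spacing",
      area_id, length(xs), n_target, config$min_plot_spacing_m
    ))
  }
  tibble(
    plot = sprintf("a%02d_p%02d", area_id, seq_along(xs)),
    area = area_id,
    lle_type = types,
    x = xs,
    y = ys
  )
}

#' Write or read LLE segment geometry as CSV
#'
#' Plain-text interchange for the element centrelines: one row per segment
#' with columns `area, seg_id, x1, y1, x2, y2, width_m, lle_type`.
#'
#' @param segments Segment tibble as produced by [generate_landscape()].
#' @param path File path.
#' @return `read_lle_segments()` returns the segment tibble.
#' @export
write_lle_segments <- function(segments, path) {
  readr::write_csv(segments, path)
  invisible(path)
}

#' @rdname write_lle_segments
#' @export
read_lle_segments <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    area = readr::col_integer(),
                    seg_id = readr::col_integer(),
                    lle_type = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @export
print.cs_landscape <- function(x, ...) {
  cat(sprintf(
    "<cs_landscape> %d areas, %d segments, %d plots\n",
    x$config$n_areas, nrow(x$segments), nrow(x$plots)
  ))
  invisible(x)
}
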