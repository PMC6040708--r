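#' Resistance raster objects
#'
#' A `cs_raster` stores a regular grid of cell resistances in row-major
#' ESRI orientation: row 1 is the northernmost row, `origin_x`/`origin_y` is
#' the lower-left corner of the grid. Finite values are the element
#' resistance (default 0.01) and the gap-buffer resistance (default 0.02);
#' the hostile landscape matrix carries infinite resistance.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param cell_m Cell size in metres.
#' @param origin_x,origin_y Coordinates of the lower-left grid corner.
#' @return A `cs_raster` object.
#' @export
resistance_raster <- function(values, cell_m = 1, origin_x = 0, origin_y = 0) {
  stopifnot(is.matrix(values), cell_m > 0)
  structure(
    list(values = values, cell_m = cell_m,
         origin_x = origin_x, origin_y = origin_y),
    class = "cs_raster"
  )
}

#' @export
print.cs_raster <- function(x, ...) {
  nf <- sum(is.finite(x$values))
  cat(sprintf(
    "<cs_raster> %d x %d cells of %g m, origin (%g, %g), %d finite (%.1f%%)\n",
    nrow(x$values), ncol(x$values), x$cell_m, x$origin_x, x$origin_y,
    nf, 100 * nf / length(x$values)
  ))
  invisible(x)
}

# cell-centre coordinates
raster_cell_centres <- function(raster) {
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  list(
    x = raster$origin_x + (seq_len(nc) - 0.5) * raster$cell_m,
    y = raster$origin_y + (nr - seq_len(nr) + 0.5) * raster$cell_m
  )
}

#' Rasterise linear-element centrelines to a resistance raster
#'
#' A cell becomes element habitat (resistance `r_lle`) iff its centre lies
#' within the element polygon, i.e. within `width_m / 2` of the segment
#' centreline; all other cells receive infinite resistance. The extent should
#' cover the study area plus its full frame so that effective resistance is
#' not biased at the raster edge.
#'
#' @param segments Segment tibble (`x1, y1, x2, y2, width_m`, ...); typically
#'   one study area's rows from [generate_landscape()].
#' @param cell_m Cell size in metres.
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`. Defaults to the segment
#'   bounding box padded by 500 m.
#' @param r_lle Resistance of element cells.
#' @return A [resistance_raster()] object.
#' @export
#' @examples
#' seg <- tibble::tibble(x1 = 0, y1 = 5, x2 = 10, y2 = 5, width_m = 2)
#' r <- rasterize_lle(seg, extent = c(0, 10, 0, 10))
#' sum(is.finite(r$values))
rasterize_lle <- function(segments, cell_m = 1, extent = NULL, r_lle = 0.01) {
  if (is.null(extent)) {
    if (nrow(segments) == 0) {
      extent <- c(0, 100, 0, 100)
    } else {
      extent <- c(min(segments$x1, segments$x2) - 500,
                  max(segments$x1, segments$x2) + 500,
                  min(segments$y1, segments$y2) - 500,
                  max(segments$y1, segments$y2) + 500)
    }
  }
  nc <- ceiling((extent[2] - extent[1]) / cell_m)
  nr <- ceiling((extent[4] - extent[3]) / cell_m)
  vals <- matrix(Inf, nr, nc)
  if (nrow(segments) == 0) {
    warn("empty geometry: all-infinite resistance raster")
    return(resistance_raster(vals, cell_m, extent[1], extent[3]))
  }
  xs <- extent[1] + (seq_len(nc) - 0.5) * cell_m
  ys <- extent[3] + (nr - seq_len(nr) + 0.5) * cell_m # row 1 = north
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    half <- s$width_m / 2
    cmin <- max(1L, floor((min(s$x1, s$x2) - half - extent[1]) / cell_m))
    cmax <- min(nc, ceiling((max(s$x1, s$x2) + half - extent[1]) / cell_m) + 1L)
    rmin <- max(1L, nr - ceiling((max(s$y1, s$y2) + half - extent[3]) / cell_m))
    rmax <- min(nr, nr - floor((min(s$y1, s$y2) - half - extent[3]) / cell_m) + 1L)
    if (cmin > cmax || rmin > rmax) next
    cx <- xs[cmin:cmax]
    cy <- ys[rmin:rmax]
    # distance from cell centres to the segment
    px <- matrix(cx, length(cy), length(cx), byrow = TRUE)
    py <- matrix(cy, length(cy), length(cx))
    dx <- s$x2 - s$x1
    dy <- s$y2 - s$y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - s$x1) * dx + (py - s$y1) * dy) / len2))
    dist2 <- (px - (s$x1 + t * dx))^2 + (py - (s$y1 + t * dy))^2
    hit <- dist2 <= half^2
    block <- vals[rmin:rmax, cmin:cmax, drop = FALSE]
    block[hit] <- r_lle
    vals[rmin:rmax, cmin:cmax] <- block
  }
  resistance_raster(vals, cell_m, extent[1], extent[3])
}

#' Close small network gaps with a doubled-resistance buffer
#'
#' Every matrix cell whose centre lies within `buffer_m` of an element cell
#' centre receives the buffer resistance (default 0.02, double the element
#' resistance); element cells are never overwritten. Because the buffer
#' grows from both sides, any gap narrower than `2 * buffer_m` (10 m by
#' default) becomes traversable at doubled resistance, while wider gaps stay
#' disconnected. The operation is idempotent: buffer cells do not seed
#' further buffering.
#'
#' @param raster A [resistance_raster()].
#' @param buffer_m Buffer distance in metres.
#' @param r_lle Element resistance identifying seed cells.
#' @param r_buffer Resistance assigned to buffer cells.
#' @return A [resistance_raster()] with buffer cells added.
#' @export
apply_gap_buffers <- function(raster, buffer_m = 5, r_lle = 0.01, r_buffer = 0.02) {
  vals <- raster$values
  lle <- vals == r_lle
  lle[!is.finite(vals)] <- FALSE
  if (!any(lle)) return(raster)
  r_cells <- buffer_m / raster$cell_m
  reach <- floor(r_cells)
  nr <- nrow(vals)
  nc <- ncol(vals)
  dil <- lle
  for (dr in -reach:reach) {
    for (dc in -reach:reach) {
      if (dr == 0 && dc == 0) next
      if (dr * dr + dc * dc > r_cells^2) next
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      rt <- max(1, 1 - dr):min(nr, nr - dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      ct <- max(1, 1 - dc):min(nc, nc - dc)
      dil[rt, ct] <- dil[rt, ct] | lle[rs, cs]
    }
  }
  vals[dil & !lle] <- r_buffer
  resistance_raster(vals, raster$cell_m, raster$origin_x, raster$origin_y)
}

#' Read and write ESRI ASCII grids
#'
#' The conventional plain-text raster format of circuit-analysis workflows:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, northernmost row first.
#' Infinite resistance is serialised as the NODATA value and restored as
#' `Inf` on read, so a write-read round trip is value-identical.
#'
#' @param path File path (`.asc`).
#' @param raster A [resistance_raster()].
#' @param nodata NODATA value used when writing.
#' @return `read_ascii_grid()` returns a [resistance_raster()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) abort("malformed ASCII grid: fewer than 7 lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      abort(sprintf("malformed ASCII grid header at line %d: '%s'", i, lines[i]))
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  missing_keys <- setdiff(need, names(hdr))
  if (length(missing_keys) > 0) {
    abort(paste0("ASCII grid header lacks: ", paste(missing_keys, collapse = ", ")))
  }
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    abort(sprintf("ASCII grid has %d data rows, header says %d", length(body), nr))
  }
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]])
    if (length(row) != nc) {
      abort(sprintf("ASCII grid row %d has %d values, expected %d", i, length(row), nc))
    }
    vals[i, ] <- row
  }
  vals[vals == hdr$nodata_value] <- Inf
  resistance_raster(vals, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  vals <- raster$values
  vals[!is.finite(vals)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(vals)),
    sprintf("nrows %d", nrow(vals)),
    sprintf("xllcorner %.10g", raster$origin_x),
    sprintf("yllcorner %.10g", raster$origin_y),
    sprintf("cellsize %.10g", raster$cell_m),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(vals, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @method autoplot cs_raster
#' @export
autoplot.cs_raster <- function(object, ...) {
  cc <- raster_cell_centres(object)
  df <- expand.grid(y = cc$y, x = cc$x)
  df$resistance <- as.vector(object$values)
  df <- df[is.finite(df$resistance), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$resistance))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "resistance\n(ohm/cell)", x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
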