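#' Build a conductance graph
#'
#' Constructs the node/edge representation used by the effective-resistance
#' solver from an explicit edge list. Conductances of parallel edges between
#' the same node pair add, so the parallel-resistor law holds by
#' construction. The graph Laplacian is assembled as a sparse symmetric
#' matrix; connected components are labelled for the disconnected-pair
#' bookkeeping.
#'
#' @param edges Tibble/data frame with columns `from`, `to` (1-based node
#'   indices) and `conductance` (> 0, siemens).
#' @param n_nodes Number of nodes.
#' @param nodes Optional tibble of per-node metadata (e.g. raster cell
#'   coordinates).
#' @return A `cs_graph` object.
#' @export
#' @examples
#' g <- conductance_graph(tibble::tibble(from = c(1, 2), to = c(2, 3),
#'                                       conductance = c(1, 1)), n_nodes = 3)
#' effective_resistance(g, 1, 3) # series: 2 ohm
conductance_graph <- function(edges, n_nodes, nodes = NULL) {
  stopifnot(all(c("from", "to", "conductance") %in% names(edges)))
  if (nrow(edges) > 0) {
    if (any(!is.finite(edges$conductance)) || any(edges$conductance <= 0)) {
      abort("edge conductances must be finite and > 0")
    }
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    if (any(edges$from < 1 | edges$from > n_nodes |
            edges$to < 1 | edges$to > n_nodes)) {
      abort("edge endpoints outside 1..n_nodes")
    }
  }
  i <- c(edges$from, edges$to)
  j <- c(edges$to, edges$from)
  x <- c(edges$conductance, edges$conductance)
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_nodes, n_nodes))
  deg <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(n_nodes, deg) - A
  comp <- graph_components(edges, n_nodes)
  structure(
    list(n = n_nodes, L = L, comp = comp, nodes = nodes,
         n_edges = nrow(edges)),
    class = "cs_graph"
  )
}

# connected-component labels via igraph's C routines
graph_components <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(seq_len(n_nodes))
  g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  igraph::components(g)$membership
}

#' @export
print.cs_graph <- function(x, ...) {
  cat(sprintf("<cs_graph> %d nodes, %d edges, %d component(s)\n",
              x$n, x$n_edges, max(x$comp)))
  invisible(x)
}

#' Convert a resistance raster to a conductance graph
#'
#' Every finite-resistance cell becomes a node. Orthogonally adjacent nodes
#' are joined by an edge whose conductance is the mean of the two cell
#' conductances (cell conductance = 1 / cell resistance); with the 8-cell
#' neighbourhood, diagonal edges get that mean divided by sqrt(2) to account
#' for the longer centre-to-centre distance — the convention of the standard
#' circuit-analysis raster tools.
#'
#' @param raster A [resistance_raster()].
#' @param neighborhood 4 or 8.
#' @return A `cs_graph`; `$nodes` holds `node`, `row`, `col`, `x`, `y`.
#' @export
raster_to_graph <- function(raster, neighborhood = 8) {
  if (!neighborhood %in% c(4, 8)) abort("`neighborhood` must be 4 or 8")
  vals <- raster$values
  nr <- nrow(vals)
  nc <- ncol(vals)
  fin <- which(is.finite(vals))
  if (length(fin) == 0) abort("raster has no finite-resistance cell")
  idx <- matrix(NA_integer_, nr, nc)
  idx[fin] <- seq_along(fin)
  rc <- arrayInd(fin, c(nr, nc))
  cond <- 1 / vals[fin]

  offs <- list(c(1, 0, 1), c(0, 1, 1))
  if (neighborhood == 8) {
    offs <- c(offs, list(c(1, 1, 1 / sqrt(2)), c(-1, 1, 1 / sqrt(2))))
  }
  pieces <- purrr::map(offs, function(o) {
    r2 <- rc[, 1] + o[1]
    c2 <- rc[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- idx[cbind(r2[ok], c2[ok])]
    keep <- !is.na(j)
    i <- seq_along(fin)[ok][keep]
    jj <- j[keep]
    tibble(from = i, to = jj,
           conductance = (cond[i] + cond[jj]) / 2 * o[3])
  })
  cc <- raster_cell_centres(raster)
  nodes <- tibble(
    node = seq_along(fin), row = rc[, 1], col = rc[, 2],
    x = cc$x[rc[, 2]], y = cc$y[rc[, 1]]
  )
  conductance_graph(purrr::list_rbind(pieces), length(fin), nodes = nodes)
}

#' Effective resistance between two nodes
#'
#' Circuit-theory resistance distance: one node is grounded, a unit current
#' is injected at the other, and the reduced graph-Laplacian system is solved
#' by sparse Cholesky factorisation; the potential at the injection node is
#' the effective resistance. Nodes in different components are flagged as
#' disconnected (`NA` resistance) rather than assigned a large value.
#'
#' @param graph A `cs_graph`.
#' @param node_a,node_b Node indices.
#' @return One row tibble: `resistance_ohm`, `connected`.
#' @export
effective_resistance <- function(graph, node_a, node_b) {
  stopifnot(node_a >= 1, node_a <= graph$n, node_b >= 1, node_b <= graph$n)
  if (node_a == node_b) return(tibble(resistance_ohm = 0, connected = TRUE))
  if (graph$comp[node_a] != graph$comp[node_b]) {
    return(tibble(resistance_ohm = NA_real_, connected = FALSE))
  }
  mask <- graph$comp == graph$comp[node_a]
  ids <- which(mask)
  a <- match(node_a, ids)
  b <- match(node_b, ids)
  Lc <- graph$L[ids, ids, drop = FALSE]
  res <- tryCatch({
    Lr <- Lc[-b, -b, drop = FALSE]
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE)
    rhs <- rep(0, length(ids) - 1L)
    ai <- a - (a > b)
    rhs[ai] <- 1
    v <- Matrix::solve(ch, rhs)
    as.numeric(v[ai])
  }, error = function(e) NA_real_)
  tibble(resistance_ohm = res, connected = !is.na(res))
}

#' Pairwise effective resistance between plots over a raster
#'
#' Maps every plot to its raster cell (snapping to the nearest
#' finite-resistance cell within `snap_m`; deterministic row-then-column tie
#' break), then computes the effective resistance between all plot pairs.
#' One Cholesky factorisation per connected component is reused for all
#' pairs in it: with ground node g, `R(i, j) = v_i[i] + v_j[j] - 2 v_i[j]`
#' where `v_k` solves the grounded system for unit injection at k. Pairs in
#' different raster components are flagged disconnected.
#'
#' @param raster A [resistance_raster()] covering all plots.
#' @param plots Plot tibble with `plot`, `area`, `x`, `y` (one study area).
#' @param neighborhood Passed to [raster_to_graph()].
#' @param snap_m Maximum snap distance from a plot to a finite cell.
#' @return Tibble `area`, `plot_a`, `plot_b`, `resistance_ohm`, `connected`,
#'   one row per unordered plot pair.
#' @export
pairwise_resistance <- function(raster, plots, neighborhood = 8, snap_m = 5) {
  graph <- raster_to_graph(raster, neighborhood = neighborhood)
  node_of <- vapply(seq_len(nrow(plots)), function(i) {
    snap_plot_node(graph, raster, plots$x[i], plots$y[i], snap_m, plots$plot[i])
  }, integer(1))

  np <- nrow(plots)
  if (np < 2) {
    return(tibble(area = integer(0), plot_a = character(0),
                  plot_b = character(0), resistance_ohm = numeric(0),
                  connected = logical(0)))
  }
  pr <- t(combn(np, 2))
  out <- tibble(
    area = plots$area[pr[, 1]],
    plot_a = plots$plot[pr[, 1]],
    plot_b = plots$plot[pr[, 2]],
    resistance_ohm = NA_real_,
    connected = FALSE
  )

  comp_of <- graph$comp[node_of]
  for (cmp in unique(comp_of)) {
    in_cmp <- which(comp_of == cmp)
    if (length(in_cmp) < 2) next
    ids <- which(graph$comp == cmp)
    loc <- match(node_of[in_cmp], ids) # local indices within component
    g <- loc[length(loc)] # ground the last plot's node
    Lr <- graph$L[ids, ids, drop = FALSE][-g, -g, drop = FALSE]
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE),
                   error = function(e) NULL)
    if (is.null(ch)) next
    # potentials for unit injection at each non-ground plot node
    red_idx <- loc - (loc > g) # index in reduced system (ground dropped)
    nred <- length(ids) - 1L
    V <- matrix(0, nred, length(in_cmp))
    for (k in seq_along(in_cmp)[-length(in_cmp)]) {
      rhs <- rep(0, nred)
      rhs[red_idx[k]] <- 1
      V[, k] <- as.numeric(Matrix::solve(ch, rhs))
    }
    for (r in seq_len(nrow(pr))) {
      ka <- match(pr[r, 1], in_cmp)
      kb <- match(pr[r, 2], in_cmp)
      if (is.na(ka) || is.na(kb)) next
      ng <- length(in_cmp)
      res <- if (kb == ng) {
        V[red_idx[ka], ka]
      } else if (ka == ng) {
        V[red_idx[kb], kb]
      } else {
        V[red_idx[ka], ka] + V[red_idx[kb], kb] - 2 * V[red_idx[kb], ka]
      }
      out$resistance_ohm[r] <- res
      out$connected[r] <- TRUE
    }
  }
  n_disc <- sum(!out$connected)
  if (n_disc > 0) {
    inform(sprintf("pairwise_resistance: %d of %d pairs disconnected",
                   n_disc, nrow(out)))
  }
  out
}

# nearest finite cell within snap_m; ties broken by (row, col) order
snap_plot_node <- function(graph, raster, x, y, snap_m, plot_id) {
  cell <- raster$cell_m
  col <- floor((x - raster$origin_x) / cell) + 1L
  row <- nrow(raster$values) - floor((y - raster$origin_y) / cell)
  nodes <- graph$nodes
  d2 <- (nodes$x - x)^2 + (nodes$y - y)^2
  near <- which(d2 <= snap_m^2 + 1e-9)
  if (length(near) == 0) {
    abort(sprintf("plot '%s' is more than %g m from any finite-resistance cell",
                  plot_id, snap_m))
  }
  ord <- near[order(d2[near], nodes$row[near], nodes$col[near])]
  nodes$node[ord[1]]
}
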