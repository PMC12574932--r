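# Roads and rivers as least-cost paths over a slope surface, carved out of
# the potential space so fields cannot be placed on them.

#' Least-cost path specification
#'
#' @param start,end 0-based `c(row, col)` endpoints, or `"random_edge"` to
#'   draw the endpoints uniformly from a random pair of opposite grid edges.
#' @param cost_kind `"road"` (avoids steep cells: cell cost `1 + slope/90`)
#'   or `"river"` (follows valleys of the relief proxy: cell cost
#'   `1 + (90 - slope)/90`).
#' @param width feature width in cells, odd, >= 1.
#' @param seed integer seed for random endpoints.
#' @return list of class `path_spec`.
#' @export
path_spec <- function(start = "random_edge", end = "random_edge",
                      cost_kind = c("road", "river"), width = 1L, seed = 1L) {
  cost_kind <- match.arg(cost_kind)
  if (width %% 2 != 1 || width < 1)
    stop("`width` must be odd and >= 1", call. = FALSE)
  structure(list(start = start, end = end, cost_kind = cost_kind,
                 width = as.integer(width), seed = as.integer(seed)),
            class = "path_spec")
}

path_cell_cost <- function(slope, cost_kind) {
  if (cost_kind == "road") 1 + slope / 90 else 1 + (90 - slope) / 90
}

# draw endpoints on a uniformly chosen pair of opposite edges, restricted to
# traversable (non-NA) cells
random_edge_endpoints <- function(valid, nr, nc) {
  horizontal <- runif(1) < 0.5   # left/right edges vs top/bottom edges
  pick <- function(idx) idx[sample.int(length(idx), 1L)]
  if (horizontal) {
    left <- which(valid[, 1]); right <- which(valid[, nc])
    if (!length(left) || !length(right))
      stop("no traversable cells on the chosen edges", call. = FALSE)
    list(start = c(pick(left) - 1L, 0L), end = c(pick(right) - 1L, nc - 1L))
  } else {
    top <- which(valid[1, ]); bottom <- which(valid[nr, ])
    if (!length(top) || !length(bottom))
      stop("no traversable cells on the chosen edges", call. = FALSE)
    list(start = c(0L, pick(top) - 1L), end = c(nr - 1L, pick(bottom) - 1L))
  }
}

# weighted 8-neighbour lattice edge list: from/to 1-based linear indices,
# weight = step length (1 or sqrt(2)) * mean of the endpoint cell costs
lattice_edges <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  e <- function(r1, c1, r2, c2, step) {
    from <- idx[r1, c1, drop = FALSE]; to <- idx[r2, c2, drop = FALSE]
    w <- step * (cost[from] + cost[to]) / 2
    keep <- !is.na(w)
    cbind(from = as.vector(from)[keep], to = as.vector(to)[keep],
          w = as.vector(w)[keep])
  }
  out <- list()
  if (nr > 1) out$s  <- e(1:(nr - 1), 1:nc, 2:nr, 1:nc, 1)
  if (nc > 1) out$e  <- e(1:nr, 1:(nc - 1), 1:nr, 2:nc, 1)
  if (nr > 1 && nc > 1) {
    out$se <- e(1:(nr - 1), 1:(nc - 1), 2:nr, 2:nc, sqrt(2))
    out$sw <- e(2:nr, 1:(nc - 1), 1:(nr - 1), 2:nc, sqrt(2))
  }
  do.call(rbind, out)
}

#' Least-cost path over a slope map
#'
#' Finds the 8-connected path between two cells that minimises accumulated
#' traversal cost on a weighted lattice graph. Cell costs are
#' `1 + slope/90` for roads (gentle routes) and `1 + (90 - slope)/90` for
#' rivers (valley routes); a step between two cells costs the mean of their
#' cell costs, times `sqrt(2)` for diagonal steps to avoid axis bias. `NA`
#' cells are barriers.
#'
#' @param slope_map continuous [ag_grid], values >= 0.
#' @param spec a [path_spec].
#' @return list with `cells` (ordered 0-based `(row, col)` matrix from start
#'   to end), `cost` (accumulated cost), `start`, `end`.
#' @examples
#' s <- generate_perlin_slope(20, 20, perlin_params(seed = 3))
#' p <- least_cost_path(s, path_spec(c(0, 0), c(19, 19), "road"))
#' p$cost
#' @export
least_cost_path <- function(slope_map, spec) {
  stopifnot_grid(slope_map)
  stopifnot(inherits(spec, "path_spec"))
  if (any(slope_map$values < 0, na.rm = TRUE))
    stop("slope values must be >= 0", call. = FALSE)
  nr <- slope_map$nrow; nc <- slope_map$ncol
  cost <- path_cell_cost(slope_map$values, spec$cost_kind)
  if (identical(spec$start, "random_edge") || identical(spec$end, "random_edge")) {
    ep <- with_seed(spec$seed, random_edge_endpoints(!is.na(cost), nr, nc))
    start <- if (identical(spec$start, "random_edge")) ep$start else spec$start
    end <- if (identical(spec$end, "random_edge")) ep$end else spec$end
  } else {
    start <- spec$start; end <- spec$end
  }
  for (p in list(start, end))
    if (p[1] < 0 || p[1] >= nr || p[2] < 0 || p[2] >= nc)
      stop("endpoint out of bounds", call. = FALSE)
  s_idx <- start[1] + 1L + start[2] * nr
  e_idx <- end[1] + 1L + end[2] * nr
  if (is.na(cost[s_idx]) || is.na(cost[e_idx]))
    stop("endpoint lies on an NA (barrier) cell", call. = FALSE)
  edges <- lattice_edges(cost)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges[, 1:2])), weight = edges[, 3])
  sp <- igraph::shortest_paths(g, from = s_idx, to = e_idx,
                               weights = igraph::E(g)$weight,
                               output = "both")
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0 && s_idx != e_idx)
    stop("no traversable path between the endpoints", call. = FALSE)
  total <- sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
  list(cells = index_to_cells(vp, nr), cost = total,
       start = start, end = end)
}

#' Buffer a path to a given width
#'
#' Dilates a set of path cells to all cells within Chebyshev radius
#' `(width - 1)/2`, clipped to the grid bounds.
#'
#' @param path 0-based `(row, col)` matrix of path cells.
#' @param width odd integer >= 1; `width = 1` is the identity.
#' @param grid [ag_grid] supplying the clipping extent.
#' @return deduplicated 0-based `(row, col)` matrix.
#' @export
buffer_path <- function(path, width, grid) {
  stopifnot_grid(grid)
  if (width %% 2 != 1 || width < 1)
    stop("`width` must be odd and >= 1", call. = FALSE)
  r <- (width - 1) %/% 2
  if (r == 0) return(unique(path))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    cbind(path[, 1] + off$dr[i], path[, 2] + off$dc[i])))
  out <- out[out[, 1] >= 0 & out[, 1] < grid$nrow &
             out[, 2] >= 0 & out[, 2] < grid$ncol, , drop = FALSE]
  out <- unique(out)
  colnames(out) <- c("row", "col")
  out
}

#' Remove linear features from the potential space
#'
#' Zeroes the potential-space mask on the given feature cells (roads,
#' rivers); all other cells are unchanged. Idempotent.
#'
#' @param space an `ag_potential_space`.
#' @param features 0-based `(row, col)` matrix of feature cells.
#' @return updated `ag_potential_space`.
#' @export
exclude_from_potential <- function(space, features) {
  stopifnot(inherits(space, "ag_potential_space"))
  if (is.null(features) || nrow(features) == 0) return(space)
  m <- space$mask$values
  idx <- cells_to_index(features, space$mask$nrow)
  keep <- !is.na(m[idx])
  m[idx[keep]] <- 0
  space$mask <- ag_grid(m, space$mask$resolution)
  space
}

#' Generate a road or river and carve it from the potential space
#'
#' Convenience wrappers: draw a least-cost path between (by default) random
#' opposite grid edges, buffer it to `width` cells and return the feature
#' cells. Pass the result to [exclude_from_potential()].
#'
#' @inheritParams least_cost_path
#' @param width feature width in cells (odd). Default 1.
#' @param start,end endpoints as in [path_spec].
#' @param seed integer seed.
#' @return 0-based `(row, col)` matrix of feature cells.
#' @export
generate_road <- function(slope_map, width = 1L, start = "random_edge",
                          end = "random_edge", seed = 1L) {
  p <- least_cost_path(slope_map, path_spec(start, end, "road", width, seed))
  buffer_path(p$cells, width, slope_map)
}

#' @rdname generate_road
#' @export
generate_river <- function(slope_map, width = 1L, start = "random_edge",
                           end = "random_edge", seed = 1L) {
  p <- least_cost_path(slope_map, path_spec(start, end, "river", width, seed))
  buffer_path(p$cells, width, slope_map)
}
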