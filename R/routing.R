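# Grid routing: breadth-first distance fields over 4-connected walkable
# cells, with greedy-descent route extraction. Distance fields are cached on
# the floor plan (keyed by target cell) because destinations are revisited
# constantly during simulation.

# BFS distances (in cells) from every walkable cell to `target` (row, col).
# NA marks unreachable cells.
distance_field <- function(plan, target) {
  h <- plan$height; w <- plan$width
  key <- as.character((target[2] - 1L) * h + target[1])
  cached <- plan$cache[[key]]
  if (!is.null(cached)) return(cached)
  walkable <- plan$walkable
  dist <- matrix(NA_integer_, h, w)
  frontier <- (target[2] - 1L) * h + target[1]
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    rows <- (frontier - 1L) %% h + 1L
    up <- frontier[rows > 1L] - 1L
    down <- frontier[rows < h] + 1L
    left <- frontier[frontier > h] - h
    right <- frontier[frontier <= h * (w - 1L)] + h
    nb <- unique(c(up, down, left, right))
    nb <- nb[walkable[nb] & is.na(dist[nb])]
    dist[nb] <- d
    frontier <- nb
  }
  plan$cache[[key]] <- dist
  dist
}

#' Shortest route between two positions over walkable cells
#'
#' Routes are computed on the 4-connected grid of walkable cells by
#' breadth-first search; the route is the sequence of cell centers from the
#' start cell to the target cell, so every segment has unit length.
#'
#' @param plan A `floor_plan`.
#' @param from,to Positions `c(x, y)` in cell units; both must lie on
#'   walkable cells.
#' @return A `route`: list with `waypoints` (n x 2 matrix of cell-center
#'   x/y) and `total_length` (cell units). `from` and `to` in the same cell
#'   yield an empty route of length 0.
#' @export
#' @examples
#' plan <- demo_ward()
#' r <- shortest_route(plan, c(5.5, 2.5), c(25.5, 12.5))
#' r$total_length
shortest_route <- function(plan, from, to) {
  from_cell <- cell_of(from)
  to_cell <- cell_of(to)
  if (!walkable_at(plan, from[1], from[2]) || !walkable_at(plan, to[1], to[2])) {
    ws_abort("route endpoints must lie on walkable cells", "wardsim_error_unreachable")
  }
  if (all(from_cell == to_cell)) {
    return(new_route(matrix(numeric(0), 0, 2)))
  }
  dist <- distance_field(plan, to_cell)
  if (is.na(dist[from_cell[1], from_cell[2]])) {
    ws_abort("target is unreachable from the start position", "wardsim_error_unreachable")
  }
  h <- plan$height
  cur <- from_cell
  n <- dist[cur[1], cur[2]]
  way <- matrix(0, n + 1L, 2)
  way[1, ] <- cell_center(cur)
  for (i in seq_len(n)) {
    d <- dist[cur[1], cur[2]]
    # fixed neighbor order (up, down, left, right) makes routes deterministic
    if (cur[1] > 1L && !is.na(dist[cur[1] - 1L, cur[2]]) && dist[cur[1] - 1L, cur[2]] == d - 1L) {
      cur <- c(cur[1] - 1L, cur[2])
    } else if (cur[1] < h && !is.na(dist[cur[1] + 1L, cur[2]]) && dist[cur[1] + 1L, cur[2]] == d - 1L) {
      cur <- c(cur[1] + 1L, cur[2])
    } else if (cur[2] > 1L && !is.na(dist[cur[1], cur[2] - 1L]) && dist[cur[1], cur[2] - 1L] == d - 1L) {
      cur <- c(cur[1], cur[2] - 1L)
    } else {
      cur <- c(cur[1], cur[2] + 1L)
    }
    way[i + 1L, ] <- cell_center(cur)
  }
  new_route(way)
}

new_route <- function(waypoints) {
  structure(list(waypoints = waypoints,
                 total_length = max(nrow(waypoints) - 1L, 0L)),
            class = "route")
}

# position after advancing to arc-length s along a route's polyline
route_position <- function(route, s) {
  n <- nrow(route$waypoints)
  if (n == 0) return(NULL)
  s <- min(max(s, 0), route$total_length)
  seg <- min(floor(s), route$total_length - 1L)
  if (route$total_length == 0) return(route$waypoints[1, ])
  frac <- s - seg
  a <- route$waypoints[seg + 1L, ]
  b <- route$waypoints[seg + 2L, ]
  a + frac * (b - a)
}

#' Euclidean distance and trajectory path length
#'
#' `straight_line_distance()` is the Euclidean distance between two
#' positions; `path_length()` sums consecutive-pair distances along a
#' trajectory. Both are in cell units. These are the two ingredients of the
#' efficiency score (straight-line distance over distance travelled).
#'
#' @param a,b Positions `c(x, y)`.
#' @param traj An n x 2 matrix (or data frame with columns x, y) of
#'   positions; fewer than 2 rows give length 0.
#' @return A non-negative scalar.
#' @export
#' @examples
#' straight_line_distance(c(0, 0), c(3, 4))
#' path_length(rbind(c(0, 0), c(3, 4), c(0, 0)))
straight_line_distance <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' @rdname straight_line_distance
#' @export
path_length <- function(traj) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 2) return(0)
  d <- diff(traj)
  sum(sqrt(rowSums(d^2)))
}
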