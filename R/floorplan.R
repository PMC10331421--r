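# Floor plans: the 2D ward geometry the simulation runs on.
#
# A floor plan is an ASCII grid ('#' wall, '.' walkable) plus a JSON sidecar
# naming destination cells (rooms residents walk between) and nurse stations.
# Coordinates: cells are unit squares; continuous positions (x, y) have the
# origin at the top-left corner, x increasing rightward (columns), y downward
# (rows). The cell at grid row r, column c (1-based) covers
# x in [c-1, c), y in [r-1, r); its center is (c - 0.5, r - 0.5).
# Sidecar coordinates are 0-based [row, col] pairs.

new_floor_plan <- function(walkable, destinations, nurse_stations, cell_size) {
  plan <- list(
    width = ncol(walkable),
    height = nrow(walkable),
    cell_size = cell_size,
    walkable = walkable,
    destinations = destinations,
    nurse_stations = nurse_stations,
    cache = new.env(parent = emptyenv())
  )
  class(plan) <- "floor_plan"
  plan
}

#' Parse a floor plan from an ASCII map and a location sidecar
#'
#' @param map_text Single string (or character vector of rows) using `#` for
#'   wall and `.` for walkable cells. All rows must have equal length.
#' @param sidecar A JSON string, or an already-parsed list, with elements
#'   `destinations` (named list of 0-based `[row, col]` pairs),
#'   `nurse_stations` (list of 0-based `[row, col]` pairs) and `cell_size_m`
#'   (meters per cell, default 1).
#'
#' @details Validation enforces that the map is rectangular and at least
#'   2 x 2, that at least two destinations are named, that every named
#'   location lies on a walkable cell, and that all named locations are
#'   mutually reachable over 4-connected walkable cells. Each violation
#'   raises a distinct classed condition (`wardsim_error_map_shape`,
#'   `wardsim_error_location_on_wall`, `wardsim_error_unreachable`, ...).
#'
#' @return A `floor_plan` object.
#' @export
#' @examples
#' plan <- load_floorplan(
#'   "...\n...\n...",
#'   list(destinations = list(A = c(0, 0), B = c(2, 2)),
#'        nurse_stations = list(c(1, 1)))
#' )
#' sum(plan$walkable)
load_floorplan <- function(map_text, sidecar) {
  rows <- if (length(map_text) == 1) strsplit(map_text, "\n", fixed = TRUE)[[1]] else map_text
  rows <- rows[nchar(rows) > 0 | seq_along(rows) < length(rows)]  # drop trailing blank
  if (length(rows) < 2) {
    ws_abort("floor-plan map must have at least 2 rows", "wardsim_error_map_shape")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    ws_abort("floor-plan map is not rectangular: row widths differ", "wardsim_error_map_shape")
  }
  if (widths[1] < 2) {
    ws_abort("floor-plan map must have at least 2 columns", "wardsim_error_map_shape")
  }
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(chars)), c("#", "."))
  if (length(bad) > 0) {
    ws_abort(paste0("unexpected map characters: ", paste(bad, collapse = " ")),
             "wardsim_error_map_shape")
  }
  walkable <- chars == "."

  if (is.character(sidecar)) sidecar <- jsonlite::fromJSON(sidecar, simplifyVector = FALSE)
  dests <- sidecar$destinations
  if (is.null(dests) || length(dests) < 2 || is.null(names(dests)) || any(names(dests) == "")) {
    ws_abort("sidecar must name at least 2 destinations", "wardsim_error_sidecar")
  }
  to_cell <- function(rc, what) {
    rc <- as.integer(unlist(rc))
    if (length(rc) != 2) ws_abort(paste0("bad cell coordinate for ", what), "wardsim_error_sidecar")
    cell <- rc + 1L  # sidecar is 0-based [row, col]
    if (cell[1] < 1 || cell[1] > nrow(walkable) || cell[2] < 1 || cell[2] > ncol(walkable)) {
      ws_abort(paste0(what, " lies outside the map"), "wardsim_error_sidecar")
    }
    if (!walkable[cell[1], cell[2]]) {
      ws_abort(paste0(what, " lies on a wall cell"), "wardsim_error_location_on_wall")
    }
    cell
  }
  destinations <- lapply(seq_along(dests), function(i) {
    to_cell(dests[[i]], paste0("destination '", names(dests)[i], "'"))
  })
  names(destinations) <- names(dests)
  destinations <- destinations[order(names(destinations))]
  stations <- lapply(seq_along(sidecar$nurse_stations), function(i) {
    to_cell(sidecar$nurse_stations[[i]], paste0("nurse station ", i))
  })
  cell_size <- sidecar$cell_size_m %||% 1

  plan <- new_floor_plan(walkable, destinations, stations, cell_size)
  check_connected(plan)
  plan
}

# all named locations must be mutually reachable (4-connected walkable cells)
check_connected <- function(plan) {
  named <- c(plan$destinations, plan$nurse_stations)
  seed <- named[[1]]
  reach <- flood_reachable(plan$walkable, seed)
  for (i in seq_along(named)) {
    cell <- named[[i]]
    if (!reach[cell[1], cell[2]]) {
      label <- if (i <= length(plan$destinations)) {
        paste0("destination '", names(plan$destinations)[i], "'")
      } else {
        "a nurse station"
      }
      ws_abort(paste0("unreachable destination: ", label,
                      " is not connected to the other named locations"),
               "wardsim_error_unreachable")
    }
  }
  invisible(plan)
}

flood_reachable <- function(walkable, seed_cell) {
  h <- nrow(walkable); w <- ncol(walkable)
  reach <- matrix(FALSE, h, w)
  frontier <- (seed_cell[2] - 1L) * h + seed_cell[1]
  reach[frontier] <- TRUE
  while (length(frontier) > 0) {
    rows <- (frontier - 1L) %% h + 1L
    up <- frontier[rows > 1L] - 1L
    down <- frontier[rows < h] + 1L
    left <- frontier[frontier > h] - h
    right <- frontier[frontier <= h * (w - 1L)] + h
    nb <- c(up, down, left, right)
    nb <- nb[walkable[nb] & !reach[nb]]
    nb <- unique(nb)
    reach[nb] <- TRUE
    frontier <- nb
  }
  reach
}

#' Serialize a floor plan back to map text and sidecar JSON
#'
#' The serialization is canonical (destinations sorted by name, 0-based
#' coordinates), so parse -> serialize -> parse is the identity and files
#' written by [write_floorplan()] round-trip byte-identically.
#'
#' @param plan A `floor_plan`.
#' @return A list with elements `map` (single string, trailing newline) and
#'   `sidecar` (single JSON string).
#' @export
floorplan_text <- function(plan) {
  chars <- ifelse(plan$walkable, ".", "#")
  rows <- apply(chars, 1, paste, collapse = "")
  map <- paste0(paste(rows, collapse = "\n"), "\n")
  side <- list(
    destinations = lapply(plan$destinations, function(cell) as.integer(cell - 1L)),
    nurse_stations = lapply(plan$nurse_stations, function(cell) as.integer(cell - 1L)),
    cell_size_m = plan$cell_size
  )
  sidecar <- as.character(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA))
  list(map = map, sidecar = sidecar)
}

#' Read / write floor-plan files
#'
#' @param map_path Path to the ASCII `.map` file.
#' @param sidecar_path Path to the JSON sidecar. Defaults to the map path
#'   with its extension replaced by `.json`.
#' @return `read_floorplan()` returns a `floor_plan`; `write_floorplan()`
#'   returns the map path invisibly.
#' @export
read_floorplan <- function(map_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% sub("\\.[^.]*$", ".json", map_path)
  map_text <- paste0(paste(readLines(map_path), collapse = "\n"), "\n")
  sidecar <- paste(readLines(sidecar_path, warn = FALSE), collapse = "\n")
  load_floorplan(map_text, sidecar)
}

#' @rdname read_floorplan
#' @param plan A `floor_plan`.
#' @export
write_floorplan <- function(plan, map_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% sub("\\.[^.]*$", ".json", map_path)
  txt <- floorplan_text(plan)
  writeLines(sub("\n$", "", txt$map), map_path)
  writeLines(txt$sidecar, sidecar_path)
  invisible(map_path)
}

# digest identifying the geometry (used to match protocols with plans)
floorplan_digest <- function(plan) {
  txt <- floorplan_text(plan)
  ws_digest(list(map = txt$map, sidecar = txt$sidecar))
}

#' Demo ward: a corridor spine with six rooms
#'
#' Builds the package's demonstration floor plan programmatically: a
#' three-cell-wide corridor flanked by six rooms (three above, three below),
#' each connected to the corridor by a one-cell doorway, with two nurse
#' stations on the corridor. Room centers are the named destinations
#' `room_1` ... `room_6`. The copies under `inst/extdata/` were written by
#' this function via [write_floorplan()].
#'
#' @param cell_size Meters per cell.
#' @return A `floor_plan` (15 rows x 31 columns, 285 walkable cells).
#' @export
#' @examples
#' plan <- demo_ward()
#' names(plan$destinations)
demo_ward <- function(cell_size = 1) {
  h <- 15L; w <- 31L
  walk <- matrix(FALSE, h, w)
  room_cols <- list(2:9, 12:19, 22:29)
  # rooms above (rows 2-5) and below (rows 11-14) a 3-wide corridor (rows 7-9)
  for (cols in room_cols) {
    walk[2:5, cols] <- TRUE
    walk[11:14, cols] <- TRUE
  }
  walk[7:9, 2:30] <- TRUE
  door_cols <- vapply(room_cols, function(cols) cols[5], integer(1))  # 6, 16, 26
  walk[6, door_cols] <- TRUE
  walk[10, door_cols] <- TRUE

  centers_top <- lapply(door_cols, function(col) c(3L, col - 1L))
  centers_bot <- lapply(door_cols, function(col) c(12L, col - 1L))
  destinations <- c(centers_top, centers_bot)
  names(destinations) <- paste0("room_", 1:6)
  stations <- list(c(8L, 10L), c(8L, 22L))
  plan <- new_floor_plan(walk, destinations, stations, cell_size)
  check_connected(plan)
  plan
}

#' @export
print.floor_plan <- function(x, ...) {
  cat(sprintf("<floor_plan> %d x %d cells (%d walkable), %d destinations, %d nurse stations\n",
              x$height, x$width, sum(x$walkable),
              length(x$destinations), length(x$nurse_stations)))
  invisible(x)
}

# ---- cell geometry helpers ----

cell_of <- function(pos) c(floor(pos[2]) + 1L, floor(pos[1]) + 1L)  # (row, col)

cell_center <- function(cell) c(cell[2] - 0.5, cell[1] - 0.5)      # (x, y)

walkable_at <- function(plan, x, y) {
  col <- floor(x) + 1L; row <- floor(y) + 1L
  if (row < 1L || row > plan$height || col < 1L || col > plan$width) return(FALSE)
  plan$walkable[row, col]
}
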