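#' Lattice geometry of the self-organizing map
#'
#' Units are arranged on a `rows x cols` grid, numbered row-major starting
#' at 1. Square lattices use the Chebyshev (8-neighbour) metric; hexagonal
#' lattices use axial hex distance with odd-row offset coordinates (odd rows
#' shifted half a cell to the right). With toroidal wrap, distances are
#' minimum-image over the lattice periods, which removes border effects.
#'
#' @param shape `"square"` or `"hexagonal"`.
#' @param wrap `"planar"` or `"toroidal"`.
#' @param rows,cols Positive lattice dimensions.
#' @return An object of class `lattice_geometry`.
#' @export
lattice_geometry <- function(shape = c("square", "hexagonal"),
                             wrap = c("planar", "toroidal"),
                             rows = 8L, cols = 8L) {
  shape <- match.arg(shape)
  wrap <- match.arg(wrap)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1", call. = FALSE)
  structure(list(shape = shape, wrap = wrap, rows = rows, cols = cols,
                 units = rows * cols),
            class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("<lattice_geometry> %dx%d %s, %s\n", x$rows, x$cols, x$shape,
              x$wrap))
  invisible(x)
}

# Row-major 0-based (row, col) coordinates of every unit.
lattice_coords <- function(geometry) {
  i <- seq_len(geometry$units) - 1L
  cbind(row = i %/% geometry$cols, col = i %% geometry$cols)
}

# Odd-r offset -> cube coordinates (works for shifted, possibly negative rows).
hex_cube <- function(row, col) {
  x <- col - (row - (row %% 2)) %/% 2
  z <- row
  cbind(x = x, y = -x - z, z = z)
}

hex_dist_from_cubes <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m axial hex distances
  (abs(outer(a[, 1], b[, 1], "-")) +
     abs(outer(a[, 2], b[, 2], "-")) +
     abs(outer(a[, 3], b[, 3], "-"))) / 2
}

# cache: lattice distance matrices are reused across trainings
.lattice_cache <- new.env(parent = emptyenv())

#' Pairwise lattice distances between map units
#'
#' @param geometry A [lattice_geometry()].
#' @return A `units x units` numeric matrix of lattice distances.
#' @export
lattice_distances <- function(geometry) {
  stopifnot(inherits(geometry, "lattice_geometry"))
  key <- paste(geometry$shape, geometry$wrap, geometry$rows, geometry$cols,
               sep = "_")
  cached <- .lattice_cache[[key]]
  if (!is.null(cached)) return(cached)
  co <- lattice_coords(geometry)
  R <- geometry$rows; C <- geometry$cols
  if (geometry$shape == "square") {
    dr <- abs(outer(co[, "row"], co[, "row"], "-"))
    dc <- abs(outer(co[, "col"], co[, "col"], "-"))
    if (geometry$wrap == "toroidal") {
      dr <- pmin(dr, R - dr)
      dc <- pmin(dc, C - dc)
    }
    d <- pmax(dr, dc)
  } else {
    base <- hex_cube(co[, "row"], co[, "col"])
    if (geometry$wrap == "planar") {
      d <- hex_dist_from_cubes(base, base)
    } else {
      d <- NULL
      for (sr in c(-R, 0L, R)) {
        for (sc in c(-C, 0L, C)) {
          img <- hex_cube(co[, "row"] + sr, co[, "col"] + sc)
          di <- hex_dist_from_cubes(base, img)
          d <- if (is.null(d)) di else pmin(d, di)
        }
      }
    }
  }
  storage.mode(d) <- "double"
  .lattice_cache[[key]] <- d
  d
}

#' Neighbourhood of a winning unit
#'
#' All units whose lattice distance to the winner is at most `radius`; the
#' winner itself is always included (radius 0 gives winner-only updates).
#'
#' @param winner Unit index (1-based).
#' @param radius Non-negative neighbourhood radius in lattice distance units.
#' @param geometry A [lattice_geometry()].
#' @return Integer vector of unit indices.
#' @export
neighborhood <- function(winner, radius, geometry) {
  stopifnot(radius >= 0)
  d <- lattice_distances(geometry)
  if (winner < 1L || winner > geometry$units) stop("winner out of range")
  which(d[winner, ] <= radius)
}
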