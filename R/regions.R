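#' Rectangular analysis region
#'
#' Defines an axis-aligned rectangular analysis window in micrometres.
#' Regions are the spatial domain for point patterns: the border-correction
#' rule for the Local Invasion Index measures each cell's distance to the
#' region boundary.
#'
#' @param x0,y0 lower corner (um).
#' @param x1,y1 upper corner (um); must exceed the lower corner.
#' @return An object of class \code{"invadex_region"}.
#' @examples
#' region_rect(0, 0, 500, 500)
#' @export
region_rect <- function(x0, y0, x1, y1) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.numeric(x1), is.numeric(y1))
  if (x1 <= x0 || y1 <= y0)
    stop("region must have positive area")
  structure(list(type = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "invadex_region")
}

#' Polygonal analysis region
#'
#' A simple (non-self-intersecting) polygon in micrometres. Used for
#' non-rectangular analysis areas such as circular tissue-microarray cores.
#' Vertices may be given in either orientation; the polygon is closed
#' implicitly (do not repeat the first vertex).
#'
#' @param x,y numeric vectors of vertex coordinates (um), length >= 3.
#' @return An object of class \code{"invadex_region"}.
#' @seealso [region_disc()] for a polygonal approximation of a circle.
#' @export
region_polygon <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3)
  if (abs(.polygon_area(x, y)) <= 0)
    stop("region must have positive area")
  structure(list(type = "poly", x = as.numeric(x), y = as.numeric(y)),
            class = "invadex_region")
}

#' Disc-shaped analysis region
#'
#' Polygonal approximation of a circular region, the usual shape of a
#' tissue-microarray core.
#'
#' @param cx,cy centre (um).
#' @param r radius (um).
#' @param n_vertices number of polygon vertices.
#' @return An object of class \code{"invadex_region"}.
#' @export
region_disc <- function(cx, cy, r, n_vertices = 180L) {
  stopifnot(r > 0, n_vertices >= 8)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  region_polygon(cx + r * cos(th), cy + r * sin(th))
}

#' @export
print.invadex_region <- function(x, ...) {
  if (x$type == "rect") {
    cat(sprintf("rectangular region [%g, %g] x [%g, %g] um\n",
                x$x0, x$x1, x$y0, x$y1))
  } else {
    cat(sprintf("polygonal region with %d vertices, area %.1f um^2\n",
                length(x$x), region_area(x)))
  }
  invisible(x)
}

#' Area of an analysis region
#' @param region an \code{invadex_region}.
#' @return Area in um^2.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "invadex_region"))
  if (region$type == "rect")
    (region$x1 - region$x0) * (region$y1 - region$y0)
  else
    abs(.polygon_area(region$x, region$y))
}

# shoelace; signed
.polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Test points for region membership
#'
#' Points exactly on the boundary count as inside (closed region).
#'
#' @param x,y point coordinates (um).
#' @param region an \code{invadex_region}.
#' @return Logical vector.
#' @export
region_contains <- function(x, y, region) {
  stopifnot(inherits(region, "invadex_region"), length(x) == length(y))
  if (region$type == "rect")
    return(x >= region$x0 & x <= region$x1 & y >= region$y0 & y <= region$y1)
  inside <- .point_in_polygon(x, y, region$x, region$y)
  # boundary points: crossing tests are unreliable there, fall back to distance
  on_edge <- .dist_to_polygon(x, y, region$x, region$y) < 1e-9
  inside | on_edge
}

# even-odd ray crossing, vectorised over query points
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from interior points to the region boundary
#'
#' The quantity compared against each cell's nearest-neighbor distance by
#' the border-correction rule: a cell is retained only when this distance
#' is at least its NND (tangency counts as contained).
#'
#' @param x,y point coordinates (um), assumed inside the region.
#' @param region an \code{invadex_region}.
#' @return Numeric vector of distances (um).
#' @export
region_boundary_distance <- function(x, y, region) {
  stopifnot(inherits(region, "invadex_region"), length(x) == length(y))
  if (region$type == "rect") {
    pmin(x - region$x0, region$x1 - x, y - region$y0, region$y1 - y)
  } else {
    .dist_to_polygon(x, y, region$x, region$y)
  }
}

# min distance from each point to any polygon edge segment
.dist_to_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- vx[j]; ay <- vy[j]; bx <- vx[i]; by <- vy[i]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    ex <- ax + t * dx - px
    ey <- ay + t * dy - py
    d2 <- pmin(d2, ex * ex + ey * ey)
    j <- i
  }
  sqrt(d2)
}

# bounding box as c(x0, y0, x1, y1)
.region_bbox <- function(region) {
  if (region$type == "rect")
    c(region$x0, region$y0, region$x1, region$y1)
  else
    c(min(region$x), min(region$y), max(region$x), max(region$y))
}
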