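#' Simulation configuration
#'
#' Bundles the random seed, the analysis window and the physical pixel size
#' shared by all synthetic-data generators. Identical configuration plus
#' identical generator parameters yields bit-identical output.
#'
#' @param seed integer random seed.
#' @param window analysis window, either an \code{invadex_region} rectangle
#'   or a numeric vector \code{c(x0, y0, x1, y1)} in um.
#' @param pixel_size physical pixel size in um per pixel (> 0).
#' @return An object of class \code{"sim_config"}.
#' @examples
#' cfg <- sim_config(seed = 1, window = c(0, 0, 500, 500), pixel_size = 0.5)
#' @export
sim_config <- function(seed, window = c(0, 0, 500, 500), pixel_size = 0.5) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.numeric(window) && length(window) == 4)
    window <- region_rect(window[1], window[2], window[3], window[4])
  stopifnot(inherits(window, "invadex_region"))
  if (window$type != "rect")
    stop("simulation window must be rectangular; polygonal analysis regions ",
         "are applied downstream")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(seed = as.integer(seed), window = window,
                 pixel_size = pixel_size),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, window %gx%g um, %g um/px\n",
              x$seed, x$window$x1 - x$window$x0, x$window$y1 - x$window$y0,
              x$pixel_size))
  invisible(x)
}

#' Spatial point pattern of cell centroids
#'
#' Cell nucleus centroids in micrometres together with the analysis region
#' they live in. This is the substrate for nearest-neighbor-distance and
#' Local Invasion Index computation.
#'
#' @param x,y centroid coordinates (um).
#' @param region an \code{invadex_region}; all points must lie inside it.
#' @return An object of class \code{"point_pattern"} with fields
#'   \code{x}, \code{y}, \code{n}, \code{region}.
#' @examples
#' pp <- point_pattern(c(10, 20), c(10, 25), region_rect(0, 0, 100, 100))
#' @export
point_pattern <- function(x, y, region) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            inherits(region, "invadex_region"))
  if (anyNA(x) || anyNA(y)) stop("centroid coordinates must not contain NA")
  if (length(x) > 0 && !all(region_contains(x, y, region)))
    stop("all points must lie inside the analysis region")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x),
                 region = region),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in a %s region (area %.0f um^2)\n",
              x$n, x$region$type, region_area(x$region)))
  invisible(x)
}

#' Multi-channel tissue image
#'
#' Named intensity channels over a common raster with a physical pixel
#' size. Channels are matrices (2D sections) or 3D arrays (confocal
#' z-series, third index = z). The pixel centre convention is
#' \code{x = (col - 0.5) * pixel_size}, \code{y = (row - 0.5) * pixel_size}
#' with the origin at the image corner and y increasing downward.
#'
#' @param channels named list of numeric matrices or 3D arrays, all of the
#'   same dimensions.
#' @param pixel_size um per pixel (> 0).
#' @param z_step um between z-slices (3D images only).
#' @return An object of class \code{"tissue_image"}.
#' @export
tissue_image <- function(channels, pixel_size, z_step = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1)
    stop("all channels must share the same dimensions")
  nd <- length(dims[[1]])
  if (!nd %in% c(2, 3)) stop("channels must be 2D matrices or 3D arrays")
  if (nd == 3 && is.null(z_step))
    stop("z_step is required for 3D images")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step, dim = dims[[1]]),
            class = "tissue_image")
}

#' @export
print.tissue_image <- function(x, ...) {
  d <- x$dim
  cat(sprintf("tissue image: %s px, %g um/px%s; channels: %s\n",
              paste(d, collapse = "x"), x$pixel_size,
              if (!is.null(x$z_step)) sprintf(", z-step %g um", x$z_step)
              else "",
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

.get_channel <- function(img, channel) {
  stopifnot(inherits(img, "tissue_image"))
  if (!channel %in% names(img$channels))
    stop(sprintf("unknown channel '%s'; available: %s", channel,
                 paste(names(img$channels), collapse = ", ")))
  img$channels[[channel]]
}

#' Kymograph (space-by-time intensity raster)
#'
#' Rows index position along the kymograph line, columns index time.
#' Ruffle traces appear as sloped streaks whose slope, after unit
#' conversion, is the ruffle speed.
#'
#' @param raster numeric matrix, space (rows) by time (columns).
#' @param space_scale um per pixel along the space axis (> 0).
#' @param time_scale seconds per frame along the time axis (> 0).
#' @return An object of class \code{"kymograph"}.
#' @export
kymograph <- function(raster, space_scale, time_scale) {
  stopifnot(is.matrix(raster), is.numeric(raster),
            space_scale > 0, time_scale > 0)
  structure(list(raster = raster, space_scale = space_scale,
                 time_scale = time_scale),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "kymograph: %d px x %d frames (%g um/px, %g s/frame; %.1f um x %.1f min)\n",
    nrow(x$raster), ncol(x$raster), x$space_scale, x$time_scale,
    nrow(x$raster) * x$space_scale, ncol(x$raster) * x$time_scale / 60))
  invisible(x)
}
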