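#' Detect membrane-ruffle traces in a kymograph
#'
#' Ruffles appear as bright, approximately linear streaks (areas of high
#' contrast) in the space-time raster. Detection thresholds the
#' background-subtracted raster at a configurable fraction of its peak
#' contrast, labels connected components, discards specks, and fits each
#' trace with a line in (space, time). Because the threshold is relative
#' to the raster's own contrast, detection (and hence speed estimation)
#' is invariant to linear intensity rescaling.
#'
#' @param kymo a [kymograph()].
#' @param contrast_threshold fraction of the peak contrast (max minus
#'   median) above background at which a pixel counts as high-contrast;
#'   default 0.5. Values >= 1 detect nothing.
#' @param min_trace_px minimum component size in pixels (filters noise
#'   specks).
#' @param smooth_px Gaussian pre-smoothing scale in pixels; keeps steep
#'   traces connected under 4-connected labelling and suppresses noise.
#'   0 disables.
#' @param robust fit trace slopes by the median of pairwise slopes
#'   (Theil-Sen) instead of least squares; useful when traces cross.
#' @return An object of class \code{"ruffle_set"}: list with \code{count},
#'   \code{speeds} (um/min, one per trace), \code{traces} (data frame:
#'   trace_id, n_px, slope_px_per_frame, speed_um_min, t_start_min,
#'   t_end_min) and \code{duration_min} (kymograph duration covered).
#' @export
detect_ruffles <- function(kymo, contrast_threshold = 0.5,
                           min_trace_px = 8, smooth_px = 1,
                           robust = FALSE) {
  stopifnot(inherits(kymo, "kymograph"), contrast_threshold > 0)
  r <- kymo$raster
  if (smooth_px >= 0.25 && all(dim(r) >= 8))
    r <- as.matrix(EBImage::gblur(r, sigma = smooth_px))
  bg <- stats::median(r)
  peak <- max(r) - bg
  traces <- data.frame(trace_id = integer(0), n_px = integer(0),
                       slope_px_per_frame = numeric(0),
                       speed_um_min = numeric(0),
                       t_start_min = numeric(0), t_end_min = numeric(0))
  dur <- ncol(r) * kymo$time_scale / 60
  if (peak <= 0 || contrast_threshold >= 1) {
    return(structure(list(count = 0L, speeds = numeric(0), traces = traces,
                          duration_min = dur), class = "ruffle_set"))
  }
  mask <- (r - bg) > contrast_threshold * peak
  lab <- EBImage::bwlabel(array(as.numeric(mask), dim = dim(mask)))
  nlab <- max(lab)
  if (nlab > 0) {
    idx <- which(lab > 0)
    labs <- lab[idx]
    nr <- nrow(r)
    space_px <- ((idx - 1L) %% nr) + 1L
    time_fr <- ((idx - 1L) %/% nr) + 1L
    for (k in seq_len(nlab)) {
      sel <- labs == k
      if (sum(sel) < min_trace_px) next
      tr <- data.frame(space_px = space_px[sel], time_frame = time_fr[sel])
      slope <- .trace_slope(tr, robust = robust)
      traces <- rbind(traces, data.frame(
        trace_id = nrow(traces) + 1L, n_px = sum(sel),
        slope_px_per_frame = slope,
        speed_um_min = ruffle_speed(tr, kymo$space_scale, kymo$time_scale,
                                    robust = robust),
        t_start_min = (min(tr$time_frame) - 1) * kymo$time_scale / 60,
        t_end_min = max(tr$time_frame) * kymo$time_scale / 60))
    }
  }
  structure(list(count = nrow(traces), speeds = traces$speed_um_min,
                 traces = traces, duration_min = dur),
            class = "ruffle_set")
}

#' @export
print.ruffle_set <- function(x, ...) {
  cat(sprintf("%d ruffle trace(s) over %.1f min", x$count, x$duration_min))
  if (x$count > 0)
    cat(sprintf("; mean speed %.2f um/min", mean(x$speeds)))
  cat("\n")
  invisible(x)
}

# slope of space (px) against time (frames) for one trace
.trace_slope <- function(trace, robust = FALSE) {
  t <- trace$time_frame; s <- trace$space_px
  if (length(unique(t)) < 2) return(0)
  if (robust) {
    # Theil-Sen on per-frame mean positions (crossing-trace tolerant)
    sm <- tapply(s, t, mean)
    tt <- as.numeric(names(sm))
    cmb <- utils::combn(seq_along(tt), 2)
    sl <- (sm[cmb[2, ]] - sm[cmb[1, ]]) / (tt[cmb[2, ]] - tt[cmb[1, ]])
    stats::median(sl)
  } else {
    tb <- t - mean(t)
    sum(tb * (s - mean(s))) / sum(tb^2)
  }
}

#' Speed of a ruffle trace
#'
#' Distance traveled per unit time: the absolute slope of the trace
#' fitted in (space, time) pixel coordinates, converted to um/min with
#' the kymograph scales. A static (time-parallel) trace has speed 0.
#'
#' @param trace data frame with columns \code{space_px} and
#'   \code{time_frame} (trace pixel coordinates).
#' @param space_scale um per pixel.
#' @param time_scale seconds per frame.
#' @param robust use the Theil-Sen slope.
#' @return Speed in um/min (>= 0).
#' @export
ruffle_speed <- function(trace, space_scale, time_scale, robust = FALSE) {
  stopifnot(space_scale > 0, time_scale > 0)
  abs(.trace_slope(trace, robust = robust)) * space_scale / time_scale * 60
}

#' Leading-edge band mask of a cell z-series
#'
#' Constructs, slice by slice, the set of cell-mask pixels lying within
#' \code{width_um} of the cell edge, and stacks the slices into a 3D
#' binary mask ("2.5D": the distance is computed within each z-slice, the
#' way slice-wise masks are drawn). The band restricts leading-edge
#' quantification to the membrane-proximal actin compartment; the default
#' width is 3 um.
#'
#' Pixel distances to the edge use the slice distance transform with a
#' half-pixel correction (the transform measures to the nearest
#' background pixel centre, half a pixel beyond the mask boundary).
#'
#' @param zseries a 3D [tissue_image()].
#' @param actin_channel channel segmented into the cell mask.
#' @param width_um band width in um (> 0).
#' @param threshold \code{"otsu"} or a fixed intensity value for the cell
#'   mask.
#' @return 3D logical band mask (subset of the cell mask) with attributes
#'   \code{"cell_mask"} and \code{"width_um"}.
#' @export
leading_edge_band <- function(zseries, actin_channel = "actin",
                              width_um = 3, threshold = "otsu") {
  stopifnot(inherits(zseries, "tissue_image"), width_um > 0)
  arr <- .get_channel(zseries, actin_channel)
  stopifnot(length(dim(arr)) == 3)
  px <- zseries$pixel_size
  cell <- array(FALSE, dim = dim(arr))
  band <- array(FALSE, dim = dim(arr))
  for (z in seq_len(dim(arr)[3])) {
    sl <- arr[, , z]
    img2 <- tissue_image(list(actin = sl), pixel_size = px)
    m <- if (identical(threshold, "otsu"))
      threshold_channel(img2, "actin", method = "otsu")
    else threshold_channel(img2, "actin", method = "fixed",
                           value = threshold)
    if (!any(m)) next
    dm <- EBImage::distmap(array(as.numeric(m), dim = dim(m)))
    cell[, , z] <- m
    band[, , z] <- m & ((dm - 0.5) * px <= width_um)
  }
  if (!any(cell)) stop("no cell found in the actin channel")
  attr(band, "cell_mask") <- cell
  attr(band, "width_um") <- width_um
  band
}

#' Mean channel intensities within a 3D band mask
#'
#' Per-channel arithmetic mean over the voxels of the leading-edge band,
#' the volumetric leading-edge quantification of markers such as pMLC or
#' Arp2/3.
#'
#' @param zseries a 3D [tissue_image()].
#' @param band 3D logical mask from [leading_edge_band()].
#' @param channels channel names to quantify (default: all).
#' @return An object of class \code{"band_quant"}: list with
#'   \code{band_width_um}, \code{band_voxels}, \code{band_volume_um3} and
#'   \code{means} (named per-channel means).
#' @export
quantify_band <- function(zseries, band, channels = NULL) {
  stopifnot(inherits(zseries, "tissue_image"))
  if (is.null(channels)) channels <- names(zseries$channels)
  if (!any(band)) stop("empty band mask")
  means <- vapply(channels, function(ch) {
    v <- .get_channel(zseries, ch)
    stopifnot(identical(dim(v), dim(band)))
    mean(v[band])
  }, numeric(1))
  vox <- sum(band)
  structure(list(band_width_um = attr(band, "width_um"),
                 band_voxels = vox,
                 band_volume_um3 = vox * zseries$pixel_size^2 *
                   (if (is.null(zseries$z_step)) 1 else zseries$z_step),
                 means = means),
            class = "band_quant")
}

#' @export
print.band_quant <- function(x, ...) {
  cat(sprintf("band quantification (width %g um, %d voxels):\n",
              x$band_width_um, x$band_voxels))
  print(round(x$means, 4))
  invisible(x)
}
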