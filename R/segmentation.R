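#' Threshold an image channel into a binary mask
#'
#' Produces the binary mask used to identify cancer cells from the
#' cytokeratin stain (and nuclei from the nuclear stain). The default is
#' Otsu's automatic threshold, a deterministic replacement for interactive
#' thresholding; a fixed intensity value can be supplied for full
#' reproducibility.
#'
#' When the stained objects cover only a small fraction of the field, a
#' global Otsu threshold can land inside the background-noise
#' distribution; Gaussian pre-smoothing at roughly the object scale
#' (\code{smooth_sigma_um}) collapses the background mode and restores a
#' clean separation. Smoothing affects only the mask, never the intensity
#' values quantified downstream.
#'
#' @param img a [tissue_image()].
#' @param channel channel name to threshold.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param value intensity threshold, required for \code{method = "fixed"};
#'   pixels with intensity \code{>= value} enter the mask.
#' @param smooth_sigma_um optional Gaussian smoothing (um) applied to the
#'   channel before thresholding; 0 (default) disables it.
#' @return Logical array of the channel's shape with attribute
#'   \code{"provenance"} (channel, method, threshold value, smoothing). A
#'   constant channel under Otsu yields an all-zero mask with a
#'   \code{"degenerate"} attribute and a warning.
#' @export
threshold_channel <- function(img, channel, method = c("otsu", "fixed"),
                              value = NULL, smooth_sigma_um = 0) {
  method <- match.arg(method)
  ch <- .get_channel(img, channel)
  if (smooth_sigma_um > 0) {
    sig_px <- smooth_sigma_um / img$pixel_size
    if (sig_px > 0.25) {
      if (length(dim(ch)) == 3) {
        for (z in seq_len(dim(ch)[3]))
          ch[, , z] <- as.matrix(EBImage::gblur(ch[, , z], sigma = sig_px))
      } else {
        ch <- as.matrix(EBImage::gblur(ch, sigma = sig_px))
      }
    }
  }
  if (method == "fixed") {
    if (is.null(value)) stop("fixed thresholding requires a value")
    mask <- ch >= value
    thr <- value
  } else {
    rng <- range(ch)
    if (diff(rng) == 0) {
      warning("constant channel: Otsu threshold undefined, returning ",
              "all-zero mask")
      mask <- array(FALSE, dim = dim(ch))
      attr(mask, "degenerate") <- TRUE
      attr(mask, "provenance") <- list(channel = channel, method = method,
                                       value = NA_real_,
                                       smooth_sigma_um = smooth_sigma_um)
      return(mask)
    }
    v01 <- (ch - rng[1]) / diff(rng)
    dim(v01) <- c(length(v01), 1L)          # otsu needs a 2D frame
    t01 <- EBImage::otsu(v01, range = c(0, 1))
    thr <- rng[1] + t01 * diff(rng)
    mask <- ch > thr
  }
  attr(mask, "provenance") <- list(channel = channel, method = method,
                                   value = thr,
                                   smooth_sigma_um = smooth_sigma_um)
  mask
}

# connected-component labelling with optional splitting of touching
# objects: watershed on the mask-restricted intensity surface, seeded at
# its local maxima; `tolerance` is the minimum peak-to-saddle intensity
# drop for two seeds to stay separate objects
.label_mask <- function(mask, surface = NULL, split_touching = TRUE,
                        tolerance = 0.1) {
  m <- array(as.numeric(mask), dim = dim(mask))
  if (!split_touching || is.null(surface))
    return(EBImage::bwlabel(m))
  surf <- ifelse(mask, surface, 0)
  EBImage::watershed(surf, tolerance = tolerance, ext = 1)
}

#' Detect nuclei in a thresholded nuclei mask
#'
#' Connected components of the nuclei mask become candidate nuclei;
#' touching nuclei are split by a watershed on the mask-restricted
#' intensity surface seeded at its local maxima, so two nuclei merged in
#' the mask separate at the intensity saddle between their peaks.
#' Components smaller than \code{min_area} are discarded. Centroids are
#' intensity-weighted and reported in micrometres (pixel-centre
#' convention; origin at the image corner, y downward). Nuclei touching
#' the image border are retained: border handling belongs to the
#' downstream NND edge-exclusion rule.
#'
#' @param img a 2D [tissue_image()] with a nuclei channel.
#' @param mask_nuclei logical mask from [threshold_channel()].
#' @param min_area minimum nucleus area in um^2 (> 0).
#' @param channel intensity channel for splitting and centroid weighting.
#' @param split_touching split touching nuclei by watershed (default
#'   TRUE).
#' @param split_tolerance minimum peak-to-saddle intensity drop for the
#'   watershed to keep two seeds separate.
#' @param split_smooth_um Gaussian smoothing (um) of the watershed
#'   surface; suppresses spurious noise maxima inside a nucleus. Set to 0
#'   to use the raw channel.
#' @return Cell table: data frame with \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{area_um2}. Empty mask gives an empty table.
#' @export
detect_nuclei <- function(img, mask_nuclei, min_area = 4,
                          channel = "nuclei", split_touching = TRUE,
                          split_tolerance = 0.1, split_smooth_um = 1) {
  stopifnot(inherits(img, "tissue_image"), min_area > 0)
  ch <- .get_channel(img, channel)
  stopifnot(identical(dim(mask_nuclei), dim(ch)), length(dim(ch)) == 2)
  px <- img$pixel_size
  empty <- data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0))
  if (!any(mask_nuclei)) return(empty)
  surf <- ch
  if (split_touching && split_smooth_um / px > 0.25)
    surf <- as.matrix(EBImage::gblur(ch, sigma = split_smooth_um / px))
  lab <- .label_mask(mask_nuclei, surface = surf,
                     split_touching = split_touching,
                     tolerance = split_tolerance)
  idx <- which(lab > 0)
  if (!length(idx)) return(empty)
  labs <- lab[idx]
  nr <- nrow(ch)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  wt <- pmax(surf[idx], 0) + 1e-12   # guard all-zero intensities
  wsum <- tapply(wt, labs, sum)
  cx <- tapply(wt * cols, labs, sum) / wsum
  cy <- tapply(wt * rows, labs, sum) / wsum
  npix <- tapply(rep(1, length(labs)), labs, sum)
  area <- npix * px^2
  keep <- area >= min_area
  if (!any(keep)) return(empty)
  data.frame(cell_id = seq_len(sum(keep)),
             x_um = as.numeric((cx - 0.5) * px)[keep],
             y_um = as.numeric((cy - 0.5) * px)[keep],
             area_um2 = as.numeric(area)[keep])
}

# pixel (row, col) containing a um coordinate, clamped to the raster
.pixel_of <- function(x_um, y_um, dims, px) {
  col <- pmin(dims[2], pmax(1L, floor(x_um / px) + 1L))
  row <- pmin(dims[1], pmax(1L, floor(y_um / px) + 1L))
  cbind(row = row, col = col)
}

#' Keep nuclei that lie inside the cytokeratin mask
#'
#' Cancer cells are identified by cytokeratin positivity: a nucleus is a
#' cancer cell if its centroid pixel falls inside the cytokeratin binary
#' mask. Stromal and immune nuclei outside the mask are dropped.
#'
#' @param cells cell table from [detect_nuclei()].
#' @param ck_mask logical cytokeratin mask.
#' @param pixel_size um per pixel of the mask raster.
#' @return The retained rows with an \code{in_ck} column (all TRUE).
#' @export
identify_cancer_cells <- function(cells, ck_mask, pixel_size) {
  stopifnot(is.data.frame(cells),
            all(c("x_um", "y_um") %in% names(cells)), pixel_size > 0)
  if (nrow(cells) == 0) {
    cells$in_ck <- logical(0)
    return(cells)
  }
  pc <- .pixel_of(cells$x_um, cells$y_um, dim(ck_mask), pixel_size)
  inmask <- ck_mask[cbind(pc[, "row"], pc[, "col"])]
  out <- cells[inmask, , drop = FALSE]
  out$in_ck <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Segment cancer-cell centroids from a two-channel tissue image
#'
#' Convenience pipeline for tissue sections: threshold the nuclei
#' channel (with pre-smoothing), detect and split nuclei, threshold the
#' cytokeratin channel, and keep the cytokeratin-positive nuclei. The
#' result feeds directly into the nearest-neighbor invasion analysis.
#'
#' @param img a 2D [tissue_image()] with nuclei and cytokeratin
#'   channels.
#' @param nuclei_channel,ck_channel channel names.
#' @param min_area minimum nucleus area in um^2.
#' @param smooth_sigma_um pre-threshold smoothing for the nuclei mask.
#' @param ... further arguments passed to [detect_nuclei()].
#' @return Cell table of cancer cells (see [identify_cancer_cells()]).
#' @export
segment_cancer_cells <- function(img, nuclei_channel = "nuclei",
                                 ck_channel = "cytokeratin",
                                 min_area = 2, smooth_sigma_um = 1, ...) {
  nmask <- threshold_channel(img, nuclei_channel, method = "otsu",
                             smooth_sigma_um = smooth_sigma_um)
  cells <- detect_nuclei(img, nmask, min_area = min_area,
                         channel = nuclei_channel, ...)
  ck <- threshold_channel(img, ck_channel, method = "otsu")
  identify_cancer_cells(cells, ck, img$pixel_size)
}

#' Cell table to point pattern
#'
#' Converts segmented centroids into a [point_pattern()] for NND/LII
#' analysis; centroids outside the region (possible for cells straddling
#' the border) are dropped.
#'
#' @param cells cell table with \code{x_um}, \code{y_um}.
#' @param region an \code{invadex_region}.
#' @return A [point_pattern()].
#' @export
cells_to_pattern <- function(cells, region) {
  stopifnot(is.data.frame(cells),
            all(c("x_um", "y_um") %in% names(cells)))
  keep <- region_contains(cells$x_um, cells$y_um, region)
  point_pattern(cells$x_um[keep], cells$y_um[keep], region)
}

#' Count invading cells outside the central region of a 3D culture assay
#'
#' Implements the invasion-count procedure: maximum-intensity projection
#' of the nuclei z-series, automatic thresholding, connected-component
#' counting, and counting of the components whose centroid falls outside
#' the central matrix area. Centroids exactly on the central-region
#' boundary count as invaded (the exclusion zone is the region's open
#' interior). The count is invariant to the z-order of the series.
#'
#' Nuclei are sparse in the projected field, so the projection is
#' Gaussian-smoothed before automatic thresholding (maximum projection
#' amplifies background noise, and a global threshold on the raw
#' projection would sit inside the noise distribution).
#'
#' @param zseries a 3D [tissue_image()] with a \code{"nuclei"} channel.
#' @param central_region an \code{invadex_region} (polygon or rectangle)
#'   marking the central, non-invaded area, in um.
#' @param min_area minimum object area in um^2.
#' @param channel nuclei channel name.
#' @param smooth_sigma_um pre-threshold smoothing scale in um.
#' @return Integer count of invading cells.
#' @export
count_invading_cells <- function(zseries, central_region, min_area = 4,
                                 channel = "nuclei", smooth_sigma_um = 1.5) {
  stopifnot(inherits(zseries, "tissue_image"),
            inherits(central_region, "invadex_region"))
  if (region_area(central_region) <= 0) stop("degenerate central region")
  arr <- .get_channel(zseries, channel)
  stopifnot(length(dim(arr)) == 3)
  mip <- apply(arr, c(1, 2), max)
  sig_px <- smooth_sigma_um / zseries$pixel_size
  if (sig_px > 0.25)
    mip <- as.matrix(EBImage::gblur(mip, sigma = sig_px))
  img2 <- tissue_image(list(nuclei = mip), pixel_size = zseries$pixel_size)
  mask <- threshold_channel(img2, "nuclei", method = "otsu")
  cells <- detect_nuclei(img2, mask, min_area = min_area)
  if (nrow(cells) == 0) return(0L)
  inside_open <- region_contains(cells$x_um, cells$y_um, central_region) &
    region_boundary_distance(cells$x_um, cells$y_um, central_region) > 0
  sum(!inside_open)
}

#' Mean signal intensity within a binary mask
#'
#' Mask-restricted protein quantification: the arithmetic mean of a signal
#' channel over the pixels (or voxels) of a mask generated from another
#' stain, e.g. a marker signal within an F-actin mask.
#'
#' @param img a [tissue_image()].
#' @param signal_channel channel to quantify.
#' @param mask logical mask of the channel's shape.
#' @return Mean intensity (scalar).
#' @export
quantify_masked_intensity <- function(img, signal_channel, mask) {
  ch <- .get_channel(img, signal_channel)
  stopifnot(identical(dim(mask), dim(ch)))
  if (!any(mask)) stop("empty mask: mean intensity undefined")
  mean(ch[mask])
}
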