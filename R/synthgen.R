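#' Generate a synthetic cell-centroid point pattern
#'
#' Simulates cancer-cell nucleus positions in the configuration window
#' under one of three spatial processes:
#' \describe{
#'   \item{poisson}{complete spatial randomness at intensity \code{intensity}
#'     (a "dispersed" architecture; mean nearest-neighbor distance
#'     \eqn{1/(2\sqrt{\lambda})}).}
#'   \item{thomas_cluster}{a Thomas (Neyman-Scott) cluster process: Poisson
#'     parents at intensity \code{kappa}, each with a Poisson
#'     (\code{mu_offspring}) number of offspring displaced by an isotropic
#'     Gaussian with s.d. \code{sigma} um (a "cohesive" architecture).
#'     Parents are simulated in a window enlarged by \code{4 * sigma} on all
#'     sides so that offspring intensity has no edge deficit.}
#'   \item{hardcore}{a minimum-distance (hard-core) process by dart
#'     throwing: candidate points closer than \code{hardcore_dist} um to an
#'     accepted point are rejected (a "regular" architecture with inflated
#'     nearest-neighbor distances).}
#' }
#'
#' @param config a [sim_config()].
#' @param process one of \code{"poisson"}, \code{"thomas_cluster"},
#'   \code{"hardcore"}.
#' @param intensity target intensity lambda in cells/um^2 (> 0).
#' @param cluster_params for \code{thomas_cluster}: a list or named vector
#'   with \code{kappa} (parents/um^2), \code{sigma} (um) and
#'   \code{mu_offspring} (mean offspring per parent). Must satisfy
#'   \code{kappa * mu_offspring == intensity} (tolerance 1e-9).
#' @param hardcore_dist for \code{hardcore}: minimum inter-point distance in
#'   um; defaults to half the Poisson mean nearest-neighbor distance,
#'   \code{0.5 / (2 * sqrt(intensity))}.
#' @return A list with elements \code{pattern} (a [point_pattern()]) and
#'   \code{ground_truth} (list with the true centroids, the process and its
#'   parameters).
#' @examples
#' cfg <- sim_config(seed = 7, window = c(0, 0, 200, 200))
#' pp <- generate_point_pattern(cfg, "poisson", intensity = 0.01)
#' pp$pattern$n
#' @export
generate_point_pattern <- function(config, process = c("poisson",
                                                       "thomas_cluster",
                                                       "hardcore"),
                                   intensity, cluster_params = NULL,
                                   hardcore_dist = NULL) {
  stopifnot(inherits(config, "sim_config"))
  process <- match.arg(process)
  if (!is.numeric(intensity) || intensity <= 0)
    stop("intensity must be > 0")
  w <- config$window
  area <- region_area(w)
  set.seed(config$seed)

  if (process == "poisson") {
    n <- stats::rpois(1, intensity * area)
    x <- stats::runif(n, w$x0, w$x1)
    y <- stats::runif(n, w$y0, w$y1)
    params <- list(lambda = intensity)
  } else if (process == "thomas_cluster") {
    if (is.null(cluster_params))
      stop("thomas_cluster requires cluster_params (kappa, sigma, mu_offspring)")
    cp <- as.list(cluster_params)
    kappa <- cp$kappa; sigma <- cp$sigma; mu <- cp$mu_offspring
    stopifnot(is.numeric(kappa), is.numeric(sigma), is.numeric(mu),
              kappa > 0, sigma > 0, mu > 0)
    if (abs(kappa * mu - intensity) > 1e-9)
      stop("cluster params inconsistent with requested intensity: ",
           "kappa * mu_offspring must equal intensity")
    # plus-sampling: parents in a 4*sigma-dilated window
    ext <- 4 * sigma
    npar <- stats::rpois(1, kappa * (w$x1 - w$x0 + 2 * ext) *
                              (w$y1 - w$y0 + 2 * ext))
    px <- stats::runif(npar, w$x0 - ext, w$x1 + ext)
    py <- stats::runif(npar, w$y0 - ext, w$y1 + ext)
    noff <- stats::rpois(npar, mu)
    x <- rep(px, noff) + stats::rnorm(sum(noff), 0, sigma)
    y <- rep(py, noff) + stats::rnorm(sum(noff), 0, sigma)
    keep <- x > w$x0 & x < w$x1 & y > w$y0 & y < w$y1
    x <- x[keep]; y <- y[keep]
    params <- list(kappa = kappa, sigma = sigma, mu_offspring = mu)
  } else {
    if (is.null(hardcore_dist))
      hardcore_dist <- 0.25 / sqrt(intensity)
    stopifnot(hardcore_dist > 0)
    n_target <- stats::rpois(1, intensity * area)
    x <- numeric(n_target); y <- numeric(n_target)
    acc <- 0L
    max_tries <- max(1000L, 200L * n_target)
    tries <- 0L
    r2 <- hardcore_dist^2
    while (acc < n_target && tries < max_tries) {
      tries <- tries + 1L
      cx <- stats::runif(1, w$x0, w$x1)
      cy <- stats::runif(1, w$y0, w$y1)
      if (acc == 0L ||
          min((x[seq_len(acc)] - cx)^2 + (y[seq_len(acc)] - cy)^2) >= r2) {
        acc <- acc + 1L
        x[acc] <- cx; y[acc] <- cy
      }
    }
    if (acc < n_target)
      warning(sprintf(
        "hardcore dart throwing saturated at %d of %d points", acc, n_target))
    x <- x[seq_len(acc)]; y <- y[seq_len(acc)]
    params <- list(lambda = intensity, hardcore_dist = hardcore_dist)
  }

  pat <- point_pattern(x, y, w)
  list(pattern = pat,
       ground_truth = list(true_centroids = cbind(x = x, y = y),
                           process = process, intensity = intensity,
                           params = params))
}

# gaussian blob patch (peak amp, s.d. sd_px pixels) centred at
# (row0, col0) in fractional 1-based pixel coordinates; returns NULL or
# list(rows, cols, vals) for caller-side assignment (avoids copying the
# full image on every call)
.blob_patch <- function(nr, ncl, row0, col0, sd_px, amp = 1) {
  half <- ceiling(4 * sd_px)
  r0 <- max(1, floor(row0 - half)); r1 <- min(nr, ceiling(row0 + half))
  c0 <- max(1, floor(col0 - half)); c1 <- min(ncl, ceiling(col0 + half))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  gr <- exp(-((rows - row0)^2) / (2 * sd_px^2))
  gc <- exp(-((cols - col0)^2) / (2 * sd_px^2))
  list(rows = rows, cols = cols, vals = amp * outer(gr, gc))
}

# disc patch: list(rows, cols, sel) with sel the in-disc logical submatrix
.disc_patch <- function(nr, ncl, row0, col0, r_px) {
  r0 <- max(1, floor(row0 - r_px)); r1 <- min(nr, ceiling(row0 + r_px))
  c0 <- max(1, floor(col0 - r_px)); c1 <- min(ncl, ceiling(col0 + r_px))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  list(rows = rows, cols = cols,
       sel = outer((rows - row0)^2, (cols - col0)^2, "+") <= r_px^2)
}

#' Render a two-channel tissue image from a point pattern
#'
#' Emulates an immunofluorescence section: the \code{"nuclei"} channel is a
#' sum of Gaussian blobs (s.d. \code{nucleus_radius / 2}) peaking at each
#' centroid, and the \code{"cytokeratin"} channel is the binary union of
#' cell footprints (discs of radius \code{2 * nucleus_radius}). Additive
#' Gaussian noise with s.d. \code{peak / snr} is applied to both channels.
#'
#' @param pattern a [point_pattern()] (its region must be rectangular and
#'   match the configuration window).
#' @param config a [sim_config()]; \code{pixel_size} sets the raster.
#' @param nucleus_radius nucleus radius in um; must be at least
#'   \code{2 * pixel_size} to be resolvable.
#' @param snr peak signal-to-noise ratio (> 0).
#' @return List with \code{image} (a [tissue_image()]) and
#'   \code{ground_truth} (true centroids in um, the cytokeratin footprint
#'   mask, nucleus radius).
#' @export
render_tissue_image <- function(pattern, config, nucleus_radius = 3,
                                snr = 10) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(config, "sim_config"))
  if (nucleus_radius < 2 * config$pixel_size)
    stop("nucleus_radius below resolvability: need >= 2 * pixel_size")
  if (snr <= 0) stop("snr must be > 0")
  w <- config$window
  px <- config$pixel_size
  nc <- max(1L, round((w$x1 - w$x0) / px))
  nr <- max(1L, round((w$y1 - w$y0) / px))
  nuc <- matrix(0, nr, nc)
  ck <- matrix(0, nr, nc)
  sd_px <- (nucleus_radius / 2) / px
  ck_r_px <- (2 * nucleus_radius) / px
  # pixel (i, j) centre at ((j - 0.5) px, (i - 0.5) px), 1-based
  col0 <- (pattern$x - w$x0) / px + 0.5
  row0 <- (pattern$y - w$y0) / px + 0.5
  for (k in seq_len(pattern$n)) {
    p <- .blob_patch(nr, nc, row0[k], col0[k], sd_px)
    if (!is.null(p))
      nuc[p$rows, p$cols] <- nuc[p$rows, p$cols] + p$vals
    p <- .disc_patch(nr, nc, row0[k], col0[k], ck_r_px)
    if (!is.null(p)) {
      sub <- ck[p$rows, p$cols, drop = FALSE]
      sub[p$sel] <- 1
      ck[p$rows, p$cols] <- sub
    }
  }
  footprint <- ck > 0.5
  set.seed(config$seed + 1L)
  nuc <- nuc + matrix(stats::rnorm(nr * nc, 0, 1 / snr), nr, nc)
  ck <- ck + matrix(stats::rnorm(nr * nc, 0, 1 / snr), nr, nc)
  img <- tissue_image(list(nuclei = nuc, cytokeratin = ck), pixel_size = px)
  list(image = img,
       ground_truth = list(true_centroids = cbind(x = pattern$x,
                                                  y = pattern$y),
                           footprint = footprint,
                           nucleus_radius = nucleus_radius, snr = snr))
}

#' Generate a synthetic kymograph with planted ruffle traces
#'
#' Membrane ruffles appear in a kymograph as bright sloped streaks; the
#' slope is the ruffle speed. Traces are rendered as Gaussian-profile lines
#' (cross-section s.d. 1 px) of unit amplitude over a noisy background. All
#' traces in one kymograph share the same signed slope (parallel streaks),
#' with starting offsets spaced so traces do not merge.
#'
#' @param config a [sim_config()]; \code{pixel_size} is the space scale in
#'   um/px.
#' @param n_ruffles number of traces to plant (>= 0).
#' @param speed ruffle speed in um/min (>= 0; 0 plants static vertical
#'   traces).
#' @param duration kymograph duration in minutes.
#' @param extent spatial extent of the kymograph line in um.
#' @param time_scale seconds per frame.
#' @param trace_duration duration of each individual trace in minutes.
#' @param snr peak signal-to-noise ratio; \code{Inf} for a noise-free
#'   raster.
#' @return List with \code{kymo} (a [kymograph()]) and \code{ground_truth}
#'   (data frame of \code{start_x} um, \code{start_t} min, signed
#'   \code{speed} um/min).
#' @export
generate_kymograph <- function(config, n_ruffles, speed, duration = 45,
                               extent = 20, time_scale = 2,
                               trace_duration = 2, snr = 10) {
  stopifnot(inherits(config, "sim_config"), n_ruffles >= 0, speed >= 0,
            duration > 0, extent > 0, trace_duration > 0)
  sp_scale <- config$pixel_size
  n_space <- max(8L, round(extent / sp_scale))
  n_time <- max(8L, round(duration * 60 / time_scale))
  set.seed(config$seed)
  raster <- if (is.finite(snr))
    matrix(stats::rnorm(n_space * n_time, 0, 1 / snr), n_space, n_time)
  else matrix(0, n_space, n_time)

  gt <- data.frame(start_x = numeric(0), start_t = numeric(0),
                   speed = numeric(0))
  if (n_ruffles > 0) {
    v_px <- (speed / 60) * time_scale / sp_scale      # px per frame
    dir <- sample(c(-1, 1), 1)
    len_frames <- min(n_time, max(4L, round(trace_duration * 60 / time_scale)))
    # spread trace positions over space so parallel traces stay separated;
    # start times are resampled until the line intercepts (x0 - v * t0)
    # are at least 6 px apart, so no two traces ever come close
    slots <- seq(2, n_space - 1, length.out = n_ruffles + 2L)[-c(1, n_ruffles + 2L)]
    jitter_amp <- if (n_ruffles > 1) min(1.5, diff(slots[1:2]) / 4) else 1.5
    x0 <- slots + stats::runif(n_ruffles, -jitter_amp, jitter_amp)
    t0 <- sample.int(max(1L, n_time - len_frames), n_ruffles, replace = TRUE)
    if (n_ruffles > 1) {
      for (try in seq_len(200L)) {
        b <- x0 - dir * v_px * t0
        if (min(dist(b)) >= 6) break
        t0 <- sample.int(max(1L, n_time - len_frames), n_ruffles,
                         replace = TRUE)
      }
      if (min(dist(x0 - dir * v_px * t0)) < 6)
        t0 <- rep(t0[1], n_ruffles)   # fall back to synchronous starts
    }
    for (k in seq_len(n_ruffles)) {
      frames <- t0[k]:(t0[k] + len_frames - 1L)
      xs <- x0[k] + dir * v_px * (frames - t0[k])
      ok <- xs >= 1 & xs <= n_space & frames <= n_time
      frames <- frames[ok]; xs <- xs[ok]
      for (m in seq_along(frames)) {
        rows <- max(1, floor(xs[m] - 3)):min(n_space, ceiling(xs[m] + 3))
        raster[rows, frames[m]] <- raster[rows, frames[m]] +
          exp(-((rows - xs[m])^2) / 2)
      }
      gt <- rbind(gt, data.frame(start_x = (x0[k] - 0.5) * sp_scale,
                                 start_t = (t0[k] - 1) * time_scale / 60,
                                 speed = dir * speed))
    }
  }
  list(kymo = kymograph(raster, space_scale = sp_scale,
                        time_scale = time_scale),
       ground_truth = gt)
}

#' Generate a confocal z-series with a membrane-proximal enriched band
#'
#' Renders a disc-shaped cell (uniform \code{"actin"} channel) and a
#' \code{"marker"} channel whose intensity inside the band within
#' \code{band_width} um of the cell edge is \code{enrichment} times the
#' interior level. Used to validate leading-edge band masking and
#' quantification.
#'
#' @param config a [sim_config()].
#' @param band_width band width in um.
#' @param enrichment in-band over interior intensity ratio (> 0).
#' @param cell_radius cell radius in um.
#' @param n_z number of z-slices.
#' @param base_intensity interior marker intensity.
#' @param snr peak signal-to-noise ratio; \code{Inf} disables noise.
#' @return List with \code{image} (3D [tissue_image()], z-step 0.2 um) and
#'   \code{ground_truth} (cell centre and radius in um, band width,
#'   enrichment).
#' @export
generate_zseries_with_band <- function(config, band_width = 3,
                                       enrichment = 2, cell_radius = 10,
                                       n_z = 5, base_intensity = 0.4,
                                       snr = 20) {
  stopifnot(inherits(config, "sim_config"), band_width > 0, enrichment > 0,
            cell_radius > band_width, n_z >= 1)
  w <- config$window; px <- config$pixel_size
  nc <- max(8L, round((w$x1 - w$x0) / px))
  nr <- max(8L, round((w$y1 - w$y0) / px))
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2           # pixel coords of centre
  r_px <- cell_radius / px
  band_px <- band_width / px
  d <- sqrt(outer(((1:nr) - cy)^2, ((1:nc) - cx)^2, "+"))
  inside <- d <= r_px
  in_band <- inside & d >= (r_px - band_px)
  actin2d <- ifelse(inside, 1, 0)
  marker2d <- ifelse(inside,
                     ifelse(in_band, base_intensity * enrichment,
                            base_intensity), 0)
  actin <- array(rep(actin2d, n_z), dim = c(nr, nc, n_z))
  marker <- array(rep(marker2d, n_z), dim = c(nr, nc, n_z))
  if (is.finite(snr)) {
    set.seed(config$seed)
    actin <- actin + array(stats::rnorm(length(actin), 0, 1 / snr),
                           dim = dim(actin))
    marker <- marker + array(stats::rnorm(length(marker), 0, 1 / snr),
                             dim = dim(marker))
  }
  img <- tissue_image(list(actin = actin, marker = marker),
                      pixel_size = px, z_step = 0.2)
  list(image = img,
       ground_truth = list(
         center = c(x = (cx - 0.5) * px, y = (cy - 0.5) * px),
         cell_radius = cell_radius, band_width = band_width,
         enrichment = enrichment, base_intensity = base_intensity))
}

#' Generate a 3D invasion-assay image with central and invaded cells
#'
#' Emulates the 3D culture invasion assay: nuclei of \code{n_central} cells
#' are placed inside a central circular matrix region and \code{n_invaded}
#' cells outside it (the invaded zone). Each nucleus is rendered as a
#' Gaussian blob in one z-slice of the \code{"nuclei"} channel. A margin
#' around the central boundary is kept free of cells so ground-truth labels
#' are unambiguous.
#'
#' @param config a [sim_config()].
#' @param n_central,n_invaded cell counts inside / outside the central
#'   region (>= 0).
#' @param central_radius radius of the central region in um; default 30\%
#'   of the window's smaller side.
#' @param nucleus_radius nucleus radius in um.
#' @param n_z number of z-slices (z-step 1.5 um).
#' @param snr peak signal-to-noise ratio.
#' @return List with \code{image} (3D [tissue_image()]),
#'   \code{central_region} (an [region_disc()]) and \code{ground_truth}
#'   (centroids, labels \code{"central"} / \code{"invaded"}, counts).
#' @export
generate_invasion_field <- function(config, n_central, n_invaded,
                                    central_radius = NULL,
                                    nucleus_radius = 3, n_z = 4, snr = 10) {
  stopifnot(inherits(config, "sim_config"), n_central >= 0, n_invaded >= 0)
  w <- config$window; px <- config$pixel_size
  if (is.null(central_radius))
    central_radius <- 0.3 * min(w$x1 - w$x0, w$y1 - w$y0)
  ccx <- (w$x0 + w$x1) / 2; ccy <- (w$y0 + w$y1) / 2
  margin <- 3 * nucleus_radius
  min_sep <- 3 * nucleus_radius
  set.seed(config$seed)

  throw <- function(n, accept) {
    xs <- numeric(n); ys <- numeric(n); acc <- 0L; tries <- 0L
    while (acc < n && tries < 500L * max(n, 1L)) {
      tries <- tries + 1L
      cx <- stats::runif(1, w$x0 + margin, w$x1 - margin)
      cy <- stats::runif(1, w$y0 + margin, w$y1 - margin)
      if (!accept(cx, cy)) next
      if (acc > 0L &&
          min((xs[seq_len(acc)] - cx)^2 + (ys[seq_len(acc)] - cy)^2) <
            min_sep^2) next
      acc <- acc + 1L; xs[acc] <- cx; ys[acc] <- cy
    }
    if (acc < n) stop("could not place requested number of cells")
    cbind(x = xs, y = ys)
  }
  rad <- function(cx, cy) sqrt((cx - ccx)^2 + (cy - ccy)^2)
  ctr <- throw(n_central, function(cx, cy)
    rad(cx, cy) < central_radius - margin)
  inv <- throw(n_invaded, function(cx, cy)
    rad(cx, cy) > central_radius + margin)
  pts <- rbind(ctr, inv)
  labels <- rep(c("central", "invaded"), c(n_central, n_invaded))

  nc <- max(8L, round((w$x1 - w$x0) / px))
  nr <- max(8L, round((w$y1 - w$y0) / px))
  nuc <- array(0, dim = c(nr, nc, n_z))
  sd_px <- (nucleus_radius / 2) / px
  ntot <- nrow(pts)
  zslice <- if (ntot > 0) sample.int(n_z, ntot, replace = TRUE) else integer(0)
  for (k in seq_len(ntot)) {
    col0 <- (pts[k, "x"] - w$x0) / px + 0.5
    row0 <- (pts[k, "y"] - w$y0) / px + 0.5
    p <- .blob_patch(nr, nc, row0, col0, sd_px)
    if (!is.null(p))
      nuc[p$rows, p$cols, zslice[k]] <- nuc[p$rows, p$cols, zslice[k]] +
        p$vals
  }
  nuc <- nuc + array(stats::rnorm(length(nuc), 0, 1 / snr), dim = dim(nuc))
  img <- tissue_image(list(nuclei = nuc), pixel_size = px, z_step = 1.5)
  list(image = img,
       central_region = region_disc(ccx, ccy, central_radius),
       ground_truth = list(true_centroids = pts, true_labels = labels,
                           true_counts = c(central = n_central,
                                           invaded = n_invaded)))
}

#' Generate a synthetic DCIS tumor section
#'
#' Renders a mid-section of an intraductal xenograft tumor: a circular
#' tumor region (\code{"tissue"} channel), a cellular compartment covering
#' approximately \code{cellular_fraction} of the tumor area, and
#' \code{n_structures} intact DCIS structures drawn as bright rings
#' (annulus intensity 1, acellular lumen) over the diffuse cellular
#' background (intensity 0.5). For cellular fractions above 0.55 the
#' diffuse compartment is the whole tumor disc with stromal holes carved
#' out; below that it is a set of non-overlapping cellular blobs.
#'
#' @param config a [sim_config()].
#' @param n_structures number of DCIS structures (>= 0).
#' @param cellular_fraction target cellular area / tumor area, in [0, 1].
#' @return List with \code{image} (2D [tissue_image()] with channels
#'   \code{tissue} and \code{cells}) and \code{ground_truth}
#'   (\code{n_structures}, planted and realized cellular fraction, tumor
#'   area in um^2).
#' @export
generate_dcis_section <- function(config, n_structures, cellular_fraction) {
  stopifnot(inherits(config, "sim_config"), n_structures >= 0,
            cellular_fraction >= 0, cellular_fraction <= 1)
  w <- config$window; px <- config$pixel_size
  set.seed(config$seed)
  nc <- max(16L, round((w$x1 - w$x0) / px))
  nr <- max(16L, round((w$y1 - w$y0) / px))
  R <- 0.4 * min(w$x1 - w$x0, w$y1 - w$y0)          # tumor radius, um
  ccx_px <- nc / 2 + 0.5; ccy_px <- nr / 2 + 0.5
  R_px <- R / px
  d <- sqrt(outer(((1:nr) - ccy_px)^2, ((1:nc) - ccx_px)^2, "+"))
  tissue <- ifelse(d <= R_px, 1, 0)
  tumor_area <- pi * R^2

  target_cell <- cellular_fraction * tumor_area
  r_o <- R / 8
  if (n_structures > 0) {
    ring_area_tot <- n_structures * pi * r_o^2 * 0.75   # lumen = r_o / 2
    if (cellular_fraction > 0 && ring_area_tot > 0.8 * target_cell)
      r_o <- sqrt(0.8 * target_cell / (n_structures * pi * 0.75))
  }
  r_i <- r_o / 2

  # dart-throw non-overlapping centres inside radius R - rad - 2 um
  place <- function(n, rad, others, other_rad) {
    xs <- numeric(n); ys <- numeric(n); acc <- 0L; tries <- 0L
    while (acc < n && tries < 2000L * max(n, 1L)) {
      tries <- tries + 1L
      th <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * max(R - rad - 2, 1)
      cx <- rr * cos(th); cy <- rr * sin(th)        # relative to tumor centre
      ok <- TRUE
      if (acc > 0L &&
          min((xs[seq_len(acc)] - cx)^2 + (ys[seq_len(acc)] - cy)^2) <
            (2 * rad + 2)^2) ok <- FALSE
      if (ok && !is.null(others) && nrow(others) > 0 &&
          min((others[, 1] - cx)^2 + (others[, 2] - cy)^2) <
            (rad + other_rad + 2)^2) ok <- FALSE
      if (ok) { acc <- acc + 1L; xs[acc] <- cx; ys[acc] <- cy }
    }
    if (acc < n) stop("could not place requested DCIS structures: ",
                      "too many for the tumor area")
    cbind(xs[seq_len(acc)], ys[seq_len(acc)])
  }

  rings <- place(n_structures, r_o, NULL, 0)
  cells <- matrix(0, nr, nc)
  cx_px <- function(ux) ccx_px + ux / px
  cy_px <- function(uy) ccy_px + uy / px
  paint <- function(mat, row0, col0, r_px, value) {
    p <- .disc_patch(nrow(mat), ncol(mat), row0, col0, r_px)
    if (is.null(p)) return(mat)
    sub <- mat[p$rows, p$cols, drop = FALSE]
    sub[p$sel] <- value
    mat[p$rows, p$cols] <- sub
    mat
  }

  # budget-driven painting: add discs (cellular blobs or stromal holes)
  # one at a time, away from the rings, until the cellular pixel budget
  # is met; overlap between discs only slows progress, never breaks it
  paint_until <- function(mat, r_disc, value, target_px, max_discs) {
    placed <- 0L; tries <- 0L
    current <- function() sum(mat > 0.25 & tissue > 0)
    done <- function() if (value > 0) current() >= target_px
                       else current() <= target_px
    while (!done() && placed < max_discs && tries < 50L * max_discs) {
      tries <- tries + 1L
      th <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * max(R - r_disc - 2, 1)
      cx <- rr * cos(th); cy <- rr * sin(th)
      if (n_structures > 0 &&
          min((rings[, 1] - cx)^2 + (rings[, 2] - cy)^2) <
            (r_disc + r_o + 2)^2) next
      mat <- paint(mat, cy_px(cy), cx_px(cx), r_disc / px, value)
      placed <- placed + 1L
    }
    mat
  }
  tissue_px <- sum(tissue > 0)
  diffuse_area <- max(0, target_cell - n_structures * pi * (r_o^2 - r_i^2))
  if (cellular_fraction > 0.55) {
    # whole-disc cellular compartment with stromal holes carved out
    cells[tissue > 0] <- 0.5
    r_h <- max(2 * px, r_o / 2)
    # the lumens carved after ring painting remove n * pi * r_i^2 more
    target_px <- round((target_cell + n_structures * pi * r_i^2) / px^2)
    cells <- paint_until(cells, r_h, 0, target_px,
                         max_discs = 4L * ceiling((1 - cellular_fraction) *
                                                  tumor_area /
                                                  (pi * r_h^2) + 1))
  } else if (diffuse_area > 0) {
    r_b <- max(2 * px, r_o / 2)
    target_px <- round(diffuse_area / px^2)
    cells <- paint_until(cells, r_b, 0.5, target_px,
                         max_discs = 6L * ceiling(diffuse_area /
                                                  (pi * r_b^2) + 1))
  }
  for (k in seq_len(n_structures)) {
    cells <- paint(cells, cy_px(rings[k, 2]), cx_px(rings[k, 1]),
                   r_o / px, value = 1)
    cells <- paint(cells, cy_px(rings[k, 2]), cx_px(rings[k, 1]),
                   r_i / px, value = 0)
  }
  realized <- sum(cells > 0.25 & tissue > 0) / sum(tissue > 0)
  img <- tissue_image(list(tissue = tissue, cells = cells), pixel_size = px)
  list(image = img,
       ground_truth = list(n_structures = n_structures,
                           cellular_fraction = cellular_fraction,
                           realized_cellular_fraction = realized,
                           tumor_area_um2 = tumor_area))
}

#' Sample a 2x2 contingency table at a known odds ratio
#'
#' Draws binomial outcome counts for an exposed and an unexposed group with
#' the exposed odds scaled by \code{true_or} relative to
#' \code{baseline_risk}. Used to validate odds-ratio estimation, Fisher's
#' exact test and exact confidence-interval coverage.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param n_exposed,n_unexposed group sizes (> 0).
#' @param baseline_risk outcome probability in the unexposed group, in
#'   (0, 1).
#' @param true_or odds ratio of the exposed relative to the unexposed
#'   group (> 0).
#' @param study_id identifier carried into the table.
#' @return List with \code{table} (a [contingency_2x2()]) and
#'   \code{ground_truth} (\code{true_or}, the two outcome probabilities).
#' @export
generate_contingency <- function(config, n_exposed, n_unexposed,
                                 baseline_risk, true_or,
                                 study_id = "synthetic") {
  stopifnot(inherits(config, "sim_config"),
            n_exposed > 0, n_unexposed > 0,
            baseline_risk > 0, baseline_risk < 1, true_or > 0)
  odds1 <- true_or * baseline_risk / (1 - baseline_risk)
  p1 <- odds1 / (1 + odds1)
  set.seed(config$seed)
  a <- stats::rbinom(1, n_exposed, p1)
  c_ <- stats::rbinom(1, n_unexposed, baseline_risk)
  tab <- contingency_2x2(a = a, b = n_exposed - a, c = c_,
                         d = n_unexposed - c_, study_id = study_id)
  list(table = tab,
       ground_truth = list(true_or = true_or, p_exposed = p1,
                           p_unexposed = baseline_risk))
}

#' Generate a grouped expression matrix with planted differential genes
#'
#' Log-normal intensities: per-gene baselines are drawn from
#' N(\code{base_log2}, 1) on the log2 scale and sample values from
#' N(baseline, \code{sigma_log2}). A planted hit set of size
#' \code{round(planted_fraction * n_genes)} receives a multiplicative
#' \code{planted_fc} fold change in group A (direction random per gene).
#' The returned matrix is on the linear intensity scale.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param n_genes number of genes.
#' @param n_samples_per_group samples in each of the two groups.
#' @param planted_fc fold change planted on hit genes (> 0).
#' @param planted_fraction fraction of genes planted as hits, in [0, 1].
#' @param sigma_log2 within-group s.d. on the log2 scale.
#' @param base_log2 mean log2 baseline intensity.
#' @return List with \code{expr} (matrix, genes x samples), \code{groups}
#'   (factor \code{"A"} / \code{"B"} per sample) and \code{ground_truth}
#'   (hit gene names and per-hit signed log2 fold change).
#' @export
generate_expression <- function(config, n_genes, n_samples_per_group,
                                planted_fc = 4, planted_fraction = 0.05,
                                sigma_log2 = 0.5, base_log2 = 8) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 1,
            n_samples_per_group >= 2, planted_fc > 0,
            planted_fraction >= 0, planted_fraction <= 1)
  set.seed(config$seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_hit <- round(planted_fraction * n_genes)
  hits <- sort(sample.int(n_genes, n_hit))
  sign_hit <- sample(c(-1, 1), n_hit, replace = TRUE)
  mu <- stats::rnorm(n_genes, base_log2, 1)
  ns <- n_samples_per_group
  log2mat <- matrix(stats::rnorm(n_genes * 2 * ns, mean = mu,
                                 sd = sigma_log2),
                    nrow = n_genes, ncol = 2 * ns)
  delta <- numeric(n_genes)
  delta[hits] <- sign_hit * log2(planted_fc)
  log2mat[, seq_len(ns)] <- log2mat[, seq_len(ns)] + delta
  expr <- 2^log2mat
  rownames(expr) <- genes
  colnames(expr) <- c(sprintf("A_%02d", seq_len(ns)),
                      sprintf("B_%02d", seq_len(ns)))
  groups <- factor(rep(c("A", "B"), each = ns), levels = c("A", "B"))
  list(expr = expr, groups = groups,
       ground_truth = list(true_de_genes = genes[hits],
                           log2fc = stats::setNames(delta[hits], genes[hits]),
                           planted_fc = planted_fc))
}
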