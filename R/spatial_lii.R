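#' Per-cell nearest-neighbor distances
#'
#' For every cell in the pattern, the Euclidean distance to the nucleus of
#' its most proximal neighboring cell. A grid-bucketed search is used
#' internally; results are exactly those of the all-pairs computation,
#' with distance ties broken by the lowest neighbor id.
#'
#' Duplicate centroids (distance 0) are rejected: identical coordinates
#' indicate an upstream segmentation fault, and a zero NND would be
#' meaningless for the invasion index.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @return Data frame with one row per cell: \code{cell_id}, \code{x},
#'   \code{y} (um), \code{nnd} (um), \code{neighbor_id}.
#' @examples
#' pp <- point_pattern(c(0, 3), c(0, 4), region_rect(-10, -10, 10, 10))
#' compute_nnd(pp)$nnd  # both 5 (3-4-5 triangle)
#' @export
compute_nnd <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2)
    stop("nearest-neighbor distance requires at least 2 points")
  res <- .nnd_grid(pattern$x, pattern$y)
  if (any(res$nnd == 0))
    stop("duplicate centroids (distance 0) found; ",
         "deduplicate upstream before NND analysis")
  data.frame(cell_id = seq_len(pattern$n), x = pattern$x, y = pattern$y,
             nnd = res$nnd, neighbor_id = res$neighbor)
}

#' Border correction: flag cells whose NND zone leaves the region
#'
#' A cell is retained only if the closed disc centred on it with radius
#' equal to its nearest-neighbor distance lies entirely within the
#' analysis region; cells near the border whose true nearest neighbor may
#' lie outside the analyzed area are excluded. Tangency (disc touching the
#' boundary) counts as contained. Exclusion never alters a cell's NND
#' value, only its \code{included} flag.
#'
#' @param records NND records from [compute_nnd()].
#' @param region the \code{invadex_region} the records were computed on.
#' @return The records with a logical \code{included} column added.
#' @export
apply_edge_exclusion <- function(records, region) {
  stopifnot(is.data.frame(records),
            all(c("x", "y", "nnd") %in% names(records)),
            inherits(region, "invadex_region"))
  if (region_area(region) <= 0) stop("region of zero area")
  bd <- region_boundary_distance(records$x, records$y, region)
  records$included <- bd >= records$nnd
  records
}

#' Local Invasion Index of a cell pattern
#'
#' The LII of a tumor region is the arithmetic mean nearest-neighbor
#' distance over the (border-corrected) cancer cells it contains. Widely
#' scattered cells give a high LII; cohesive nests give a low one.
#'
#' @param records NND records, optionally carrying an \code{included}
#'   column from [apply_edge_exclusion()]; without one, all cells enter
#'   the mean.
#' @param low_cut,high_cut bin boundaries in um passed to
#'   [classify_lii()].
#' @return An object of class \code{"lii_result"}: list with \code{lii}
#'   (um), \code{n_total}, \code{n_included}, \code{bin} and
#'   \code{per_cell} (the input records).
#' @export
compute_lii <- function(records, low_cut = 7, high_cut = 9) {
  stopifnot(is.data.frame(records), "nnd" %in% names(records),
            nrow(records) >= 1)
  inc <- if ("included" %in% names(records)) records$included
         else rep(TRUE, nrow(records))
  if (!any(inc))
    stop("all cells excluded by the border correction; no LII defined")
  lii <- mean(records$nnd[inc])
  structure(list(lii = lii, n_total = nrow(records),
                 n_included = sum(inc),
                 bin = classify_lii(lii, low_cut, high_cut),
                 per_cell = records),
            class = "lii_result")
}

#' @export
print.lii_result <- function(x, ...) {
  cat(sprintf("LII = %.2f um (%s bin); %d of %d cells after border correction\n",
              x$lii, x$bin, x$n_included, x$n_total))
  invisible(x)
}

#' Classify an LII value into invasion bins
#'
#' Tumors with LII at or below \code{low_cut} are "low" (cohesive, weakly
#' invasive); at or above \code{high_cut} they are "high" (scattered,
#' invasive); values in the open gap are "intermediate". Both boundaries
#' are inclusive of their extreme bin.
#'
#' @param lii LII value(s) in um.
#' @param low_cut,high_cut bin boundaries in um (default 7 and 9);
#'   \code{low_cut} must not exceed \code{high_cut}.
#' @return Character vector of \code{"low"}, \code{"intermediate"},
#'   \code{"high"}.
#' @examples
#' classify_lii(c(6.5, 8, 9.5))
#' @export
classify_lii <- function(lii, low_cut = 7, high_cut = 9) {
  if (low_cut > high_cut) stop("low_cut must not exceed high_cut")
  out <- ifelse(lii <= low_cut, "low",
                ifelse(lii >= high_cut, "high", "intermediate"))
  unname(out)
}

#' Pattern-to-LII convenience wrapper
#'
#' Runs [compute_nnd()], [apply_edge_exclusion()] and [compute_lii()] in
#' sequence. The border correction can be disabled to average over all
#' cells instead.
#'
#' @param pattern a [point_pattern()].
#' @param edge_exclusion apply the border correction (default TRUE).
#' @param low_cut,high_cut bin boundaries in um.
#' @return An \code{"lii_result"}.
#' @export
lii_from_pattern <- function(pattern, edge_exclusion = TRUE,
                             low_cut = 7, high_cut = 9) {
  rec <- compute_nnd(pattern)
  if (edge_exclusion) rec <- apply_edge_exclusion(rec, pattern$region)
  compute_lii(rec, low_cut = low_cut, high_cut = high_cut)
}

#' Welch comparison of two LII (or NND) samples
#'
#' Unequal-variance two-sample comparison used for cohort-level contrasts
#' of tumor LII values or per-cell NND distributions.
#'
#' @param a,b numeric vectors (um), each with at least 2 values.
#' @return List with \code{mean_difference} (mean(a) - mean(b)),
#'   \code{statistic} (Welch t), \code{df} and \code{p}.
#' @export
compare_lii_groups <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      stop("both groups constant and equal: comparison degenerate")
    stop("zero variance in both groups: comparison degenerate")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_difference = mean(a) - mean(b),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

.summarize_nnd <- function(v, breaks) {
  med <- stats::median(v)
  counts <- as.vector(table(cut(v, breaks, right = TRUE,
                                include.lowest = TRUE)))
  names(counts) <- paste0("(", breaks[-length(breaks)], ",", breaks[-1], "]")
  list(n = length(v), mean = mean(v), median = med,
       # exactly-median values are assigned to the lower subset
       n_above_median = sum(v > med), n_below_median = sum(v <= med),
       histogram_counts = counts,
       histogram_pct = 100 * counts / length(v))
}

#' Population analysis of per-cell NND distributions
#'
#' Summarizes two per-cell NND samples (for example, matched tumor samples
#' before and after endocrine therapy): per-group median split (cells with
#' exactly the median value go to the lower subset), bin histogram over
#' configurable um breaks, and a Welch comparison of the two
#' distributions.
#'
#' @param nnd_a,nnd_b numeric vectors of per-cell NND (um), or NND record
#'   data frames from [compute_nnd()] (included cells only are used when
#'   an \code{included} column is present).
#' @param breaks histogram bin boundaries in um; the last break is raised
#'   to cover the data when needed.
#' @return List with \code{group_a}, \code{group_b} (per-group summaries),
#'   \code{welch} (statistic, df, p) and \code{mean_difference}
#'   (a minus b).
#' @export
population_analysis <- function(nnd_a, nnd_b,
                                breaks = c(0, 3, 5, 7, 9, 11, 13, 20)) {
  pull <- function(v) {
    if (is.data.frame(v)) {
      inc <- if ("included" %in% names(v)) v$included else TRUE
      v <- v$nnd[inc]
    }
    as.numeric(v)
  }
  a <- pull(nnd_a); b <- pull(nnd_b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 cells")
  top <- max(a, b)
  if (top > max(breaks)) breaks[length(breaks)] <- top
  cmp <- compare_lii_groups(a, b)
  list(group_a = .summarize_nnd(a, breaks),
       group_b = .summarize_nnd(b, breaks),
       welch = list(statistic = cmp$statistic, df = cmp$df, p = cmp$p),
       mean_difference = cmp$mean_difference)
}
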