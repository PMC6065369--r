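#' Write a tissue image to a multi-directory TIFF
#'
#' One TIFF directory per channel (and per z-slice for 3D images,
#' channel-major order), 32-bit samples, intensities clipped to [0, 1].
#' Because baseline TIFF tags cannot carry the channel layout, the
#' physical pixel size, channel names and z-step are written to a YAML
#' sidecar file at \code{<path>.yml}; [read_tissue_tiff()] uses it to
#' reconstruct the object (or takes the metadata as arguments).
#'
#' @param img a [tissue_image()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tissue_tiff <- function(img, path) {
  stopifnot(inherits(img, "tissue_image"))
  nz <- if (length(img$dim) == 3) img$dim[3] else 1L
  frames <- list()
  for (ch in names(img$channels)) {
    v <- img$channels[[ch]]
    for (z in seq_len(nz)) {
      m <- if (nz > 1L) v[, , z] else v
      frames[[length(frames) + 1L]] <- pmax(pmin(m, 1), 0)
    }
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none")
  meta <- list(channels = as.list(names(img$channels)), nz = nz,
               pixel_size = img$pixel_size,
               z_step = if (is.null(img$z_step)) "NA" else img$z_step)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a tissue image written by [write_tissue_tiff()]
#'
#' @param path TIFF file path; metadata comes from the \code{<path>.yml}
#'   sidecar unless overridden by the arguments.
#' @param pixel_size um per pixel (overrides the sidecar).
#' @param channel_names channel names in directory order (overrides the
#'   sidecar; with \code{n_z} they define the layout when no sidecar
#'   exists).
#' @param n_z number of z-slices per channel.
#' @param z_step um between z-slices.
#' @return A [tissue_image()].
#' @export
read_tissue_tiff <- function(path, pixel_size = NULL, channel_names = NULL,
                             n_z = NULL, z_step = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (is.null(channel_names)) channel_names <- unlist(meta$channels)
    if (is.null(n_z)) n_z <- meta$nz
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    if (is.null(z_step) && !identical(meta$z_step, "NA"))
      z_step <- meta$z_step
  }
  if (is.null(pixel_size) || is.null(channel_names))
    stop("no metadata sidecar found; supply pixel_size and channel_names")
  if (is.null(n_z)) n_z <- 1L
  stopifnot(length(frames) == length(channel_names) * n_z)
  channels <- list()
  k <- 0L
  for (ch in channel_names) {
    if (n_z > 1L) {
      sl <- lapply(seq_len(n_z), function(z) frames[[k + z]])
      channels[[ch]] <- array(unlist(sl), dim = c(dim(sl[[1]]), n_z))
    } else {
      channels[[ch]] <- frames[[k + 1L]]
    }
    k <- k + n_z
  }
  tissue_image(channels, pixel_size = pixel_size, z_step = z_step)
}

#' Write a cell table to CSV
#'
#' Columns \code{cell_id}, \code{x_um}, \code{y_um}, \code{area_um2} and,
#' when present, \code{in_ck}.
#'
#' @param cells cell table from [detect_nuclei()] /
#'   [identify_cancer_cells()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Read a cell-centroid CSV into a point pattern
#'
#' Accepts a cell table written by [write_cell_table()] or any CSV with
#' \code{x_um}, \code{y_um} columns.
#'
#' @param path CSV path.
#' @param region an \code{invadex_region} the centroids live in.
#' @return A [point_pattern()].
#' @export
read_cell_table <- function(path, region) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(df)))
  point_pattern(df$x_um, df$y_um, region)
}

#' Read per-study 2x2 tables from CSV
#'
#' Expected columns: \code{study_id}, \code{exp_pos}, \code{exp_neg},
#' \code{unexp_pos}, \code{unexp_neg}. Negative counts act as
#' missing-data sentinels and lead to exclusion downstream.
#'
#' @param path CSV path.
#' @return Data frame suitable for [filter_studies()] / [forest_table()].
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("study_id", "exp_pos", "exp_neg", "unexp_pos",
                  "unexp_neg") %in% names(df)))
  df
}

#' Write a forest table to CSV
#'
#' @param forest result of [forest_table()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_forest_csv <- function(forest, path) {
  stopifnot(is.list(forest), is.data.frame(forest$results))
  utils::write.csv(forest$results, path, row.names = FALSE)
  invisible(path)
}

#' Read a grouped expression TSV
#'
#' Layout: first row holds group labels (tab-separated, first field
#' empty or "gene"), following rows hold gene name then intensities.
#'
#' @param path TSV path.
#' @return List with \code{expr} (matrix) and \code{groups} (factor).
#' @export
read_expression_tsv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  groups <- factor(hdr[-1])
  df <- utils::read.delim(path, skip = 1L, header = FALSE,
                          row.names = 1L, check.names = FALSE)
  expr <- as.matrix(df)
  colnames(expr) <- paste0(as.character(groups), "_", seq_along(groups))
  list(expr = expr, groups = groups)
}

#' Write a grouped expression TSV
#'
#' @param expr genes x samples matrix.
#' @param groups group label per sample.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(expr, groups, path) {
  stopifnot(is.matrix(expr), length(groups) == ncol(expr))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", as.character(groups)), collapse = "\t"), con)
  utils::write.table(expr, con, sep = "\t", col.names = FALSE,
                     row.names = TRUE, quote = FALSE)
  invisible(path)
}
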