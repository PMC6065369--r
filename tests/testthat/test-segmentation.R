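test_that("thresholding follows its contract on constructed images", {
  img <- tissue_image(list(ch = matrix(0, 20, 20)), pixel_size = 1)
  expect_warning(m <- threshold_channel(img, "ch", "otsu"), "constant")
  expect_false(any(m))

  half <- cbind(matrix(0, 20, 10), matrix(100, 20, 10))
  img2 <- tissue_image(list(ch = half), pixel_size = 1)
  m2 <- threshold_channel(img2, "ch", "fixed", value = 50)
  expect_identical(array(m2, dim(m2)), half >= 50)
  expect_equal(attr(m2, "provenance")$value, 50)
  expect_error(threshold_channel(img2, "nope"), "unknown channel")
  expect_error(threshold_channel(img2, "ch", "fixed"), "requires a value")
})

test_that("raising a fixed threshold never adds mask pixels", {
  set.seed(3)
  img <- tissue_image(list(ch = matrix(runif(400), 20, 20)), pixel_size = 1)
  m1 <- threshold_channel(img, "ch", "fixed", value = 0.3)
  m2 <- threshold_channel(img, "ch", "fixed", value = 0.6)
  expect_true(all(m1[m2]))
})

test_that("otsu mask covers the rendered cytokeratin footprint", {
  cfg <- sim_config(3, c(0, 0, 200, 200), pixel_size = 0.5)
  g <- generate_point_pattern(cfg, "hardcore", 0.005, hardcore_dist = 9)
  r <- render_tissue_image(g$pattern, cfg, nucleus_radius = 3, snr = 10)
  ck <- threshold_channel(r$image, "cytokeratin", "otsu")
  expect_gte(mean(ck[r$ground_truth$footprint]), 0.99)
})

test_that("nuclei detection recovers planted cells and centroids", {
  cfg <- sim_config(21, c(0, 0, 100, 100), pixel_size = 0.5)
  r1 <- render_tissue_image(point_pattern(50, 50, cfg$window), cfg,
                            nucleus_radius = 3, snr = 20)
  # a single nucleus is a sparse signal: smooth before Otsu
  m <- threshold_channel(r1$image, "nuclei", "otsu", smooth_sigma_um = 1.5)
  tab <- detect_nuclei(r1$image, m, min_area = 4)
  expect_equal(nrow(tab), 1)
  expect_lt(sqrt((tab$x_um - 50)^2 + (tab$y_um - 50)^2), 0.5)

  # empty image -> empty table
  blank <- tissue_image(list(nuclei = matrix(0, 50, 50)), pixel_size = 1)
  expect_equal(nrow(detect_nuclei(blank, matrix(FALSE, 50, 50))), 0)

  # 200 planted nuclei, min separation 10 um, all matched within 1 um;
  # rendered with a small margin so no blob is cut by the image border
  cfg2 <- sim_config(22, c(0, 0, 400, 400), pixel_size = 0.5)
  g <- generate_point_pattern(cfg2, "hardcore", 200 / 160000,
                              hardcore_dist = 10)
  cfg_r <- sim_config(22, c(-5, -5, 405, 405), pixel_size = 0.5)
  r <- render_tissue_image(g$pattern, cfg_r, nucleus_radius = 3, snr = 10)
  m <- threshold_channel(r$image, "nuclei", "otsu", smooth_sigma_um = 1.5)
  # min_area at ~1/3 of the expected nucleus area rejects border
  # smoothing artifacts without touching real nuclei
  tab <- detect_nuclei(r$image, m, min_area = 10)
  expect_equal(nrow(tab), g$pattern$n)
  # detected centroids are in the image frame, whose origin is (-5, -5)
  d <- match_to_truth(tab$x_um - 5, tab$y_um - 5, g$pattern$x, g$pattern$y)
  expect_lt(max(d), 1)
})

test_that("cytokeratin gating keeps tumor nuclei and drops stromal ones", {
  mask1 <- matrix(TRUE, 100, 100)
  cells <- data.frame(cell_id = 1:3, x_um = c(10, 50, 90),
                      y_um = c(10, 50, 90), area_um2 = 20)
  expect_equal(nrow(identify_cancer_cells(cells, mask1, 1)), 3)
  expect_equal(nrow(identify_cancer_cells(cells, !mask1, 1)), 0)

  # planted mixture: 150 tumor inside the ck mask, 50 stromal outside
  set.seed(9)
  ck <- matrix(FALSE, 200, 200)
  ck[1:200, 1:100] <- TRUE                      # left half (x < 100 um)
  tumor <- data.frame(x_um = runif(150, 5, 95), y_um = runif(150, 5, 195))
  stroma <- data.frame(x_um = runif(50, 105, 195),
                       y_um = runif(50, 5, 195))
  mix <- rbind(tumor, stroma)
  mix$cell_id <- seq_len(nrow(mix)); mix$area_um2 <- 20
  kept <- identify_cancer_cells(mix, ck, 1)
  expect_equal(nrow(kept), 150)
  expect_true(all(kept$x_um < 100))
})

test_that("invasion counting matches planted ground truth and projection rules", {
  f <- generate_invasion_field(sim_config(8, c(0, 0, 400, 400),
                                          pixel_size = 1),
                               n_central = 60, n_invaded = 25)
  expect_equal(count_invading_cells(f$image, f$central_region), 25)

  # no invaded cells -> 0
  f0 <- generate_invasion_field(sim_config(9, c(0, 0, 400, 400),
                                           pixel_size = 1),
                                n_central = 40, n_invaded = 0)
  expect_equal(count_invading_cells(f0$image, f0$central_region), 0)

  # invariant to z-order permutation (projection commutes)
  perm <- f$image
  perm$channels$nuclei <- perm$channels$nuclei[, , c(3, 1, 4, 2)]
  expect_equal(count_invading_cells(perm, f$central_region), 25)

  # a degenerate (collinear) central polygon cannot even be constructed
  expect_error(region_polygon(c(0, 1, 2), c(0, 1, 2)), "positive area")
})

test_that("a centroid on the central-region boundary counts as invaded", {
  # the exclusion zone is the open interior: boundary distance 0 is out
  reg <- region_rect(0, 0, 100, 100)
  inside_open <- region_contains(100, 50, reg) &
    region_boundary_distance(100, 50, reg) > 0
  expect_false(inside_open)
  expect_true(region_contains(100, 50, reg))
})

test_that("masked intensity is the plain mean over mask pixels", {
  img <- tissue_image(list(sig = matrix(7, 10, 10)), pixel_size = 1)
  mask <- matrix(FALSE, 10, 10); mask[3:5, 3:5] <- TRUE
  expect_equal(quantify_masked_intensity(img, "sig", mask), 7)
  img2 <- tissue_image(list(sig = ifelse(mask, 1, 0)), pixel_size = 1)
  expect_equal(quantify_masked_intensity(img2, "sig", mask), 1)
  expect_error(quantify_masked_intensity(img, "sig", mask & FALSE), "empty")

  # planted 2x enrichment recovered within 2%
  z <- generate_zseries_with_band(sim_config(5, c(0, 0, 30, 30),
                                             pixel_size = 0.2),
                                  band_width = 3, enrichment = 2)
  band <- leading_edge_band(z$image, width_um = 3)
  cell <- attr(band, "cell_mask")
  ratio <- mean(z$image$channels$marker[band]) /
    mean(z$image$channels$marker[cell & !band])
  expect_equal(ratio, 2, tolerance = 0.02)
})
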