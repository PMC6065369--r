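test_that("every generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(99, c(0, 0, 50, 50), pixel_size = 0.5)
  a <- generate_point_pattern(cfg, "poisson", 0.04)
  b <- generate_point_pattern(cfg, "poisson", 0.04)
  expect_identical(a, b)
  tc <- list(kappa = 0.004, sigma = 5, mu_offspring = 10)
  expect_identical(
    generate_point_pattern(cfg, "thomas_cluster", 0.04, cluster_params = tc),
    generate_point_pattern(cfg, "thomas_cluster", 0.04, cluster_params = tc))
  expect_identical(generate_point_pattern(cfg, "hardcore", 0.01),
                   generate_point_pattern(cfg, "hardcore", 0.01))
  expect_identical(generate_kymograph(cfg, 3, 2), generate_kymograph(cfg, 3, 2))
  expect_identical(generate_dcis_section(cfg, 2, 0.3),
                   generate_dcis_section(cfg, 2, 0.3))
  expect_identical(generate_contingency(cfg, 50, 50, 0.3, 2),
                   generate_contingency(cfg, 50, 50, 0.3, 2))
  expect_identical(generate_expression(cfg, 50, 5),
                   generate_expression(cfg, 50, 5))
})

test_that("generator preconditions are enforced", {
  cfg <- sim_config(1, c(0, 0, 100, 100))
  expect_error(generate_point_pattern(cfg, "poisson", -1), "intensity")
  expect_error(generate_point_pattern(cfg, "thomas_cluster", 0.04,
               cluster_params = list(kappa = 0.001, sigma = 5,
                                     mu_offspring = 10)),
               "inconsistent")
  expect_error(generate_dcis_section(cfg, -1, 0.5), "n_structures")
  expect_error(generate_dcis_section(cfg, 1, 1.5), "cellular_fraction")
  expect_error(generate_contingency(cfg, 50, 50, 1.5, 2), "baseline_risk")
  expect_error(render_tissue_image(
    generate_point_pattern(cfg, "poisson", 0.01)$pattern,
    sim_config(1, c(0, 0, 100, 100), pixel_size = 2), nucleus_radius = 3),
    "resolvability")
})

test_that("Poisson counts match lambda * area over replicates", {
  lam <- 0.01
  counts <- vapply(1:100, function(s) {
    generate_point_pattern(sim_config(s, c(0, 0, 1000, 1000)),
                           "poisson", lam)$pattern$n
  }, numeric(1))
  expect_equal(mean(counts), 1e4, tolerance = 0.01)
  # and within 3 monte-carlo standard errors
  expect_lt(abs(mean(counts) - 1e4), 3 * sd(counts) / sqrt(100) + 1e-9)
})

test_that("Thomas realized intensity honors kappa * mu_offspring", {
  lam <- 0.04
  counts <- vapply(1:100, function(s) {
    generate_point_pattern(sim_config(s, c(0, 0, 300, 300)),
                           "thomas_cluster", lam,
                           cluster_params = list(kappa = 0.001, sigma = 5,
                                                 mu_offspring = 40))$pattern$n
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam * 9e4), 3 * sd(counts) / sqrt(100))
})

test_that("points fall strictly inside the window and match ground truth", {
  cfg <- sim_config(5, c(10, 20, 110, 140))
  for (pr in c("poisson", "hardcore")) {
    g <- generate_point_pattern(cfg, pr, 0.02)
    p <- g$pattern
    expect_true(all(p$x > 10 & p$x < 110 & p$y > 20 & p$y < 140))
    expect_equal(nrow(g$ground_truth$true_centroids), p$n)
  }
  g <- generate_point_pattern(cfg, "thomas_cluster", 0.02,
         cluster_params = list(kappa = 0.002, sigma = 4, mu_offspring = 10))
  expect_true(all(g$pattern$x > 10 & g$pattern$x < 110))
  expect_equal(nrow(g$ground_truth$true_centroids), g$pattern$n)
})

test_that("hardcore patterns respect the minimum distance", {
  g <- generate_point_pattern(sim_config(3, c(0, 0, 200, 200)),
                              "hardcore", 0.005, hardcore_dist = 8)
  expect_gte(min(compute_nnd(g$pattern)$nnd), 8)
})

test_that("rendering places blob peaks at the planted centroids", {
  cfg <- sim_config(2, c(0, 0, 100, 100), pixel_size = 0.5)
  # single centroid at (50, 50) um -> brightest pixel near (100, 100) px
  p1 <- point_pattern(50, 50, cfg$window)
  r1 <- render_tissue_image(p1, cfg, nucleus_radius = 3, snr = 50)
  ij <- arrayInd(which.max(r1$image$channels$nuclei), c(200, 200))
  expect_lte(max(abs(ij - c(100, 100))), 1)

  # empty pattern -> noise only, well below the blob peak at snr = 5
  r0 <- render_tissue_image(point_pattern(numeric(0), numeric(0),
                                          cfg$window), cfg,
                            nucleus_radius = 3, snr = 5)
  expect_lt(max(r0$image$channels$nuclei), 0.95)

  # every planted centroid has a local maximum within 1 px
  g <- generate_point_pattern(sim_config(8, c(0, 0, 300, 300),
                                         pixel_size = 0.5),
                              "hardcore", 0.0025, hardcore_dist = 12)
  r <- render_tissue_image(g$pattern,
                           sim_config(8, c(0, 0, 300, 300),
                                      pixel_size = 0.5),
                           nucleus_radius = 3, snr = 10)
  # after matched filtering (smoothing at the blob scale), some pixel
  # within 1 px of each interior centroid is a local maximum of its 3x3
  # neighborhood; centroids closer than one nucleus radius to the window
  # edge render truncated blobs and are exempt
  nuc <- as.matrix(EBImage::gblur(r$image$channels$nuclei, sigma = 3))
  is_local_max <- function(i, j) {
    nb <- nuc[max(1, i - 1):min(600, i + 1), max(1, j - 1):min(600, j + 1)]
    nuc[i, j] >= max(nb)
  }
  interior <- g$pattern$x > 3 & g$pattern$x < 297 &
    g$pattern$y > 3 & g$pattern$y < 297
  ok <- vapply(which(interior), function(k) {
    i0 <- round(g$pattern$y[k] / 0.5 + 0.5)
    j0 <- round(g$pattern$x[k] / 0.5 + 0.5)
    any(outer((i0 - 1):(i0 + 1), (j0 - 1):(j0 + 1),
              Vectorize(is_local_max)))
  }, logical(1))
  expect_gt(sum(interior), 150)   # the exemption is a thin border strip
  expect_true(all(ok))
})

test_that("contingency sampling is unbiased at the null odds ratio", {
  ors <- vapply(1:1000, function(s) {
    tb <- generate_contingency(sim_config(s, c(0, 0, 10, 10)),
                               200, 200, 0.4, true_or = 1)$table
    (tb$a * tb$d) / (tb$b * tb$c)
  }, numeric(1))
  expect_equal(mean(ors), 1, tolerance = 0.05)
})

test_that("expression generator plants exactly the requested hit set", {
  g <- generate_expression(sim_config(4, c(0, 0, 10, 10)), n_genes = 1000,
                           n_samples_per_group = 10, planted_fc = 4,
                           planted_fraction = 0.05)
  expect_length(g$ground_truth$true_de_genes, 50)
  expect_true(all(abs(g$ground_truth$log2fc) == 2))
  expect_equal(dim(g$expr), c(1000, 20))
  expect_true(all(g$expr > 0))
})

test_that("DCIS and invasion generators record complete ground truth", {
  d0 <- generate_dcis_section(sim_config(6, c(0, 0, 300, 300),
                                         pixel_size = 1), 0, 0.3)
  expect_equal(d0$ground_truth$n_structures, 0)
  f <- generate_invasion_field(sim_config(7, c(0, 0, 300, 300),
                                          pixel_size = 1),
                               n_central = 30, n_invaded = 10)
  expect_equal(unname(f$ground_truth$true_counts), c(30, 10))
  expect_equal(nrow(f$ground_truth$true_centroids), 40)
  expect_equal(sum(f$ground_truth$true_labels == "invaded"), 10)
})

test_that("kymograph ground truth records every planted trace", {
  cfg <- sim_config(12, c(0, 0, 20, 20), pixel_size = 0.2)
  g0 <- generate_kymograph(cfg, 0, 2, snr = Inf)
  expect_equal(max(g0$kymo$raster), 0)          # uniform background
  expect_equal(nrow(g0$ground_truth), 0)
  g3 <- generate_kymograph(cfg, 3, 2)
  expect_equal(nrow(g3$ground_truth), 3)
  expect_true(all(abs(g3$ground_truth$speed) == 2))
})
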