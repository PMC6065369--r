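test_that("study inclusion filter applies the 10-per-group minimum", {
  tabs <- list(contingency_2x2(5, 3, 20, 20, "small_exposed"),
               contingency_2x2(5, 5, 5, 5, "boundary"),
               contingency_2x2(20, 10, 5, 4, "small_unexposed"))
  f <- filter_studies(tabs)
  expect_equal(f$included, c(FALSE, TRUE, FALSE))
  expect_match(f$reason[1], "exposed group < 10")
  expect_match(f$reason[3], "unexposed group < 10")

  # data frame input with a negative sentinel for missing counts
  df <- data.frame(study_id = c("a", "b"), exp_pos = c(10, -1),
                   exp_neg = c(10, 5), unexp_pos = c(10, 5),
                   unexp_neg = c(10, 5))
  f2 <- filter_studies(df)
  expect_true(f2$included[1])
  expect_false(f2$included[2])
  expect_equal(f2$reason[2], "incomplete counts")
})

test_that("odds ratio matches hand arithmetic, with continuity correction", {
  expect_equal(as.numeric(odds_ratio(contingency_2x2(10, 10, 10, 10))), 1)
  expect_equal(as.numeric(odds_ratio(contingency_2x2(20, 10, 5, 40))), 16)
  or0 <- odds_ratio(contingency_2x2(0, 10, 5, 40))
  expect_equal(as.numeric(or0), (0.5 * 40.5) / (10.5 * 5.5))
  expect_true(attr(or0, "corrected"))
  expect_error(odds_ratio(contingency_2x2(5, 0, 5, 5), correction = "none"),
               "denominator")
})

test_that("Fisher p reproduces worked examples and the enumeration oracle", {
  expect_equal(fisher_exact_p(contingency_2x2(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_p(contingency_2x2(3, 0, 0, 3)), 0.1,
               tolerance = 1e-12)
  set.seed(17)
  for (i in 1:200) {
    cnt <- random_table(40)
    tb <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(fisher_exact_p(tb),
                 fisher_enumeration_oracle(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p agrees with the reference implementation", {
  set.seed(23)
  for (i in 1:50) {
    cnt <- random_table(60)
    tb <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    ref <- stats::fisher.test(matrix(cnt, 2, 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact_p(tb), min(1, ref), tolerance = 1e-10)
  }
})

test_that("row swap inverts the odds ratio and preserves the Fisher p", {
  set.seed(31)
  for (i in 1:50) {
    cnt <- random_table(40) + 1L    # keep the uncorrected OR finite
    tb <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    sw <- contingency_2x2(cnt[3], cnt[4], cnt[1], cnt[2])
    expect_equal(as.numeric(odds_ratio(sw)),
                 1 / as.numeric(odds_ratio(tb)), tolerance = 1e-12)
    expect_equal(fisher_exact_p(sw), fisher_exact_p(tb), tolerance = 1e-12)
  }
})

test_that("exact CI brackets the point estimate, nests, and matches the
           reference inversion", {
  tb <- contingency_2x2(10, 10, 10, 10)
  ci <- exact_ci(tb)
  expect_lt(ci[["low"]], 1)
  expect_gt(ci[["high"]], 1)
  ci99 <- exact_ci(tb, level = 0.99)
  expect_lt(ci99[["low"]], ci[["low"]])
  expect_gt(ci99[["high"]], ci[["high"]])
  # mid-p interval is narrower
  cim <- exact_ci(tb, midp = TRUE)
  expect_gt(cim[["low"]], ci[["low"]])
  expect_lt(cim[["high"]], ci[["high"]])

  set.seed(41)
  for (i in 1:25) {
    cnt <- random_table(50) + 1L
    tb <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    ref <- stats::fisher.test(matrix(cnt, 2, 2, byrow = TRUE))$conf.int
    ci <- exact_ci(tb)
    # the reference inverts the same tail tests with a much looser
    # root-finding tolerance, so agreement is only to ~3 digits
    expect_equal(ci[["low"]], ref[1], tolerance = 5e-3)
    expect_equal(ci[["high"]], ref[2], tolerance = 5e-3)
    or <- as.numeric(odds_ratio(tb))
    expect_lte(ci[["low"]], or)
    expect_gte(ci[["high"]], or)
  }

  # boundary cells give one-sided intervals
  expect_equal(exact_ci(contingency_2x2(0, 10, 5, 5))[["low"]], 0)
  expect_equal(exact_ci(contingency_2x2(10, 0, 5, 5))[["high"]], Inf)
  expect_error(exact_ci(contingency_2x2(0, 0, 5, 5)), "degenerate")
})

test_that("CI excludes 1 exactly when the one-sided tests reject at 2.5%", {
  set.seed(53)
  for (i in 1:40) {
    cnt <- random_table(60)
    tb <- contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    ok <- tryCatch({ ci <- exact_ci(tb); TRUE }, error = function(e) FALSE)
    if (!ok) next
    hs <- invadex:::.hyper_support(tb)
    up <- invadex:::.nchyper_tails(tb$a, hs, 1)[["upper"]]  # P(X >= a | OR=1)
    lo <- invadex:::.nchyper_tails(tb$a, hs, 1)[["lower"]]
    excl <- ci[["low"]] > 1 || ci[["high"]] < 1
    expect_equal(excl, up < 0.025 || lo < 0.025)
  }
})

test_that("forest table reports per-study results and optional MH pooling", {
  one <- contingency_2x2(20, 10, 5, 40, "s1")
  ft <- forest_table(list(one), pool = TRUE)
  expect_equal(nrow(ft$results), 1)
  expect_equal(ft$results$or, 16)
  expect_equal(ft$pooled_or, 16)

  tabs <- list(one, contingency_2x2(5, 3, 20, 20, "tiny"),
               contingency_2x2(12, 18, 11, 19, "s2"))
  ft2 <- forest_table(tabs)
  expect_equal(ft2$results$study_id, c("s1", "s2"))
  expect_equal(ft2$exclusions$study_id, "tiny")
  expect_null(ft2$pooled_or)
})

test_that("MH pooled OR agrees with metafor and recovers a planted OR", {
  set.seed(61)
  tabs <- lapply(1:8, function(s)
    generate_contingency(sim_config(s * 3 + 1, c(0, 0, 10, 10)),
                         120, 120, 0.3, true_or = 2,
                         study_id = paste0("s", s))$table)
  ft <- forest_table(tabs, pool = TRUE)
  a <- vapply(tabs, `[[`, 0L, "a"); b <- vapply(tabs, `[[`, 0L, "b")
  cc <- vapply(tabs, `[[`, 0L, "c"); d <- vapply(tabs, `[[`, 0L, "d")
  mh <- metafor::rma.mh(ai = a, bi = b, ci = cc, di = d, measure = "OR")
  expect_equal(ft$pooled_or, exp(as.numeric(mh$beta)), tolerance = 1e-8)
  expect_equal(ft$pooled_or, 2, tolerance = 0.25)
})
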