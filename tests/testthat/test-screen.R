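test_that("fold grid is geometric, centred on 1 and symmetric", {
  g <- make_fold_grid()
  expect_length(g, 41)
  expect_equal(g[21], 1)
  expect_equal(g[-1] / g[-41], rep(1.2, 40), tolerance = 1e-12)
  expect_equal(max(g), 1.2^20, tolerance = 1e-12)
  expect_equal(max(g), 38.3376, tolerance = 1e-5)
  expect_equal(min(g), 0.026084, tolerance = 1e-4)
  expect_equal(g * rev(g), rep(1, 41), tolerance = 1e-12)
  expect_equal(make_fold_grid(1), 1)
  expect_error(make_fold_grid(40), "odd")
})

test_that("classification thresholds use inclusive bounds", {
  th <- classification_thresholds(reference_total = 1e4)
  # monoclonal: at least 300% of physiological count, at least 80% prelk
  expect_true(classify_totals(3.5e4, 0.9, "monoclonal", th))
  expect_true(classify_totals(3.0e4, 0.8, "monoclonal", th))   # boundary
  expect_false(classify_totals(2.9e4, 0.9, "monoclonal", th))
  expect_false(classify_totals(3.5e4, 0.7, "monoclonal", th))
  # polyclonal: at most 120% of physiological count, at most 50% prelk
  expect_true(classify_totals(1e4, 0.01, "polyclonal", th))
  expect_true(classify_totals(1.2e4, 0.5, "polyclonal", th))   # boundary
  expect_false(classify_totals(1.3e4, 0.1, "polyclonal", th))
  expect_false(classify_totals(1e4, 0.6, "polyclonal", th))
  expect_error(classification_thresholds(poly_max_prelk_frac = 0.9))
})

test_that("classify_outcome measures totals and the preleukemic share", {
  cfg <- model_config(q = 2, n = 2)
  th <- classification_thresholds(reference_total = 1e4)
  out <- classify_outcome(c(100, 100, 300, 500), cfg, th,
                          clonality = "monoclonal")
  expect_equal(out$total, 1000)
  expect_equal(out$prelk_frac, 0.8)
  expect_false(out$premalignant)  # total below 3 * 1e4
  # with the reference resolved from the config (v_h * sum(p) = 200) the
  # same state crosses the 300% bound
  expect_true(classify_outcome(c(100, 100, 300, 500), cfg,
                               clonality = "monoclonal")$premalignant)
  # empty system: fraction 0 by convention, trivially controlled
  out0 <- classify_outcome(rep(0, 4), cfg, clonality = "polyclonal")
  expect_equal(out0$prelk_frac, 0)
  expect_true(out0$controlled)
})

test_that("a preleukemic species identical to healthy changes nothing", {
  rec <- evaluate_parameter_set(1, 1, 1, "P100")
  expect_equal(rec$mono_total, 1e4, tolerance = 1e-3)
  expect_equal(rec$poly_total, 1e4, tolerance = 1e-3)
  # identical dynamics preserve the transplanted proportions
  expect_equal(rec$mono_prelk_frac, 0.2, tolerance = 1e-3)
  expect_true(rec$poly_controlled)
  expect_false(rec$mono_premalignant)
  expect_false(rec$consistent)
})

test_that("toy screens enumerate the grid deterministically", {
  g <- make_fold_grid(3, 4)
  rec <- run_screen(scenarios = "P100", grid = g)
  expect_equal(nrow(rec), 27)
  expect_equal(rec$consistent, rec$mono_premalignant & rec$poly_controlled)
  # order: s_fold slowest, v_fold fastest
  expect_equal(rec$v_fold, rep(g, 9))
  expect_equal(rec$s_fold, rep(g, each = 9))
  rec2 <- run_screen(scenarios = c("P1", "P100"), grid = g)
  expect_equal(nrow(rec2), 54)
  expect_equal(unique(rec2$scenario), c("P1", "P100"))
})

test_that("low efficiency folds cannot reach the premalignant total", {
  g <- make_fold_grid(5, 2.5)
  rec <- run_screen(scenarios = "P100", grid = g)
  low_v <- rec[rec$v_fold < 3, ]
  expect_true(all(low_v$mono_total < 3 * 1e4))
  expect_false(any(low_v$consistent))
})

test_that("reduced and full systems reach the same steady states", {
  g <- make_fold_grid()
  pts <- rbind(c(1, 11, 35), c(21, 21, 21), c(5, 15, 31), c(41, 41, 41),
               c(9, 4, 25))
  for (i in seq_len(nrow(pts))) {
    f <- g[pts[i, ]]
    red <- evaluate_parameter_set(f[1], f[2], f[3], "P10",
                                  method = "reduced")
    ful <- evaluate_parameter_set(f[1], f[2], f[3], "P10", method = "full")
    expect_equal(red$mono_total, ful$mono_total, tolerance = 1e-4)
    expect_equal(red$poly_total, ful$poly_total, tolerance = 1e-4)
    expect_equal(red$mono_prelk_frac, ful$mono_prelk_frac,
                 tolerance = 1e-4)
    expect_equal(red$poly_prelk_frac, ful$poly_prelk_frac,
                 tolerance = 1e-4)
  }
})

test_that("screens can be resumed from completed slices on disk", {
  g <- make_fold_grid(3, 4)
  dir <- withr::local_tempdir()
  rec <- run_screen(scenarios = "P100", grid = g, out_dir = dir)
  slices <- list.files(dir, pattern = "^slice_.*\\.csv$")
  expect_length(slices, 3)  # one per s_fold value
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # tamper with one slice: resuming must reuse it verbatim, not recompute
  marked <- rec[rec$s_fold == g[1], ]
  marked$mono_total <- -1
  data.table::fwrite(marked,
                     file.path(dir, sprintf("slice_P100_sh1_s%03d.csv", 1)))
  rec2 <- run_screen(scenarios = "P100", grid = g, out_dir = dir,
                     resume = TRUE)
  expect_equal(nrow(rec2), 27)
  expect_true(all(rec2$mono_total[rec2$s_fold == g[1]] == -1))
  expect_equal(rec2[rec2$s_fold != g[1], c("mono_total", "poly_total")],
               rec[rec$s_fold != g[1], c("mono_total", "poly_total")],
               ignore_attr = TRUE)
})

test_that("screen records round-trip through CSV", {
  rec <- run_screen(scenarios = "P1", grid = make_fold_grid(3, 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(rec, f)
  back <- read_screen_csv(f)
  expect_equal(back$consistent, rec$consistent)
  expect_equal(back$mono_total, rec$mono_total, tolerance = 1e-12)
  expect_error(read_screen_csv({
    f2 <- withr::local_tempfile(fileext = ".csv")
    data.table::fwrite(rec[setdiff(names(rec), "v_fold")], f2)
    f2
  }), "v_fold")
})
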