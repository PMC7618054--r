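test_that("event generation hits the requested median and is reproducible", {
  ev <- generate_events(1000, cv = 1e-6, n_events = 10000, seed = 41)
  expect_equal(stats::median(ev$values), 1000, tolerance = 1e-3)

  a <- generate_events(500, cv = 0.4, n_events = 1000, seed = 42)
  b <- generate_events(500, cv = 0.4, n_events = 1000, seed = 42)
  expect_identical(a$values, b$values)

  expect_error(generate_events(-1, 0.4), "positive")
  expect_error(generate_events(10, 2.5), "cv")
})

test_that("the sample median of 10k events stays within 2% of truth across seeds", {
  hits <- 0L
  for (s in 1:100) {
    ev <- generate_events(1000, cv = 0.4, n_events = 10000, seed = s)
    if (abs(stats::median(ev$values) - 1000) / 1000 < 0.02) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("bead calibration recovers exact affine log-log relations", {
  mef <- c(792, 2079, 6588, 16471, 47497, 137049, 271647, 709431)
  cal2 <- fit_calibration(bead_reference(2 * mef, mef))
  expect_equal(cal2$slope, 1, tolerance = 1e-12)
  expect_equal(cal2$intercept, -log10(2), tolerance = 1e-12)
  expect_equal(cal2$r_squared, 1, tolerance = 1e-12)

  cal1 <- fit_calibration(bead_reference(mef, mef))
  expect_equal(cal1$slope, 1, tolerance = 1e-12)
  expect_equal(cal1$intercept, 0, tolerance = 1e-10)

  expect_error(bead_reference(c(1, 2, 3), c(1, 2, 3)), "at least 4")
})

test_that("calibration slope is stable under 1% peak noise", {
  slopes <- vapply(1:100, function(s) {
    beads <- synthetic_bead_reference(gain = 2, noise_cv = 0.01, seed = s)
    fit_calibration(beads)$slope
  }, numeric(1))
  expect_true(all(slopes > 0.97 & slopes < 1.03))
})

test_that("well summaries take the median and the monotone transform commutes", {
  ev <- generate_events(10, cv = 1e-6, n_events = 3, seed = 1)
  ev$values <- c(1, 10, 100)
  ws <- summarize_well(ev, identity_calibration())
  expect_equal(ws$median_au, 10)
  expect_equal(ws$median_mef, 10)

  cal <- fit_calibration(synthetic_bead_reference(gain = 3))
  set.seed(43)
  for (i in 1:50) {
    vals <- stats::rlnorm(2 * sample(5:50, 1) + 1, 3, 1)  # odd length
    med_then_transform <- au_to_mef(cal, stats::median(vals))
    transform_then_med <- stats::median(au_to_mef(cal, vals))
    expect_equal(med_then_transform, transform_then_med, tolerance = 1e-12)
  }
})

test_that("fixtures encode the reported half-maximal doses and amplitude ordering", {
  a0 <- hill_fixture("asah0")
  expect_equal(a0$K, 344)
  expect_equal(a0$fold_change, 115)
  expect_equal(a0$dynamic_range, 114)
  h2 <- hill_fixture("asah2j06")
  l2 <- hill_fixture("asal2j06")
  expect_equal(h2$K, 31.7)
  expect_equal(l2$K, 40.1)
  # genome-expressed sensor: lowest basal, largest amplitude; low-copy
  # plasmid variant sits below the high-copy one
  expect_lt(a0$fmin, h2$fmin)
  expect_gt(a0$fmax, h2$fmax)
  expect_lt(l2$fmin, h2$fmin)
  expect_lt(l2$fmax, h2$fmax)
  # fold change and dynamic range differ by one, identically
  for (f in list(a0, h2, l2))
    expect_identical(f$fold_change - f$dynamic_range, 1)
})

test_that("a noise-free study round-trips the fixture through the full pipeline", {
  fx <- hill_fixture("asah0")
  study <- generate_study(fx, noise_cv = 0, seed = 1)
  fit <- fit_study(study)
  expect_true(fit$converged)
  expect_equal(fit$fmin, fx$fmin, tolerance = 1e-3)
  expect_equal(fit$fmax, fx$fmax, tolerance = 1e-3)
  expect_equal(fit$K, fx$K, tolerance = 1e-3)
  expect_equal(fit$n, fx$n, tolerance = 1e-3)
})

test_that("a flat fixture yields unit fold change", {
  flat <- list(fmin = 500, fmax = 500, K = 100, n = 1)
  study <- generate_study(flat, noise_cv = 0, seed = 1)
  fit <- fit_study(study)
  expect_equal(fit$fold_change, 1, tolerance = 0.01)
})

test_that("synthetic studies are deterministic given the seed and preserve order under calibration", {
  fx <- hill_fixture("asah2j06")
  s1 <- generate_study(fx, noise_cv = 0.05, seed = 7)
  s2 <- generate_study(fx, noise_cv = 0.05, seed = 7)
  expect_identical(s1$wells, s2$wells)

  cal <- fit_calibration(synthetic_bead_reference(gain = 2))
  s3 <- generate_study(fx, noise_cv = 0.05, seed = 7, calibration = cal)
  expect_identical(order(s3$wells$median_au), order(s3$wells$median_mef))
})

test_that("fitted K covers the generating value within 3 SE for noisy studies", {
  fx <- hill_fixture("asah0")
  covered <- 0L
  for (s in 1:20) {
    fit <- fit_study(generate_study(fx, noise_cv = 0.05, seed = s))
    if (fit$converged && abs(fit$K - fx$K) <= 3 * fit$se_K)
      covered <- covered + 1L
  }
  expect_gte(covered, 19L)
})

test_that("study preconditions are enforced", {
  fx <- hill_fixture("asah0")
  expect_error(generate_study(fx, conc_grid = numeric(0)), "non-empty")
  expect_error(generate_study(fx, replicates = 2), "at least 3")
  expect_error(generate_study(list(fmin = 10, fmax = 5, K = 1, n = 1)),
               "invariants")
})

test_that("wells and events export as tidy CSV", {
  fx <- hill_fixture("asal2j06")
  study <- generate_study(fx, conc_grid = c(0, 10, 100, 1000, 10000),
                          n_events = 100, seed = 3, keep_events = TRUE)
  wpath <- tempfile(fileext = ".csv")
  write_wells_csv(study, wpath)
  w <- utils::read.csv(wpath)
  expect_identical(nrow(w), 15L)
  expect_true(all(c("well_id", "inducer_conc", "replicate", "median_au",
                    "median_mef") %in% names(w)))
  epath <- tempfile(fileext = ".csv")
  write_events_csv(study, epath)
  e <- utils::read.csv(epath)
  expect_identical(nrow(e), 1500L)
})
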