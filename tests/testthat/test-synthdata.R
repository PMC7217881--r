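test_that("background noise has the requested spectral slope and is reproducible", {
  # white noise: negligible autocorrelation
  w <- make_background(8192, noise_exponent = 0, seed = 2)
  expect_lt(max(abs(acf(w, lag.max = 5, plot = FALSE)$acf[-1])), 0.05)
  # pink noise: periodogram log-log slope near -1
  x <- make_background(4096, noise_exponent = 1, seed = 1)
  sp <- spec.pgram(ts(x, frequency = 512), plot = FALSE, taper = 0)
  keep <- sp$freq > 2 & sp$freq < 200
  slope <- unname(coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
  expect_lt(abs(slope + 1), 0.2)
  # determinism and zero mean
  expect_identical(make_background(768, 1, seed = 5),
                   make_background(768, 1, seed = 5))
  expect_lt(abs(mean(x)), 1e-12)
  expect_error(make_background(1, 1), "n_samples")
})

test_that("implanted increases reach the requested binned power ratio", {
  set.seed(31)
  rs <- replicate(80, {
    tr <- make_background(768, 1)
    m <- tf_map(implant_signature(tr, 61, 90, 100, 300, gain = 3))
    c(inside = region_ratio(m, 61, 90, 100, 300),
      outside = region_ratio(m, 100, 140, 500, 900))
  })
  expect_lt(abs(mean(rs["inside", ]) - 3), 0.5)
  # away from the implant the map matches a null probe's level
  null_out <- replicate(40, {
    m <- tf_map(make_background(768, 1))
    region_ratio(m, 100, 140, 500, 900)
  })
  expect_lt(abs(mean(rs["outside", ]) - mean(null_out)), 0.15)
})

test_that("implanted suppressions reduce a standing rhythm toward the gain", {
  set.seed(32)
  rs <- replicate(60, {
    tt <- epoch_times(768) / 1000
    osc <- 2 * sin(2 * pi * 11 * tt + runif(1, 0, 2 * pi))
    tr <- make_background(768, 1) + osc
    m <- tf_map(implant_signature(tr, 9, 14, 200, 800, gain = 0.5))
    region_ratio(m, 9, 14, 250, 750)
  })
  expect_lt(abs(mean(rs) - 0.5), 0.15)
})

test_that("implant_signature validates arguments and honors the identity case", {
  tr <- make_background(768, 1, seed = 7)
  expect_identical(implant_signature(tr, 61, 90, 100, 300, gain = 1), tr)
  expect_error(implant_signature(tr, 61, 90, -100, 300, 2), "window")
  expect_error(implant_signature(tr, 61, 90, 100, 1200, 2), "window")
  expect_error(implant_signature(tr, 90, 61, 100, 300, 2), "freq_lo")
  expect_error(implant_signature(tr, 61, 90, 100, 300, 0), "gain")
})

test_that("cohorts are balanced, counted and classified per the manifest rules", {
  specs <- dplyr::bind_rows(
    probe_spec("noise1"),
    probe_spec("resp1", contact_index = 1,
               signatures = signature_spec(NA, 20, 40, 100, 400, 3)),
    probe_spec("mono1", contact_index = 2,
               signatures = signature_spec("face", 61, 90, 100, 300, 3)),
    probe_spec("poly1", contact_index = 3,
               signatures = dplyr::bind_rows(
                 signature_spec("face", 61, 90, 100, 300, 3),
                 signature_spec("house", 20, 30, 200, 500, 3)))
  )
  coh <- generate_cohort(specs, trials_per_category = 2, seed = 4)
  expect_equal(vapply(coh$epochs, nrow, integer(1)), rep(16L, 4))
  expect_true(all(table(coh$labels[[1]]) == 2))
  expect_equal(coh$truth_class,
               c("non_responsive", "responsive_only", "monopredictive",
                 "polypredictive"))
  man <- cohort_manifest(coh)
  expect_equal(man$n_trials, rep(16L, 4))
  expect_error(generate_cohort(dplyr::bind_rows(probe_spec("a"),
                                                probe_spec("a")), 2, 1),
               "Duplicate")
  expect_error(generate_cohort(probe_spec("a"), 1, 1), "trials_per_category")
})

test_that("cohort regeneration under the same seed is bit-identical", {
  spec <- probe_spec("p", signatures = signature_spec("face", 61, 90, 100, 300, 2))
  a <- generate_cohort(spec, 2, seed = 9)
  b <- generate_cohort(spec, 2, seed = 9)
  expect_identical(a$epochs, b$epochs)
  c2 <- generate_cohort(spec, 2, seed = 10)
  expect_false(identical(a$epochs, c2$epochs))
})

test_that("pure-noise probes yield baseline-normalized maps near 1", {
  coh <- generate_cohort(probe_spec("n"), trials_per_category = 13, seed = 12)
  maps <- probe_features(coh$epochs[[1]])
  expect_lt(abs(mean(maps) - 1), 0.1)
})

test_that("cohort round-trips through the plain-text container", {
  dir <- withr::local_tempdir()
  spec <- dplyr::bind_rows(probe_spec("pA"), probe_spec("pB", contact_index = 1))
  coh <- generate_cohort(spec, 2, seed = 3)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$probe_id, coh$probe_id)
  expect_equal(back$labels, coh$labels, ignore_attr = TRUE)
  expect_equal(back$epochs[[1]], coh$epochs[[1]], tolerance = 1e-12)
  expect_equal(back$truth_class, coh$truth_class)
})
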