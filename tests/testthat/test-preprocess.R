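test_that("signal vector magnitude is the per-sample Euclidean norm", {
  st <- triaxial_stream(0:2, c(3, 0, 1), c(4, 0, 2), c(0, 0, 2))
  expect_equal(svm_magnitude(st)$value, c(5, 0, 3))
  expect_equal(svm_magnitude(st)$time, c(0, 1, 2))
})

test_that("malformed streams are rejected as structural errors", {
  expect_error(triaxial_stream(0:2, c(1, 2), c(1, 2, 3), c(1, 2, 3)),
               class = "hr_structural_input")
  expect_error(triaxial_stream(c(0, 1, 1), c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
               class = "hr_structural_input")
  expect_error(triaxial_stream(0:1, c(9, 0), c(0, 0), c(0, 0)),
               class = "hr_structural_input")
})

test_that("rectification is elementwise absolute value and idempotent", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(rep(0, 4)), rep(0, 4))
  x <- c(0.5, 2, 0)
  expect_identical(rectify(rectify(x)), x)
})

test_that("band-pass rejects DC, keeps mid-band, crushes sub-band frequencies", {
  rate <- 12.5
  t <- seq(0, 600 - 1 / rate, by = 1 / rate)
  mid <- 2000:5500   # away from filtfilt edge transients
  suppressMessages({
    out_dc <- suppressWarnings(bandpass(rep(3, length(t)), rate))
    out_mid <- suppressWarnings(bandpass(sin(2 * pi * 2 * t), rate))
    out_slow <- suppressWarnings(bandpass(sin(2 * pi * 0.01 * t), rate))
  })
  # DC is rejected (edge transients excluded: zero-phase filtering rings at
  # the series boundaries)
  expect_lt(max(abs(out_dc[mid])), 1e-6)
  # oracle: evaluate the designed filter's own frequency response
  g2 <- bandpass_gain(2, rate)
  expect_gt(g2, 0.95)
  expect_equal(max(abs(out_mid[mid])), g2, tolerance = 0.05)
  expect_lt(bandpass_gain(0.01, rate), 0.1)
  expect_lt(max(abs(out_slow[mid])), 0.1)
})

test_that("upper band edge above Nyquist is clamped with a warning", {
  rate <- 12.5
  x <- sin(2 * pi * 2 * seq(0, 60, by = 1 / rate))
  expect_warning(suppressMessages(bandpass(x, rate)), "Nyquist")
  # a band fully inside Nyquist raises no clamp warning
  expect_no_warning(suppressMessages(bandpass(x, 100, filter_spec(4, 0.5, 20))))
})

test_that("unusable bands and too-short series are classed errors", {
  expect_error(suppressMessages(bandpass(rnorm(100), 12.5, filter_spec(4, 10, 20))),
               class = "hr_unusable_band")
  expect_error(suppressMessages(bandpass(rnorm(10), 12.5)),
               class = "hr_insufficient_data")
})

test_that("epoch aggregation means half-open bins and flags sparse epochs", {
  rate <- 12.5
  t <- seq(0, length.out = 750, by = 1 / rate)  # exactly one 60 s epoch
  es <- epoch_aggregate(tibble::tibble(time = t, value = rep(1, 750)), 60, rate = rate)
  expect_equal(nrow(es), 1L)
  expect_equal(es$value, 1)
  expect_false(es$missing)

  es2 <- epoch_aggregate(tibble::tibble(time = t, value = rep(c(0, 2), 375)),
                         60, rate = rate)
  expect_equal(es2$value, 1)

  # a 60 s hole: the empty epoch is flagged, rows are never absent
  t3 <- c(t, t + 120)
  es3 <- epoch_aggregate(tibble::tibble(time = t3, value = rep(1, length(t3))),
                         60, rate = rate)
  expect_equal(nrow(es3), 3L)
  expect_equal(es3$missing, c(FALSE, TRUE, FALSE))
  expect_true(is.na(es3$value[2]))

  expect_error(epoch_aggregate(tibble::tibble(time = numeric(0), value = numeric(0)),
                               60, rate = rate),
               class = "hr_empty_series")
})

test_that("every sample lands in exactly one epoch (count conservation)", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(500:3000, 1)
    t <- cumsum(runif(n, 0.02, 0.2))
    es <- suppressWarnings(epoch_aggregate(tibble::tibble(time = t, value = rnorm(n)),
                                           epoch_len = 10, rate = 10))
    idx <- floor((t - t[1]) / 10)
    expect_equal(nrow(es), max(idx) + 1)
    expect_equal(sum(tabulate(idx + 1L, nbins = nrow(es))), n)
  }
  # irregular sampling triggers the rate-deviation warning
  expect_warning(epoch_aggregate(tibble::tibble(time = cumsum(runif(200, 0.5, 1.5)),
                                                value = rnorm(200)),
                                 epoch_len = 10, rate = 10),
                 class = "herdrhythm_warning")
})

test_that("preprocessing is invariant under collar rotation", {
  cfg <- sim_config(n_animals = 1, birth_dates = 0, days_logged = 0.1,
                    n_gap_animals = 0, welfare_curve = make_welfare_curve(NULL),
                    collar_on_delay_days = c(0, 0), seed = 11)
  st <- simulate_animal(cfg, 1, mode = "raw")$data
  base <- suppressMessages(suppressWarnings(preprocess_stream(st)))
  set.seed(5)
  for (i in 1:5) {
    rot <- suppressMessages(suppressWarnings(
      preprocess_stream(rotate_stream(st, random_rotation()))))
    expect_equal(rot$value, base$value, tolerance = 1e-9)
    expect_identical(rot$missing, base$missing)
  }
})

test_that("the chain is homogeneous: scaling the stream scales the epochs", {
  cfg <- sim_config(n_animals = 1, birth_dates = 0, days_logged = 0.05,
                    n_gap_animals = 0, welfare_curve = make_welfare_curve(NULL),
                    collar_on_delay_days = c(0, 0), seed = 3)
  st <- simulate_animal(cfg, 1, mode = "raw")$data
  st3 <- triaxial_stream(st$time, 3 * st$x, 3 * st$y, 3 * st$z,
                         nominal_rate = attr(st, "nominal_rate"))
  a <- suppressMessages(suppressWarnings(preprocess_stream(st)))
  b <- suppressMessages(suppressWarnings(preprocess_stream(st3)))
  expect_equal(b$value, 3 * a$value, tolerance = 1e-9)
  expect_error(preprocess_stream(triaxial_stream(numeric(0), numeric(0),
                                                 numeric(0), numeric(0))),
               class = "hr_empty_series")
})

test_that("raw CSV dialect round-trips with numeric and ISO-8601 timestamps", {
  st <- triaxial_stream(1600000000 + (0:49) * 0.08, rnorm(50) / 4,
                        rnorm(50) / 4, 1 + rnorm(50) / 4, animal_id = "c1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_triaxial_csv(st, f)
  back <- read_triaxial_csv(f, animal_id = "c1")
  expect_equal(back$time, st$time)
  expect_equal(back$x, st$x)

  iso <- tibble::tibble(
    timestamp = format(as.POSIXct(st$time, origin = "1970-01-01", tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%OS3"),
    x = st$x, y = st$y, z = st$z)
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(iso, f2)
  back2 <- read_triaxial_csv(f2)
  expect_equal(back2$time, st$time, tolerance = 1e-3)
})

test_that("epoch CSV round-trips with empty fields for missing epochs", {
  es <- make_epochs(seq(0, 540, by = 60), c(1:7, NA, 9, 10),
                    missing = c(rep(FALSE, 7), TRUE, FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(es, f)
  expect_true(any(grepl(",,", readLines(f), fixed = TRUE)))
  back <- read_epoch_csv(f, animal_id = "a")
  expect_equal(back$value, es$value)
  expect_equal(back$missing, es$missing)
})
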