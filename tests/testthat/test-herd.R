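test_that("alignment builds the union grid with boundary missingness", {
  a <- make_trace(seq(0, 9000, 900), runif(11), id = "a")
  b <- make_trace(seq(900, 9900, 900), runif(11), id = "b")
  panel <- align_traces(list(a, b))
  expect_equal(length(panel$grid), 12L)
  expect_true(is.na(panel$intensities[12, "a"]))
  expect_true(is.na(panel$intensities[1, "b"]))
  expect_equal(sum(is.na(panel$intensities)), 2L)

  single <- align_traces(list(a))
  expect_equal(single$grid, a$anchor)
  expect_equal(unname(single$intensities[, 1]), a$intensity)

  bad <- make_trace(seq(0, 9000, 450), runif(21), id = "c", step = 450)
  expect_error(align_traces(list(a, bad)), class = "hr_incompatible_traces")
  off <- make_trace(seq(300, 9300, 900), runif(11), id = "d")
  expect_error(align_traces(list(a, off)), class = "hr_incompatible_traces")
})

test_that("panel alignment spans the simulated herd's metadata", {
  cfg <- sim_config(n_animals = 4, days_logged = 9, n_gap_animals = 0,
                    birth_dates = c("2019-03-02", "2019-03-04", "2019-03-05",
                                    "2019-03-06"),
                    welfare_curve = make_welfare_curve(NULL), seed = 2)
  herd <- simulate_herd(cfg, mode = "epoch")
  traces <- lapply(herd$animals, function(a) suppressMessages(sliding_trace(a$data)))
  panel <- align_traces(traces)
  expect_equal(panel$grid[1], min(herd$manifest$start))
  expect_equal(panel$grid[length(panel$grid)] + 7 * 86400 + 900,
               max(herd$manifest$end), tolerance = 900)
})

test_that("the exclusion rule flags heavy-gap animals and is monotone", {
  full <- make_trace(seq(0, 900 * 99, 900), runif(100), id = "full")
  gone <- make_trace(seq(0, 900 * 99, 900), rep(NA_real_, 100), id = "gone")
  v <- runif(100); v[30:60] <- NA
  holey <- make_trace(seq(0, 900 * 99, 900), v, id = "holey")
  panel <- suppressMessages(exclude_missing(align_traces(list(full, gone, holey)), 0.2))
  expect_false(panel$animals$excluded[panel$animals$animal_id == "full"])
  expect_true(panel$animals$excluded[panel$animals$animal_id == "gone"])
  expect_true(panel$animals$excluded[panel$animals$animal_id == "holey"])
  expect_match(panel$animals$reason[panel$animals$animal_id == "holey"], "missing")

  # monotonicity: a higher threshold never excludes a previously included animal
  for (thr in c(0.05, 0.1, 0.32, 0.5, 0.9)) {
    p_lo <- suppressMessages(exclude_missing(panel, thr))
    p_hi <- suppressMessages(exclude_missing(panel, min(thr + 0.09, 0.99)))
    expect_true(all(p_lo$animals$excluded | !p_hi$animals$excluded))
  }
})

test_that("the stacked aggregate sums included animals and counts contributors", {
  tr <- function(id) make_trace(seq(0, 900 * 49, 900),
                                0.5 + 0.3 * sin(seq(0, 4, length.out = 50)), id = id)
  panel <- align_traces(list(tr("a"), tr("b"), tr("c")))
  agg <- herd_aggregate(panel)
  expect_equal(agg$aggregate, 3 * tr("x")$intensity)
  expect_equal(agg$n_contributing, rep(3L, 50))

  panel$intensities[10, "b"] <- NA
  agg2 <- herd_aggregate(panel)
  expect_equal(agg2$n_contributing[10], 2L)
  expect_equal(agg2$aggregate[10], 2 * tr("x")$intensity[10])

  # stacking conservation: top layer boundary == aggregate wherever defined
  layers <- stack_layers(panel)
  top <- layers[layers$animal_id == "c", ]
  expect_equal(top$upper[!is.na(agg2$aggregate)],
               agg2$aggregate[!is.na(agg2$aggregate)], tolerance = 1e-12)

  panel$animals$excluded <- rep(TRUE, 3)
  expect_error(herd_aggregate(panel), class = "hr_empty_aggregate")
})

test_that("sub-group aggregates agree with the herd when shape is shared", {
  base <- 0.5 + 0.3 * sin(seq(0, 6, length.out = 80))
  traces <- lapply(sprintf("calf%02d", 1:8), function(id)
    make_trace(seq(0, 900 * 79, 900), base, id = id))
  panel <- align_traces(traces)

  whole <- suppressMessages(subgroup_check(panel, "contiguous-ranges",
                                           ranges = list(c(1, 8))))
  expect_equal(whole$agreement$agreement, 1, tolerance = 1e-12)

  sg <- suppressMessages(subgroup_check(panel, "random-partition",
                                        k_groups = 3, seed = 5))
  expect_true(all(abs(sg$agreement$agreement - 1) < 1e-9))
  expect_equal(sum(lengths(sg$groups)), 8L)

  contig <- suppressMessages(subgroup_check(panel))
  expect_true(all(vapply(contig$groups, function(g) all(g %in% included_ids(panel)),
                         logical(1))))
  expect_error(suppressMessages(subgroup_check(panel, "contiguous-ranges",
                                               ranges = list(c(1, 20)))),
               class = "hr_invalid_grouping")
})

test_that("deviation flags single out an animal drifting from the herd", {
  set.seed(8)
  n <- 200
  base <- 0.5 + 0.2 * sin(seq(0, 8, length.out = n))
  mk <- function(id, v) make_trace(seq(0, 900 * (n - 1), 900), v, id = id)
  traces <- lapply(sprintf("calf%02d", 1:6), function(id)
    mk(id, pmin(1, pmax(0, base + rnorm(n, 0, 0.03)))))
  # herd-faithful animal: no flags
  panel <- align_traces(traces)
  flags0 <- detect_deviation(panel, "calf03", z_threshold = 2, min_duration = 4)
  expect_equal(nrow(flags0), 0L)

  # private collapse over anchors 80..140
  v <- pmin(1, pmax(0, base + rnorm(n, 0, 0.03)))
  v[80:140] <- pmax(0, v[80:140] - 0.45)
  panel2 <- align_traces(c(traces, list(mk("calf07", v))))
  flags <- detect_deviation(panel2, "calf07", z_threshold = 2, min_duration = 4)
  expect_gte(nrow(flags), 1L)
  grid <- panel2$grid
  lo <- grid[80]; hi <- grid[140]
  inter <- sum(pmax(0, pmin(flags$end, hi) - pmax(flags$start, lo)))
  union <- (hi - lo) + sum(flags$end - flags$start) - inter
  expect_gte(inter / union, 0.5)

  # degenerate threshold: one flag spanning the full common grid
  all_flag <- detect_deviation(panel2, "calf07", z_threshold = 0, min_duration = 4)
  expect_equal(nrow(all_flag), 1L)
  expect_equal(all_flag$start, grid[1])
  expect_equal(all_flag$end, grid[n])

  expect_error(detect_deviation(align_traces(traces[1:3]), "calf01"),
               class = "hr_insufficient_herd")
  expect_error(detect_deviation(panel2, "nobody"), class = "hr_invalid_grouping")
})

test_that("the event lag bound is the window length", {
  expect_equal(event_lag_bound(window_spec()), 604800)
  expect_equal(event_lag_bound(window_spec(window_len = 86400 * 2, step = 900,
                                           target_period = 86400)), 172800)
})

test_that("panel CSV round-trips wide data plus metadata sidecar", {
  a <- make_trace(seq(0, 9000, 900), c(runif(10), NA), id = "a")
  b <- make_trace(seq(0, 9000, 900), runif(11), id = "b")
  panel <- suppressMessages(exclude_missing(align_traces(list(a, b)), 0.5))
  d <- withr::local_tempdir()
  f <- file.path(d, "panel.csv")
  write_panel_csv(panel, f)
  expect_true(file.exists(file.path(d, "panel_meta.csv")))
  back <- read_panel_csv(f)
  expect_equal(back$grid, panel$grid)
  expect_equal(back$intensities, panel$intensities)
  expect_equal(back$animals$excluded, panel$animals$excluded)
})
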