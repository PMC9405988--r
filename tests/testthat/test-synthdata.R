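# The synthetic-data generator: determinism, event construction, the
# coupling model, and the ground-truth rating link.

test_that("configuration validation catches bad coupling and spacing", {
  expect_error(sim_config(sfreq = 60), "twice the highest band edge")
  expect_error(sim_config(band_coupling = list(
    sigma = list(list(pair = c(1, 2), kappa = 0.5)))), "unknown band")
  expect_error(sim_config(n_channels = 4, band_coupling = list(
    alpha = list(list(pair = c(1, 9), kappa = 0.5)))), "distinct channels")
  expect_error(sim_config(band_coupling = list(
    alpha = list(list(pair = c(1, 2), kappa = 1.4)))), "\\[0, 1\\]")
  expect_error(sim_config(event_spacing = 5), "non-overlapping")
})

test_that("a fixed seed fully determines events and recordings", {
  cfg <- sim_config(n_subjects = 2, n_channels = 3,
                    n_events_per_subject = 5, seed = 42)
  expect_identical(make_events(cfg, 1), make_events(cfg, 1))
  expect_false(identical(make_events(cfg, 1)$onset,
                         make_events(cfg, 2)$onset))
  r1 <- make_recording(cfg, 1)
  r2 <- make_recording(cfg, 1)
  expect_identical(r1$data, r2$data)
})

test_that("events respect counts, scale bounds and window spacing", {
  cfg <- sim_config(n_subjects = 1, n_channels = 2,
                    n_events_per_subject = 9, seed = 7)
  ev <- make_events(cfg, 1)
  expect_equal(nrow(ev), 9)
  expect_true(all(ev$valence >= 1 & ev$valence <= 9))
  expect_true(all(ev$arousal >= 1 & ev$arousal <= 9))
  expect_true(all(ev$dominance >= 1 & ev$dominance <= 9))
  expect_true(all(ev$liking >= 1 & ev$liking <= 5))
  expect_true(all(ev$familiarity >= 1 & ev$familiarity <= 5))
  expect_true(all(ev$relevance >= 1 & ev$relevance <= 5))
  expect_true(all(ev$emotion %in% emotion_vocabulary()$label))
  # 7-s windows [onset - 6, onset + 1) never overlap
  on <- sort(ev$onset)
  expect_true(all(diff(on) >= 7))
  expect_true(all(on - 6 >= cfg$baseline_duration))
})

test_that("arousal carries the injected variability slope", {
  # plain regression on the hidden index recovers tv_slope within 2 SE;
  # adding label fixed effects (absorbing the prototype means) gives a
  # sharp estimate
  cfg <- sim_config(n_subjects = 1, n_channels = 2,
                    n_events_per_subject = 250, tv_slope = 0.5, seed = 5)
  ev <- make_events(cfg, 1)
  f1 <- stats::lm(arousal ~ tv_index, ev)
  expect_lt(abs(stats::coef(f1)[2] - 0.5),
            2 * sqrt(diag(stats::vcov(f1)))[2])
  f2 <- stats::lm(arousal ~ tv_index + emotion, ev)
  expect_lt(abs(stats::coef(f2)["tv_index"] - 0.5),
            2 * sqrt(diag(stats::vcov(f2)))["tv_index"])
  # and with tv_slope = 0, arousal is independent of the index
  cfg0 <- sim_config(n_subjects = 1, n_channels = 2,
                     n_events_per_subject = 250, tv_slope = 0, seed = 6)
  ev0 <- make_events(cfg0, 1)
  f0 <- stats::lm(arousal ~ tv_index + emotion, ev0)
  tval <- stats::coef(f0)["tv_index"] /
    sqrt(diag(stats::vcov(f0)))["tv_index"]
  expect_lt(abs(tval), 3)
})

test_that("perfect coupling yields near-unit PLV in every segment", {
  cfg <- sim_config(n_subjects = 1, n_channels = 4,
                    n_events_per_subject = 2,
                    band_coupling = list(upper_beta = list(
                      list(pair = c(1, 2), kappa = 1))),
                    signal_noise_sd = 0.1, seed = 11)
  rec <- make_recording(cfg, 1)
  ev <- make_events(cfg, 1)
  tens <- plv_tensor(list(
    band_decompose(extract_event_epoch(rec, ev[1, ]))$upper_beta))
  expect_true(all(tens$values[1, , 1] > 0.9))
  # an uncoupled pair in the same band stays well below
  expect_lt(mean(tens$values[1, , 6]), 0.85)
})

test_that("measured PLV increases with the coupling strength kappa", {
  seeds <- 1:50
  lo <- vapply(seeds, function(s) measure_coupled_plv(0.2, s), numeric(1))
  hi <- vapply(seeds, function(s) measure_coupled_plv(0.8, s + 500),
               numeric(1))
  expect_gt(mean(hi), mean(lo))
  expect_gt(mean(hi) - mean(lo), 0.1)   # clearly separated, not a tie
})

test_that("write_dataset round-trips and is byte-reproducible", {
  cfg <- sim_config(n_subjects = 2, n_channels = 3,
                    n_events_per_subject = 4, tv_slope = 0.37, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset(cfg, d1)
  m2 <- write_dataset(cfg, d2)
  expect_equal(length(m1$recordings), 2)
  expect_identical(m1$recordings, m2$recordings)
  for (f in c("events.tsv", "ground_truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  truth <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$tv_slope, 0.37)
  ds <- read_dataset(d1)
  expect_equal(length(ds$recordings), 2)
  expect_equal(nrow(ds$events), 8)
  rec <- make_recording(cfg, 1)
  expect_equal(ds$recordings[["1"]]$data, rec$data)
})
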