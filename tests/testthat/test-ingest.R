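# Epoch extraction, overlapping-click exclusion, band decomposition and
# segmentation.

make_rec <- function(n_sec = 120, nch = 2, sfreq = 250, seed = 1) {
  withr::with_seed(seed, new_recording(
    matrix(rnorm(nch * n_sec * sfreq), nch), sfreq,
    paste0("ch", seq_len(nch)), subject = 1))
}

test_that("event epochs span 6 s pre-click to 1 s post-click, sample-exact", {
  rec <- make_rec()
  ep <- extract_event_epoch(rec, data.frame(onset = 10, subject = 1))
  # click at 10.0 s, 250 Hz -> samples [1000, 2750) 0-based
  expect_equal(ncol(ep$data), 1750)
  expect_identical(ep$data, rec$data[, 1001:2750])
  expect_error(extract_event_epoch(rec, data.frame(onset = 5, subject = 1)),
               "outside the recording")
  expect_error(extract_event_epoch(rec, data.frame(onset = 119.5,
                                                   subject = 1)),
               "outside the recording")
})

test_that("baseline epochs are seeded, in-span and non-overlapping", {
  rec <- make_rec()
  eps <- extract_baseline_epochs(rec, 8, seed = 4)
  expect_length(eps, 8)
  expect_true(all(vapply(eps, function(e) ncol(e$data) == 1750,
                         logical(1))))
  eps2 <- extract_baseline_epochs(rec, 8, seed = 4)
  expect_identical(eps[[3]]$data, eps2[[3]]$data)
  # n = 9 exceeds the packing bound floor(60 / 7) = 8
  expect_error(extract_baseline_epochs(rec, 9, seed = 1), "maximum 8")
  # window starts lie in [10, 63] s: verify by locating each epoch
  for (e in eps) {
    hit <- which(rec$data[1, ] == e$data[1, 1])[1]
    start_s <- (hit - 1) / 250
    expect_gte(start_s, 10)
    expect_lte(start_s, 63)
  }
})

test_that("overlapping 7-s event windows are dropped pairwise", {
  ev <- function(...) data.frame(subject = 1, onset = c(...))
  expect_equal(nrow(drop_overlapping_events(ev(20, 40))), 2)
  expect_equal(nrow(drop_overlapping_events(ev(20, 24))), 0)
  # windows [14, 21) and [21, 28) touch at a point: kept (half-open)
  expect_equal(nrow(drop_overlapping_events(ev(20, 27))), 2)
  # a chain 20, 24, 28: all three pairwise-linked windows go
  expect_equal(nrow(drop_overlapping_events(ev(20, 24, 28))), 0)
  # overlap is per subject only
  two <- data.frame(subject = c(1, 2), onset = c(20, 24))
  expect_equal(nrow(drop_overlapping_events(two)), 2)
})

test_that("band decomposition is spectrally selective and near-complete", {
  t <- seq(0, 7 - 1 / 250, by = 1 / 250)
  ep <- toy_epoch(rbind(sin(2 * pi * 25 * t), cos(2 * pi * 25 * t)))
  bd <- band_decompose(ep)
  expect_length(bd, 6)
  expect_named(bd, eeg_bands()$name)
  pow <- vapply(bd, function(e) mean(e$data^2), numeric(1))
  expect_equal(names(which.max(pow)), "upper_beta")
  expect_gt(pow["upper_beta"] / sum(pow), 0.95)
  # reconstruction: the band sum approximates the 1-40 Hz signal; the
  # overlap of adjacent Butterworth bands leaves crossover ripple, so a
  # 35% relative RMS tolerance is the documented filter-bank leakage
  ep2 <- toy_epoch(seed = 9)
  f <- butter_bandpass(1, 40, 250)
  wide <- filtfilt_zero_phase(f$b, f$a, ep2$data)
  recon <- Reduce(`+`, lapply(band_decompose(ep2), function(e) e$data))
  rel <- sqrt(mean((recon - wide)^2)) / sqrt(mean(wide^2))
  expect_lt(rel, 0.35)
})

test_that("segmentation yields the printed window layout", {
  w <- segment_windows(1750)
  expect_equal(nrow(w), 9)
  expect_equal(w$start, (0:8) * 175)
  expect_equal(w$end - w$start, rep(250, 9))
  expect_equal(w$start[9], 1400)
  expect_equal(w$end[9], 1650)
  expect_equal(nrow(segment_windows(250)), 1)
  expect_error(segment_windows(200), "shorter than one")
  segs <- segment_epoch(toy_epoch(seed = 2))
  expect_length(segs, 9)
  expect_identical(segs[[2]]$data, toy_epoch(seed = 2)$data[, 176:425])
})

test_that("window count matches brute-force enumeration for random sizes", {
  brute <- function(L, w, s) {
    k <- 0; start <- 0
    while (start + w <= L) { k <- k + 1; start <- start + s }
    k
  }
  withr::with_seed(31, {
    for (i in 1:25) {
      w <- sample(50:400, 1)
      s <- sample(10:w, 1)
      L <- sample(w:4000, 1)
      expect_equal(nrow(segment_windows(L, w, s)), brute(L, w, s),
                   info = sprintf("L=%d w=%d s=%d", L, w, s))
    }
  })
})

test_that("event tables are validated on read", {
  d <- withr::local_tempdir()
  ev <- data.frame(onset = 20, duration = 0, subject = 1, emotion = "sad",
                   valence = 2, arousal = 3, dominance = 4, liking = 3,
                   familiarity = 3, relevance = 3)
  p <- file.path(d, "ev.tsv")
  utils::write.table(ev, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(read_events(p))
  bad <- ev; bad$valence <- 11
  utils::write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(p), "1-9")
  bad <- ev; bad$onset <- 3
  utils::write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(p), "pre-click")
  utils::write.table(ev[, -3], p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_events(p), "lacks columns")
})
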