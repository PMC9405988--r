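# Reading recordings and events, epoch extraction, band decomposition and
# sliding-window segmentation.

#' Construct a recording
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param sfreq Sampling rate, Hz.
#' @param channels Character vector of channel labels (10-10 names),
#'   length `nrow(data)`.
#' @param subject Subject identifier.
#' @return Object of class `recording`.
#' @export
new_recording <- function(data, sfreq, channels, subject) {
  stopifnot(is.matrix(data), sfreq > 0, nrow(data) == length(channels))
  if (anyNA(data)) stop("recording data contains NA")
  structure(list(data = data, sfreq = sfreq,
                 channels = as.character(channels), subject = subject),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              as.character(x$subject), nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq))
  invisible(x)
}

#' Read one recording written by [write_dataset()]
#'
#' @param sidecar_path Path to the `*_eeg.json` sidecar; the signal file
#'   it names is read from the same directory.
#' @return A `recording`.
#' @export
read_recording <- function(sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  sig_path <- file.path(dirname(sidecar_path), meta$file)
  if (!file.exists(sig_path)) stop("signal file not found: ", sig_path)
  data <- readRDS(sig_path)
  new_recording(data, sfreq = meta$sfreq, channels = meta$channels,
                subject = meta$subject)
}

#' Read an events table (BIDS-events dialect TSV)
#'
#' Validates rating bounds (valence/arousal/dominance in 1-9,
#' liking/familiarity/relevance in 1-5) and the pre-click margin
#' (onset >= 6 s, room for the 6-s pre-click window).
#'
#' @param path Path to a tab-separated events file with columns `onset`,
#'   `duration`, `subject`, `emotion`, `valence`, `arousal`, `dominance`,
#'   `liking`, `familiarity`, `relevance`.
#' @return data.frame of events.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "subject", "emotion", "valence",
            "arousal", "dominance", "liking", "familiarity", "relevance")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop("events file lacks columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("valence", "arousal", "dominance")) {
    if (any(ev[[col]] < 1 | ev[[col]] > 9)) {
      stop(col, " ratings outside the 1-9 scale")
    }
  }
  for (col in c("liking", "familiarity", "relevance")) {
    if (any(ev[[col]] < 1 | ev[[col]] > 5)) {
      stop(col, " ratings outside the 1-5 scale")
    }
  }
  if (any(ev$onset < 6)) {
    stop("events with onset < 6 s cannot hold the 6-s pre-click window")
  }
  ev
}

#' Read a whole dataset directory
#'
#' @param dir Directory containing `manifest.json` from [write_dataset()].
#' @return list with `recordings` (list of `recording`), `events`
#'   (data.frame) and `manifest`.
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  recs <- lapply(man$recordings, function(f) {
    read_recording(file.path(dir, sub("\\.rds$", ".json", f)))
  })
  names(recs) <- vapply(recs, function(r) as.character(r$subject), "")
  list(recordings = recs,
       events = read_events(file.path(dir, man$events)),
       manifest = man)
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per
#' channel; shape and metadata preserved.
#'
#' @param rec A `recording`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered `recording`.
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "recording"))
  f <- butter_bandpass(low, high, rec$sfreq, order)
  out <- rec
  out$data <- filtfilt_zero_phase(f$b, f$a, rec$data)
  out
}

new_epoch <- function(data, sfreq, channels, band = NA_character_,
                      subject = NA, event_id = NA, baseline = FALSE) {
  structure(list(data = data, sfreq = sfreq, channels = channels,
                 band = band, subject = subject, event_id = event_id,
                 baseline = baseline),
            class = "epoch")
}

#' Extract the 7-s epoch around one emotional event
#'
#' The analysis window runs from 6 s before the click to 1 s after it
#' (half-open in samples), i.e. exactly `7 * sfreq` samples.
#'
#' @param rec A `recording`.
#' @param ev One events row (with `onset` in seconds and `subject`).
#' @return An `epoch` (channels x `7 * sfreq` samples).
#' @export
extract_event_epoch <- function(rec, ev) {
  stopifnot(inherits(rec, "recording"))
  click <- ev$onset
  start <- round((click - 6) * rec$sfreq)      # 0-based sample offset
  end <- start + 7 * rec$sfreq                 # half-open
  if (start < 0 || end > ncol(rec$data)) {
    stop(sprintf(
      "event window [%g, %g] s for subject %s stimulus %s is outside the recording (%.1f s)",
      click - 6, click + 1, as.character(ev$subject),
      as.character(ev$stimulus %||% NA), ncol(rec$data) / rec$sfreq))
  }
  new_epoch(rec$data[, (start + 1):end, drop = FALSE], rec$sfreq,
            rec$channels, subject = rec$subject,
            event_id = ev$stimulus %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomly extract non-overlapping 7-s baseline epochs
#'
#' Windows are drawn wholly inside the baseline span (default 10-70 s of
#' the recording) and are pairwise non-overlapping. Placement uses the
#' uniform-spacings construction, so any feasible `n`
#' (`n <= floor(span / 7)`) always succeeds and a fixed seed reproduces
#' identical window starts.
#'
#' @param rec A `recording`.
#' @param n Number of epochs.
#' @param seed Integer seed.
#' @param span Two-element vector, baseline start/end in seconds
#'   (default `c(10, 70)`).
#' @return list of `epoch` objects (`baseline = TRUE`).
#' @export
extract_baseline_epochs <- function(rec, n, seed, span = c(10, 70)) {
  stopifnot(inherits(rec, "recording"), n >= 1)
  len <- span[2] - span[1]
  if (span[2] * rec$sfreq > ncol(rec$data)) {
    stop("recording shorter than the baseline span [", span[1], ", ",
         span[2], "] s")
  }
  kmax <- floor(len / 7)
  if (n > kmax) {
    stop("cannot place ", n, " non-overlapping 7-s windows in a ", len,
         "-s span (maximum ", kmax, ")")
  }
  slack <- len - n * 7
  starts <- with_seed(seed, {
    u <- sort(stats::runif(n))
    span[1] + slack * u + 7 * (seq_len(n) - 1)
  })
  lapply(seq_len(n), function(i) {
    s0 <- round(starts[i] * rec$sfreq)
    new_epoch(rec$data[, (s0 + 1):(s0 + 7 * rec$sfreq), drop = FALSE],
              rec$sfreq, rec$channels, subject = rec$subject,
              event_id = paste0("baseline-", i), baseline = TRUE)
  })
}

#' Drop events whose 7-s windows overlap
#'
#' Within each subject, every event whose window `[onset - 6, onset + 1)`
#' intersects another event's window is removed — both members of an
#' overlapping pair are dropped, mirroring the exclusion of all
#' overlapping clicks rather than keeping one of each pair. Windows are
#' half-open, so two windows that merely touch at a boundary do not count
#' as overlapping.
#'
#' @param events data.frame with `subject` and `onset` columns.
#' @return The events data.frame with overlapping events removed, sorted
#'   by subject then onset.
#' @export
drop_overlapping_events <- function(events) {
  ev <- events[order(events$subject, events$onset), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  for (s in unique(ev$subject)) {
    idx <- which(ev$subject == s)
    if (length(idx) < 2) next
    st <- ev$onset[idx] - 6
    en <- ev$onset[idx] + 1
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        if (st[b] < en[a] && st[a] < en[b]) {      # open-interval overlap
          keep[idx[c(a, b)]] <- FALSE
        }
      }
    }
  }
  ev[keep, , drop = FALSE]
}

#' Decompose a wideband epoch into the six frequency bands
#'
#' Each band is obtained by zero-phase Butterworth filtering of the FULL
#' 7-s epoch (filtering always precedes segmentation, so segment-level
#' phase estimates are not contaminated by per-segment filter edges).
#'
#' @param epoch A wideband `epoch`.
#' @param bands Band table as from [eeg_bands()].
#' @param order Butterworth prototype order.
#' @return Named list of six band-limited `epoch` objects.
#' @export
band_decompose <- function(epoch, bands = eeg_bands(), order = 4) {
  stopifnot(inherits(epoch, "epoch"))
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    f <- butter_bandpass(bands$low[i], bands$high[i], epoch$sfreq, order)
    e <- epoch
    e$data <- filtfilt_zero_phase(f$b, f$a, epoch$data)
    e$band <- bands$name[i]
    out[[i]] <- e
  }
  out
}

#' Sliding segment windows
#'
#' 0-based half-open windows `[k * step, k * step + width)` for
#' `k = 0, 1, ...` as long as the window fits: `1 + floor((L - width) /
#' step)` windows for an epoch of `L` samples. With the pipeline defaults
#' (1750-sample epoch, 250-sample windows, 175-sample step, i.e. 75
#' samples of overlap) this yields exactly nine segments, the last one
#' covering samples \[1400, 1650).
#'
#' @param n_samples Epoch length L in samples.
#' @param width Window length (default 250).
#' @param step Hop between window starts (default 175).
#' @return data.frame with columns `index` (0-based), `start`, `end`
#'   (0-based half-open sample offsets).
#' @export
segment_windows <- function(n_samples, width = 250, step = 175) {
  if (n_samples < width) {
    stop("epoch of ", n_samples, " samples is shorter than one ", width,
         "-sample window")
  }
  k <- 0:((n_samples - width) %/% step)
  data.frame(index = k, start = k * step, end = k * step + width)
}

#' Cut an epoch into overlapping segments
#'
#' @param epoch An `epoch`.
#' @param width,step Window length and hop in samples (defaults 250/175).
#' @return list of `list(window = <one-row window frame>, data =
#'   channels x width matrix)`.
#' @export
segment_epoch <- function(epoch, width = 250, step = 175) {
  stopifnot(inherits(epoch, "epoch"))
  w <- segment_windows(ncol(epoch$data), width, step)
  lapply(seq_len(nrow(w)), function(i) {
    list(window = w[i, ],
         data = epoch$data[, (w$start[i] + 1):w$end[i], drop = FALSE])
  })
}
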