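# Synthetic recordings, events and ratings with known ground truth.
# The generator emulates the study design the pipeline targets: an 80-s
# eyes-open baseline followed by a stimulus period in which the subject
# reports temporally localized emotional events by mouse click, each click
# labelled with one of 24 emotion words and rated on six self-assessment
# scales.

#' The 24-label emotion vocabulary with latent structure
#'
#' Twenty-four emotion words arranged as eight tight triads in
#' valence-arousal space (the latent groups the grouping stage should
#' recover), each with a prototype valence, arousal and dominance
#' position on the 1-9 scales.
#'
#' @return data.frame with columns `label`, `group` (1-8), `valence`,
#'   `arousal`, `dominance` (prototype means).
#' @export
emotion_vocabulary <- function() {
  v <- rbind(
    c("happy",        1, 8.0, 6.0, 6.5),
    c("joyous",       1, 8.2, 6.4, 6.3),
    c("delighted",    1, 7.8, 5.8, 6.0),
    c("excited",      2, 7.4, 8.2, 6.0),
    c("enthusiastic", 2, 7.2, 7.8, 6.2),
    c("triumphant",   2, 7.6, 8.0, 7.0),
    c("calm",         3, 6.8, 2.2, 5.8),
    c("relaxed",      3, 7.0, 2.0, 6.0),
    c("contented",    3, 6.6, 2.6, 5.6),
    c("adventurous",  4, 6.0, 7.4, 6.4),
    c("aroused",      4, 5.8, 7.8, 5.4),
    c("surprised",    4, 6.2, 7.6, 4.8),
    c("afraid",       5, 2.4, 7.6, 2.6),
    c("alarmed",      5, 2.8, 7.8, 3.0),
    c("anxious",      5, 2.6, 7.2, 2.8),
    c("angry",        6, 2.0, 6.6, 4.6),
    c("disgusted",    6, 2.2, 6.2, 4.2),
    c("annoyed",      6, 2.4, 6.0, 4.4),
    c("melancholic",  7, 2.8, 3.4, 3.4),
    c("miserable",    7, 2.4, 3.6, 2.8),
    c("gloomy",       7, 2.6, 3.0, 3.2),
    c("sad",          8, 3.0, 1.8, 3.0),
    c("bored",        8, 3.4, 2.0, 4.0),
    c("tired",        8, 3.2, 2.6, 3.8)
  )
  data.frame(
    label = v[, 1],
    group = as.integer(v[, 2]),
    valence = as.numeric(v[, 3]),
    arousal = as.numeric(v[, 4]),
    dominance = as.numeric(v[, 5]),
    stringsAsFactors = FALSE
  )
}

# A 10-10 montage label pool; the first n_channels entries are used.
montage_1010 <- function(n) {
  labels <- c(
    "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6", "T7", "C3", "Cz",
    "C4", "T8", "CP5", "CP1", "CPz", "CP2", "CP6", "P7",
    "P3", "Pz", "P4", "P8", "PO3", "POz", "PO4", "Oz",
    "O1", "O2", "AF3", "AF4", "AF7", "AF8", "F5", "F1",
    "F2", "F6", "FT7", "FC3", "FC4", "FT8", "C5", "C1",
    "C2", "C6", "TP7", "CP3", "CP4", "TP8", "P5", "P1",
    "P2", "P6", "PO7", "PO8", "AFz", "F9", "F10", "Iz"
  )
  if (n > length(labels)) {
    stop("at most ", length(labels), " channels supported; asked for ", n)
  }
  labels[seq_len(n)]
}

#' Simulation configuration
#'
#' Defines a complete synthetic study: subjects, montage, event counts,
#' the per-band phase-coupling structure, and the ground-truth link
#' between injected connectivity variability and the arousal rating.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Channels (default 32; labels from the 10-10 montage).
#' @param sfreq Sampling rate in Hz (default 250; must exceed twice the
#'   highest band edge, 40 Hz).
#' @param n_events_per_subject Emotional events (clicks) per subject.
#' @param baseline_duration Seconds of eyes-open baseline prepended before
#'   the stimulus period (default 80).
#' @param band_coupling Named list keyed by band name; each element a list
#'   of coupling entries `list(pair = c(i, j), kappa = k, groups = g)`.
#'   `kappa` in \[0, 1\] sets the phase-locking strength (1 = constant lag,
#'   0 = independent phases); `groups` restricts the coupling to events of
#'   those latent emotion groups (`NULL` = all events).
#' @param tv_slope True slope linking each event's injected
#'   coupling-variability index (uniform on \[0, 1\]) to its arousal
#'   rating.
#' @param noise_sd Rating noise standard deviation, in rating-scale units.
#' @param signal_noise_sd Standard deviation of the 1/f background noise
#'   added to every channel, in microvolts (default 6; set near 0 for
#'   noise-free oscillator checks).
#' @param event_spacing Mean seconds allotted per event in the stimulus
#'   period (default 12; must leave room for non-overlapping 7-s windows).
#' @param seed Integer root seed; fully determines the dataset.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 4,
                       n_channels = 32,
                       sfreq = 250,
                       n_events_per_subject = 10,
                       baseline_duration = 80,
                       band_coupling = list(),
                       tv_slope = 0.5,
                       noise_sd = 0.5,
                       signal_noise_sd = 6,
                       event_spacing = 12,
                       seed = 1L) {
  if (sfreq <= 2 * 40) {
    stop("sfreq must exceed twice the highest band edge (40 Hz); got ",
         sfreq)
  }
  band_names <- eeg_bands()$name
  for (bn in names(band_coupling)) {
    if (!bn %in% band_names) {
      stop("band_coupling references unknown band '", bn, "'")
    }
    for (ent in band_coupling[[bn]]) {
      if (is.null(ent$pair) || length(ent$pair) != 2) {
        stop("coupling entry in band '", bn, "' lacks a 2-element pair")
      }
      if (any(ent$pair < 1) || any(ent$pair > n_channels) ||
          ent$pair[1] == ent$pair[2]) {
        stop("coupling pair (", ent$pair[1], ", ", ent$pair[2],
             ") does not index two distinct channels out of ", n_channels)
      }
      if (is.null(ent$kappa) || ent$kappa < 0 || ent$kappa > 1) {
        stop("coupling strength kappa must lie in [0, 1]")
      }
      if (!is.null(ent$groups) &&
          (any(ent$groups < 1) || any(ent$groups > 8))) {
        stop("coupling group set must index groups 1-8")
      }
    }
  }
  if (event_spacing < 7.5) {
    stop("event_spacing of ", event_spacing,
         " s cannot hold non-overlapping 7-s event windows")
  }
  structure(
    list(n_subjects = n_subjects, n_channels = n_channels, sfreq = sfreq,
         n_events_per_subject = n_events_per_subject,
         baseline_duration = baseline_duration,
         band_coupling = band_coupling, tv_slope = tv_slope,
         noise_sd = noise_sd, signal_noise_sd = signal_noise_sd,
         event_spacing = event_spacing,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# kappa in [0,1] -> von Mises concentration of the phase jitter.
# Monotone increasing; kappa = 0 gives uniform jitter (independent
# phases), kappa = 1 gives zero jitter (constant lag).
kappa_concentration <- function(kappa) {
  if (kappa >= 1) Inf else 4 * kappa / (1 - kappa)
}

#' Generate one subject's event table
#'
#' Click times are placed in the stimulus period (after the baseline) so
#' that the 7-s analysis windows (6 s pre-click to 1 s post-click) never
#' overlap; a small guard gap of 0.5 s is kept between windows. Each
#' event draws an emotion label from the 24-word vocabulary, a hidden
#' coupling-variability index `tv_index` ~ U(0, 1), and ratings: valence,
#' arousal and dominance around the label prototype (1-9), liking,
#' familiarity and relevance (1-5). Arousal additionally carries the
#' ground-truth linear term `tv_slope * tv_index` before noise and
#' clipping.
#'
#' @param cfg A [sim_config()].
#' @param subject Subject index (1-based).
#' @return data.frame with one row per event: `subject`, `stimulus`,
#'   `onset` (click time, s), `duration` (0), `emotion`, the six rating
#'   columns, plus ground-truth columns `group` and `tv_index`.
#' @export
make_events <- function(cfg, subject) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_events_per_subject
  voc <- emotion_vocabulary()
  span <- n * cfg$event_spacing
  win <- 7.5                        # 7-s window + 0.5-s guard
  slack <- span - n * win
  if (slack < 0) {
    stop("cannot place ", n, " non-overlapping 7.5-s event windows in a ",
         span, "-s stimulus period (need >= ", n * win, " s)")
  }
  with_seed(derive_seed(cfg$seed, subject * 2L), {
    u <- sort(stats::runif(n))
    starts <- cfg$baseline_duration + slack * u + win * (seq_len(n) - 1)
    clicks <- starts + 6
    lab_i <- sample.int(nrow(voc), n, replace = TRUE)
    tv_index <- stats::runif(n)
    proto <- voc[lab_i, ]
    valence <- clip(proto$valence + stats::rnorm(n, 0, cfg$noise_sd), 1, 9)
    arousal <- clip(proto$arousal + cfg$tv_slope * tv_index +
                      stats::rnorm(n, 0, cfg$noise_sd), 1, 9)
    dominance <- clip(proto$dominance + stats::rnorm(n, 0, cfg$noise_sd),
                      1, 9)
    liking <- clip(3 + stats::rnorm(n, 0, 1), 1, 5)
    familiarity <- clip(3 + stats::rnorm(n, 0, 1), 1, 5)
    relevance <- clip(3 + stats::rnorm(n, 0, 1), 1, 5)
    data.frame(
      subject = subject,
      stimulus = seq_len(n),
      onset = round(clicks, 3),
      duration = 0,
      emotion = proto$label,
      valence = round(valence, 3),
      arousal = round(arousal, 3),
      dominance = round(dominance, 3),
      liking = round(liking, 3),
      familiarity = round(familiarity, 3),
      relevance = round(relevance, 3),
      group = proto$group,
      tv_index = round(tv_index, 6),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate one subject's multichannel recording
#'
#' Each channel is a sum over the six frequency bands of a narrowband
#' oscillation (center-frequency carrier with diffusing phase) plus
#' 1/f-shaped Gaussian background noise. For every configured coupled
#' pair and band, inside the 7-s windows of the events the coupling
#' applies to, the second channel's band phase is rewritten as the first
#' channel's phase plus a constant lag plus von Mises jitter whose
#' concentration grows with the coupling strength kappa
#' (kappa = 1: zero jitter; kappa = 0: uniform jitter, i.e. independent).
#' The per-event hidden index `tv_index` modulates kappa block-wise
#' across the window, so connectivity varies more over time for
#' high-`tv_index` events — the ground truth behind the tvDFC regression.
#'
#' The events are re-derived internally from the same seed, so
#' `make_recording()` and [make_events()] always agree.
#'
#' @param cfg A [sim_config()].
#' @param subject Subject index (1-based).
#' @return A `recording` object (see [new_recording()]).
#' @export
make_recording <- function(cfg, subject) {
  stopifnot(inherits(cfg, "sim_config"))
  events <- make_events(cfg, subject)
  sf <- cfg$sfreq
  dur <- cfg$baseline_duration +
    cfg$n_events_per_subject * cfg$event_spacing + 2
  n <- round(dur * sf)
  nc <- cfg$n_channels
  bands <- eeg_bands()
  with_seed(derive_seed(cfg$seed, subject * 2L + 1L), {
    tt <- (seq_len(n) - 1) / sf
    data <- matrix(0, nrow = nc, ncol = n)
    for (bi in seq_len(nrow(bands))) {
      fc <- (bands$low[bi] + bands$high[bi]) / 2
      amp <- 10 / sqrt(fc)
      # diffusing phases -> independent channels decohere within ~1 s
      phase <- matrix(stats::rnorm(nc * n, 0, 0.12), nrow = nc)
      phase <- t(apply(phase, 1, cumsum)) + 2 * pi * fc *
        matrix(tt, nrow = nc, ncol = n, byrow = TRUE)
      entries <- cfg$band_coupling[[bands$name[bi]]]
      for (ent in entries) {
        i <- ent$pair[1]; j <- ent$pair[2]
        lag <- stats::runif(1, 0.3, pi - 0.3)
        applicable <- if (is.null(ent$groups)) seq_len(nrow(events))
          else which(events$group %in% ent$groups)
        for (e in applicable) {
          s0 <- round((events$onset[e] - 6) * sf) + 1
          s1 <- round((events$onset[e] + 1) * sf)
          idx <- s0:s1
          nw <- length(idx)
          # block-wise modulation of the jitter concentration by the
          # event's hidden tv index; kappa = 1 keeps zero jitter in
          # every block (constant lag), kappa = 0 stays uniform
          nblk <- 9L
          blk <- pmin(ceiling(seq_along(idx) / (nw / nblk)), nblk)
          mod <- stats::runif(nblk)
          conc <- kappa_concentration(ent$kappa)
          jit <- numeric(nw)
          for (b in seq_len(nblk)) {
            cb <- if (is.finite(conc))
              conc * (1 - 0.95 * events$tv_index[e] * mod[b]) else conc
            sel <- which(blk == b)
            jit[sel] <- rvonmises(length(sel), 0, cb)
          }
          phase[j, idx] <- phase[i, idx] + lag + jit
        }
      }
      data <- data + amp * cos(phase)
    }
    if (cfg$signal_noise_sd > 0) {
      for (ch in seq_len(nc)) {
        data[ch, ] <- data[ch, ] + cfg$signal_noise_sd * pink_noise(n)
      }
    }
    new_recording(data, sfreq = sf, channels = montage_1010(nc),
                  subject = subject)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Writes one recording per subject (an `.rds` signal matrix with a JSON
#' sidecar carrying sampling rate, channel labels and subject id), a
#' single BIDS-events-dialect TSV for all subjects, a ground-truth JSON
#' (true couplings, true tv slope, per-event hidden indices, seed), and
#' a manifest JSON listing every file. Re-running with the same
#' configuration reproduces byte-identical TSV/JSON outputs.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  rec_files <- character(cfg$n_subjects)
  all_events <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    rec <- make_recording(cfg, s)
    base <- sprintf("sub-%02d", s)
    sig_path <- file.path(out_dir, paste0(base, "_eeg.rds"))
    saveRDS(rec$data, sig_path, compress = FALSE)
    sidecar <- list(subject = s, sfreq = cfg$sfreq,
                    channels = rec$channels,
                    n_samples = ncol(rec$data),
                    file = basename(sig_path))
    jsonlite::write_json(sidecar, file.path(out_dir, paste0(base, "_eeg.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rec_files[s] <- basename(sig_path)
    all_events[[s]] <- make_events(cfg, s)
  }
  events <- do.call(rbind, all_events)
  bids_cols <- c("onset", "duration", "subject", "emotion", "valence",
                 "arousal", "dominance", "liking", "familiarity",
                 "relevance")
  ev_path <- file.path(out_dir, "events.tsv")
  utils::write.table(events[, bids_cols], ev_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    seed = cfg$seed,
    tv_slope = cfg$tv_slope,
    band_coupling = cfg$band_coupling,
    events = events[, c("subject", "stimulus", "onset", "group",
                        "tv_index")]
  )
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    n_subjects = cfg$n_subjects,
    sfreq = cfg$sfreq,
    n_channels = cfg$n_channels,
    seed = cfg$seed,
    recordings = rec_files,
    events = basename(ev_path),
    ground_truth = basename(truth_path)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
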