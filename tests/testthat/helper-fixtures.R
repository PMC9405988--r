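# Shared fixtures, all generated in code.

# A 1750-sample 2-channel epoch from given data (or white noise).
toy_epoch <- function(data = NULL, nch = 2, n = 1750, sfreq = 250,
                      seed = 1) {
  if (is.null(data)) {
    data <- withr::with_seed(seed, matrix(rnorm(nch * n), nch, n))
  }
  structure(list(data = data, sfreq = sfreq,
                 channels = paste0("ch", seq_len(nrow(data))),
                 band = NA_character_, subject = 1, event_id = 1,
                 baseline = FALSE),
            class = "epoch")
}

# Per-event records with a KNOWN standardized slope beta between tv and
# the arousal outcome: var(y) = beta^2 + subj_sd^2 + resid^2 = 1, so the
# population standardized slope equals beta exactly.
gen_tv_records <- function(beta, n_subjects = 40, n_per_subject = 10,
                           subj_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    n <- n_subjects * n_per_subject
    subj <- rep(seq_len(n_subjects), each = n_per_subject)
    tv <- rnorm(n)
    resid_sd <- sqrt(max(1 - beta^2 - subj_sd^2, 0.05))
    y <- beta * tv + subj_sd * rnorm(n_subjects)[subj] +
      rnorm(n, 0, resid_sd)
    data.frame(tv = tv, arousal = y, dominance = rnorm(n),
               valence = rnorm(n), subject = subj)
  })
}

# Null PLV observations: independent uniform phases per channel, PLV per
# pair over 250 samples (observations x pairs matrix).
gen_null_plv_obs <- function(n_obs, n_channels, n_samples = 250) {
  t(vapply(seq_len(n_obs), function(i) {
    ph <- matrix(runif(n_channels * n_samples, -pi, pi), n_channels)
    E <- exp(1i * ph)
    M <- Mod(E %*% Conj(t(E))) / n_samples
    M[upper.tri(M)]
  }, numeric(choose(n_channels, 2))))
}

# Mean upper-beta PLV of the coupled pair (1, 2) for one simulated event
# at coupling strength kappa: the generator-to-measurement round trip.
measure_coupled_plv <- function(kappa, seed) {
  cfg <- sim_config(n_subjects = 1, n_channels = 2,
                    n_events_per_subject = 2,
                    band_coupling = list(upper_beta = list(
                      list(pair = c(1, 2), kappa = kappa))),
                    seed = seed)
  rec <- make_recording(cfg, 1)
  ev <- make_events(cfg, 1)
  tens <- plv_tensor(list(
    band_decompose(extract_event_epoch(rec, ev[1, ]))$upper_beta))
  mean(tens$values[1, , 1])
}
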