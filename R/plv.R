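# Phase-locking value connectivity: per event, per band, per segment,
# for every channel pair.

#' Lexicographic channel-pair index
#'
#' The stable pair ordering used by every PLV tensor, connectivity vector
#' and significance result in the pipeline: all (i, j) with i < j in
#' channel order, j varying fastest.
#'
#' @param channels Character vector of channel labels.
#' @return data.frame with columns `i`, `j` (1-based channel indices),
#'   `chan_a`, `chan_b`; `choose(n, 2)` rows.
#' @export
pair_index <- function(channels) {
  n <- length(channels)
  if (n < 2) stop("need at least 2 channels to form pairs")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             chan_a = channels[idx[, 1]], chan_b = channels[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Phase-locking value of two phase series
#'
#' `PLV = | mean_t exp(i (phi_a(t) - phi_b(t))) |`, the length of the
#' time-averaged unit phasor of the phase difference. 1 means a perfectly
#' constant phase relation, 0 no consistent relation. Invariant to adding
#' a common constant to both series.
#'
#' @param phase_a,phase_b Phase series in radians, equal length >= 2.
#' @return Scalar in \[0, 1\].
#' @export
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase series differ in length (", length(phase_a), " vs ",
         length(phase_b), ")")
  }
  if (length(phase_a) < 2) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

# upper.tri() extracts column-major; this permutation reorders the
# extracted vector to lexicographic (i, j) pair order.
order_upper_tri <- function(nch) {
  idx <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  order(idx[, 1], idx[, 2])
}

#' PLV tensor for a set of band-limited event epochs
#'
#' For each epoch, instantaneous phases are computed from the analytic
#' signal of the FULL 7-s band epoch (never per segment, avoiding Hilbert
#' edge distortion inside the 1-s windows), then each segment's 250 phase
#' samples give one PLV per channel pair.
#'
#' @param epochs list of band-limited `epoch` objects with identical
#'   channel sets (one per event or baseline epoch).
#' @param width,step Segment window parameters (defaults 250/175).
#' @return Object of class `plv_tensor`: list with `values` (events x
#'   segments x pairs array), `pairs` (the [pair_index()] frame),
#'   `band`, `epoch_ids`, `subjects`, `windows`.
#' @export
plv_tensor <- function(epochs, width = 250, step = 175) {
  stopifnot(length(epochs) >= 1)
  channels <- epochs[[1]]$channels
  bad <- which(!vapply(epochs, function(e)
    identical(e$channels, channels), logical(1)))
  if (length(bad)) {
    stop("epochs with inconsistent channel sets at positions: ",
         paste(bad, collapse = ", "))
  }
  n_samp <- ncol(epochs[[1]]$data)
  windows <- segment_windows(n_samp, width, step)
  # segments touching the Hilbert edge zone (first/last 125 samples of
  # the epoch) carry slightly distorted phases; flag them in metadata
  windows$edge_affected <- windows$start < 125 | windows$end > n_samp - 125
  pairs <- pair_index(channels)
  ord <- order_upper_tri(length(channels))
  n_ev <- length(epochs)
  n_seg <- nrow(windows)
  vals <- array(NA_real_, dim = c(n_ev, n_seg, nrow(pairs)))
  for (e in seq_len(n_ev)) {
    ph <- t(apply(epochs[[e]]$data, 1, instantaneous_phase))
    EE <- exp(1i * ph)
    for (s in seq_len(n_seg)) {
      idx <- (windows$start[s] + 1):windows$end[s]
      Es <- EE[, idx, drop = FALSE]
      M <- Mod(Es %*% Conj(t(Es))) / length(idx)
      vals[e, s, ] <- M[upper.tri(M)][ord]
    }
  }
  structure(list(
    values = vals, pairs = pairs,
    band = epochs[[1]]$band,
    epoch_ids = vapply(epochs, function(e) as.character(e$event_id), ""),
    subjects = vapply(epochs, function(e) as.character(e$subject), ""),
    baseline = vapply(epochs, function(e) isTRUE(e$baseline), logical(1)),
    windows = windows
  ), class = "plv_tensor")
}

#' Cache a PLV tensor to disk (array container + JSON sidecar)
#'
#' The values array goes to `<path>.rds`; the sidecar `<path>.json`
#' carries band, pair index, epoch ids, subjects and window layout. No
#' bespoke binary format.
#'
#' @param tens A `plv_tensor`.
#' @param path Output path stem (without extension).
#' @return `path`, invisibly.
#' @export
save_plv_tensor <- function(tens, path) {
  stopifnot(inherits(tens, "plv_tensor"))
  saveRDS(tens$values, paste0(path, ".rds"), compress = FALSE)
  meta <- list(band = tens$band, pair_index = tens$pairs,
               epoch_ids = tens$epoch_ids, subjects = tens$subjects,
               baseline = tens$baseline, windows = tens$windows,
               dim = dim(tens$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a PLV tensor cached by [save_plv_tensor()]
#'
#' @param path Path stem used when saving.
#' @return A `plv_tensor`.
#' @export
load_plv_tensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(values = readRDS(paste0(path, ".rds")),
                 pairs = meta$pair_index, band = meta$band,
                 epoch_ids = meta$epoch_ids, subjects = meta$subjects,
                 baseline = meta$baseline, windows = meta$windows),
            class = "plv_tensor")
}

#' @export
print.plv_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<plv_tensor> band %s: %d epochs x %d segments x %d pairs\n",
              x$band %||% "?", d[1], d[2], d[3]))
  invisible(x)
}
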