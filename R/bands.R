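#' Canonical EEG frequency bands
#'
#' The six band definitions used throughout the pipeline: delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-12 Hz), lower beta (12-20 Hz), upper beta
#' (20-30 Hz) and gamma (30-40 Hz).
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz), one row
#'   per band, in ascending frequency order.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "lower_beta", "upper_beta", "gamma"),
    low  = c(1, 4, 8, 12, 20, 30),
    high = c(4, 8, 12, 20, 30, 40),
    stringsAsFactors = FALSE
  )
}

#' Look up one band definition by name
#'
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"lower_beta"`,
#'   `"upper_beta"`, `"gamma"`.
#' @return A one-row data.frame with `name`, `low`, `high`.
#' @export
band_definition <- function(name) {
  b <- eeg_bands()
  i <- match(name, b$name)
  if (is.na(i)) {
    stop("unknown band '", name, "'; expected one of: ",
         paste(b$name, collapse = ", "))
  }
  b[i, , drop = FALSE]
}
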