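#' Looming-stimulus diameter profile
#'
#' Angular diameter of the expanding dark disc used as the threat stimulus.
#' Each loom expands linearly from `start_deg` at `expansion_rate` deg/s for
#' `expansion_s` seconds, holds at its final size for `hold_s` seconds, and
#' is followed immediately by the next loom; a bout contains `n_looms`
#' expansions.
#'
#' @param t Time in seconds from bout onset (vectorised).
#' @param expansion_rate Expansion speed in deg/s (default 80).
#' @param expansion_s Expansion duration per loom in s (default 0.5).
#' @param hold_s Hold duration at full size in s (default 0.25).
#' @param n_looms Number of consecutive looms in a bout (default 5).
#' @param start_deg Initial diameter in deg (default 0).
#' @return Numeric vector of angular diameters (deg); `NA` outside the bout.
#' @examples
#' loom_diameter(0.5)   # full size after a single 500 ms expansion
#' @export
loom_diameter <- function(t, expansion_rate = 80, expansion_s = 0.5,
                          hold_s = 0.25, n_looms = 5, start_deg = 0) {
  stop_if(expansion_rate <= 0 || expansion_s <= 0 || hold_s < 0,
          "loom timing parameters must be positive")
  period <- expansion_s + hold_s
  phase <- t %% period
  idx <- floor(t / period)
  d <- ifelse(phase < expansion_s,
              start_deg + expansion_rate * phase,
              start_deg + expansion_rate * expansion_s)
  d[t < 0 | idx >= n_looms] <- NA_real_
  d
}

#' Loom bout schedule
#'
#' Onset and duration of each loom within a bout, used to map reaction times
#' to loom number and to window unit responses.
#'
#' @inheritParams loom_diameter
#' @return data.frame with columns `loom`, `onset_s`, `offset_s`.
#' @export
loom_schedule <- function(n_looms = 5, expansion_s = 0.5, hold_s = 0.25) {
  period <- expansion_s + hold_s
  data.frame(loom = seq_len(n_looms),
             onset_s = (seq_len(n_looms) - 1) * period,
             offset_s = seq_len(n_looms) * period)
}

#' Loom contrast
#'
#' Michelson-free contrast convention used for the low-contrast variants:
#' `(background - disc) / background * 100`; the background luminance stays
#' fixed while the disc is brightened.
#'
#' @param disc_lum,background_lum Luminances in common units.
#' @return Contrast in percent.
#' @export
loom_contrast <- function(disc_lum, background_lum) {
  stop_if(background_lum <= 0, "background luminance must be positive")
  (background_lum - disc_lum) / background_lum * 100
}
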