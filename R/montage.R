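#' Default 30-channel scalp montage
#'
#' The 10-20-system scalp channels used throughout the package as the default
#' montage for synthetic data: frontal, central, temporal, centro-parietal,
#' parietal and occipital sites (EOG and mastoid reference channels excluded).
#'
#' @return character vector of 30 channel labels.
#' @examples
#' defaultMontage()
#' @export
defaultMontage <- function() {
  c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "F9", "F10",
    "Cz", "C1", "C2", "C3", "C4", "T7", "T8",
    "CPz", "CP1", "CP2", "CP3", "CP4",
    "Pz", "P1", "P2", "P3", "P4", "P7", "P8",
    "O1", "O2")
}

#' Sampling grid of a half-open analysis window
#'
#' Timepoint latencies for a half-open window `[t0, t1)` sampled at
#' `samplingRate` Hz: `t0, t0 + dt, ..., t1 - dt` with `dt = 1000 /
#' samplingRate` ms. At the default 250 Hz the step is 4 ms, so `[0, 600)`
#' yields 150 samples and `[600, 2000)` yields 350.
#'
#' @param window numeric(2), `(t0_ms, t1_ms)`.
#' @param samplingRate sampling rate in Hz (default 250).
#' @return numeric vector of latencies in ms.
#' @examples
#' length(windowTimes(c(0, 600)))   # 150
#' @export
windowTimes <- function(window, samplingRate = 250) {
  stopifnot(length(window) == 2, window[2] > window[1], samplingRate > 0)
  dt <- 1000 / samplingRate
  seq(from = window[1], to = window[2] - dt, by = dt)
}

#' @rdname windowTimes
#' @return `windowSamples()`: the number of samples in the window.
#' @export
windowSamples <- function(window, samplingRate = 250) {
  length(windowTimes(window, samplingRate))
}
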