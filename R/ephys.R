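#' Peak-current I-V curve
#'
#' @param voltages_mV Unique holding voltages, mV.
#' @param currents_pA Peak oeEPSC amplitude per voltage, pA (sweep-averaged;
#'   inward currents negative).
#' @return An `iv_curve` data frame (`voltage_mV`, `current_pA`).
#' @export
iv_curve <- function(voltages_mV, currents_pA) {
  if (anyDuplicated(voltages_mV)) abort_config("voltages must be unique")
  if (length(voltages_mV) != length(currents_pA))
    abort_config("voltages and currents must have equal length")
  structure(data.frame(voltage_mV = voltages_mV, current_pA = currents_pA),
            class = c("iv_curve", "data.frame"))
}

iv_current_at <- function(curve, v) {
  i <- which(curve$voltage_mV == v)
  if (length(i) != 1)
    stop("I-V curve must contain ", v, " mV", call. = FALSE)
  curve$current_pA[i]
}

#' Normalize an I-V curve to the -80 mV peak
#'
#' Divides every current by the magnitude of the peak current at -80 mV, so
#' the normalized curve is unitless with I(-80) = -1 under the standard sign
#' convention (inward negative).
#'
#' @param curve An `iv_curve` containing -80 mV.
#' @return A normalized `iv_curve`.
#' @export
normalize_iv <- function(curve) {
  i80 <- iv_current_at(curve, -80)
  if (i80 == 0) stop("cannot normalize: I(-80 mV) is zero", call. = FALSE)
  iv_curve(curve$voltage_mV, curve$current_pA / abs(i80))
}

#' AMPA rectification index
#'
#' RI = I(+50 mV) / (-I(-70 mV)). An ohmic synapse with a 0 mV reversal has
#' RI = 5/7; values well below that indicate inward rectification, the
#' signature of calcium-permeable AMPA receptors. Being a ratio, RI is
#' invariant to current rescaling, so raw and normalized curves give the
#' same index.
#'
#' @param curve An `iv_curve` containing +50 and -70 mV.
#' @return The rectification index (unitless).
#' @export
rectification_index <- function(curve) {
  i50 <- iv_current_at(curve, 50)
  i70 <- iv_current_at(curve, -70)
  if (i70 >= 0)
    stop("sign-convention error: I(-70 mV) must be negative (inward)",
         call. = FALSE)
  i50 / (-i70)
}

#' Drug-wash amplitude series
#'
#' @param time_s Sweep timestamps, seconds.
#' @param amplitude_pA Peak oeEPSC amplitude per sweep, pA.
#' @param drug_on_s Drug application time, seconds.
#' @return A `wash_series` data frame with a `drug_on_s` attribute.
#' @export
wash_series <- function(time_s, amplitude_pA, drug_on_s) {
  if (length(time_s) != length(amplitude_pA))
    abort_config("time and amplitude must have equal length")
  structure(data.frame(time_s = time_s, amplitude_pA = amplitude_pA),
            class = c("wash_series", "data.frame"), drug_on_s = drug_on_s)
}

#' Drug-wash effect: first-5-min vs last-5-min amplitude windows
#'
#' Mean peak amplitude over the first `window_s` of the recording (before
#' drug application) and over the last `window_s`, plus the percent change
#' `100 * (post - pre) / pre`.
#'
#' @param series A `wash_series`.
#' @param window_s Window length, seconds (default 300 = 5 min).
#' @param min_samples Minimum sweeps required in each window.
#' @return A list: `pre_mean`, `post_mean`, `percent_change`.
#' @export
wash_effect <- function(series, window_s = 300, min_samples = 3) {
  stopifnot(inherits(series, "wash_series"))
  t_end <- max(series$time_s)
  pre <- series$amplitude_pA[series$time_s < min(series$time_s) + window_s]
  post <- series$amplitude_pA[series$time_s > t_end - window_s]
  if (length(pre) < min_samples || length(post) < min_samples)
    stop("insufficient samples: need >= ", min_samples,
         " amplitudes in each 5-min window", call. = FALSE)
  pre_mean <- mean(pre); post_mean <- mean(post)
  list(pre_mean = pre_mean, post_mean = post_mean,
       percent_change = 100 * (post_mean - pre_mean) / pre_mean)
}

#' Evoked-spike change ratio
#'
#' Post-wash evoked spiking normalized to the baseline recording:
#' `mean(post) / mean(baseline)`.
#'
#' @param baseline_counts,post_counts Per-sweep evoked spike counts in the
#'   baseline and post-wash phases (non-negative).
#' @return The ratio (1 = unchanged; < 0.5 = more than a 50% reduction).
#' @export
spike_change_ratio <- function(baseline_counts, post_counts) {
  if (any(baseline_counts < 0) || any(post_counts < 0))
    abort_config("spike counts must be >= 0")
  b <- mean(baseline_counts)
  if (!is.finite(b) || b <= 0)
    stop("cannot normalize: baseline mean spike count is zero", call. = FALSE)
  mean(post_counts) / b
}
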