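#' Band-pass filter specification
#'
#' Butterworth IIR band-pass design. The default — order 10 (a 5th-order
#' low-pass prototype transformed to band-pass), 2-20 Hz — passes every
#' clinically relevant tremor band (rest 4-6 Hz, postural 4-12 Hz, kinetic
#' 2-7 Hz) while the 2 Hz edge removes DC, gravity offset and slow drift
#' and the 20 Hz edge removes broadband sensor noise. `zero_phase = TRUE`
#' (the default) applies the filter forward and backward so in-band
#' components keep their phase — features are computed offline, and phase
#' distortion would bias the regularity features — at the cost of doubling
#' the stop-band attenuation; set it to `FALSE` for a single causal pass.
#'
#' @param order Total filter order (must be even; realized from an
#'   order/2 low-pass prototype).
#' @param low_cut_hz,high_cut_hz Band edges (Hz), `0 < low < high < fs/2`.
#' @param zero_phase Forward-backward application?
#' @return A `pd_filter_spec` list.
#' @export
filter_spec <- function(order = 10, low_cut_hz = 2, high_cut_hz = 20,
                        zero_phase = TRUE) {
  if (order < 2 || order %% 2 != 0)
    abort_invalid("`order` must be a positive even integer.")
  if (!(low_cut_hz > 0 && high_cut_hz > low_cut_hz))
    abort_invalid("need 0 < low_cut_hz < high_cut_hz.")
  structure(list(order = order, low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz, zero_phase = isTRUE(zero_phase)),
            class = "pd_filter_spec")
}

# Design the Butterworth band-pass for a given sampling rate; errors if the
# band does not fit under Nyquist or the realized transfer function is
# numerically unstable at this fs.
butter_design <- function(spec, fs) {
  if (spec$high_cut_hz >= fs / 2)
    abort_invalid(sprintf("high_cut_hz (%g) must be below Nyquist (%g).",
                          spec$high_cut_hz, fs / 2))
  ba <- signal::butter(spec$order / 2,
                       c(spec$low_cut_hz, spec$high_cut_hz) / (fs / 2),
                       type = "pass")
  poles <- polyroot(rev(ba$a))
  if (max(Mod(poles)) >= 1)
    abort("unstable filter design at this sampling rate; widen the band or lower the order.",
          class = "pdmotor_numerical_design_error")
  ba
}

#' Filter magnitude response
#'
#' Exact magnitude of the designed single-pass transfer function at given
#' frequencies (the Butterworth design puts 1/sqrt(2) at both cut-offs).
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate (Hz).
#' @param f Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of |H(f)| for one filter pass.
#' @export
filter_magnitude <- function(spec, fs, f) {
  ba <- butter_design(spec, fs)
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    Mod(sum(ba$b * z^(seq_along(ba$b) - 1)) /
          sum(ba$a * z^(seq_along(ba$a) - 1)))
  }, numeric(1))
}

#' Hampel outlier removal
#'
#' Replaces samples that deviate from the centered rolling median by more
#' than `n_mad` scaled median absolute deviations (scale factor 1.4826,
#' consistent for Gaussian noise) with that rolling median. Windows are
#' truncated at the sequence edges. Output length equals input length.
#'
#' @param x Numeric vector.
#' @param window Odd window length (samples), >= 3.
#' @param n_mad Rejection threshold in scaled MADs.
#' @return Numeric vector with outliers replaced.
#' @examples
#' x <- c(rep(1, 10), 100, rep(1, 10))
#' remove_outliers(x)[11]
#' @export
remove_outliers <- function(x, window = 11, n_mad = 3) {
  if (window < 3 || window %% 2 == 0)
    abort_invalid("`window` must be an odd integer >= 3.")
  if (length(x) < window)
    abort_invalid("sequence shorter than the window.")
  .hampel_cpp(as.numeric(x), as.integer(window), n_mad)
}

#' Zero-phase (or causal) Butterworth band-pass
#'
#' Applies the [filter_spec()] design to a sequence. Zero-phase mode runs
#' the filter forward and backward over the signal extended by odd
#' reflection at both ends (pad length `min(n - 1, 1000)` samples), which
#' suppresses the start-up transient that a plain forward-backward pass
#' would leave; the padding is discarded, so output length equals input
#' length.
#'
#' @inheritParams remove_outliers
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  n <- length(x)
  if (n <= 3 * spec$order)
    abort_invalid(sprintf(
      "sequence length %d too short for an order-%d filter (need > %d).",
      n, spec$order, 3 * spec$order))
  ba <- butter_design(spec, fs)
  if (!spec$zero_phase)
    return(as.numeric(signal::filter(ba, x)))
  pad <- min(n - 1L, 1000L)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filter(ba, xe))
  y <- rev(as.numeric(signal::filter(ba, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Preprocess a recording or a cohort
#'
#' Cleans each of the six channels exactly once, in the order outlier
#' removal (Hampel) then band-pass filtering; drift and DC are removed
#' implicitly by the 2 Hz high-pass edge. Metadata and timestamps are
#' preserved.
#'
#' @param rec A `pd_recording`.
#' @param spec A [filter_spec()].
#' @param window,n_mad Hampel parameters, see [remove_outliers()].
#' @return A `pd_recording` (or `pd_cohort`) of identical shape.
#' @export
preprocess_recording <- function(rec, spec = filter_spec(), window = 11,
                                 n_mad = 3) {
  if (!inherits(rec, "pd_recording"))
    abort_invalid("`rec` must be a `pd_recording`.")
  fs <- attr(rec, "sampling_rate_hz")
  out <- tibble::as_tibble(rec)
  for (ch in CHANNELS)
    out[[ch]] <- bandpass(remove_outliers(out[[ch]], window, n_mad), fs, spec)
  m <- recording_meta(rec)
  new_recording(out, m$subject_id, m$class_label, m$task, m$sampling_rate_hz)
}

#' @rdname preprocess_recording
#' @param cohort A `pd_cohort`.
#' @export
preprocess_cohort <- function(cohort, spec = filter_spec(), window = 11,
                              n_mad = 3) {
  cohort$data <- purrr::map(cohort$data, preprocess_recording,
                            spec = spec, window = window, n_mad = n_mad)
  cohort
}
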