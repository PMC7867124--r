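#' Linear time-domain features
#'
#' The six linear descriptive statistics of a channel: arithmetic mean,
#' sample SD (n-1), root mean square, kurtosis, skewness and peak value
#' (max absolute amplitude, an impulsiveness metric). Kurtosis is reported
#' in the Pearson convention (a Gaussian scores 3, not 0); skewness is the
#' standardized third moment. For a constant input these two are undefined:
#' they are returned as `NA` with a warning while the other four remain
#' valid (partial-result contract).
#'
#' @param x Numeric vector, length >= 4.
#' @return A named list: `mean`, `sd`, `rms`, `kurtosis`, `skewness`,
#'   `peak_value`.
#' @examples
#' linear_time_features(sin(seq(0, 10, by = 0.01)))
#' @export
linear_time_features <- function(x) {
  if (length(x) < 4) abort_invalid("need at least 4 samples.")
  s <- sd(x)
  if (s == 0) {
    warn("constant input: kurtosis and skewness are undefined, returned as NA.",
         class = "pdmotor_partial_result")
    kur <- NA_real_
    ske <- NA_real_
  } else {
    kur <- e1071::kurtosis(x, type = 1) + 3  # Pearson: Gaussian -> 3
    ske <- e1071::skewness(x, type = 1)
  }
  list(mean = mean(x), sd = s, rms = sqrt(mean(x^2)),
       kurtosis = kur, skewness = ske, peak_value = max(abs(x)))
}

#' Approximate entropy (ApEn)
#'
#' Pincus approximate entropy: `ApEn = Phi_m(r) - Phi_{m+1}(r)` where
#' `Phi_m(r)` is the mean over templates of the log fraction of length-`m`
#' templates within Chebyshev distance `r` (self-matches included, natural
#' log). Low values mean a regular, predictable signal (pure tremor tone);
#' high values mean irregularity. Defaults follow the standard convention
#' `m = 2` and tolerance 0.2 x SD(x).
#'
#' @param x Numeric vector, length >= 50.
#' @param m Template length, >= 1.
#' @param r Match tolerance (same units as `x`); default `0.2 * sd(x)`.
#' @return A single non-negative number (up to numerical tolerance).
#' @examples
#' approximate_entropy(rep(c(0, 1), 50))         # periodic: ~0
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (length(x) < 50) abort_invalid("need at least 50 samples for ApEn.")
  if (m < 1) abort_invalid("`m` must be >= 1.")
  if (!is.finite(r) || r <= 0) abort_invalid("`r` must be positive.")
  .apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Grassberger-Procaccia correlation dimension
#'
#' Delay-embeds the series, computes correlation sums C(r) on a log-spaced
#' radius grid spanning the configured scaling region (by default radii
#' between the 10th and 50th percentile of pairwise embedded distances) and
#' returns the least-squares slope of log C(r) vs log r. The estimate is
#' invariant to positive rescaling of the input. A pure sinusoid (a limit
#' cycle) scores ~1; noise filling the embedding space scores ~ the
#' embedding dimension.
#'
#' @param x Numeric vector; at least 200 points must remain after
#'   embedding.
#' @param emb_dim Embedding dimension, >= 2.
#' @param delay Embedding delay in samples; `NULL` picks the first
#'   non-positive lag of the autocorrelation (fallback 10).
#' @param scaling_quantiles Two probabilities bounding the scaling region
#'   on the pairwise-distance distribution.
#' @param n_radii Number of log-spaced radii.
#' @return The correlation-dimension estimate (slope).
#' @export
correlation_dimension <- function(x, emb_dim = 10, delay = NULL,
                                  scaling_quantiles = c(0.10, 0.50),
                                  n_radii = 12) {
  if (emb_dim < 2) abort_invalid("`emb_dim` must be >= 2.")
  if (sd(x) == 0) abort_invalid("constant input: correlation dimension undefined.")
  if (is.null(delay)) delay <- default_delay(x)
  if (delay < 1) abort_invalid("`delay` must be >= 1.")
  np <- length(x) - (emb_dim - 1) * delay
  if (np < 200)
    abort_invalid(sprintf(
      "only %d embedded points (need >= 200); sequence too short for emb_dim = %d, delay = %d.",
      np, emb_dim, delay))
  d <- .embed_dist_sample_cpp(as.numeric(x), as.integer(emb_dim),
                              as.integer(delay), 20000L)
  q <- quantile(d[d > 0], scaling_quantiles, names = FALSE)
  if (!all(is.finite(q)) || q[1] <= 0 || q[2] <= q[1])
    abort_invalid("empty scaling region: degenerate pairwise-distance distribution.")
  radii <- exp(seq(log(q[1]), log(q[2]), length.out = n_radii))
  cs <- .corr_sums_cpp(as.numeric(x), as.integer(emb_dim),
                       as.integer(delay), radii)
  keep <- cs > 0
  if (sum(keep) < 2)
    abort_invalid("empty scaling region: correlation sums vanish on the radius grid.")
  unname(coef(lm(log(cs[keep]) ~ log(radii[keep])))[2])
}

# First non-positive autocorrelation lag, the usual embedding-delay
# heuristic; falls back to 10 samples when the ACF never crosses zero.
default_delay <- function(x, max_lag = min(length(x) - 1, 100)) {
  a <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  k <- which(a <= 0)
  if (length(k) == 0) 10L else as.integer(k[1])
}

#' Welch power spectral density
#'
#' Mean of Hamming-windowed modified periodograms over overlapping
#' segments; one-sided, normalized by the window power so the integrated
#' PSD approximates the signal variance (power per Hz).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param segment_length Segment length in samples (<= `length(x)`).
#' @param overlap_fraction Fractional overlap between segments, in [0, 1).
#' @return A `pd_spectral_estimate`: a tibble with columns `frequency`
#'   (0 to fs/2) and `psd`, plus the estimation settings as attributes.
#' @examples
#' est <- welch_psd(sin(2 * pi * 5 * seq(0, 10, by = 0.01)), fs = 100)
#' est$frequency[which.max(est$psd)]
#' @export
welch_psd <- function(x, fs, segment_length = 256, overlap_fraction = 0.5) {
  n <- length(x)
  if (segment_length > n)
    abort_invalid("`segment_length` exceeds the signal length.")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort_invalid("`overlap_fraction` must be in [0, 1).")
  L <- as.integer(segment_length)
  step <- max(1L, L - as.integer(floor(L * overlap_fraction)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- signal::hamming(L)
  U <- sum(w^2)
  nf <- L %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    X <- fft(x[s:(s + L - 1L)] * w)
    acc <- acc + (Mod(X[seq_len(nf)])^2) / (fs * U)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  est <- tibble::tibble(frequency = (seq_len(nf) - 1) * fs / L, psd = p * dbl)
  structure(est, class = c("pd_spectral_estimate", class(est)),
            segment_length = L, overlap_fraction = overlap_fraction,
            window = "hamming", fs = fs)
}

#' Spectral features of a PSD estimate
#'
#' Peak frequency and amplitude within a search band, and trapezoidal
#' band power over each configured band (PSD interpolated linearly at the
#' exact band edges, so a flat PSD of height c over a width-w band yields
#' exactly c*w).
#'
#' @param est A [welch_psd()] estimate.
#' @param bands Named list of `c(low, high)` bands (Hz).
#' @param search_band `c(low, high)` band (Hz) searched for the peak.
#' @return Named list: `peak_amplitude`, `peak_frequency`, then one
#'   `band_power_*` entry per band.
#' @export
spectral_features <- function(est,
                              bands = list(band_power_4_6 = c(4, 6)),
                              search_band = c(2, 20)) {
  f <- est$frequency
  p <- est$psd
  sel <- f >= search_band[1] & f <= search_band[2]
  if (!any(sel)) abort_invalid("empty search band.")
  i <- which(sel)[which.max(p[sel])]
  out <- list(peak_amplitude = p[i], peak_frequency = f[i])
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!(b[1] < b[2]) || b[1] < min(f) || b[2] > max(f))
      abort_invalid(sprintf("band '%s' empty or outside the estimate range.", nm))
    out[[nm]] <- band_power_trapz(f, p, b[1], b[2])
  }
  out
}

band_power_trapz <- function(f, p, lo, hi) {
  inside <- f > lo & f < hi
  fb <- c(lo, f[inside], hi)
  pb <- c(stats::approx(f, p, xout = lo)$y, p[inside],
          stats::approx(f, p, xout = hi)$y)
  sum(diff(fb) * (head(pb, -1) + pb[-1]) / 2)
}

#' Feature-extraction configuration
#'
#' Every tunable of the feature stage with its default: ApEn template
#' length/tolerance, correlation-dimension embedding, Welch segmentation,
#' and the spectral band set. The long O(n^2) kernels (ApEn, correlation
#' dimension) run on an evenly strided subsample of the channel
#' (`apen_max_n`, `cd_max_n` samples) — regularity contrasts survive
#' decimation while the cost drops by two orders of magnitude.
#'
#' @param apen_m,apen_r_factor ApEn template length and tolerance factor
#'   (tolerance = factor x SD).
#' @param apen_max_n Sample cap for ApEn.
#' @param cd_emb_dim,cd_delay Correlation-dimension embedding dimension and
#'   delay (`NULL` = autocorrelation heuristic).
#' @param cd_max_n Sample cap for the correlation dimension.
#' @param welch_segment,welch_overlap Welch segment length (samples) and
#'   overlap fraction; 256 samples at 100 Hz gives ~0.39 Hz resolution,
#'   enough to separate the 4-6 Hz rest-tremor band.
#' @param bands Named list of `c(low, high)` power bands; default the 4-6
#'   Hz Parkinsonian rest-tremor band.
#' @param search_band Peak-search band, default the 2-20 Hz passband.
#' @param magnitude Compute features on the 3-D magnitude signals
#'   (`amag = sqrt(ax^2+ay^2+az^2)`, likewise `gmag`) instead of per axis;
#'   22 features per subject instead of 66.
#' @return A `pd_feature_config` list.
#' @export
feature_config <- function(apen_m = 2, apen_r_factor = 0.2, apen_max_n = 1500,
                           cd_emb_dim = 6, cd_delay = NULL, cd_max_n = 1600,
                           welch_segment = 256, welch_overlap = 0.5,
                           bands = list(band_power_4_6 = c(4, 6)),
                           search_band = c(2, 20), magnitude = FALSE) {
  structure(list(apen_m = apen_m, apen_r_factor = apen_r_factor,
                 apen_max_n = apen_max_n, cd_emb_dim = cd_emb_dim,
                 cd_delay = cd_delay, cd_max_n = cd_max_n,
                 welch_segment = welch_segment, welch_overlap = welch_overlap,
                 bands = bands, search_band = search_band,
                 magnitude = isTRUE(magnitude)),
            class = "pd_feature_config")
}

strided_subsample <- function(x, max_n) {
  if (length(x) <= max_n) return(x)
  x[unique(round(seq(1, length(x), length.out = max_n)))]
}

channel_features <- function(x, fs, config) {
  lin <- linear_time_features(x)
  xs <- strided_subsample(x, config$apen_max_n)
  apen <- approximate_entropy(xs, m = config$apen_m,
                              r = config$apen_r_factor * sd(xs))
  xc <- strided_subsample(x, config$cd_max_n)
  cd <- correlation_dimension(xc, emb_dim = config$cd_emb_dim,
                              delay = config$cd_delay)
  est <- welch_psd(x, fs, config$welch_segment, config$welch_overlap)
  spec <- spectral_features(est, bands = config$bands,
                            search_band = config$search_band)
  c(lin, list(apen = apen, corr_dim = cd), spec)
}

#' Extract the per-subject feature vector
#'
#' Computes, per channel, the 6 linear temporal features, approximate
#' entropy, correlation dimension and the spectral features (peak
#' amplitude, peak frequency, one power per configured band) — 11 features
#' x 6 channels = 66 with the defaults. When a subject performed several
#' tasks, the (already preprocessed) per-task channels are concatenated
#' first, yielding one feature vector per subject. Feature names follow
#' `<channel>_<feature>` (e.g. `ax_apen`, `gz_band_power_4_6`) in a fixed
#' deterministic order. With `feature_config(magnitude = TRUE)` the six
#' axes are collapsed to the two 3-D magnitude signals first (22
#' features).
#'
#' @param recs A `pd_recording` or a list of them (one per task, same
#'   subject).
#' @param config A [feature_config()].
#' @return A named numeric vector.
#' @export
extract_feature_vector <- function(recs, config = feature_config()) {
  if (inherits(recs, "pd_recording")) recs <- list(recs)
  fs <- attr(recs[[1]], "sampling_rate_hz")
  signals <- if (isTRUE(config$magnitude)) {
    list(amag = unlist(lapply(recs, function(r)
           sqrt(r$ax^2 + r$ay^2 + r$az^2)), use.names = FALSE),
         gmag = unlist(lapply(recs, function(r)
           sqrt(r$gx^2 + r$gy^2 + r$gz^2)), use.names = FALSE))
  } else {
    setNames(lapply(CHANNELS, function(ch)
      unlist(lapply(recs, function(r) r[[ch]]), use.names = FALSE)),
      CHANNELS)
  }
  out <- list()
  for (ch in names(signals)) {
    fx <- channel_features(signals[[ch]], fs, config)
    names(fx) <- paste0(ch, "_", names(fx))
    out <- c(out, fx)
  }
  v <- unlist(out)
  if (anyNA(v))
    abort_invalid(sprintf("undefined feature value(s): %s.",
                          paste(names(v)[is.na(v)], collapse = ", ")))
  v
}

#' Build the cohort feature table
#'
#' One row per subject: `subject_id`, `class_label`, then the full feature
#' vector of [extract_feature_vector()] computed on the subject's
#' concatenated per-task channels. Any per-feature failure aborts that
#' subject with a diagnostic naming the subject.
#'
#' @param cohort A preprocessed `pd_cohort`.
#' @param config A [feature_config()].
#' @return A feature-table tibble (40 x 2+66 for the default study).
#' @export
build_feature_table <- function(cohort, config = feature_config()) {
  subjects <- unique(cohort$subject_id)
  rows <- purrr::map(subjects, function(sid) {
    idx <- which(cohort$subject_id == sid)
    v <- tryCatch(extract_feature_vector(cohort$data[idx], config),
                  error = function(e) abort_invalid(sprintf(
                    "feature extraction failed for subject %s: %s",
                    sid, conditionMessage(e))))
    tibble::tibble(subject_id = sid,
                   class_label = cohort$class_label[idx[1]], !!!as.list(v))
  })
  tbl <- dplyr::bind_rows(rows)
  check_feature_table(tbl)
  tbl
}
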