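test_that("linear time features match their closed forms", {
  expect_warning(f <- linear_time_features(c(1, 1, 1, 1)),
                 class = "pdmotor_partial_result")
  expect_equal(f$mean, 1)
  expect_equal(f$sd, 0)
  expect_equal(f$rms, 1)
  expect_equal(f$peak_value, 1)
  expect_true(is.na(f$kurtosis) && is.na(f$skewness))

  g <- linear_time_features(c(-2, 2, -2, 2))
  expect_equal(g$mean, 0)
  expect_equal(g$rms, 2)
  expect_equal(g$peak_value, 2)
  expect_equal(g$skewness, 0)

  expect_error(linear_time_features(c(1, 2)),
               class = "pdmotor_invalid_argument")
})

test_that("moment features are calibrated on Gaussian samples (Pearson kurtosis = 3)", {
  withr::local_seed(11)
  x <- rnorm(1e5)
  f <- linear_time_features(x)
  expect_equal(f$kurtosis, 3, tolerance = 0.1 / 3)
  expect_lt(abs(f$skewness), 0.05)
})

test_that("RMS, mean and SD satisfy the exact moment identity", {
  withr::local_seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1), mean = runif(1, -5, 5),
               sd = runif(1, 0.1, 3))
    n <- length(x)
    f <- linear_time_features(x)
    expect_equal(f$rms^2, f$mean^2 + (n - 1) / n * f$sd^2,
                 tolerance = 1e-9)
  }
})

test_that("ApEn vanishes for periodic signals and ranks noise above tones", {
  sq <- rep(c(0, 1), 100)
  expect_lt(approximate_entropy(sq, m = 2, r = 0.2 * sd(sq)), 0.01)

  withr::local_seed(13)
  t <- seq(0, 10, length.out = 500)
  tone <- sin(2 * pi * 2 * t)
  noise <- rnorm(500)
  noise <- noise / sd(noise) * sd(tone)
  expect_gt(approximate_entropy(noise, 2, 0.2 * sd(noise)),
            approximate_entropy(tone, 2, 0.2 * sd(tone)))

  expect_error(approximate_entropy(rnorm(20)),
               class = "pdmotor_invalid_argument")
})

test_that("ApEn equals the brute-force template-counting oracle", {
  withr::local_seed(14)
  x <- rnorm(100)
  expect_equal(approximate_entropy(x, m = 2, r = 0.25),
               apen_oracle(x, 2, 0.25), tolerance = 1e-10)
  y <- sin(seq(0, 20, length.out = 120)) + rnorm(120, 0, 0.2)
  expect_equal(approximate_entropy(y, m = 3, r = 0.4),
               apen_oracle(y, 3, 0.4), tolerance = 1e-10)
})

test_that("correlation sums match the all-pairs oracle and the slope behaves", {
  withr::local_seed(15)
  x <- rnorm(300)
  radii <- quantile(dist(cbind(x[1:299], x[2:300])), c(0.2, 0.35, 0.5),
                    names = FALSE)
  expect_equal(as.numeric(pdmotor:::.corr_sums_cpp(x, 2L, 1L, radii)),
               corr_sums_oracle(x, 2, 1, radii), tolerance = 1e-12)

  # limit cycle: dimension ~ 1
  t <- seq(0, 60, by = 0.02)
  tone <- sin(2 * pi * 1 * t)
  d_tone <- correlation_dimension(tone, emb_dim = 5, delay = 12)
  expect_gt(d_tone, 0.9)
  expect_lt(d_tone, 1.2)

  # space-filling noise in 2-D embedding: dimension ~ 2 (read off the
  # small-radius scaling region, where edge effects do not flatten C(r))
  u <- runif(1500)
  d_noise <- correlation_dimension(u, emb_dim = 2, delay = 1,
                                   scaling_quantiles = c(0.02, 0.2))
  expect_gt(d_noise, 1.7)
  expect_lt(d_noise, 2.1)
})

test_that("correlation dimension is scale invariant and rejects degenerate input", {
  withr::local_seed(16)
  x <- as.numeric(arima.sim(list(ar = 0.9), 800))
  expect_equal(correlation_dimension(3.7 * x, emb_dim = 4, delay = 2),
               correlation_dimension(x, emb_dim = 4, delay = 2),
               tolerance = 1e-9)
  expect_error(correlation_dimension(rep(1, 800)),
               class = "pdmotor_invalid_argument")
  expect_error(correlation_dimension(rnorm(100), emb_dim = 6),
               class = "pdmotor_invalid_argument")
})

test_that("Welch PSD localizes tones and conserves power", {
  fs <- 100
  t <- (0:5999) / fs
  est <- welch_psd(sin(2 * pi * 5 * t), fs)
  expect_true(all(est$psd >= 0))
  expect_equal(est$frequency[which.max(est$psd)], 5,
               tolerance = fs / 256 / 2 + 1e-9)

  expect_true(all(welch_psd(rep(0, 1000), fs)$psd == 0))

  withr::local_seed(17)
  x <- rnorm(6000, sd = 1.3)
  est <- welch_psd(x, fs)
  power <- sum(diff(est$frequency) * (head(est$psd, -1) + est$psd[-1]) / 2)
  expect_equal(power, var(x), tolerance = 0.1)

  expect_error(welch_psd(rnorm(100), fs, segment_length = 256),
               class = "pdmotor_invalid_argument")
})

test_that("spectral features read peaks and integrate bands correctly", {
  # delta-like peak at 5 Hz
  f <- seq(0, 50, by = 0.25)
  p <- numeric(length(f))
  p[f == 5] <- 10
  est <- tibble::tibble(frequency = f, psd = p)
  sf <- spectral_features(est, bands = list(band_power_4_6 = c(4, 6)))
  expect_equal(sf$peak_frequency, 5)
  expect_equal(sf$peak_amplitude, 10)

  # flat PSD: band power is height times width
  flat <- tibble::tibble(frequency = f, psd = rep(3, length(f)))
  sf2 <- spectral_features(flat, bands = list(band_power_4_6 = c(4, 6)))
  expect_equal(sf2$band_power_4_6, 6)

  # two tones: the larger wins the peak, the smaller still carries power
  p2 <- numeric(length(f))
  p2[f == 5] <- 10
  p2[f == 9] <- 4
  est2 <- tibble::tibble(frequency = f, psd = p2)
  sf3 <- spectral_features(est2, bands = list(band_power_8_12 = c(8, 12)))
  expect_equal(sf3$peak_frequency, 5)
  expect_gt(sf3$band_power_8_12, 0)

  expect_error(spectral_features(est, bands = list(bad = c(40, 60))),
               class = "pdmotor_invalid_argument")
})

test_that("feature vectors have the 66 canonical names and are deterministic", {
  co <- preprocess_cohort(generate_cohort(tiny_cohort_spec(seed = 18)))
  v <- extract_feature_vector(co$data[co$subject_id == co$subject_id[1]])
  expect_length(v, 66)
  expect_true(all(grepl("^(ax|ay|az|gx|gy|gz)_", names(v))))
  expect_equal(sum(grepl("_apen$", names(v))), 6)
  expect_equal(sum(grepl("_band_power_4_6$", names(v))), 6)
  v2 <- extract_feature_vector(co$data[co$subject_id == co$subject_id[1]])
  expect_identical(v, v2)
})

test_that("spectral features are invariant to a DC offset once preprocessed", {
  p <- motion_params("tremor", "rest", tremor_freq_hz = 5,
                     tremor_amp_g = 0.3, tremor_amp_dps = 30,
                     outlier_rate = 0)
  rec <- simulate_recording(p, fs = 100, duration = 20, seed = 19)
  shifted <- rec
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz"))
    shifted[[ch]] <- shifted[[ch]] + 5
  f1 <- extract_feature_vector(preprocess_recording(rec))
  f2 <- extract_feature_vector(preprocess_recording(shifted))
  spec_cols <- grepl("peak_amplitude|peak_frequency|band_power", names(f1))
  expect_equal(f1[spec_cols], f2[spec_cols], tolerance = 1e-6)
})

test_that("the cohort feature table aligns rows with subject labels", {
  co <- preprocess_cohort(generate_cohort(tiny_cohort_spec(seed = 20)))
  tbl <- build_feature_table(co)
  expect_equal(nrow(tbl), 6)
  expect_equal(ncol(tbl), 68)  # id + label + 66 features
  labs <- cohort_labels(co)
  expect_equal(tbl$class_label,
               labs$class_label[match(tbl$subject_id, labs$subject_id)])
})

test_that("magnitude mode collapses the axes to two 22-feature channels", {
  co <- preprocess_cohort(generate_cohort(tiny_cohort_spec(seed = 44)))
  recs <- co$data[co$subject_id == co$subject_id[1]]
  v <- extract_feature_vector(recs, feature_config(magnitude = TRUE))
  expect_length(v, 22)
  expect_true(all(grepl("^(amag|gmag)_", names(v))))
  # the magnitude channel is computed from the same filtered axes
  amag <- sqrt(recs[[1]]$ax^2 + recs[[1]]$ay^2 + recs[[1]]$az^2)
  expect_equal(unname(v["amag_peak_value"]),
               max(abs(c(amag, sqrt(recs[[2]]$ax^2 + recs[[2]]$ay^2 +
                                      recs[[2]]$az^2)))))
})
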