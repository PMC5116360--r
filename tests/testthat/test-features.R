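test_that("mean energy decay averages the residual fractions", {
  # residual fractions 0.5, 0.25, 0.125 after m = 1..3
  mp <- fake_mp(coefficients = sqrt(c(0.5, 0.25, 0.125)),
                bands = c("HF", "LF", "HF"),
                signal_energy = 1,
                residual_energy = c(1, 0.5, 0.25, 0.125))
  expect_equal(mean_energy_decay(mp, "total"), mean(c(0.5, 0.25, 0.125)))
})

test_that("band-restricted decay follows the band energy budget", {
  mp <- fake_mp(coefficients = c(2, 1), bands = c("HF", "LF"),
                signal_energy = 5)
  # LF budget 1 is untouched after iteration 1, gone after iteration 2
  expect_equal(mean_energy_decay(mp, "LF"), (1 + 0) / 2 / 5)
  expect_equal(mean_energy_decay(mp, "HF"), 0)
  expect_equal(mean_energy_decay(mp, "VLF"), 0)
})

test_that("a single dictionary atom decays to zero immediately", {
  d <- test_dict(64)
  g <- gabor_waveform(16, 32, pi * 6 / 16, 0.2, 64)
  fit <- mp_decompose(3 * g, d, M = 5)
  expect_lt(mean_energy_decay(fit, "total"), 1e-10)
})

test_that("decomposition entropy has its closed-form values", {
  one <- fake_mp(1.5, "HF")
  expect_equal(mp_entropy(one, "HF"), 0, tolerance = 1e-9)
  two <- fake_mp(c(2, 2), c("LF", "LF"))
  expect_equal(mp_entropy(two, "LF"), 1, tolerance = 1e-9)
  thirty <- fake_mp(rep(0.7, 30), rep("HF", 30))
  expect_equal(mp_entropy(thirty, "HF"), log2(30), tolerance = 1e-9)
  # global normalisation: band summation over globally normalised p_n
  mixed <- fake_mp(c(1, 1), c("LF", "HF"))
  expect_equal(mp_entropy(mixed, "LF"), 0.5) # -0.5 log2 0.5
})

test_that("frequency distribution counts atoms per band", {
  mp <- fake_mp(rep(1, 30), c(rep("LF", 12), rep("HF", 10), rep("none", 8)))
  expect_equal(freq_distribution(mp, "LF"), 0.4)
  expect_equal(freq_distribution(mp, "HF"), 1 / 3)
  all_hf <- fake_mp(rep(1, 10), rep("HF", 10))
  expect_equal(freq_distribution(all_hf, "HF"), 1)
  expect_equal(freq_distribution(all_hf, "LF"), 0)
})

test_that("Welch PSD matches a direct DFT periodogram oracle", {
  fs <- 4
  t <- (0:1023) / fs
  x <- sin(2 * pi * 0.25 * t)
  spec <- welch_psd(x, fs = fs)
  expect_equal(spec$frequency[which.max(spec$power)], 0.25)
  # single full-length rectangular frame reduces to the plain periodogram
  spec1 <- welch_psd(x, fs = fs, seg_len = 1024)
  X <- fft(x)
  oracle <- Mod(X[1:513])^2 / (fs * 1024)
  oracle[2:512] <- 2 * oracle[2:512]
  expect_equal(spec1$power, oracle, tolerance = 1e-10)
  expect_equal(welch_psd(rep(0, 512), fs = fs)$power, rep(0, 129))
  expect_error(welch_psd(rnorm(100), seg_len = 256), "exceeds")
})

test_that("Welch PSD is Parseval-consistent on white noise", {
  set.seed(10)
  fs <- 4
  tot <- replicate(50, {
    x <- rnorm(1024)
    spec <- welch_psd(x, fs = fs)
    sum(spec$power) * fs / 256
  })
  expect_lt(abs(mean(tot) - 1), 0.1)
})

test_that("a planted narrowband atom concentrates its band power", {
  d <- test_dict(1024)
  fs <- 4
  w_lf <- 2 * pi * 0.1 / fs # 0.1 Hz in angular per-sample units
  g <- gabor_waveform(256, 512, w_lf, 0.3, 1024)
  fit <- mp_decompose(g, d, M = 5, fs = fs)
  sub <- band_subsignal(fit, "LF")
  spec <- welch_psd(sub, fs = fs)
  lf <- sum(spec$power[spec$frequency >= 0.04 & spec$frequency < 0.15])
  expect_gt(lf, 0.9 * sum(spec$power))
  ps <- psd_features(fit)
  expect_gt(ps$psd_lf, 0)
  # no VLF content: the capped ratio policy keeps HF/VLF finite
  expect_true(is.finite(ps$psd_hf_vlf))
})

test_that("empty bands give zero subsignals and zero band power", {
  mp <- fake_mp(c(1, 2), c("HF", "HF"), n = 512,
                Phi = cbind(gabor_waveform(8, 100, pi / 2, 0, 512),
                            gabor_waveform(8, 300, pi / 2, 1, 512)))
  expect_equal(band_subsignal(mp, "LF"), rep(0, 512))
  ps <- psd_features(mp)
  expect_equal(ps$psd_vlf, 0)
  expect_equal(ps$psd_hf_vlf, 1e6) # capped: HF power over an empty VLF band
})

test_that("the 16-feature vector is complete, finite and scale-invariant", {
  d <- test_dict(1024)
  rr <- simulate_rr(chf_preset(), seed = 21)
  h <- preprocess_rr(rr, label = "CHF", subject_id = "chf21")
  fv <- hrv_features(h, d)
  expect_named(fv, c("subject_id", "label", feature_names()))
  expect_true(all(is.finite(as.numeric(fv[feature_names()]))))
  # determinism
  expect_identical(fv, hrv_features(h, d))
  # positive rescaling leaves every feature unchanged
  h2 <- h
  h2$values <- 7.3 * h$values
  fv2 <- hrv_features(h2, d)
  expect_equal(as.numeric(fv2[feature_names()]),
               as.numeric(fv[feature_names()]), tolerance = 1e-8)
  expect_error(hrv_features(rep(0, 1024), d), "zero signal")
})

test_that("cohort extraction matches per-segment extraction", {
  d <- test_dict(1024)
  cohort <- simulate_cohort(2, 1, seed = 6)
  tab <- extract_feature_table(cohort, dict = d)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$label, c("NSR", "NSR", "CHF"))
  h1 <- preprocess_rr(cohort$rr[[1]], label = cohort$label[1],
                      subject_id = cohort$subject_id[1])
  expect_equal(as.numeric(tab[1, feature_names()]),
               as.numeric(hrv_features(h1, d)[feature_names()]),
               tolerance = 1e-10)
})
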