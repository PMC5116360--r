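test_that("Gabor waveforms are unit norm with the expected shapes", {
  params <- list(c(4, 10, pi / 2, 0.5), c(32, 100, 0.3, -1),
                 c(128, 0, pi, 2), c(2, 127, pi / 2, 0))
  for (p in params) {
    g <- gabor_waveform(p[1], p[2], p[3], p[4], 128)
    expect_equal(sum(g^2), 1, tolerance = 1e-10)
  }
  # zero frequency, zero phase: a strictly positive Gaussian bump
  bump <- gabor_waveform(16, 64, 0, 0, 128)
  expect_true(all(bump > 0))
  expect_equal(which.max(bump), 65)
  # huge scale: indistinguishable from a pure cosine
  n <- 256
  g <- gabor_waveform(n * 1e6, n / 2, 2 * pi * 8 / n, 0, n)
  ref <- cos(2 * pi * 8 / n * ((0:(n - 1)) - n / 2))
  expect_gt(stats::cor(g, ref), 0.999)
  expect_error(gabor_waveform(8, 200, 1, 0, 128), "translation")
  expect_error(gabor_waveform(-1, 0, 1, 0, 128), "positive")
  # envelope times cos(pi/2) is numerically zero
  expect_error(gabor_waveform(16, 64, 0, pi / 2, 128), "degenerate")
})

test_that("the dyadic dictionary matches its closed-form grid census", {
  d <- test_dict(16)
  n_expected <- sum(sapply(1:4, function(j) (2 * 16 / 2^j) * (2^j + 1)))
  expect_equal(nrow(d$triples), n_expected)
  expect_equal(gabor_grid_size(16), n_expected)
  expect_gt(nrow(d$triples), 16) # overcomplete
  expect_equal(colSums(d$G^2), rep(1, ncol(d$G)), tolerance = 1e-10)
  expect_error(gabor_dictionary(4), "at least 8")
  expect_error(gabor_dictionary(24), "power of two")
})

test_that("a scaled dictionary atom is captured exactly in one iteration", {
  d <- test_dict(64)
  g <- gabor_waveform(8, 32, pi * 3 / 8, 1.1, 64) # on-grid (s, u, w)
  fit <- mp_decompose(5 * g, d, M = 3)
  expect_equal(abs(fit$coefficients[1]), 5, tolerance = 1e-8)
  expect_lt(fit$residual_energy[2], 1e-12)
})

test_that("residual energy is non-increasing and exactly bookkept", {
  d <- test_dict(64)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(64)
    fit <- mp_decompose(x, d, M = 10)
    expect_equal(fit$residual_energy[1], sum(x^2))
    expect_true(all(diff(fit$residual_energy) <= 1e-12))
    expect_equal(fit$signal_energy,
                 sum(fit$coefficients^2) + fit$residual_energy[11],
                 tolerance = 1e-6 * fit$signal_energy)
  }
})

test_that("each greedy selection attains the dictionary-wide best projection", {
  d <- test_dict(64)
  grid <- oracle_grid(64)
  set.seed(7)
  for (i in 1:3) {
    x <- rnorm(64)
    fit <- mp_decompose(x, d, M = 4)
    r <- x
    for (m in 1:4) {
      scores <- apply(grid, 1, function(p)
        oracle_triple_score(r, p["s"], p["u"], p["w"], 64))
      expect_equal(fit$coefficients[m]^2, max(scores),
                   tolerance = 1e-8 * max(scores))
      r <- r - fit$coefficients[m] * fit$Phi[, m]
    }
  }
})

test_that("the closed-form optimal phase matches numeric phase search", {
  set.seed(3)
  x <- rnorm(64)
  for (i in 1:15) {
    s <- sample(c(4, 8, 16, 32), 1)
    u <- sample(seq(0, 63, by = s / 2), 1)
    w <- pi * sample(1:(s - 1), 1) / s
    closed <- oracle_triple_score(x, s, u, w, 64)
    f <- function(phi) sum(x * gabor_waveform(s, u, w, phi, 64))^2
    num <- stats::optimize(f, c(-pi, pi), maximum = TRUE, tol = 1e-10)
    expect_equal(closed, num$objective, tolerance = 1e-6)
  }
})

test_that("planted noiseless signals are reconstructed to numerical accuracy", {
  d <- test_dict(256)
  atoms <- list(
    gabor_waveform(16, 64, pi * 3 / 16, 0.4, 256),
    gabor_waveform(64, 128, pi * 10 / 64, -1.2, 256),
    gabor_waveform(8, 200, pi * 2 / 8, 2.2, 256)
  )
  x <- planted_signal(atoms, c(4, -3, 2))
  fit <- mp_decompose(x, d, M = 20)
  rec <- mp_reconstruct(fit)
  expect_lt(sqrt(sum((x - rec)^2) / sum(x^2)), 1e-6)
  expect_true(all(diff(fit$residual_energy) <= 1e-12))
})

test_that("reconstruction bookkeeping holds for subsets", {
  d <- test_dict(64)
  set.seed(2)
  x <- rnorm(64)
  fit <- mp_decompose(x, d, M = 8)
  expect_equal(mp_reconstruct(fit, integer(0)), rep(0, 64))
  expect_equal(sum((x - mp_reconstruct(fit))^2), fit$residual_energy[9],
               tolerance = 1e-6 * fit$signal_energy)
  both <- mp_reconstruct(fit, 1:2)
  expect_equal(both, fit$Phi[, 1] * fit$coefficients[1] +
                 fit$Phi[, 2] * fit$coefficients[2])
  expect_error(mp_reconstruct(fit, 9), "out of range")
})

test_that("decomposition rejects invalid input", {
  d <- test_dict(64)
  expect_error(mp_decompose(rep(0, 64), d), "zero signal")
  expect_error(mp_decompose(rnorm(32), d), "length")
})

test_that("atom centre frequencies map to the standard HRV bands", {
  expect_equal(atom_band(c(0.25, 0.10, 0.02, 0.45, 0.001)),
               c("HF", "LF", "VLF", "none", "none"))
  expect_equal(atom_band(0.4), "HF")    # inclusive upper HF edge
  expect_equal(atom_band(0.04), "LF")   # half-open VLF/LF boundary
  # angular-frequency conversion: w = 2 pi f / fs
  expect_equal(atom_band(2 * pi * 0.25 / 4, fs = 4), "HF")
})

test_that("tidy and glance summarise a decomposition consistently", {
  d <- test_dict(64)
  set.seed(5)
  fit <- mp_decompose(rnorm(64), d, M = 6)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_equal(td$energy, fit$coefficients^2)
  gl <- glance(fit)
  expect_equal(gl$energy_explained,
               sum(fit$coefficients^2) / fit$signal_energy, tolerance = 1e-6)
  expect_s3_class(autoplot(fit), "ggplot")
})
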