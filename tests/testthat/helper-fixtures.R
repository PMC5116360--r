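# Shared fixtures built once per test run. Dictionaries are cached because
# the 1024-sample build takes a few seconds and several files need it.

.fixture_cache <- new.env(parent = emptyenv())

test_dict <- function(n) {
  key <- paste0("dict", n)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- gabor_dictionary(n)
  }
  .fixture_cache[[key]]
}

# default study cohort and its feature table (40 NSR + 29 CHF)
cohort_feature_table <- function(seed = 1) {
  key <- paste0("feat", seed)
  if (is.null(.fixture_cache[[key]])) {
    cohort <- simulate_cohort(40, 29, seed = seed)
    .fixture_cache[[key]] <- extract_feature_table(cohort,
                                                   dict = test_dict(1024))
  }
  .fixture_cache[[key]]
}

# a synthetic mp_fit with prescribed coefficients and bands, for testing the
# feature formulas in isolation from the decomposition
fake_mp <- function(coefficients, bands, signal_energy = NULL,
                    residual_energy = NULL, n = 64, fs = 4,
                    Phi = NULL) {
  M <- length(coefficients)
  if (is.null(signal_energy)) signal_energy <- sum(coefficients^2)
  if (is.null(residual_energy)) {
    residual_energy <- signal_energy - cumsum(c(0, coefficients^2))
  }
  if (is.null(Phi)) Phi <- matrix(0, n, M)
  hrvmp:::new_mp_fit(
    coefficients = coefficients,
    atoms = tibble::tibble(
      iteration = seq_len(M),
      s = rep(8, M), u = rep(0, M), w = rep(0.5, M),
      w_hz = rep(0.2, M), phi = rep(0, M),
      band = bands
    ),
    Phi = Phi,
    residual_energy = residual_energy,
    signal_energy = signal_energy,
    fs = fs
  )
}

# enumerate the documented dyadic (s, u, w) grid independently of
# gabor_dictionary(), for oracle scans
oracle_grid <- function(n) {
  out <- list()
  for (j in seq_len(as.integer(log2(n)))) {
    s <- 2^j
    for (u in seq(0, n - 1, by = s / 2)) {
      for (k in 0:s) {
        out[[length(out) + 1]] <- c(s = s, u = u, w = pi * k / s)
      }
    }
  }
  do.call(rbind, out)
}

# best squared projection of r onto the phase family of one (s, u, w)
# triple, from first principles: project onto the 2-dimensional span of the
# cosine- and sine-phase atoms via an explicit Gram solve
oracle_triple_score <- function(r, s, u, w, n) {
  gc <- gabor_waveform(s, u, w, 0, n)
  gs <- tryCatch(gabor_waveform(s, u, w, -pi / 2, n), error = function(e) NULL)
  a <- sum(r * gc)
  if (is.null(gs) || w < 1e-12 || abs(w - pi) < 1e-12) return(a^2)
  b <- sum(r * gs)
  G <- matrix(c(1, sum(gc * gs), sum(gc * gs), 1), 2)
  if (abs(det(G)) < 1e-10) return(a^2)
  drop(crossprod(c(a, b), solve(G, c(a, b))))
}
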