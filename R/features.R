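#' The 16 matching-pursuit HRV feature names, in canonical order
#'
#' Residual-energy decay `E_vlf, E_lf, E_hf, E_total`; Welch band powers per
#' unit signal energy `psd_vlf, psd_lf, psd_hf`, the ratio `psd_hf_vlf` and
#' the sum `psd_lf_hf`; decomposition entropies `H_lf, H_hf`; atom
#' centre-frequency distribution `D_lf, D_hf` and ratios `D_hf_vlf,
#' D_vlf_lf, D_lf_hf`.
#'
#' @return Character vector of length 16.
#' @export
feature_names <- function() {
  c("E_vlf", "E_lf", "E_hf", "E_total",
    "psd_vlf", "psd_lf", "psd_hf", "psd_hf_vlf", "psd_lf_hf",
    "H_lf", "H_hf",
    "D_lf", "D_hf", "D_hf_vlf", "D_vlf_lf", "D_lf_hf")
}

# ratio with the documented zero-denominator policy: denominators below eps
# are replaced by eps and the ratio capped, keeping every feature finite
safe_ratio <- function(num, den, eps = 1e-12, cap = 1e6) {
  min(num / max(den, eps), cap)
}

#' Mean residual-energy decay rate
#'
#' For `band = "total"`, the average over iterations of the residual energy
#' fraction \eqn{(1/M)\sum_{m=1}^M \|R^m\|^2 / \|x\|^2}: slow decay (large
#' values) indicates noise-like, noncoherent structure; fast decay indicates
#' a coherent signal captured by few atoms. For a specific band, the atoms
#' whose centre frequency falls in that band define a band energy budget
#' \eqn{B = \sum_{n \in band} c_n^2}; the band residual after `m` iterations
#' is `B` minus the band energy already extracted, and the feature is its
#' iteration average, again normalised by the signal energy.
#'
#' @param mp An `mp_fit`.
#' @param band `"total"`, `"VLF"`, `"LF"` or `"HF"`.
#' @return A non-negative scalar.
#' @export
mean_energy_decay <- function(mp, band = "total") {
  stopifnot(inherits(mp, "mp_fit"))
  if (mp$signal_energy <= 0) stop("signal energy must be positive")
  M <- mp$M
  if (band == "total") {
    return(mean(mp$residual_energy[-1]) / mp$signal_energy)
  }
  in_band <- mp$atoms$band == band
  e_n <- mp$coefficients^2 * in_band
  B <- sum(e_n)
  band_resid <- B - cumsum(e_n)
  mean(band_resid) / mp$signal_energy
}

#' Band-restricted reconstruction
#'
#' Rebuilds the part of the signal carried by atoms whose centre frequency
#' lies in one HRV band (the "subsignal" whose Welch spectrum yields the
#' band-power features). Returns the zero vector when no atom falls in the
#' band.
#'
#' @inheritParams mean_energy_decay
#' @param band `"VLF"`, `"LF"` or `"HF"`.
#' @return Numeric vector of the signal length.
#' @export
band_subsignal <- function(mp, band) {
  stopifnot(inherits(mp, "mp_fit"))
  mp_reconstruct(mp, which = which(mp$atoms$band == band))
}

#' Welch periodogram-averaging power spectral density
#'
#' Splits the signal into `K` overlapping frames of `seg_len` samples,
#' windows each (rectangular by default), and averages the per-frame
#' periodograms into a one-sided density scaled so that
#' \eqn{\sum_k S(f_k)\,\Delta f} approximates the signal's mean square
#' (Parseval-consistent).
#'
#' @param x Numeric vector, or a `uniform_hrv`.
#' @param fs Sampling rate in Hz (taken from `x` if it is a `uniform_hrv`).
#' @param seg_len Frame length (default 256; must not exceed `length(x)`).
#' @param overlap Fractional frame overlap in `[0, 1)` (default 0.5).
#' @param window `"rectangular"` or `"hamming"`.
#' @return A tibble with columns `frequency` (Hz, `0` to `fs/2`) and
#'   `power`, with attributes `fs`, `seg_len`, `overlap`, `window`.
#' @export
welch_psd <- function(x, fs = 4, seg_len = 256, overlap = 0.5,
                      window = c("rectangular", "hamming")) {
  if (inherits(x, "uniform_hrv")) {
    fs <- x$fs
    x <- x$values
  }
  window <- match.arg(window)
  n <- length(x)
  if (seg_len > n) stop("`seg_len` exceeds the signal length")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  win <- switch(window,
    rectangular = rep(1, seg_len),
    hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  )
  U <- sum(win^2)
  half <- floor(seg_len / 2)
  acc <- numeric(half + 1)
  for (s0 in starts) {
    frame <- x[seq(s0, s0 + seg_len - 1)] * win
    X <- stats::fft(frame)
    p2 <- Mod(X[seq_len(half + 1)])^2 / (fs * U) # two-sided density
    p2[2:half] <- 2 * p2[2:half]                 # fold negative frequencies
    acc <- acc + p2
  }
  out <- tibble::tibble(
    frequency = (0:half) * fs / seg_len,
    power = acc / length(starts)
  )
  attr(out, "fs") <- fs
  attr(out, "seg_len") <- seg_len
  attr(out, "overlap") <- overlap
  attr(out, "window") <- window
  out
}

# sum of PSD values over the bins of one band
band_power <- function(spec, band,
                       edges = c(vlf = 0.003, lf = 0.04, hf = 0.15, top = 0.4)) {
  sum(spec$power[atom_band(spec$frequency, edges = edges) == band])
}

#' Welch band-power features of a decomposition
#'
#' For each HRV band, reconstructs the band subsignal, takes its Welch PSD,
#' and sums the density over the bins inside that band. Absolute band powers
#' are stored per unit signal energy (mean square), making them invariant to
#' rescaling of the input; the ratio `HF/VLF` and the sum `HF + LF` are
#' formed from the band sums. A vanishing denominator in the ratio is
#' handled by the capped-ratio policy (see package vignette).
#'
#' @inheritParams mean_energy_decay
#' @param seg_len,overlap,window Passed to [welch_psd()].
#' @return Named list `psd_vlf`, `psd_lf`, `psd_hf`, `psd_hf_vlf`,
#'   `psd_lf_hf`.
#' @export
psd_features <- function(mp, seg_len = 256, overlap = 0.5,
                         window = "rectangular") {
  stopifnot(inherits(mp, "mp_fit"))
  ms <- mp$signal_energy / nrow(mp$Phi) # mean square of the input signal
  bp <- vapply(c("VLF", "LF", "HF"), function(b) {
    sub <- band_subsignal(mp, b)
    if (all(sub == 0)) return(0)
    band_power(welch_psd(sub, fs = mp$fs, seg_len = seg_len,
                         overlap = overlap, window = window), b)
  }, numeric(1))
  list(
    psd_vlf = bp[["VLF"]] / ms,
    psd_lf = bp[["LF"]] / ms,
    psd_hf = bp[["HF"]] / ms,
    psd_hf_vlf = safe_ratio(bp[["HF"]], bp[["VLF"]]),
    psd_lf_hf = (bp[["LF"]] + bp[["HF"]]) / ms
  )
}

#' Entropy of the matching-pursuit energy distribution over a band
#'
#' Each atom carries energy \eqn{E_n = c_n^2} (atoms are unit norm); with
#' \eqn{p_n = E_n / \sum_n E_n} taken over *all* atoms, the band entropy is
#' \eqn{H_w = -\sum_{n \in band} p_n \log_2 p_n} — the summation is
#' restricted to the band but the probabilities are globally normalised, so
#' a band holding a single dominant atom scores near zero while energy
#' spread over many band atoms scores high.
#'
#' @inheritParams band_subsignal
#' @param band `"VLF"`, `"LF"` or `"HF"`.
#' @return Entropy in bits, in `[0, log2(M)]`.
#' @export
mp_entropy <- function(mp, band) {
  stopifnot(inherits(mp, "mp_fit"))
  e_n <- mp$coefficients^2
  e_x <- sum(e_n)
  if (e_x <= 0) stop("decomposition carries no energy")
  p <- e_n / e_x
  sel <- mp$atoms$band == band & p > 0
  -sum(p[sel] * log2(p[sel]))
}

#' Fraction of atoms whose centre frequency falls in a band
#'
#' \eqn{D(band) = M_{cf}(band) / M} where \eqn{M_{cf}} counts the atoms in
#' the band and `M` is the total atom count (30 by default). Counts are of
#' atoms, not energy: many low-energy atoms in a band indicate noise-like
#' structure there.
#'
#' @inheritParams mp_entropy
#' @return A fraction in `[0, 1]`.
#' @export
freq_distribution <- function(mp, band) {
  stopifnot(inherits(mp, "mp_fit"))
  mean(mp$atoms$band == band)
}

#' Extract the 16 matching-pursuit HRV features from one segment
#'
#' Decomposes a preprocessed segment with [mp_decompose()] (unless an
#' `mp_fit` is supplied directly) and assembles the full feature vector in
#' the order of [feature_names()]. All 16 features are invariant to positive
#' rescaling of the input signal.
#'
#' @param x A `uniform_hrv` from [preprocess_rr()], a numeric vector, or an
#'   `mp_fit`.
#' @param dict A [gabor_dictionary()] matching the segment length (ignored
#'   when `x` is an `mp_fit`).
#' @param M Number of matching-pursuit atoms (default 30).
#' @param fs Sampling rate when `x` is a plain vector.
#' @return A one-row tibble: `subject_id`, `label`, then the 16 features.
#' @export
hrv_features <- function(x, dict = NULL, M = 30, fs = 4) {
  label <- NA_character_
  subject_id <- NA_character_
  if (inherits(x, "mp_fit")) {
    mp <- x
  } else {
    if (inherits(x, "uniform_hrv")) {
      label <- x$label
      subject_id <- x$subject_id
    }
    if (is.null(dict)) stop("`dict` is required unless `x` is an mp_fit")
    mp <- mp_decompose(x, dict, M = M, fs = fs)
  }
  features_from_mp(mp, subject_id = subject_id, label = label)
}

features_from_mp <- function(mp, subject_id = NA_character_,
                             label = NA_character_) {
  psd <- psd_features(mp)
  d_vlf <- freq_distribution(mp, "VLF")
  d_lf <- freq_distribution(mp, "LF")
  d_hf <- freq_distribution(mp, "HF")
  tibble::tibble(
    subject_id = subject_id,
    label = label,
    E_vlf = mean_energy_decay(mp, "VLF"),
    E_lf = mean_energy_decay(mp, "LF"),
    E_hf = mean_energy_decay(mp, "HF"),
    E_total = mean_energy_decay(mp, "total"),
    psd_vlf = psd$psd_vlf,
    psd_lf = psd$psd_lf,
    psd_hf = psd$psd_hf,
    psd_hf_vlf = psd$psd_hf_vlf,
    psd_lf_hf = psd$psd_lf_hf,
    H_lf = mp_entropy(mp, "LF"),
    H_hf = mp_entropy(mp, "HF"),
    D_lf = d_lf,
    D_hf = d_hf,
    D_hf_vlf = safe_ratio(d_hf, d_vlf),
    D_vlf_lf = safe_ratio(d_vlf, d_lf),
    D_lf_hf = safe_ratio(d_lf, d_hf)
  )
}

#' Feature table for a whole cohort
#'
#' Preprocesses every RR series in a cohort tibble, decomposes all segments
#' in one batched matching-pursuit pass, and stacks the per-segment feature
#' vectors into the `n x 16` table consumed by the classifier stages.
#'
#' @param cohort Tibble with columns `subject_id`, `label` and list-column
#'   `rr` (as from [simulate_cohort()] or [read_cohort()]).
#' @param dict Optional pre-built [gabor_dictionary()]; built once if `NULL`.
#' @param M Atoms per decomposition (default 30).
#' @param start,seg_length,n_out,lambda Passed to [preprocess_rr()].
#' @return A tibble: `subject_id`, `label`, then the 16 features.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(3, 3, seed = 1)
#' extract_feature_table(cohort)
#' }
#' @export
extract_feature_table <- function(cohort, dict = NULL, M = 30, start = 1,
                                  seg_length = 256, n_out = 1024,
                                  lambda = 500) {
  segs <- purrr::pmap(
    list(cohort$rr, cohort$subject_id, cohort$label),
    function(rr, id, lab) {
      preprocess_rr(rr, start = start, seg_length = seg_length, n_out = n_out,
                    lambda = lambda, label = lab, subject_id = id)
    }
  )
  if (is.null(dict)) dict <- gabor_dictionary(n_out)
  X <- vapply(segs, function(s) s$values, numeric(n_out))
  fits <- mp_decompose_batch(X, dict, M = M,
                             fs = vapply(segs, function(s) s$fs, numeric(1)))
  purrr::map2_dfr(fits, seq_along(fits), function(fit, i) {
    features_from_mp(fit, subject_id = cohort$subject_id[i],
                     label = cohort$label[i])
  })
}

#' Boxplots of a feature table by class
#'
#' Min-max scales the features and draws one panel per feature with a box
#' per class — the usual at-a-glance view of which features separate the
#' groups.
#'
#' @param table Feature table from [extract_feature_table()].
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(table) {
  long <- table |>
    minmax_scale() |>
    tidyr::pivot_longer(dplyr::all_of(feature_names()),
                        names_to = "feature", values_to = "value") |>
    dplyr::mutate(feature = factor(.data$feature, levels = feature_names()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, nrow = 4) +
    ggplot2::labs(x = NULL, y = "min-max scaled value") +
    ggplot2::theme_minimal()
}
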