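#' Parameter set for the synthetic RR-interval generator
#'
#' Describes one synthetic subject: a mean RR interval modulated by three
#' sinusoids at fixed VLF/LF/HF frequencies plus white and 1/f-coloured
#' noise. Fixing the modulation frequencies makes the spectral ground truth
#' of generated series analytically known, which is what the test-bench
#' needs from a generator.
#'
#' @param mean_rr Mean RR interval in ms (> 0).
#' @param vlf_amp,lf_amp,hf_amp Amplitudes (ms) of the sinusoidal
#'   modulations at `vlf_freq`, `lf_freq`, `hf_freq`.
#' @param noise_sd White Gaussian noise SD in ms.
#' @param one_over_f_sd SD (ms) of a 1/f-coloured noise component.
#' @param n_beats Number of beats (>= 256).
#' @param vlf_freq,lf_freq,hf_freq Modulation frequencies in Hz, inside
#'   (0, 0.5).
#' @param clip Physiological clipping bounds in ms.
#' @param sdnn Nominal overall RR SD in ms; if `NULL`, the analytic value
#'   `sqrt(sum(amp^2)/2 + noise_sd^2 + one_over_f_sd^2)` is recorded.
#' @return A list of class `rr_gen_params`.
#' @seealso [nsr_preset()], [chf_preset()], [simulate_rr()]
#' @export
rr_gen_params <- function(mean_rr = 800, vlf_amp = 0, lf_amp = 0, hf_amp = 0,
                          noise_sd = 0, one_over_f_sd = 0, n_beats = 256,
                          vlf_freq = 0.01, lf_freq = 0.1, hf_freq = 0.25,
                          clip = c(200, 2500), sdnn = NULL) {
  if (mean_rr <= 0) stop("`mean_rr` must be positive")
  if (n_beats < 256) stop("`n_beats` must be at least 256")
  amps <- c(vlf_amp, lf_amp, hf_amp, noise_sd, one_over_f_sd)
  if (any(amps < 0)) stop("amplitudes and noise SDs must be non-negative")
  freqs <- c(vlf_freq, lf_freq, hf_freq)
  if (any(freqs <= 0 | freqs >= 0.5)) stop("frequencies must lie in (0, 0.5) Hz")
  if (is.null(sdnn)) {
    sdnn <- sqrt(sum(c(vlf_amp, lf_amp, hf_amp)^2) / 2 +
                   noise_sd^2 + one_over_f_sd^2)
  }
  structure(
    list(
      mean_rr = mean_rr, sdnn = sdnn,
      vlf_amp = vlf_amp, lf_amp = lf_amp, hf_amp = hf_amp,
      noise_sd = noise_sd, one_over_f_sd = one_over_f_sd,
      n_beats = as.integer(n_beats),
      vlf_freq = vlf_freq, lf_freq = lf_freq, hf_freq = hf_freq,
      clip = clip
    ),
    class = "rr_gen_params"
  )
}

#' Normal-sinus-rhythm-like generator preset
#'
#' High overall variability with a clear HF (respiratory-like) oscillation
#' and substantial broadband white and 1/f noise, so that matching pursuit
#' needs many noncoherent atoms and the residual energy decays slowly. The
#' VLF modulation sits at 0.035 Hz, near the upper edge of the VLF band,
#' where the smoothness-priors detrender still passes it.
#'
#' @return An [rr_gen_params()] object.
#' @export
nsr_preset <- function() {
  rr_gen_params(
    mean_rr = 900, vlf_amp = 3, lf_amp = 20, hf_amp = 25,
    noise_sd = 28, one_over_f_sd = 32, n_beats = 256,
    vlf_freq = 0.035
  )
}

#' Congestive-heart-failure-like generator preset
#'
#' Reduced overall variability with HF power strongly suppressed and the
#' remaining energy concentrated in coherent VLF/LF oscillations, which
#' matching pursuit captures with few atoms (fast residual decay).
#'
#' @return An [rr_gen_params()] object.
#' @export
chf_preset <- function() {
  rr_gen_params(
    mean_rr = 700, vlf_amp = 35, lf_amp = 10, hf_amp = 1.5,
    noise_sd = 4, one_over_f_sd = 2, n_beats = 256,
    vlf_freq = 0.035
  )
}

# 1/f-coloured Gaussian noise of unit SD via spectral shaping
one_over_f_noise <- function(n) {
  half <- floor(n / 2)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # symmetric frequency index
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))
  z <- stats::rnorm(n) + 1i * stats::rnorm(n)
  x <- Re(stats::fft(amp * z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

#' Simulate one synthetic RR-interval series
#'
#' Interval `k` is `mean_rr` plus the three sinusoidal modulations evaluated
#' at the cumulative beat time (built iteratively, since the beat times
#' depend on the intervals themselves) plus white and 1/f noise, clipped to
#' the physiological bounds in `params$clip`. Each realisation draws random
#' phases for the three modulations. Deterministic for a fixed seed.
#'
#' @param params An [rr_gen_params()] object.
#' @param seed Integer seed.
#' @return Numeric vector of `n_beats` RR intervals in ms, with attributes
#'   `label = "unknown"` retained out of band by the cohort generator.
#' @export
simulate_rr <- function(params, seed = 1) {
  stopifnot(inherits(params, "rr_gen_params"))
  set.seed(seed)
  n <- params$n_beats
  phases <- stats::runif(3, 0, 2 * pi)
  white <- stats::rnorm(n, 0, params$noise_sd)
  pink <- params$one_over_f_sd * one_over_f_noise(n)
  rr <- numeric(n)
  t_prev <- 0 # seconds
  for (k in seq_len(n)) {
    mod <- params$vlf_amp * sin(2 * pi * params$vlf_freq * t_prev + phases[1]) +
      params$lf_amp * sin(2 * pi * params$lf_freq * t_prev + phases[2]) +
      params$hf_amp * sin(2 * pi * params$hf_freq * t_prev + phases[3])
    val <- params$mean_rr + mod + white[k] + pink[k]
    rr[k] <- min(max(val, params$clip[1]), params$clip[2])
    t_prev <- t_prev + rr[k] / 1000
  }
  rr
}

#' Superpose Gabor atoms with optional noise
#'
#' Builds \eqn{\sum_i c_i \phi_i(t)} from explicit atom waveforms (all of the
#' same length, typically from [gabor_waveform()]) plus white Gaussian noise.
#' With `noise_sd = 0` this is an exact linear combination — the planted
#' ground truth used to validate the matching-pursuit recovery.
#'
#' @param atoms List of equal-length numeric waveforms.
#' @param coefficients Numeric vector, one per atom.
#' @param noise_sd White noise SD.
#' @param n Signal length; required when `atoms` is empty.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Numeric vector of length `n`.
#' @export
planted_signal <- function(atoms, coefficients, noise_sd = 0, n = NULL,
                           seed = 1) {
  if (length(atoms) != length(coefficients)) {
    stop("`atoms` and `coefficients` must have the same length")
  }
  if (length(atoms) > 0) {
    lens <- vapply(atoms, length, integer(1))
    if (length(unique(lens)) != 1) stop("atoms must all have the same length")
    if (!is.null(n) && n != lens[1]) stop("`n` does not match atom length")
    n <- lens[1]
    x <- Reduce(`+`, Map(`*`, atoms, coefficients))
  } else {
    if (is.null(n)) stop("`n` is required when no atoms are given")
    x <- numeric(n)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  x
}

#' Simulate a labelled two-class study cohort
#'
#' Generates `n_nsr` subjects from [nsr_preset()] and `n_chf` from
#' [chf_preset()], with independent per-subject uniform jitter (default
#' +/-10%) applied to the mean RR and all modulation amplitudes, mirroring
#' the 40-versus-29-subject design the classifier stages assume.
#'
#' @param n_nsr,n_chf Subject counts per class (default 40 and 29).
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @param jitter Fractional per-subject jitter on `mean_rr` and amplitudes.
#' @return A tibble with one row per subject: `subject_id`, `label`
#'   (`"NSR"`/`"CHF"`), `seed`, and a list-column `rr` of interval vectors.
#' @examples
#' cohort <- simulate_cohort(3, 2, seed = 7)
#' cohort
#' @export
simulate_cohort <- function(n_nsr = 40, n_chf = 29, seed = 1, jitter = 0.1) {
  stopifnot(n_nsr >= 1, n_chf >= 1)
  set.seed(seed)
  specs <- c(
    replicate(n_nsr, nsr_preset(), simplify = FALSE),
    replicate(n_chf, chf_preset(), simplify = FALSE)
  )
  labels <- c(rep("NSR", n_nsr), rep("CHF", n_chf))
  sub_seeds <- sample.int(.Machine$integer.max, length(specs))
  rr <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    p <- specs[[i]]
    jf <- stats::runif(4, 1 - jitter, 1 + jitter)
    pj <- rr_gen_params(
      mean_rr = p$mean_rr * jf[1],
      vlf_amp = p$vlf_amp * jf[2],
      lf_amp = p$lf_amp * jf[3],
      hf_amp = p$hf_amp * jf[4],
      noise_sd = p$noise_sd, one_over_f_sd = p$one_over_f_sd,
      n_beats = p$n_beats,
      vlf_freq = p$vlf_freq, lf_freq = p$lf_freq, hf_freq = p$hf_freq
    )
    rr[[i]] <- simulate_rr(pj, seed = sub_seeds[i])
  }
  tibble::tibble(
    subject_id = sprintf("%s%02d", tolower(labels),
                         c(seq_len(n_nsr), seq_len(n_chf))),
    label = labels,
    seed = sub_seeds,
    rr = rr
  )
}

#' Write a cohort as RR text files plus a manifest
#'
#' Each subject's intervals are written one per line in ms; the manifest CSV
#' records filename, label and seed.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, paste0(cohort$subject_id, ".rr.txt"))
  purrr::walk2(cohort$rr, files,
               ~ writeLines(formatC(.x, format = "g", digits = 15), .y))
  manifest <- tibble::tibble(
    file = basename(files),
    subject_id = cohort$subject_id,
    label = cohort$label,
    seed = cohort$seed
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and RR text files.
#' @return A cohort tibble with `subject_id`, `label`, `seed` and `rr`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  rr <- lapply(file.path(dir, manifest$file),
               function(f) as.numeric(readLines(f)))
  tibble::tibble(
    subject_id = manifest$subject_id,
    label = manifest$label,
    seed = manifest$seed,
    rr = rr
  )
}
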