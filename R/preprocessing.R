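#' Extract a contiguous 256-beat segment from an RR series
#'
#' @param rr Numeric vector of RR intervals in ms.
#' @param start 1-based index of the first beat (default 1).
#' @param length Segment length in beats (default 256).
#' @return Numeric vector of `length` intervals.
#' @export
rr_segment <- function(rr, start = 1, length = 256) {
  if (start < 1 || start + length - 1 > base::length(rr)) {
    stop("segment [", start, ", ", start + length - 1,
         "] is out of range for a series of ", base::length(rr), " beats")
  }
  rr[seq(start, start + length - 1)]
}

#' Resample an RR segment to an evenly spaced HRV signal
#'
#' The tachogram points `(t_k, RR_k)` with `t_k = cumsum(RR)/1000` seconds
#' are interpolated with a natural cubic spline and evaluated on `n_out`
#' equally spaced points spanning `[0, sum(RR)/1000]`. The nominal design is
#' 4 Hz x 256 beats -> 1024 samples; since the actual segment duration
#' depends on heart rate, `n_out` is held fixed and the effective sampling
#' rate `fs = (n_out - 1) / duration` is recorded and used for all band
#' arithmetic downstream.
#'
#' @param rr Numeric vector of RR intervals in ms (at least 4 beats, all
#'   positive).
#' @param n_out Number of output samples (default 1024).
#' @param label,subject_id Optional metadata carried along.
#' @return An object of class `uniform_hrv`: `values` (ms), `n`, `fs` (Hz),
#'   `duration` (s), `label`, `subject_id`, `detrended = FALSE`.
#' @export
rr_resample <- function(rr, n_out = 1024, label = NA_character_,
                        subject_id = NA_character_) {
  if (length(rr) < 4) stop("cubic-spline resampling needs at least 4 beats")
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be positive and finite")
  }
  t_beat <- cumsum(rr) / 1000
  duration <- t_beat[length(t_beat)]
  grid <- seq(0, duration, length.out = n_out)
  values <- stats::spline(t_beat, rr, xout = grid, method = "natural")$y
  new_uniform_hrv(values, fs = (n_out - 1) / duration, duration = duration,
                  label = label, subject_id = subject_id, detrended = FALSE)
}

new_uniform_hrv <- function(values, fs, duration, label = NA_character_,
                            subject_id = NA_character_, detrended = FALSE) {
  structure(
    list(values = values, n = length(values), fs = fs, duration = duration,
         label = label, subject_id = subject_id, detrended = detrended),
    class = "uniform_hrv"
  )
}

#' @export
print.uniform_hrv <- function(x, ...) {
  cat(
    "Uniformly sampled HRV segment\n",
    "  n: ", x$n, " samples, fs: ", signif(x$fs, 5), " Hz, duration: ",
    signif(x$duration, 5), " s\n",
    "  detrended: ", x$detrended,
    if (!is.na(x$label)) paste0(", label: ", x$label) else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Smoothness-priors detrending
#'
#' Removes the low-frequency trend
#' \eqn{\hat z = (I + \lambda^2 D_2^\top D_2)^{-1} x}, where \eqn{D_2} is the
#' second-difference operator — a regularised least-squares smoother that
#' acts like a time-varying high-pass FIR filter on the HRV signal. The
#' returned signal is `x - trend` with its mean subtracted, so it is exactly
#' zero-mean. `lambda = 500` at ~4 Hz places the effective cutoff near the
#' lower edge of the VLF band.
#'
#' @param x A `uniform_hrv` from [rr_resample()], or a plain numeric vector.
#' @param lambda Smoothing parameter (> 0).
#' @return Same type as `x`, detrended and zero-mean.
#' @export
detrend_sp <- function(x, lambda = 500) {
  if (lambda <= 0) stop("`lambda` must be positive")
  v <- if (inherits(x, "uniform_hrv")) x$values else x
  if (any(!is.finite(v))) stop("input contains non-finite values")
  n <- length(v)
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2),
                                            rep(-2, n - 2),
                                            rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
  trend <- as.numeric(Matrix::solve(A, v))
  out <- v - trend
  out <- out - mean(out)
  if (inherits(x, "uniform_hrv")) {
    x$values <- out
    x$detrended <- TRUE
    x
  } else {
    out
  }
}

#' Preprocess an RR series into an analysis-ready HRV segment
#'
#' Composition [rr_segment()] -> [rr_resample()] -> [detrend_sp()]: a
#' 256-beat window becomes a zero-mean, evenly sampled 1024-point segment
#' ready for [mp_decompose()].
#'
#' @inheritParams rr_segment
#' @inheritParams rr_resample
#' @inheritParams detrend_sp
#' @param seg_length Beats per segment (default 256).
#' @return A zero-mean `uniform_hrv`.
#' @examples
#' rr <- simulate_rr(nsr_preset(), seed = 2)
#' preprocess_rr(rr)
#' @export
preprocess_rr <- function(rr, start = 1, seg_length = 256, n_out = 1024,
                          lambda = 500, label = NA_character_,
                          subject_id = NA_character_) {
  rr |>
    rr_segment(start = start, length = seg_length) |>
    rr_resample(n_out = n_out, label = label, subject_id = subject_id) |>
    detrend_sp(lambda = lambda)
}
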