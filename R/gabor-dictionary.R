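#' Sampled Gabor atom
#'
#' Evaluates a Gaussian-windowed cosine
#' \deqn{\phi(t) = A\, e^{-\pi((t-u)/s)^2} \cos(w(t-u) + \varphi)}
#' on the integer grid \eqn{t = 0, \dots, n-1} and rescales it to unit
#' Euclidean norm. These atoms are the basis functions of the matching-pursuit
#' decomposition; `w` is an angular frequency in radians per sample
#' (`w = 2*pi*f/fs` for a physical frequency `f` at sampling rate `fs`).
#'
#' @param s Scale (envelope width) in samples; must be positive.
#' @param u Translation (envelope centre) in samples, in `[0, n)`.
#' @param w Angular frequency in radians per sample, in `[0, pi]`.
#' @param phi Phase in radians.
#' @param n Signal length in samples.
#' @return A unit-norm numeric vector of length `n`.
#' @examples
#' g <- gabor_waveform(s = 32, u = 64, w = pi / 4, phi = 0, n = 128)
#' sum(g^2)
#' @export
gabor_waveform <- function(s, u, w, phi, n) {
  stopifnot(is.numeric(s), length(s) == 1, is.numeric(n), length(n) == 1)
  if (s <= 0) stop("scale `s` must be positive")
  if (u < 0 || u >= n) stop("translation `u` must lie in [0, n)")
  tau <- seq_len(n) - 1 - u
  x <- exp(-pi * (tau / s)^2) * cos(w * tau + phi)
  nrm <- sqrt(sum(x^2))
  if (nrm < 1e-12) {
    stop("degenerate Gabor parameters: waveform is numerically zero")
  }
  x / nrm
}

#' Dyadic Gabor dictionary
#'
#' Builds the overcomplete dictionary used by [mp_decompose()]: for each
#' dyadic scale \eqn{s = 2^j}, \eqn{j = 1, \dots, \log_2 n}, translations are
#' placed every `s/2` samples and angular frequencies on the grid
#' \eqn{w = \pi k / s}, \eqn{k = 0, \dots, s}. The phase is not discretised:
#' for every `(s, u, w)` triple the dictionary stores the unit-normalised
#' cosine-phase and sine-phase (quadrature) waveforms together with their
#' inner product, from which the decomposition computes the optimal phase in
#' closed form.
#'
#' @param n Signal length; a power of two, at least 8.
#' @return An object of class `gabor_dictionary`: a list with the atom
#'   waveform matrix `G` (one column per stored waveform), a tibble `triples`
#'   of `(s, u, w)` parameters with column bookkeeping, and `n`.
#' @examples
#' d <- gabor_dictionary(64)
#' d
#' @export
gabor_dictionary <- function(n = 1024) {
  if (!is.numeric(n) || length(n) != 1 || n < 8) stop("`n` must be at least 8")
  n <- as.integer(n)
  if (bitwAnd(n, n - 1L) != 0L) stop("`n` must be a power of two")

  scales <- 2^seq_len(as.integer(log2(n)))
  t0 <- seq_len(n) - 1

  # closed-form triple count per scale: (2n/s) translations x (s+1) frequencies
  n_triples <- sum((2 * n / scales) * (scales + 1))
  n_sin_max <- sum((2 * n / scales) * (scales - 1))

  G <- matrix(0, nrow = n, ncol = n_triples + n_sin_max)
  s_v <- u_v <- w_v <- numeric(n_triples)
  icos <- isin <- integer(n_triples)
  rho_v <- norm_c <- norm_s <- numeric(n_triples)

  it <- 0L   # triple counter
  ic <- 0L   # column counter in G
  for (s in scales) {
    w_grid <- pi * (0:s) / s
    for (u in seq(0, n - 1, by = s / 2)) {
      env <- exp(-pi * ((t0 - u) / s)^2)
      tau <- t0 - u
      C <- env * cos(outer(tau, w_grid))
      nc <- sqrt(colSums(C^2))
      S <- NULL
      if (s > 1) {
        S <- env * sin(outer(tau, w_grid[-c(1, s + 1)]))
        ns <- sqrt(colSums(S^2))
      }
      for (k in 0:s) {
        it <- it + 1L
        s_v[it] <- s; u_v[it] <- u; w_v[it] <- w_grid[k + 1]
        ic <- ic + 1L
        nck <- nc[k + 1]
        G[, ic] <- C[, k + 1] / nck
        icos[it] <- ic
        norm_c[it] <- nck
        if (k > 0 && k < s && ns[k] > 1e-10) {
          ic <- ic + 1L
          G[, ic] <- S[, k] / ns[k]
          isin[it] <- ic
          norm_s[it] <- ns[k]
          rho_v[it] <- sum(G[, ic - 1L] * G[, ic])
        } else {
          isin[it] <- NA_integer_
          norm_s[it] <- NA_real_
          rho_v[it] <- 0
        }
      }
    }
  }
  G <- G[, seq_len(ic), drop = FALSE]

  structure(
    list(
      n = n,
      G = G,
      triples = tibble::tibble(
        s = s_v, u = u_v, w = w_v,
        icos = icos, isin = isin,
        rho = rho_v, norm_c = norm_c, norm_s = norm_s
      )
    ),
    class = "gabor_dictionary"
  )
}

#' @export
print.gabor_dictionary <- function(x, ...) {
  cat(
    "Dyadic Gabor dictionary\n",
    "  signal length n: ", x$n, "\n",
    "  (s, u, w) triples: ", nrow(x$triples),
    "  (stored waveforms: ", ncol(x$G), ")\n",
    "  scales: ", paste(sort(unique(x$triples$s)), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of (s, u, w) parameter triples in a dyadic dictionary
#'
#' Closed-form count of the dictionary grid built by [gabor_dictionary()],
#' useful for checking overcompleteness without constructing the atoms.
#'
#' @param n Signal length (power of two).
#' @return Integer count of triples.
#' @export
gabor_grid_size <- function(n) {
  scales <- 2^seq_len(as.integer(log2(n)))
  as.integer(sum((2 * n / scales) * (scales + 1)))
}
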