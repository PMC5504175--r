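# DFT convention (fixed package-wide): unitary, 1/sqrt(n) both ways;
# spectrum bin k corresponds to exp(+2i*pi*k*t/n) in the time domain.
# fft_vec is the forward (time -> spectrum) transform, ifft_vec its inverse.
fft_vec <- function(y) stats::fft(y) / sqrt(length(y))
ifft_vec <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Fourier transform of an FID (time domain to spectrum)
#'
#' Unitary discrete Fourier transform: both directions carry a `1/sqrt(n)`
#' factor, so the l2 norm is preserved and bin `k` of the spectrum pairs
#' with the time-domain oscillation `exp(+2i*pi*k*t/n)`. The unitary scaling
#' makes coherence values and residual-norm stopping criteria scale-free.
#'
#' @param fid a [fid()].
#' @return A `nus_spectrum`.
#' @seealso [ifft_fid()]
#' @export
fft_spectrum <- function(fid) {
  fid <- as_fid(fid)
  spectrum_vec(fft_vec(fid$samples))
}

#' Inverse Fourier transform of a spectrum (spectrum to time domain)
#'
#' Exact inverse of [fft_spectrum()] (unitary convention).
#'
#' @param spec a `nus_spectrum` (or complex vector).
#' @return A `nus_fid`.
#' @export
ifft_fid <- function(spec) {
  spec <- as_spectrum(spec)
  fid(ifft_vec(spec$values))
}

#' Synthesize a Lorentzian FID
#'
#' Builds the standard NMR signal model: a sum of decaying complex
#' exponentials plus circular complex Gaussian noise,
#' \deqn{y_t = \sum_k a_k e^{i\phi_k} e^{2\pi i f_k t/n} e^{-R_k t} + \eta_t,}
#' with `sd(Re eta) = sd(Im eta) = noise_sigma`. Deterministic given `seed`.
#'
#' @param model a [peak_list()]; frequencies must lie in `[0, n)`.
#' @param n grid size (>= 1).
#' @param noise_sigma noise standard deviation per real/imaginary component.
#' @param seed integer seed (mandatory whenever `noise_sigma > 0`).
#' @return A `nus_fid` of length `n`.
#' @export
synth_fid <- function(model, n, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(model, "peak_list"))
  if (!is_count(n)) stop_data("n must be a positive integer")
  if (!is_scalar_num(noise_sigma) || noise_sigma < 0)
    stop_data("noise_sigma must be >= 0")
  if (nrow(model) > 0L && (any(model$frequency < 0) || any(model$frequency >= n)))
    stop_data("peak frequencies must lie in [0, n)")
  t <- 0:(n - 1L)
  y <- complex(real = numeric(n), imaginary = numeric(n))
  for (k in seq_len(nrow(model))) {
    y <- y + model$amplitude[k] * exp(1i * model$phase[k]) *
      exp(2i * pi * model$frequency[k] * t / n) * exp(-model$decay[k] * t)
  }
  if (noise_sigma > 0) {
    y <- y + with_seed(seed, complex(real = stats::rnorm(n, 0, noise_sigma),
                                     imaginary = stats::rnorm(n, 0, noise_sigma)))
  }
  fid(y, label = sprintf("synthetic K=%d", nrow(model)))
}

#' Zero-fill an FID
#'
#' Extends the signal to `factor * n` samples by appending zeros; the
#' standard trick that interpolates the spectrum and, for sparse
#' reconstruction, provides room for the mirror-image "echo".
#'
#' @param fid a [fid()].
#' @param factor integer >= 1; `factor = 1` is the identity.
#' @return A `nus_fid` of length `factor * n`.
#' @export
zero_fill <- function(fid, factor = 2L) {
  fid <- as_fid(fid)
  if (!is_count(factor)) stop_data("factor must be a positive integer")
  out <- c(fid$samples, complex(length.out = (factor - 1L) * fid$n))
  fid(out, label = fid$label)
}

#' Virtual Echo symmetrization
#'
#' Combines the zero-filled signal (length `2n`) with its own conjugated
#' time reversal so the spectrum becomes purely real, which sharpens the
#' sparsity assumption (the dispersive imaginary part with its long tails
#' disappears). The input must already be phase-corrected so that the ideal
#' spectrum's real part is absorptive. The `t = 0` sample is halved before
#' mirroring so it is counted once, a discrete symmetrization choice not
#' fixed by the construction itself (documented here; it keeps the spectrum
#' real and the integral unchanged).
#'
#' @param fid a phase-corrected [fid()] of length `n`.
#' @return A `nus_fid` of length `2n` whose spectrum is real to numerical
#'   precision for noiseless phase-0 input.
#' @export
virtual_echo <- function(fid) {
  fid <- as_fid(fid)
  n <- fid$n
  v <- fid$samples
  v[1L] <- v[1L] / 2
  v <- c(v, complex(length.out = n))            # length 2n
  idx <- c(1L, seq.int(2L * n, 2L, by = -1L))   # (2n - t) mod 2n, t = 0..2n-1
  out <- v + Conj(v[idx])
  fid(out, label = paste0(fid$label, " [virtual echo]"))
}

#' Hankel lift of an FID
#'
#' Rearranges the signal into the Hankel matrix with entry
#' `(i, j) = samples[i + j]` (zero-based), shape `(n - Q + 1) x Q`. Its rank
#' equals the number of decaying complex exponentials in the signal, which
#' is the sparsity notion the low-rank method exploits.
#'
#' @param fid a [fid()] of length `n`.
#' @param Q column count, `2 <= Q <= n - 1`; in practice choose `Q` larger
#'   than the expected number of peaks.
#' @return A complex matrix of dimension `(n - Q + 1) x Q`.
#' @export
hankel_lift <- function(fid, Q) {
  fid <- as_fid(fid)
  n <- fid$n
  if (!is_count(Q) || Q < 2L || Q > n - 1L)
    stop_data("Q must satisfy 2 <= Q <= n - 1")
  nr <- n - Q + 1L
  # entry (i, j), zero-based, is samples[i + j]
  outer(seq_len(nr), seq_len(Q),
        function(i, j) fid$samples[i + j - 1L])
}

#' Adjoint of the Hankel lift
#'
#' Sums each anti-diagonal of `M` into one time-domain sample; the exact
#' adjoint of [hankel_lift()] under the standard (real part of the complex)
#' inner product. Needed by the low-rank solver's x-update, where the
#' composition `t(R) R` is the diagonal of anti-diagonal multiplicities.
#'
#' @param M complex matrix of Hankel-compatible shape `(n - Q + 1) x Q`.
#' @return A `nus_fid` of length `nrow(M) + ncol(M) - 1`.
#' @export
hankel_adjoint <- function(M) {
  if (!is.matrix(M)) stop_data("M must be a matrix")
  nr <- nrow(M); nc <- ncol(M)
  if (nr < 1L || nc < 1L) stop_data("M must be non-empty")
  n <- nr + nc - 1L
  out <- complex(length.out = n)
  for (j in seq_len(nc)) {
    idx <- seq.int(j, j + nr - 1L)
    out[idx] <- out[idx] + M[, j]
  }
  fid(out)
}

# anti-diagonal multiplicities w[t] with w = diag(t(R) R), length n
hankel_weights <- function(n, Q) {
  nr <- n - Q + 1L
  pmin(seq_len(n), nr, Q, n - seq_len(n) + 1L)
}
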