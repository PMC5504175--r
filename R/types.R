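#' Free induction decay (FID) container
#'
#' A complex time-domain vector of length `n` together with a free-text
#' label. This is the package's fundamental time-domain object; all
#' reconstruction methods consume and produce it.
#'
#' @param samples complex (or numeric) vector of time-domain samples.
#' @param label optional free-text description.
#' @return An object of class `nus_fid` with fields `samples`, `n`, `label`.
#' @export
fid <- function(samples, label = "") {
  if (length(samples) < 1L) stop_data("an FID needs at least one sample")
  samples <- as.complex(samples)
  if (any(!is.finite(Re(samples)) | !is.finite(Im(samples))))
    stop_data("FID samples must be finite")
  structure(list(samples = samples, n = length(samples),
                 label = as.character(label)[1L]),
            class = "nus_fid")
}

#' @export
print.nus_fid <- function(x, ...) {
  cat(sprintf("<nus_fid> n = %d%s\n", x$n,
              if (nzchar(x$label)) paste0("  (", x$label, ")") else ""))
  invisible(x)
}

as_fid <- function(x, label = "") {
  if (inherits(x, "nus_fid")) x else fid(x, label)
}

#' Spectrum container
#'
#' The discrete Fourier transform of an [fid()], under the package's fixed
#' unitary convention (see [fft_spectrum()]).
#'
#' @param values complex vector of spectral bin values.
#' @return An object of class `nus_spectrum` with fields `values`, `n`, and
#'   `transform_convention` (always `"unitary+"`).
#' @export
spectrum_vec <- function(values) {
  if (length(values) < 1L) stop_data("a spectrum needs at least one bin")
  values <- as.complex(values)
  structure(list(values = values, n = length(values),
                 transform_convention = "unitary+"),
            class = "nus_spectrum")
}

#' @export
print.nus_spectrum <- function(x, ...) {
  cat(sprintf("<nus_spectrum> n = %d, convention = %s\n", x$n,
              x$transform_convention))
  invisible(x)
}

as_spectrum <- function(x) if (inherits(x, "nus_spectrum")) x else spectrum_vec(x)

#' Ground-truth spectral model: a list of Lorentzian peaks
#'
#' Each peak is a decaying complex exponential in the time domain, i.e. a
#' Lorentzian line in the spectrum. Frequencies are expressed in cycles per
#' full grid (bin units) and need not lie on the integer grid: off-grid
#' frequencies give approximately sparse spectra, the realistic NMR case.
#'
#' @param frequency numeric vector, each in `[0, n)` of the grid it will be
#'   synthesized on (validated at synthesis time against `n`).
#' @param amplitude non-negative numeric vector.
#' @param phase phase in radians (recycled).
#' @param decay non-negative per-sample relaxation rate (recycled).
#' @return A `peak_list` data frame with one row per peak and attribute `K`.
#' @export
peak_list <- function(frequency = numeric(), amplitude = numeric(),
                      phase = 0, decay = 0) {
  K <- length(frequency)
  if (length(amplitude) != K)
    stop_data("frequency and amplitude must have equal length")
  if (K > 0L) {
    phase <- rep_len(phase, K)
    decay <- rep_len(decay, K)
    if (any(amplitude < 0)) stop_data("amplitudes must be non-negative")
    if (any(decay < 0)) stop_data("decay rates must be non-negative")
  } else {
    phase <- numeric(); decay <- numeric()
  }
  structure(data.frame(frequency = as.numeric(frequency),
                       amplitude = as.numeric(amplitude),
                       phase = as.numeric(phase),
                       decay = as.numeric(decay)),
            K = K, class = c("peak_list", "data.frame"))
}

#' Number of peaks in a peak list
#' @param model a [peak_list()].
#' @return integer count of peaks.
#' @export
n_peaks <- function(model) {
  stopifnot(inherits(model, "peak_list"))
  nrow(model)
}

#' Reconstruction result container
#'
#' Common return type of every reconstruction method: the reconstructed
#' spectrum, its inverse transform (the reconstructed FID), the support
#' found, the per-iteration residual norm trace, and convergence state.
#'
#' @name recon_result
#' @keywords internal
recon_result <- function(spectrum, support = integer(),
                         residual_trace = numeric(), iterations = 0L,
                         converged = FALSE, method = "", diagnostics = list()) {
  spectrum <- as_spectrum(spectrum)
  structure(list(spectrum = spectrum,
                 fid = fid(ifft_vec(spectrum$values), label = method),
                 support = sort(unique(as.integer(support))),
                 residual_trace = as.numeric(residual_trace),
                 iterations = as.integer(iterations),
                 converged = isTRUE(converged),
                 method = method,
                 diagnostics = diagnostics),
            class = "nus_recon")
}

#' @export
print.nus_recon <- function(x, ...) {
  cat(sprintf("<nus_recon> method = %s, n = %d, |support| = %d, iters = %d, converged = %s\n",
              x$method, x$spectrum$n, length(x$support), x$iterations,
              x$converged))
  if (length(x$residual_trace))
    cat(sprintf("  final residual l2 = %.3e\n", utils::tail(x$residual_trace, 1)))
  invisible(x)
}
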