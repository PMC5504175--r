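#' NUS sampling schedule
#'
#' A set of `m` distinct zero-based time-grid indices out of a full Nyquist
#' grid of size `n`. Indices are stored sorted; duplicates are rejected.
#'
#' @param indices integer vector of zero-based indices in `[0, n)`.
#' @param n full grid size.
#' @return An object of class `nus_schedule` with fields `indices`, `n`, `m`.
#' @export
schedule <- function(indices, n) {
  if (!is_count(n)) stop_data("n must be a positive integer")
  if (length(indices) < 1L) stop_data("a schedule needs at least one index")
  if (any(indices != round(indices))) stop_data("indices must be integers")
  indices <- as.integer(indices)
  if (any(indices < 0L) || any(indices >= n))
    stop_data("schedule indices must lie in [0, n)")
  if (anyDuplicated(indices)) stop_data("schedule indices must be unique")
  indices <- sort(indices)
  structure(list(indices = indices, n = as.integer(n),
                 m = length(indices)),
            class = "nus_schedule")
}

#' @export
print.nus_schedule <- function(x, ...) {
  cat(sprintf("<nus_schedule> m = %d of n = %d (%.1f%%)\n", x$m, x$n,
              100 * x$m / x$n))
  invisible(x)
}

#' Draw a uniform-density NUS schedule
#'
#' Selects `m` of the `n` grid indices without replacement with uniform
#' probability; deterministic given `seed`. Uniform density is the only
#' sampling type implemented (weighted/decaying densities are out of scope).
#'
#' @param n full grid size.
#' @param m number of sampled points, `1 <= m <= n`.
#' @param seed integer seed.
#' @param keep_first force index 0 (the first FID point) into the schedule.
#'   Off by default: the plain uniform scheme does not force it, though
#'   practitioners often do.
#' @return A [schedule()].
#' @export
uniform_schedule <- function(n, m, seed, keep_first = FALSE) {
  if (!is_count(n) || !is_count(m)) stop_data("n and m must be positive integers")
  if (m > n) stop_data("m must not exceed n")
  idx <- with_seed(seed, {
    if (keep_first) {
      if (m == 1L) 0L else c(0L, sample(seq_len(n - 1L), m - 1L))
    } else {
      sample.int(n, m) - 1L
    }
  })
  schedule(idx, n)
}

#' Restrict a fully sampled FID to a NUS schedule
#'
#' Produces the NUS data object holding the measured vector `y~` (values at
#' the scheduled indices) and the zero-filled full-length vector `y~0`
#' (omitted points set to zero), the starting point of every reconstruction.
#'
#' @param fid a [fid()] of length `sched$n`.
#' @param sched a [schedule()].
#' @return An object of class `nus_data` with fields `schedule`, `measured`,
#'   `zero_filled`.
#' @export
restrict_fid <- function(fid, sched) {
  fid <- as_fid(fid)
  stopifnot(inherits(sched, "nus_schedule"))
  if (fid$n != sched$n)
    stop_data("FID length (", fid$n, ") does not match schedule grid (",
              sched$n, ")")
  measured <- fid$samples[sched$indices + 1L]
  zf <- complex(length.out = sched$n)
  zf[sched$indices + 1L] <- measured
  structure(list(schedule = sched, measured = measured, zero_filled = zf),
            class = "nus_data")
}

#' Assemble NUS data from measured values
#'
#' Inverse-direction constructor of [restrict_fid()]: given the measured
#' vector in schedule order, builds the `nus_data` object.
#'
#' @param measured complex vector of length `sched$m`, ordered as
#'   `sched$indices`.
#' @param sched a [schedule()].
#' @return A `nus_data`.
#' @export
nus_data <- function(measured, sched) {
  stopifnot(inherits(sched, "nus_schedule"))
  measured <- as.complex(measured)
  if (length(measured) != sched$m)
    stop_data("measured length (", length(measured),
              ") does not match schedule m (", sched$m, ")")
  zf <- complex(length.out = sched$n)
  zf[sched$indices + 1L] <- measured
  structure(list(schedule = sched, measured = measured, zero_filled = zf),
            class = "nus_data")
}

#' @export
print.nus_data <- function(x, ...) {
  cat(sprintf("<nus_data> m = %d of n = %d\n", x$schedule$m, x$schedule$n))
  invisible(x)
}

#' Zero-filled FID of NUS data
#'
#' Returns `y~0` as a [fid()]: the full-length vector with omitted points
#' set to zero.
#'
#' @param nus a `nus_data`.
#' @return A `nus_fid` of length `n`.
#' @export
zero_fill_nus <- function(nus) {
  stopifnot(inherits(nus, "nus_data"))
  fid(nus$zero_filled, label = "zero-filled NUS data")
}

# zero out the non-measured entries of a full-length complex vector
mask_to_schedule <- function(v, sched) {
  out <- complex(length.out = sched$n)
  out[sched$indices + 1L] <- v[sched$indices + 1L]
  out
}

#' Point spread function of a sampling schedule
#'
#' DFT of the schedule's indicator vector, normalized so that `PSF(0) = 1`.
#' The artifacts a NUS spectrum shows are the true spectrum convolved with
#' this function; its largest off-center magnitude equals the coherence of
#' the restricted Fourier matrix.
#'
#' @param sched a [schedule()].
#' @return A `nus_spectrum` of length `n` with value 1 at bin 0.
#' @export
psf <- function(sched) {
  stopifnot(inherits(sched, "nus_schedule"))
  ind <- numeric(sched$n)
  ind[sched$indices + 1L] <- 1
  spectrum_vec(stats::fft(ind) / sched$m)
}

#' Coherence of the restricted Fourier matrix
#'
#' Maximum absolute inner product between distinct columns of the restricted
#' DFT matrix, with every column normalized to unit l2 norm (for a uniform
#' grid all columns share the norm `sqrt(m/n)`, so normalization is a single
#' scale). Equals the highest off-center PSF artifact,
#' `max_{w != 0} |PSF(w)|`.
#'
#' @param sched a [schedule()].
#' @return Coherence `mu` in `[0, 1]` (0 for full sampling).
#' @export
coherence <- function(sched) {
  p <- Mod(psf(sched)$values)
  if (length(p) == 1L) return(0)
  max(p[-1L])
}

#' s-column coherence
#'
#' Worst case over columns `i` of the sum of the `s` largest inner products
#' `|<f_i, f_j>|`, `j != i` — an upper bound on the overlapping-artifact
#' height for `s` peaks at arbitrary positions. For a uniform-grid schedule
#' the inner products depend only on the index difference mod `n`, so the
#' maximum reduces to the sum of the `s` largest off-zero PSF magnitudes
#' (the exhaustive subset form is kept as a test oracle).
#'
#' @param sched a [schedule()].
#' @param s positive integer, `s <= n - 1`.
#' @return `mu_s >= mu`, non-decreasing in `s`.
#' @export
s_coherence <- function(sched, s) {
  stopifnot(inherits(sched, "nus_schedule"))
  if (!is_count(s) || s > sched$n - 1L)
    stop_data("s must be a positive integer <= n - 1")
  p <- Mod(psf(sched)$values)[-1L]
  sum(sort(p, decreasing = TRUE)[seq_len(s)])
}

#' Exact-recovery guarantee for orthogonal matching pursuit
#'
#' Returns whether `mu_s + mu_{s-1} < 1` (with `mu_0 = 0`), the sufficient
#' condition under which OMP recovers every `s`-sparse spectrum exactly in
#' at most `s` iterations.
#'
#' @param sched a [schedule()].
#' @param s sparsity level.
#' @return `TRUE` if the guarantee holds.
#' @export
omp_guarantee <- function(sched, s) {
  mu_s <- s_coherence(sched, s)
  mu_sm1 <- if (s == 1L) 0 else s_coherence(sched, s - 1L)
  (mu_s + mu_sm1) < 1
}

#' Sampling diagnostic report
#'
#' Bundles the PSF, coherence, the s-column coherence profile and the
#' largest sparsity `s` for which the OMP guarantee holds.
#'
#' @param sched a [schedule()].
#' @param s_max largest `s` to tabulate (default `min(n - 1, 16)`).
#' @return An object of class `coherence_report` with fields `psf`, `mu`,
#'   `mu_s` (named numeric vector), `guarantee_s` (0 if the condition fails
#'   already at `s = 1`).
#' @export
coherence_report <- function(sched, s_max = NULL) {
  stopifnot(inherits(sched, "nus_schedule"))
  if (is.null(s_max)) s_max <- min(sched$n - 1L, 16L)
  if (!is_count(s_max) || s_max > sched$n - 1L)
    stop_data("s_max must be a positive integer <= n - 1")
  p <- psf(sched)
  mags <- sort(Mod(p$values)[-1L], decreasing = TRUE)
  mu_s <- cumsum(mags)[seq_len(s_max)]
  names(mu_s) <- as.character(seq_len(s_max))
  ok <- (mu_s + c(0, mu_s[-s_max])) < 1
  guarantee_s <- if (any(ok)) max(which(ok)) else 0L
  structure(list(psf = p, mu = if (length(mags)) mags[1L] else 0,
                 mu_s = mu_s, guarantee_s = as.integer(guarantee_s)),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("<coherence_report> mu = %.4f, OMP guarantee holds up to s = %d\n",
              x$mu, x$guarantee_s))
  invisible(x)
}
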