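#' Configuration for the greedy solvers
#'
#' @param mode `"clean"` or `"omp"`.
#' @param epsilon residual l2 stopping threshold (>= 0). A practical rule:
#'   set it to the l2 norm of the noise; with per-component noise sd
#'   `sigma`, `epsilon = sigma * sqrt(2 m)` (heuristic, exposed by the CLI
#'   as `--noise-sigma`).
#' @param max_iter iteration cap; for OMP this also caps the support size.
#' @param gain CLEAN loop gain in `(0, 1]`; 1 reproduces the textbook
#'   description, fractional values give the classic cautious CLEAN.
#' @param apodize_lw exponential line width applied to the output FID
#'   (`>= 0`, 0 = none); damps the peak-splitting tendency of greedy
#'   point-wise reconstructions.
#' @return A `greedy_config` list.
#' @export
greedy_config <- function(mode = c("omp", "clean"), epsilon = 0,
                          max_iter = 50L, gain = 1, apodize_lw = 0) {
  mode <- match.arg(mode)
  if (!is_scalar_num(epsilon) || epsilon < 0) stop_data("epsilon must be >= 0")
  if (!is_count(max_iter)) stop_data("max_iter must be a positive integer")
  if (!is_scalar_num(gain) || gain <= 0 || gain > 1)
    stop_data("gain must be in (0, 1]")
  if (!is_scalar_num(apodize_lw) || apodize_lw < 0)
    stop_data("apodize_lw must be >= 0")
  structure(list(mode = mode, epsilon = epsilon,
                 max_iter = as.integer(max_iter), gain = gain,
                 apodize_lw = apodize_lw),
            class = "greedy_config")
}

# restricted-DFT column for bin k (zero-based) at the scheduled time points:
# exp(+2i*pi*k*t/n)/sqrt(n)
restricted_columns <- function(sched, bins) {
  t <- sched$indices
  n <- sched$n
  vapply(bins, function(k) exp(2i * pi * k * t / n) / sqrt(n),
         complex(length(t)))
}

#' CLEAN (matching pursuit) reconstruction
#'
#' Iteratively (1) locates the global maximum-magnitude bin of the spectrum
#' with artifacts (FT of the current zero-filled residual) and adds
#' `gain` times its value to the accumulator `x`; (2) inverse transforms
#' the increment; (3) zeroes the non-measured time points; (4) subtracts
#' from the residual. The height of a once-found bin is never re-fit.
#' Stops when the residual l2 norm drops to `epsilon` or after `max_iter`
#' iterations.
#'
#' @param nus a `nus_data` (see [restrict_fid()]).
#' @param cfg a [greedy_config()] with `mode = "clean"`.
#' @return A `nus_recon`.
#' @export
clean <- function(nus, cfg = greedy_config(mode = "clean")) {
  stopifnot(inherits(nus, "nus_data"), inherits(cfg, "greedy_config"))
  if (cfg$mode != "clean") stop_data("cfg$mode must be 'clean'")
  greedy_run(nus, cfg)
}

#' Orthogonal matching pursuit reconstruction
#'
#' As [clean()], but after each support addition the values on the whole
#' support are refit by least squares: the orthogonal projection of the
#' measured vector onto the span of the restricted-DFT columns indexed by
#' the support. Both stopping criteria (residual norm and iteration cap)
#' apply. When the coherence condition `mu_s + mu_{s-1} < 1` holds, an
#' `s`-sparse spectrum is recovered exactly in at most `s` iterations.
#'
#' @param nus a `nus_data`.
#' @param cfg a [greedy_config()] with `mode = "omp"`.
#' @return A `nus_recon`; `diagnostics$degenerate_support` flags a
#'   numerically rank-deficient support system (solved with a tiny ridge).
#' @export
omp <- function(nus, cfg = greedy_config(mode = "omp")) {
  stopifnot(inherits(nus, "nus_data"), inherits(cfg, "greedy_config"))
  if (cfg$mode != "omp") stop_data("cfg$mode must be 'omp'")
  greedy_run(nus, cfg)
}

greedy_run <- function(nus, cfg) {
  sched <- nus$schedule
  if (sched$m < 1L) stop_data("empty schedule")
  n <- sched$n
  sel <- sched$indices + 1L
  x <- complex(length.out = n)          # spectrum accumulator
  r <- nus$zero_filled                  # residual, supported on the schedule
  support <- integer()
  trace <- numeric()
  degenerate <- FALSE
  res <- l2(r)
  iter <- 0L
  while (res > cfg$epsilon && iter < cfg$max_iter) {
    iter <- iter + 1L
    art <- fft_vec(r)                   # spectrum with artifacts
    b <- which.max(Mod(art))            # ties: lowest bin index wins
    if (cfg$mode == "clean") {
      x[b] <- x[b] + cfg$gain * art[b]
      support <- union(support, b - 1L)
      inc <- complex(length.out = n); inc[b] <- cfg$gain * art[b]
      tinc <- ifft_vec(inc)
      tinc[-sel] <- 0
      r <- r - tinc
    } else {
      if ((b - 1L) %in% support) {      # residual not orthogonal: degenerate
        degenerate <- TRUE
        iter <- iter - 1L
        break
      }
      support <- c(support, b - 1L)
      A <- restricted_columns(sched, support)
      G <- Conj(t(A)) %*% A
      rhs <- Conj(t(A)) %*% nus$measured
      cvals <- tryCatch(solve(G, rhs), error = function(e) NULL)
      if (is.null(cvals) || any(!is.finite(Mod(cvals)))) {
        degenerate <- TRUE
        cvals <- solve(G + diag(1e-12, nrow(G)), rhs)
      }
      x <- complex(length.out = n)
      x[support + 1L] <- cvals
      fitted <- as.vector(A %*% cvals)
      r <- complex(length.out = n)
      r[sel] <- nus$measured - fitted
    }
    res <- l2(r)
    trace <- c(trace, res)
  }
  out <- recon_result(spectrum_vec(x), support = support,
                      residual_trace = trace, iterations = iter,
                      converged = res <= cfg$epsilon, method = cfg$mode,
                      diagnostics = list(degenerate_support = degenerate))
  if (cfg$apodize_lw > 0) out <- apodize_output(out, cfg$apodize_lw) else out
}

#' Exponential apodization of a reconstruction
#'
#' Multiplies the reconstructed FID by `exp(-lw * t)` and re-transforms,
#' turning each stick into a Lorentzian of half-width set by `lw`; `lw = 0`
#' is the identity. The first time point has weight 1, so the spectral
#' integral is unchanged.
#'
#' @param result a `nus_recon`.
#' @param lw line width per sample (>= 0).
#' @return A `nus_recon` with updated `fid` and `spectrum`.
#' @export
apodize_output <- function(result, lw) {
  stopifnot(inherits(result, "nus_recon"))
  if (!is_scalar_num(lw) || lw < 0) stop_data("lw must be >= 0")
  if (lw == 0) return(result)
  n <- result$fid$n
  y <- result$fid$samples * exp(-lw * (0:(n - 1L)))
  out <- result
  out$fid <- fid(y, label = result$fid$label)
  out$spectrum <- fft_spectrum(out$fid)
  out$diagnostics$apodize_lw <- lw
  out
}
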