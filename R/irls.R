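#' Configuration for iteratively reweighted least squares
#'
#' IRLS approximates lp-norm minimization (`0 < p <= 1`) by a sequence of
#' weighted l2 problems with weights `d_i = max(|x_i|, eps)^(p - 2)`.
#'
#' @param p norm exponent in `(0, 1]`.
#' @param lam sparsity/data-agreement balance `lambda > 0`: larger values
#'   favor sparsity; too large and small peaks are shrunk away.
#' @param eps0 floor regularizer `eps_0 > 0` guarding the weights where
#'   coordinates of the solution are (near) zero.
#' @param delta per-iteration decrease of `p` (>= 0). With
#'   `delta = 1/n_iter` the effective exponent anneals toward the l0
#'   problem over the run.
#' @param n_iter iteration count (20 is a practical default for desk-size
#'   problems).
#' @param eps_rule `"fixed"` (always `eps0`) or `"k"`: the adaptive rule
#'   `eps = max(|x|_(i0), eps0)` with `i0 = round(m / (4 log(n/m)))`, the
#'   heuristic tied to the `m ~ K log(n/K)` sampling relation.
#' @return An `irls_config` list.
#' @export
irls_config <- function(p = 1, lam = 1e-4, eps0 = 1e-6, delta = 0,
                        n_iter = 20L, eps_rule = c("fixed", "k")) {
  eps_rule <- match.arg(eps_rule)
  if (!is_scalar_num(p) || p <= 0 || p > 1) stop_data("p must be in (0, 1]")
  if (!is_scalar_num(lam) || lam <= 0) stop_data("lam must be > 0")
  if (!is_scalar_num(eps0) || eps0 <= 0) stop_data("eps0 must be > 0")
  if (!is_scalar_num(delta) || delta < 0) stop_data("delta must be >= 0")
  if (!is_count(n_iter)) stop_data("n_iter must be a positive integer")
  structure(list(p = p, lam = lam, eps0 = eps0, delta = delta,
                 n_iter = as.integer(n_iter), eps_rule = eps_rule),
            class = "irls_config")
}

# Solve (B + lam I) z = y~ with B = F~ W^-2 F~^H, then x = W^-2 F~^H z.
# B is the schedule-restriction of a circulant matrix whose symbol is the
# inverse DFT of w^-2, so it is built with one FFT instead of forming F~.
reweighted_core <- function(nus, lam, w2inv) {
  sched <- nus$schedule
  n <- sched$n
  t <- sched$indices
  csym <- stats::fft(as.complex(w2inv), inverse = TRUE) / n
  d <- outer(t, t, "-") %% n
  B <- matrix(csym[d + 1L], sched$m, sched$m)
  z <- tryCatch(solve(B + diag(lam, sched$m), nus$measured),
                error = function(e)
                  stop_num("reweighted system is singular: ",
                           conditionMessage(e)))
  zf <- complex(length.out = n)
  zf[t + 1L] <- z
  w2inv * fft_vec(zf)                  # W^-2 F~^H z
}

#' Tikhonov-regularized least-squares spectrum
#'
#' Closed-form solution `x = F~^H (F~ F~^H + lambda I)^{-1} y~` of the
#' l2-regularized problem. Under the unitary convention the rows of the
#' restricted DFT are orthonormal (`F~ F~^H = I`), so for full sampling the
#' result is `FT(y) / (1 + lambda)`; the general case is solved through the
#' same m-by-m system as [reweighted_solve()] with unit weights.
#'
#' @param nus a `nus_data`.
#' @param lam regularization strength `> 0`.
#' @return A `nus_spectrum` (not sparse: l2 regularization never is).
#' @export
tikhonov <- function(nus, lam) {
  stopifnot(inherits(nus, "nus_data"))
  if (!is_scalar_num(lam) || lam <= 0) stop_data("lam must be > 0")
  spectrum_vec(reweighted_core(nus, lam, rep(1, nus$schedule$n)))
}

#' Weighted-regularization least-squares spectrum
#'
#' Evaluates the closed form
#' `x = W^{-2} F~^H (F~ W^{-2} F~^H + lambda I)^{-1} y~`
#' of the reweighted l2 problem `min ||F~ x - y~||^2 + lambda ||W x||^2`,
#' the building block of each IRLS iteration.
#'
#' @param nus a `nus_data`.
#' @param lam regularization strength `> 0`.
#' @param W_diag strictly positive weight vector of length `n` (the
#'   diagonal of `W`).
#' @return A `nus_spectrum`.
#' @export
reweighted_solve <- function(nus, lam, W_diag) {
  stopifnot(inherits(nus, "nus_data"))
  if (!is_scalar_num(lam) || lam <= 0) stop_data("lam must be > 0")
  n <- nus$schedule$n
  if (length(W_diag) != n) stop_data("W_diag must have length n")
  if (any(!is.finite(W_diag)) || any(W_diag <= 0))
    stop_data("all weights must be positive and finite")
  spectrum_vec(reweighted_core(nus, lam, as.numeric(W_diag)^(-2)))
}

#' Adaptive epsilon from the sampling-theory k-rule
#'
#' Returns `max(|x|_(i0), eps0)` where `|x|_(i)` is the decreasing
#' reordering of the spectrum magnitudes and
#' `i0 = round(m / (4 log(n/m)))` (natural log, floored at 1) — the number
#' of spectral points the `m ~ K log(n/K)` relation predicts can be
#' reconstructed reliably from `m` samples.
#'
#' @param x a `nus_spectrum` (or complex vector), the current IRLS iterate.
#' @param m number of sampled points (`m < n`; for `m = n` the rule is
#'   undefined and `eps0` is returned).
#' @param n full grid size.
#' @param eps0 floor value.
#' @return A scalar epsilon `>= eps0`.
#' @export
eps_k_rule <- function(x, m, n, eps0) {
  x <- as_spectrum(x)
  if (!is_count(m) || !is_count(n) || m > n) stop_data("need 1 <= m <= n")
  if (m == n) return(eps0)
  i0 <- max(1L, as.integer(round(m / (4 * log(n / m)))))
  mags <- sort(Mod(x$values), decreasing = TRUE)
  max(mags[min(i0, length(mags))], eps0)
}

#' IRLS reconstruction with optional p-annealing
#'
#' Iterates [reweighted_solve()] with weights
#' `d_i = max(|x_i|, eps)^(p - 2)` (the floor `eps` is clamped inside the
#' power, which is exactly what keeps the weights well defined at zero
#' coordinates). The first solve uses unit weights, so a single iteration
#' reduces to [tikhonov()]. With `delta > 0` the exponent `p` decreases by
#' `delta` each iteration (floored at 0.05 for numerical stability of the
#' power), steering the solution toward the l0 problem after about
#' `1/delta` iterations.
#'
#' @param nus a `nus_data`.
#' @param cfg an [irls_config()].
#' @return A `nus_recon`. If the data-domain residual grows for 5
#'   consecutive iterations the run stops and is flagged non-converged.
#' @export
irls <- function(nus, cfg = irls_config()) {
  stopifnot(inherits(nus, "nus_data"), inherits(cfg, "irls_config"))
  sched <- nus$schedule
  n <- sched$n
  sel <- sched$indices + 1L
  x <- fft_vec(nus$zero_filled)         # x^(0): the artifact spectrum
  p <- cfg$p
  trace <- numeric()
  rises <- 0L
  converged <- TRUE
  iters_done <- 0L
  for (l in seq_len(cfg$n_iter)) {
    if (l == 1L) {
      w2inv <- rep(1, n)                # W = I: the Tikhonov step
    } else {
      eps <- if (cfg$eps_rule == "fixed") cfg$eps0
             else eps_k_rule(spectrum_vec(x), sched$m, n, cfg$eps0)
      # d_i = max(|x_i|, eps)^(p-2); the solver needs w^-2 = 1/d
      w2inv <- pmax(Mod(x), eps)^(2 - p)
    }
    x <- reweighted_core(nus, cfg$lam, w2inv)
    if (any(!is.finite(Mod(x))))
      stop_num("IRLS produced a non-finite iterate at iteration ", l)
    res <- l2(ifft_vec(x)[sel] - nus$measured)
    trace <- c(trace, res)
    iters_done <- l
    # divergence guard: the residual drifts up a little during reweighting
    # and p-annealing by design, so only count rises once the misfit is a
    # sizable fraction of the data norm
    if (l > 1L && res > trace[l - 1L] * (1 + 1e-12) &&
        res > 0.1 * l2(nus$measured)) {
      rises <- rises + 1L
      if (rises >= 5L) { converged <- FALSE; break }
    } else rises <- 0L
    p <- max(p - cfg$delta, 0.05)
  }
  recon_result(spectrum_vec(x), support = which(Mod(x) > 1e-8 * max(Mod(x))) - 1L,
               residual_trace = trace, iterations = iters_done,
               converged = converged, method = "irls",
               diagnostics = list(final_p = p))
}
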