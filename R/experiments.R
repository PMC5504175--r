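# reusable, seeded pitfall workflows: residual-vs-m curves, extrapolation,
# L-curve / cross-validation parameter selection, residual re-addition

method_registry <- function() c("clean", "omp", "ist-d", "ist-s", "irls", "lowrank")

# dispatch a reconstruction by method name with its config object
reconstruct_by_name <- function(nus, method, config) {
  switch(method,
         "clean"   = clean(nus, config),
         "omp"     = omp(nus, config),
         "ist-d"   = ist_d(nus, config),
         "ist-s"   = ist_s(nus, config),
         "irls"    = irls(nus, config),
         "lowrank" = lowrank_reconstruct(nus, config),
         stop_data("unknown method '", method, "'"))
}

default_config_for <- function(method) {
  switch(method,
         "clean"   = greedy_config(mode = "clean"),
         "omp"     = greedy_config(mode = "omp"),
         "ist-d"   = ist_config("D"),
         "ist-s"   = ist_config("S"),
         "irls"    = irls_config(),
         "lowrank" = lowrank_config(),
         stop_data("unknown method '", method, "'"))
}

#' Specification of a residual-vs-sampling-level sweep
#'
#' @param truth the fully sampled ground-truth [fid()] (or a [peak_list()]
#'   plus `n`, synthesized noiselessly).
#' @param levels increasing vector of sampling-point counts `m`, all `<= n`.
#' @param n_schedules schedules drawn per level (the residual is averaged
#'   over them; 20 reproduces the standard protocol).
#' @param method one of `"clean"`, `"omp"`, `"ist-d"`, `"ist-s"`, `"irls"`,
#'   `"lowrank"`.
#' @param config the method's config object (`NULL` = method default).
#' @param seed integer seed controlling every schedule draw.
#' @param n grid size, only needed when `truth` is a [peak_list()].
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(truth, levels, n_schedules = 20L, method = "ist-d",
                       config = NULL, seed = 1L, n = NULL) {
  if (inherits(truth, "peak_list")) {
    if (is.null(n)) stop_data("n is required when truth is a peak_list")
    truth <- synth_fid(truth, n, noise_sigma = 0)
  }
  truth <- as_fid(truth)
  levels <- as.integer(levels)
  if (length(levels) < 1L || is.unsorted(levels, strictly = TRUE))
    stop_data("levels must be strictly increasing")
  if (any(levels < 1L) || any(levels > truth$n))
    stop_data("levels must lie in [1, n]")
  if (!is_count(n_schedules)) stop_data("n_schedules must be >= 1")
  method <- match.arg(method, method_registry())
  if (is.null(config)) config <- default_config_for(method)
  structure(list(truth = truth, levels = levels,
                 n_schedules = as.integer(n_schedules), method = method,
                 config = config, seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Residual-vs-sampling-level curve
#'
#' For each sampling level `m`, draws `n_schedules` seeded uniform
#' schedules, reconstructs, and records the residue
#' `||truth_spectrum - reconstruction||_2` together with the data-domain
#' residual. The mean curve falls steeply while peaks are being
#' reconstructed and flattens once only low spectral points remain —
#' the behavior behind the `m ~ K log(n/K)` sampling rule. A method
#' failure at a level is recorded as `NA`, not an error.
#'
#' @param spec a [sweep_spec()].
#' @return An object of class `nus_curve`: `summary` (data frame with one
#'   row per level: `m`, `mean_residual`, `sd_residual`,
#'   `mean_data_residual`), `residuals` (levels x schedules matrix), and
#'   `examples` (first reconstruction per level).
#' @export
residual_curve <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  truth_spec <- fft_vec(spec$truth$samples)
  L <- length(spec$levels)
  res <- matrix(NA_real_, L, spec$n_schedules)
  dres <- matrix(NA_real_, L, spec$n_schedules)
  examples <- vector("list", L)
  sub_seeds <- with_seed(spec$seed,
                         matrix(sample.int(2^31 - 2, L * spec$n_schedules),
                                L, spec$n_schedules))
  for (i in seq_len(L)) {
    for (j in seq_len(spec$n_schedules)) {
      sched <- uniform_schedule(spec$truth$n, spec$levels[i],
                                seed = sub_seeds[i, j])
      nus <- restrict_fid(spec$truth, sched)
      rec <- tryCatch(reconstruct_by_name(nus, spec$method, spec$config),
                      error = function(e) NULL)
      if (is.null(rec)) next
      res[i, j] <- l2(truth_spec - rec$spectrum$values)
      dres[i, j] <- l2(rec$fid$samples[sched$indices + 1L] - nus$measured)
      if (j == 1L) examples[[i]] <- rec
    }
  }
  summary <- data.frame(m = spec$levels,
                        mean_residual = rowMeans(res, na.rm = TRUE),
                        sd_residual = apply(res, 1, stats::sd, na.rm = TRUE),
                        mean_data_residual = rowMeans(dres, na.rm = TRUE))
  structure(list(summary = summary, residuals = res, examples = examples,
                 spec = spec),
            class = "nus_curve")
}

#' @export
print.nus_curve <- function(x, ...) {
  cat(sprintf("<nus_curve> method = %s, n = %d, %d levels x %d schedules\n",
              x$spec$method, x$spec$truth$n, length(x$spec$levels),
              x$spec$n_schedules))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sampling points needed for K significant spectral points
#'
#' The compressed-sensing sampling rule `m ~ c K log(n/K)` (natural log,
#' rounded up). Note that it grows only logarithmically with the grid size
#' `n` — a fixed-percentage rule `m = a n` has no such basis and is
#' misleading for large grids.
#'
#' @param K number of significant spectral points, `1 <= K < n`.
#' @param n full grid size.
#' @param c proportionality constant `> 0`.
#' @return Integer `ceiling(c * K * log(n/K))`.
#' @export
required_m <- function(K, n, c = 1) {
  if (!is_count(K) || !is_count(n) || K >= n) stop_data("need 1 <= K < n")
  if (!is_scalar_num(c) || c <= 0) stop_data("c must be > 0")
  as.integer(ceiling(c * K * log(n / K)))
}

#' FID extrapolation by sparse reconstruction
#'
#' Truncates the signal to its first `keep` points and reconstructs the
#' missing tail with IST (the truncation schedule `{0, ..., keep-1}` is
#' just a special NUS pattern). Reports a decay-rate fit of the
#' extrapolated tail: an over-sparse threshold yields an artificially
#' narrowed peak, i.e. a tail with (almost) no decay.
#'
#' Sparse reconstruction of a truncated tail tends to produce the signal's
#' conjugated mirror image (an "echo") growing toward the end of the grid;
#' reconstructing on a `zf_factor`-times zero-filled grid provides space
#' for that reflection and the output is truncated back to `n`.
#'
#' @param fid_full the fully sampled [fid()] (ground truth).
#' @param keep number of leading points kept, `1 <= keep < n`.
#' @param cfg an [ist_config()]; the variant field selects IST-D or IST-S.
#' @param zf_factor reconstruction-grid zero-filling factor (default 2;
#'   1 disables).
#' @return A `nus_recon` (length `n`) with `diagnostics$tail_decay_rate`:
#'   minus the slope of a linear fit of `log |fid|` over the extrapolated
#'   indices (`NA` if the tail is numerically zero).
#' @export
extrapolate <- function(fid_full, keep, cfg = ist_config("D"),
                        zf_factor = 2L) {
  fid_full <- as_fid(fid_full)
  n <- fid_full$n
  if (!is_count(keep) || keep >= n) stop_data("need 1 <= keep < n")
  if (!is_count(zf_factor)) stop_data("zf_factor must be a positive integer")
  n_rec <- zf_factor * n
  sched <- schedule(0:(keep - 1L), n_rec)
  nus <- restrict_fid(zero_fill(fid_full, zf_factor), sched)
  rec <- if (cfg$variant == "D") ist_d(nus, cfg) else ist_s(nus, cfg)
  if (zf_factor > 1L) {
    y_rec <- rec$fid$samples[seq_len(n)]
    rec <- recon_result(fft_spectrum(fid(y_rec)),
                        support = integer(),
                        residual_trace = rec$residual_trace,
                        iterations = rec$iterations,
                        converged = rec$converged, method = rec$method,
                        diagnostics = rec$diagnostics)
    rec$support <- which(Mod(rec$spectrum$values) >
                           1e-8 * max(Mod(rec$spectrum$values))) - 1L
  }
  tail_idx <- (keep + 1L):n
  mag <- Mod(rec$fid$samples[tail_idx])
  ok <- mag > 1e-12 * max(Mod(rec$fid$samples))
  rec$diagnostics$tail_decay_rate <- if (sum(ok) >= 2L) {
    tt <- (tail_idx - 1L)[ok]
    -unname(stats::coef(stats::lm(log(mag[ok]) ~ tt))[2L])
  } else NA_real_
  rec$diagnostics$keep <- keep
  rec
}

#' L-curve selection of the regularization balance
#'
#' Runs the method once per candidate `lambda`, records the (data misfit,
#' sparsity term) pairs, and picks the corner of the L-shaped log-log
#' curve: the point of maximum curvature by three-point finite
#' differences, tie-broken toward the larger (sparser) `lambda`.
#'
#' @param nus a `nus_data`.
#' @param method `"irls"` (the regularized family the curve is defined
#'   for) or `"tikhonov"`.
#' @param lam_grid increasing grid of at least 4 candidate `lambda`s.
#' @param config base [irls_config()] whose `lam` field is swept
#'   (ignored for `"tikhonov"`).
#' @return A list: `lam` (selected), `curve` (data frame `lam`, `misfit`,
#'   `penalty`, `curvature`), `flag` (`"ok"` or `"degenerate"`; a flat
#'   curve falls back to the grid midpoint).
#' @export
l_curve <- function(nus, method = "irls", lam_grid, config = NULL) {
  stopifnot(inherits(nus, "nus_data"))
  method <- match.arg(method, c("irls", "tikhonov"))
  lam_grid <- sort(unique(as.numeric(lam_grid)))
  if (length(lam_grid) < 4L) stop_data("lam_grid needs at least 4 points")
  if (any(lam_grid <= 0)) stop_data("all lambdas must be > 0")
  if (is.null(config)) config <- irls_config()
  sel <- nus$schedule$indices + 1L
  p_exp <- if (method == "irls") config$p else 2
  misfit <- penalty <- numeric(length(lam_grid))
  for (i in seq_along(lam_grid)) {
    x <- if (method == "irls") {
      cfg_i <- config; cfg_i$lam <- lam_grid[i]
      irls(nus, cfg_i)$spectrum$values
    } else {
      tikhonov(nus, lam_grid[i])$values
    }
    misfit[i] <- l2(ifft_vec(x)[sel] - nus$measured)
    penalty[i] <- sum(Mod(x)^p_exp)
  }
  xi <- log(pmax(misfit, .Machine$double.xmin))
  eta <- log(pmax(penalty, .Machine$double.xmin))
  k <- length(lam_grid)
  curv <- rep(NA_real_, k)
  for (i in 2:(k - 1L)) {
    d1x <- (xi[i + 1L] - xi[i - 1L]) / 2; d1y <- (eta[i + 1L] - eta[i - 1L]) / 2
    d2x <- xi[i + 1L] - 2 * xi[i] + xi[i - 1L]
    d2y <- eta[i + 1L] - 2 * eta[i] + eta[i - 1L]
    den <- (d1x^2 + d1y^2)^1.5
    curv[i] <- if (den > 0) (d1x * d2y - d1y * d2x) / den else NA_real_
  }
  flag <- "ok"
  # corner = the bend where the curve leaves the flat data-agreement branch:
  # the first interior local extremum of the (negative) curvature scanning
  # lambda upward; the later, larger-|curvature| cliff where peaks collapse
  # is past the corner and must not win
  finite <- which(is.finite(curv) & abs(curv) > 1e-12)
  neg <- which(is.finite(curv) & curv < -1e-12)
  local_min <- neg[vapply(neg, function(i) {
    left <- if ((i - 1L) %in% neg) curv[i - 1L] else 0
    right <- if ((i + 1L) %in% neg) curv[i + 1L] else 0
    curv[i] <= left && curv[i] <= right
  }, NA)]
  if (!length(finite)) {
    sel_i <- as.integer(ceiling(k / 2)); flag <- "degenerate"
  } else if (length(local_min)) {
    sel_i <- local_min[1L]
  } else {
    best <- max(abs(curv[finite]))
    cand <- finite[abs(curv[finite]) >= best * (1 - 1e-9)]
    sel_i <- max(cand)                 # tie-break toward larger lambda
  }
  list(lam = lam_grid[sel_i],
       curve = data.frame(lam = lam_grid, misfit = misfit, penalty = penalty,
                          curvature = curv),
       flag = flag)
}

#' Cross-validated parameter selection
#'
#' Holds out a seeded uniform fraction of the *scheduled* points,
#' reconstructs from the remaining ones for every candidate configuration,
#' scores each by the l2 misfit at the held-out measured points, and
#' returns the argmin. The held-out data do not contribute to the winning
#' reconstruction — the price of the method.
#'
#' @param nus a `nus_data`.
#' @param method a method name (see [sweep_spec()]).
#' @param param_grid list of config objects for `method` (duplicates are
#'   collapsed).
#' @param holdout_frac fraction in `(0, 0.5]` of scheduled points held out
#'   (0.25 is customary).
#' @param seed integer seed for the holdout draw.
#' @return A list: `best` (winning config), `best_index` (into the
#'   deduplicated grid), `scores` (numeric), `holdout` (zero-based held-out
#'   indices), `train_m`.
#' @export
cross_validate <- function(nus, method, param_grid, holdout_frac = 0.25,
                           seed = 1L) {
  stopifnot(inherits(nus, "nus_data"))
  method <- match.arg(method, method_registry())
  if (!is_scalar_num(holdout_frac) || holdout_frac <= 0 || holdout_frac > 0.5)
    stop_data("holdout_frac must be in (0, 0.5]")
  if (!is.list(param_grid) || !length(param_grid))
    stop_data("param_grid must be a non-empty list of configs")
  param_grid <- param_grid[!duplicated(param_grid)]
  sched <- nus$schedule
  n_hold <- round(holdout_frac * sched$m)
  if (n_hold < 1L) stop_data("holdout would be empty")
  if (sched$m - n_hold < 1L) stop_data("training set would be empty")
  hold_pos <- with_seed(seed, sort(sample.int(sched$m, n_hold)))
  train_pos <- setdiff(seq_len(sched$m), hold_pos)
  train_sched <- schedule(sched$indices[train_pos], sched$n)
  train_nus <- nus_data(nus$measured[train_pos], train_sched)
  hold_idx <- sched$indices[hold_pos]
  hold_val <- nus$measured[hold_pos]
  scores <- vapply(param_grid, function(cfg) {
    rec <- tryCatch(reconstruct_by_name(train_nus, method, cfg),
                    error = function(e) NULL)
    if (is.null(rec)) return(Inf)
    l2(rec$fid$samples[hold_idx + 1L] - hold_val)
  }, 0)
  best_index <- which.min(scores)
  list(best = param_grid[[best_index]], best_index = best_index,
       scores = scores, holdout = hold_idx,
       train_m = length(train_pos))
}

#' Re-add the reconstruction residual to the spectrum
#'
#' Adds the FT of the zero-filled final data-domain residual back onto the
#' reconstructed spectrum. Peaks the solver stopped short of appear in the
#' result (above the artifact floor), and the restriction of the output's
#' inverse FT to the schedule reproduces the measured data exactly. An
#' optional per-point weight hook is kept for non-uniform sampling
#' densities; with the uniform densities in scope it is the identity.
#'
#' @param result a `nus_recon`.
#' @param nus the `nus_data` it was computed from.
#' @param density_weights optional numeric vector of length `m` scaling the
#'   residual per scheduled point (default 1).
#' @return A `nus_spectrum`.
#' @export
readd_residual <- function(result, nus, density_weights = NULL) {
  stopifnot(inherits(result, "nus_recon"), inherits(nus, "nus_data"))
  sched <- nus$schedule
  if (result$fid$n != sched$n) stop_data("result and nus sizes differ")
  r <- nus$measured - result$fid$samples[sched$indices + 1L]
  if (!is.null(density_weights)) {
    if (length(density_weights) != sched$m)
      stop_data("density_weights must have length m")
    r <- r * density_weights
  }
  r0 <- complex(length.out = sched$n)
  r0[sched$indices + 1L] <- r
  spectrum_vec(result$spectrum$values + fft_vec(r0))
}
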