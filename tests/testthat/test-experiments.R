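test_that("the sampling rule arithmetic is right and monotone", {
  expect_equal(required_m(4, 512), 20L)  # ceil(4 ln 128)
  expect_equal(required_m(8, 16), as.integer(ceiling(8 * log(2))))
  expect_error(required_m(16, 16), class = "nuscs_data_error")
  grid <- expand.grid(K = c(1, 2, 4, 8), n = c(64, 128, 256))
  v <- mapply(required_m, grid$K, grid$n)
  expect_true(all(diff(matrix(v, 4)[, 1]) >= 0))       # monotone in K
  expect_true(all(diff(matrix(v, 4)[1, ]) >= 0))       # monotone in n
})

test_that("residual curves fall with m and reach the floor at full sampling", {
  n <- 64
  y <- synth_fid(peak_list(frequency = c(9, 30, 47), amplitude = c(1, 0.8, 0.6)),
                 n)
  cfg <- ist_config("D", threshold = 0.9,
                    epsilon = 1e-10 * sqrt(sum(Mod(y$samples)^2)),
                    n_iter = 3000)
  spec <- sweep_spec(y, levels = c(8, 16, 24, 32, 48, 64), n_schedules = 5,
                     method = "ist-d", config = cfg, seed = 17)
  cv <- residual_curve(spec)
  expect_equal(nrow(cv$summary), 6L)
  # complete data: residual at machine level
  expect_lt(cv$summary$mean_residual[6], 1e-8)
  # overall downward trend
  expect_lt(stats::cor(cv$summary$m, cv$summary$mean_residual,
                       method = "spearman"), -0.9)
  # reproducible from the same spec
  cv2 <- residual_curve(spec)
  expect_identical(cv$residuals, cv2$residuals)
  # OMP pipeline works through the same interface
  co <- residual_curve(sweep_spec(y, levels = c(16, 64), n_schedules = 3,
                                  method = "omp",
                                  config = greedy_config("omp", epsilon = 1e-9,
                                                         max_iter = 10),
                                  seed = 3))
  expect_lt(co$summary$mean_residual[2], 1e-8)
})

test_that("extrapolation completes a truncated FID and flags over-sparsity", {
  n <- 512
  pl <- peak_list(frequency = c(120, 300), amplitude = c(5, 1),
                  decay = c(0.01, 0.01))
  y <- synth_fid(pl, n)
  truth <- fft_spectrum(y)$values
  cfg <- ist_config("D", threshold = 0.95,
                    epsilon = 1e-6 * sqrt(sum(Mod(y$samples)^2)),
                    n_iter = 3000)
  rec <- extrapolate(y, n / 2, cfg)
  expect_equal(rec$fid$n, n)
  # 2x extrapolation keeps the small peak within 20%
  small_err <- abs(peak_window(rec$spectrum$values, 300) -
                     peak_window(truth, 300)) / peak_window(truth, 300)
  expect_lt(small_err, 0.2)

  # extreme truncation + over-sparse threshold: tail decay collapses
  y1 <- synth_fid(peak_list(frequency = 120, amplitude = 1, decay = 0.01), n)
  r2 <- extrapolate(y1, n / 32,
                    ist_config("D", threshold = 0.999, epsilon = 1e-10,
                               n_iter = 2000), zf_factor = 1)
  expect_lt(abs(r2$diagnostics$tail_decay_rate), 0.2 * 0.01)
  expect_error(extrapolate(y1, n), class = "nuscs_data_error")
})

test_that("L-curve selection balances misfit against sparsity", {
  n <- 64
  pl <- peak_list(frequency = c(12, 40), amplitude = c(1, 0.5))
  y <- synth_fid(pl, n, noise_sigma = 0.05, seed = 77)
  truth <- fft_spectrum(synth_fid(pl, n))$values
  nus <- restrict_fid(y, uniform_schedule(n, 24, seed = 19))
  lam_grid <- 10^seq(-5, 3, by = 0.5)
  out <- l_curve(nus, "irls", lam_grid,
                 config = irls_config(p = 1, n_iter = 10))
  expect_true(out$lam %in% lam_grid)
  # misfit is non-increasing as lambda decreases
  expect_true(all(diff(out$curve$misfit) >= -1e-9))
  # selected lambda reconstructs within 2x of the grid-best error
  errs <- vapply(lam_grid, function(l)
    rel_err(irls(nus, irls_config(p = 1, lam = l, n_iter = 10))$spectrum$values,
            truth), 0)
  sel_err <- errs[match(out$lam, lam_grid)]
  expect_lte(sel_err, 2 * min(errs) + 1e-12)
  expect_error(l_curve(nus, "irls", c(1, 2, 3)), class = "nuscs_data_error")
})

test_that("cross-validation splits correctly and finds a sane parameter", {
  n <- 128
  y <- synth_fid(peak_list(frequency = c(30, 90), amplitude = c(1, 0.7)), n)
  sched <- uniform_schedule(n, 48, seed = 23)
  nus <- restrict_fid(y, sched)
  grid <- lapply(c(0.5, 0.9, 0.998),
                 function(t) ist_config("D", threshold = t, epsilon = 1e-9,
                                        n_iter = 400))
  res <- cross_validate(nus, "ist-d", grid, holdout_frac = 0.25, seed = 31)
  expect_equal(res$train_m, 48 - round(0.25 * 48))
  expect_length(res$scores, 3L)
  # duplicated entries collapse to the same selection
  res2 <- cross_validate(nus, "ist-d", c(grid, grid[2]),
                         holdout_frac = 0.25, seed = 31)
  expect_equal(res2$best_index, res$best_index)
  # CV-selected config beats the clearly over-sparse one
  expect_lt(res$scores[res$best_index], res$scores[3])
  expect_error(cross_validate(nus, "ist-d", grid, holdout_frac = 0.7),
               class = "nuscs_data_error")
})

test_that("re-adding the residual restores exact data agreement", {
  n <- 64
  y <- synth_fid(peak_list(frequency = c(10, 40), amplitude = c(1, 0.6)), n)
  sched <- uniform_schedule(n, 32, seed = 3)
  nus <- restrict_fid(y, sched)

  # converged exact recovery: residual zero, identity
  rec <- omp(nus, greedy_config("omp", epsilon = 1e-12, max_iter = 2))
  out <- readd_residual(rec, nus)
  expect_lt(max(Mod(out$values - rec$spectrum$values)), 1e-10)

  # stopping OMP after one of two peaks: the second peak reappears
  early <- omp(nus, greedy_config("omp", epsilon = 1e-12, max_iter = 1))
  out2 <- readd_residual(early, nus)
  off_peak <- Mod(out2$values)
  off_peak[c(10, 40) + 1] <- 0
  expect_gt(Mod(out2$values[41]), 3 * max(off_peak))
  # data-domain consistency is exact
  back <- ifft_fid(out2)$samples[sched$indices + 1]
  expect_lt(max(Mod(back - nus$measured)), 1e-12)
})
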