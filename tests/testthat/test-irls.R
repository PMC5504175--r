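test_that("Tikhonov matches its closed forms", {
  n <- 32
  withr::with_seed(1, y <- fid(rcplx(n)))
  # full sampling: x = FT(y)/(1 + lambda) because the restricted rows are
  # orthonormal under the unitary convention
  full <- restrict_fid(y, schedule(0:(n - 1), n))
  expect_lt(rel_err(tikhonov(full, 0.5)$values,
                    fft_spectrum(y)$values / 1.5), 1e-12)
  expect_lt(rel_err(tikhonov(full, 1e-10)$values, fft_spectrum(y)$values),
            1e-8)

  # NUS case against the explicit-matrix evaluation
  for (trial in 1:10) {
    withr::with_seed(trial, {
      nn <- sample(8:32, 1)
      m <- sample(2:(nn - 1), 1)
      lam <- stats::runif(1, 0.01, 2)
      yy <- fid(rcplx(nn))
    })
    sched <- uniform_schedule(nn, m, seed = trial + 7)
    nus <- restrict_fid(yy, sched)
    Ft <- explicit_Ft(sched)
    oracle <- Conj(t(Ft)) %*% solve(Ft %*% Conj(t(Ft)) + lam * diag(m),
                                    nus$measured)
    expect_lt(max(Mod(tikhonov(nus, lam)$values - as.vector(oracle))), 1e-10)
  }
})

test_that("reweighted solve matches the explicit-matrix closed form", {
  for (trial in 1:10) {
    withr::with_seed(trial + 50, {
      n <- sample(8:32, 1)
      m <- sample(2:(n - 1), 1)
      lam <- stats::runif(1, 0.05, 1)
      W <- stats::runif(n, 0.5, 3)
      yy <- fid(rcplx(n))
    })
    sched <- uniform_schedule(n, m, seed = trial + 11)
    nus <- restrict_fid(yy, sched)
    Ft <- explicit_Ft(sched)
    oracle <- diag(1 / W^2) %*% Conj(t(Ft)) %*%
      solve(Ft %*% diag(1 / W^2) %*% Conj(t(Ft)) + lam * diag(m),
            nus$measured)
    got <- reweighted_solve(nus, lam, W)$values
    expect_lt(max(Mod(got - as.vector(oracle))), 1e-10)
    # unit weights collapse to Tikhonov
    expect_lt(max(Mod(reweighted_solve(nus, lam, rep(1, n))$values -
                        tikhonov(nus, lam)$values)), 1e-12)
    # scaling W by c only rescales the effective lambda (by c^2)
    cc <- 1.7
    a <- reweighted_solve(nus, lam, cc * W)$values
    b <- reweighted_solve(nus, cc^2 * lam, W)$values
    expect_lt(max(Mod(a - b)) / max(Mod(b)), 1e-10)
  }
})

test_that("the adaptive epsilon k-rule follows the printed index formula", {
  # i0 = round(64 / (4 log(512/64))) = 8 (natural log): the 8th largest
  mags <- seq(100, 1, length.out = 512)
  x <- spectrum_vec(complex(real = mags))
  i0 <- round(64 / (4 * log(512 / 64)))
  expect_equal(i0, 8)
  expect_equal(eps_k_rule(x, 64, 512, 1e-6), sort(mags, decreasing = TRUE)[8])
  expect_equal(eps_k_rule(spectrum_vec(rep(0 + 0i, 512)), 64, 512, 1e-6), 1e-6)
  expect_equal(eps_k_rule(x, 512, 512, 1e-3), 1e-3)  # m = n guard
  # monotone in eps0
  expect_gte(eps_k_rule(x, 64, 512, 1e3), eps_k_rule(x, 64, 512, 1e-6))
})

test_that("IRLS reduces to Tikhonov after one iteration and recovers sparse truth", {
  n <- 64
  y <- synth_fid(peak_list(frequency = 13, amplitude = 1), n)
  sched <- uniform_schedule(n, 16, seed = 5)
  nus <- restrict_fid(y, sched)
  one <- irls(nus, irls_config(p = 1, lam = 0.3, n_iter = 1))
  expect_lt(max(Mod(one$spectrum$values - tikhonov(nus, 0.3)$values)), 1e-12)

  # 1-sparse recovery with 20 iterations at m = n/4
  rec <- irls(nus, irls_config(p = 1, lam = 1e-6, eps0 = 1e-8, n_iter = 20))
  expect_lt(rel_err(rec$spectrum$values, fft_spectrum(y)$values), 1e-4)
})

test_that("IRLS parameter recovery holds over seeded 3-peak trials", {
  n <- 128
  errs <- vapply(1:12, function(trial) {
    withr::with_seed(trial + 300, {
      freqs <- sample(0:(n - 1), 3)
      amps <- stats::runif(3, 0.5, 2)
    })
    y <- synth_fid(peak_list(frequency = freqs, amplitude = amps), n)
    nus <- restrict_fid(y, uniform_schedule(n, 40, seed = trial))
    rec <- irls(nus, irls_config(p = 0.5, lam = 1e-6, eps0 = 1e-8,
                                 n_iter = 20))
    rel_err(rec$spectrum$values, fft_spectrum(y)$values)
  }, 0)
  expect_lte(stats::median(errs), 1e-3)
})

test_that("increasing lambda shrinks the solution monotonically", {
  n <- 64
  y <- synth_fid(peak_list(frequency = c(9, 30), amplitude = c(1, 0.4),
                           decay = c(0.02, 0.02)), n)
  nus <- restrict_fid(y, uniform_schedule(n, 24, seed = 9))
  lams <- 10^seq(-4, 4, by = 1)
  mass <- vapply(lams, function(l)
    sum(Mod(irls(nus, irls_config(p = 1, lam = l, n_iter = 5))$spectrum$values)),
    0)
  expect_true(all(diff(mass) <= 1e-8 * mass[1]))
  # high lambda neglects peaks entirely
  expect_lt(mass[length(lams)], 0.01 * mass[1])
})

test_that("delta annealing sharpens the support", {
  n <- 64
  y <- synth_fid(peak_list(frequency = c(12.4, 33.7), amplitude = c(1, 0.8),
                           decay = c(0.02, 0.02)), n)
  nus <- restrict_fid(y, uniform_schedule(n, 24, seed = 13))
  base <- irls(nus, irls_config(p = 1, lam = 1e-4, n_iter = 20, delta = 0))
  annealed <- irls(nus, irls_config(p = 1, lam = 1e-4, n_iter = 20,
                                    delta = 1 / 20))
  expect_lt(annealed$diagnostics$final_p, base$diagnostics$final_p)
  thr <- function(r) sum(Mod(r$spectrum$values) >
                           1e-3 * max(Mod(r$spectrum$values)))
  expect_lt(thr(annealed), thr(base))
})
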