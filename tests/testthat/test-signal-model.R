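test_that("synthesis follows the Lorentzian model", {
  # empty model is silence
  expect_equal(synth_fid(peak_list(), 16)$samples, rep(0 + 0i, 16))

  # one on-grid non-decaying peak occupies exactly one spectral bin
  y <- synth_fid(peak_list(frequency = 5, amplitude = 2), 64)
  s <- Mod(fft_spectrum(y)$values)
  expect_equal(which.max(s) - 1L, 5L)
  expect_equal(s[6L], 2 * sqrt(64), tolerance = 1e-12)
  expect_lt(max(s[-6L]), 1e-12)

  # decay spreads the peak into a Lorentzian but keeps the Hankel rank at 1
  y <- synth_fid(peak_list(frequency = 11.0, amplitude = 1, decay = 0.05), 64)
  d <- svd(hankel_lift(y, 32))$d
  expect_equal(sum(d > 1e-10 * d[1]), 1L)

  # noise is seeded and reproducible; frequency/decay domains are enforced
  a <- synth_fid(peak_list(frequency = 3, amplitude = 1), 32, 0.1, seed = 9)
  b <- synth_fid(peak_list(frequency = 3, amplitude = 1), 32, 0.1, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_error(synth_fid(peak_list(frequency = 64, amplitude = 1), 64),
               class = "nuscs_data_error")
  expect_error(peak_list(frequency = 1, amplitude = 1, decay = -0.1),
               class = "nuscs_data_error")
})

test_that("DFT pair is unitary and mutually inverse up to n = 4096", {
  for (n in c(1L, 7L, 64L, 4096L)) {
    withr::with_seed(n, {
      y <- rcplx(n)
      s <- fft_spectrum(fid(y))
      expect_lt(rel_err(ifft_fid(s)$samples, y), 1e-12)
      expect_equal(sqrt(sum(Mod(s$values)^2)), sqrt(sum(Mod(y)^2)),
                   tolerance = 1e-12)
    })
  }
  # unit impulse at t=0 has constant magnitude across all bins
  imp <- fid(c(1 + 0i, rep(0 + 0i, 31)))
  expect_equal(Mod(fft_spectrum(imp)$values), rep(1 / sqrt(32), 32),
               tolerance = 1e-14)
})

test_that("zero filling appends zeros and interpolates the spectrum", {
  y <- fid(1:4 + 0i)
  expect_equal(zero_fill(y, 1L)$samples, y$samples)
  z <- zero_fill(y, 2L)
  expect_equal(z$n, 8L)
  expect_equal(z$samples[5:8], rep(0 + 0i, 4))
  # even bins of the 2x spectrum reproduce the original up to the unitary
  # scale factor sqrt(1/2); oracle = explicit DFT sums
  withr::with_seed(5, yy <- rcplx(16))
  s1 <- fft_spectrum(fid(yy))$values
  s2 <- fft_spectrum(zero_fill(fid(yy), 2L))$values
  expect_equal(s2[seq(1, 32, by = 2)], s1 / sqrt(2), tolerance = 1e-12)
  oracle <- vapply(0:31, function(k)
    sum(yy * exp(-2i * pi * k * (0:15) / 32)) / sqrt(32), 0i)
  expect_equal(s2, oracle, tolerance = 1e-12)
})

test_that("Virtual Echo yields a purely real spectrum", {
  expect_equal(virtual_echo(fid(rep(0 + 0i, 8)))$samples, rep(0 + 0i, 16))

  y <- synth_fid(peak_list(frequency = 7.3, amplitude = 1, decay = 0.1), 32)
  ve <- virtual_echo(y)
  sv <- fft_spectrum(ve)$values
  expect_lt(max(abs(Im(sv))), 1e-10 * max(abs(Re(sv))))

  # conjugate-reflection symmetry by construction
  out <- ve$samples
  n2 <- length(out)
  for (t in 1:(n2 / 2 - 1)) {
    expect_equal(out[n2 - t + 1L], Conj(out[t + 1L]), tolerance = 1e-14)
  }

  # multi-peak phase-0 model stays real too
  y2 <- synth_fid(peak_list(frequency = c(3, 11.6), amplitude = c(1, 2),
                            decay = c(0.02, 0.3)), 64)
  sv2 <- fft_spectrum(virtual_echo(y2))$values
  expect_lt(max(abs(Im(sv2))), 1e-10 * max(abs(Re(sv2))))
})

test_that("Hankel lift matches the anti-diagonal pattern and rank counts peaks", {
  H <- hankel_lift(fid(c(1, 2, 3, 4) + 0i), 2L)
  expect_equal(H, matrix(c(1, 2, 3, 2, 3, 4) + 0i, 3, 2))
  expect_error(hankel_lift(fid(1:4 + 0i), 4L), class = "nuscs_data_error")
  expect_error(hankel_lift(fid(1:4 + 0i), 1L), class = "nuscs_data_error")

  # rank = K for K noiseless exponentials with distinct frequencies
  for (K in 1:5) {
    for (n in c(32L, 128L)) {
      withr::with_seed(100 * K + n, {
        pl <- peak_list(frequency = sort(stats::runif(K, 0, n - 1)),
                        amplitude = stats::runif(K, 0.5, 2),
                        decay = stats::runif(K, 0, 0.1))
        Q <- floor(n / 2) + 1L
        d <- svd(hankel_lift(synth_fid(pl, n), Q))$d
        expect_equal(sum(d > 1e-10 * d[1]), K)
      })
    }
  }
})

test_that("hankel_adjoint is the exact adjoint of hankel_lift", {
  expect_equal(hankel_adjoint(matrix(1 + 0i, 3, 2))$samples,
               c(1, 2, 2, 1) + 0i)
  for (trial in 1:10) {
    withr::with_seed(trial, {
      n <- sample(4:20, 1)
      Q <- sample(2:(n - 1), 1)
      f <- rcplx(n)
      M <- matrix(rcplx((n - Q + 1) * Q), n - Q + 1, Q)
      lhs <- sum(Conj(hankel_lift(fid(f), Q)) * M)
      rhs <- sum(Conj(f) * hankel_adjoint(M)$samples)
      expect_equal(lhs, rhs, tolerance = 1e-12)
      # composition is diagonal with the anti-diagonal multiplicities
      w <- pmin(seq_len(n), n - Q + 1L, Q, n - seq_len(n) + 1L)
      expect_equal(hankel_adjoint(hankel_lift(fid(f), Q))$samples, w * f,
                   tolerance = 1e-12)
    })
  }
})
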