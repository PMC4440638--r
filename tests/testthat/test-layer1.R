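# Layer 1: real sparse coding, Hilbert quadrature extension, and
# complex phase/amplitude inference.

test_that("Hilbert transform turns cosines into sines and preserves the spectrum", {
  T <- 128
  tt <- 0:(T - 1)
  for (k in c(2, 8, 31)) {
    h <- hilbert_transform(cos(2 * pi * k * tt / T))
    expect_lt(max(abs(h - sin(2 * pi * k * tt / T))), 1e-10)
  }
  # amplitude spectra of atom and quadrature partner agree on
  # non-DC, non-Nyquist bins
  set.seed(1)
  theta <- random_dictionary(T, 6)
  dict <- build_complex_dictionary(theta, 8000)
  sp_re <- Mod(stats::mvfft(dict$A_re))
  sp_im <- Mod(stats::mvfft(dict$A_im))
  bins <- 2:(T / 2)
  expect_lt(max(abs(sp_re[bins, ] - sp_im[bins, ])), 1e-10)
})

test_that("complex dictionary metadata reports peak frequency and cycle count", {
  dict <- cosine_dictionary(T = 128, cycles = 8, sampling_rate = 8000)
  expect_equal(dict$peak_freq, 500)
  expect_equal(dict$n_cycles, 8)
  # dominant-DC atom warns but is still transformed
  flat <- matrix(1 + 0.01 * sin(2 * pi * (0:63) / 64), ncol = 1)
  expect_warning(build_complex_dictionary(flat, 8000), "DC")
})

test_that("real energy matches its closed forms and its analytic gradient", {
  set.seed(2)
  T <- 24; N <- 10
  theta <- random_dictionary(T, N)
  x <- rnorm(T)
  # zero code: pure residual term
  expect_equal(real_energy(x, rep(0, N), theta, 0.2, 2), sum(x^2) / 2)
  # perfect one-atom reconstruction at lambda = 0
  e3 <- real_energy(theta[, 3], replace(rep(0, N), 3, 1), theta,
                    lambda = 0, sigma_sq = 2)
  expect_equal(e3, 0, tolerance = 1e-12)
  # finite-difference oracle at random points
  for (r in 1:3) {
    c0 <- rnorm(N)
    g <- binsparse:::.real_grad(matrix(x, ncol = 1), matrix(c0, ncol = 1),
                                theta, 0.2, 2)
    fd <- finite_diff(function(cc) real_energy(x, cc, theta, 0.2, 2), c0)
    expect_lt(max(abs(g - fd)), 1e-6)
  }
})

test_that("planted dictionaries are recovered across seeds (bipartite cosine matching)", {
  for (seed in c(11, 12, 13)) {
    res <- cached_l1_recovery(seed)
    expect_gte(mean(res$match > 0.9), 0.9)
  }
})

test_that("learning energy trend decreases after smoothing", {
  res <- cached_l1_recovery(11)
  tr <- res$fit$energy_trace
  smooth <- stats::filter(tr, rep(1 / 100, 100), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  early <- mean(utils::head(smooth, 100))
  late <- mean(utils::tail(smooth, 100))
  expect_lt(late, early)
})

test_that("single-atom epochs are recovered with accurate amplitude and phase", {
  set.seed(5)
  dict <- cosine_dictionary(T = 64, phases = runif(6, 0, 2 * pi))
  a0 <- 2.5; phi0 <- 0.8; atom <- 3
  x <- a0 * (cos(phi0) * dict$A_re[, atom] + sin(phi0) * dict$A_im[, atom])
  code <- infer_complex(x, dict, lambda = 1e-4, sigma_sq = 2, n_steps = 40)
  expect_lt(abs(code$a[atom, 1] - a0) / a0, 0.05)
  expect_lt(abs(code$phi[atom, 1] - phi0), 0.05)
  expect_true(all(code$a[-atom, 1] < 0.05 * a0))
})

test_that("zero input drives all amplitudes to zero", {
  dict <- cosine_dictionary(T = 64)
  code <- infer_complex(rep(0, 64), dict, lambda = 0.2, sigma_sq = 2,
                        n_steps = 40)
  expect_true(all(code$a < 1e-3))
})

test_that("inference never accepts an energy-increasing step", {
  set.seed(6)
  dict <- cosine_dictionary(T = 64)
  x <- rnorm(64)
  energies <- vapply(c(1, 5, 10, 20), function(ns)
    infer_complex(x, dict, n_steps = ns)$energy, numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("a sub-sample delay shifts low-frequency phases by 2*pi*f*dt and spares amplitudes", {
  T <- 64; fs <- 8000
  set.seed(7)
  dict <- cosine_dictionary(T = T, cycles = c(3, 5), sampling_rate = fs)
  # band-limited epoch built from the atoms themselves, delayed via the
  # analytic-signal phase ramp
  shift <- 0.4                          # samples
  x <- 1.8 * (cos(0.5) * dict$A_re[, 1] + sin(0.5) * dict$A_im[, 1]) +
    1.2 * (cos(-0.9) * dict$A_re[, 2] + sin(-0.9) * dict$A_im[, 2])
  X <- stats::fft(x)
  freqs <- c(0:(T / 2), -(T / 2 - 1):-1) / T
  xs <- Re(stats::fft(X * exp(-2i * pi * freqs * shift), inverse = TRUE)) / T
  c0 <- infer_complex(x, dict, lambda = 1e-3, n_steps = 60)
  c1 <- infer_complex(xs, dict, lambda = 1e-3, n_steps = 60)
  for (i in 1:2) {
    expected <- 2 * pi * dict$peak_freq[i] * shift / fs
    expect_equal(wrap_angle(c1$phi[i, 1] - c0$phi[i, 1]), expected,
                 tolerance = 0.02)
    expect_lt(abs(c1$a[i, 1] - c0$a[i, 1]) / c0$a[i, 1], 0.02)
  }
})
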