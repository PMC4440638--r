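# Layer 2: joint amplitude/IPD energy, inference and learning.

toy_model <- function(seed = 1, M = 6, n_amp = 10, P = 4,
                      hyper = layer2_hyper()) {
  set.seed(seed)
  list(B = matrix(rnorm(n_amp * M), n_amp),
       xi = matrix(rnorm(P * M), P), hyper = hyper)
}

test_that("layer-2 energy matches its closed forms", {
  model <- toy_model()
  M <- ncol(model$B); n_amp <- nrow(model$B); P <- nrow(model$xi)
  # zero obs, zero code, w at the prior location: only the circular
  # term survives, at its minimum -kappa*P
  e0 <- layer2_energy(rep(0, M), model$hyper$mu_w, rep(0, n_amp),
                      rep(0, P), model)
  expect_equal(e0, -model$hyper$kappa * P)
  # zero code on arbitrary obs
  set.seed(2)
  a <- rnorm(n_amp); dphi <- runif(P, -pi, pi)
  e1 <- layer2_energy(rep(0, M), model$hyper$mu_w, a, dphi, model)
  expect_equal(e1, sum(a^2) / model$hyper$sigma_sq -
                 model$hyper$kappa * sum(cos(dphi)))
})

test_that("analytic layer-2 gradients agree with central finite differences", {
  model <- toy_model(seed = 3)
  M <- ncol(model$B)
  set.seed(4)
  for (r in 1:3) {
    s0 <- rnorm(M); w0 <- runif(1, 0.5, 1.5)
    a <- rnorm(nrow(model$B)); dphi <- runif(nrow(model$xi), -pi, pi)
    g <- binsparse:::.l2_grad(matrix(s0, ncol = 1), w0,
                              matrix(a, ncol = 1), matrix(dphi, ncol = 1),
                              model$B, model$xi, model$hyper)
    fd_s <- finite_diff(function(s) layer2_energy(s, w0, a, dphi, model), s0)
    fd_w <- finite_diff(function(w) layer2_energy(s0, w, a, dphi, model), w0)
    expect_lt(max(abs(g[seq_len(M), 1] - fd_s)), 1e-6)
    expect_lt(abs(g[M + 1, 1] - fd_w), 1e-6)
  }
})

test_that("energy is invariant to 2*pi shifts of any observed IPD", {
  model <- toy_model(seed = 5)
  set.seed(5)
  s <- rnorm(ncol(model$B)); w <- 1.2
  a <- rnorm(nrow(model$B)); dphi <- runif(nrow(model$xi), -pi, pi)
  e <- layer2_energy(s, w, a, dphi, model)
  for (m in seq_along(dphi)) {
    shifted <- dphi
    shifted[m] <- shifted[m] + 2 * pi
    expect_equal(layer2_energy(s, w, a, shifted, model), e,
                 tolerance = 1e-10)
  }
})

test_that("inference finds a planted sparse support", {
  set.seed(6)
  M <- 16; n_amp <- 32; P <- 8
  B <- matrix(rnorm(n_amp * M), n_amp); xi <- matrix(rnorm(P * M), P)
  nr <- sqrt(colSums(B^2) + colSums(xi^2))
  model <- list(B = sweep(B, 2, nr, "/"), xi = sweep(xi, 2, nr, "/"),
                hyper = layer2_hyper(sigma_sq = 0.3^2, kappa = 8))
  support <- c(2, 9, 14)
  s_star <- replace(rep(0, M), support, c(3, -2.5, 2))
  a <- model$B %*% s_star + 0.05 * rnorm(n_amp)
  dphi <- wrap_angle(1.1 * model$xi %*% s_star + 0.1 * rnorm(P))
  code <- infer_layer2(list(a = matrix(a, ncol = 1),
                            dphi = matrix(dphi, ncol = 1)),
                       model, n_steps = 100)
  expect_setequal(order(-abs(code$s[, 1]))[1:3], support)
})

test_that("zero observations collapse the code onto the prior", {
  model <- toy_model(seed = 7)
  code <- infer_layer2(list(a = matrix(0, nrow(model$B), 1),
                            dphi = matrix(0, nrow(model$xi), 1)),
                       model, n_steps = 200)
  expect_true(all(abs(code$s) < 1e-3))
  expect_lt(abs(code$w - model$hyper$mu_w), 1e-3)
})

test_that("inference energy is non-increasing in the step budget", {
  model <- toy_model(seed = 8)
  set.seed(8)
  obs <- list(a = matrix(rnorm(nrow(model$B)), ncol = 1),
              dphi = matrix(runif(nrow(model$xi), -pi, pi), ncol = 1))
  energies <- vapply(c(1, 5, 20, 50), function(ns)
    infer_layer2(obs, model, n_steps = ns)$energy, numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("planted layer-2 dictionaries are recovered with high joint cosine", {
  for (seed in c(8, 21, 35)) {
    res <- cached_l2_recovery(seed)
    expect_gte(sum(res$match > 0.8), 6)
  }
})

test_that("amplitude-dominance / IPD-sign coupling survives learning", {
  res <- cached_l2_recovery(8, coupled = TRUE)
  badv <- apply(res$fit$B, 2, bad)
  xim <- apply(res$fit$xi, 2, ipd_atom_average)
  expect_true(all(xim[badv > 0.05] < 0))
  expect_true(all(xim[badv < -0.05] > 0))
})

test_that("swapping ears in observation and model leaves energies identical", {
  model <- toy_model(seed = 9, n_amp = 10)
  set.seed(9)
  n <- nrow(model$B) / 2
  s <- rnorm(ncol(model$B)); w <- 0.9
  a <- rnorm(2 * n); dphi <- runif(nrow(model$xi), -pi, pi)
  e <- layer2_energy(s, w, a, dphi, model)
  swap <- c(n + seq_len(n), seq_len(n))
  model_sw <- model
  model_sw$B <- model$B[swap, , drop = FALSE]
  model_sw$xi <- -model$xi
  e_sw <- layer2_energy(s, w, a[swap], -dphi, model_sw)
  expect_equal(e_sw, e, tolerance = 1e-12)
})

test_that("learning energy trend decreases after smoothing", {
  res <- cached_l2_recovery(8)
  tr <- res$fit$energy_trace
  smooth <- stats::filter(tr, rep(1 / 100, 100), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_lt(mean(utils::tail(smooth, 100)), mean(utils::head(smooth, 100)))
})
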