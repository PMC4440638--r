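# Gaussian sector decoding, confusion matrices and mutual information.

test_that("response averaging uses disjoint groups with 1/D variance scaling", {
  s <- matrix(1:12, 2)
  expect_equal(average_responses(s, 1), s)
  expect_equal(average_responses(s, 3),
               cbind(rowMeans(s[, 1:3]), rowMeans(s[, 4:6])))
  v <- c(2, -1)
  expect_equal(average_responses(matrix(rep(v, 5), 2), 5), matrix(v))
  expect_error(average_responses(s, 7), "exceeds")
  # Monte-Carlo: variance of averaged entries scales like 1/D
  set.seed(1)
  vars <- vapply(c(1, 4, 16), function(D) {
    d <- average_responses(matrix(rnorm(2 * 6400), 2), D)
    mean(apply(d, 1, var))
  }, numeric(1))
  expect_equal(vars[1] / vars[2], 4, tolerance = 0.35)
  expect_equal(vars[2] / vars[3], 4, tolerance = 0.35)
})

test_that("decoder means are class means and the two-class boundary is symmetric", {
  set.seed(2)
  d <- cbind(matrix(rnorm(40, -1, 0.1), 1), matrix(rnorm(40, 1, 0.1), 1))
  lab <- rep(1:2, each = 40)
  dec <- fit_decoder(d, lab, n_classes = 2, delta_scale = 0)
  expect_equal(dec$means[1, 1], mean(d[lab == 1]))
  expect_equal(dec$means[1, 2], mean(d[lab == 2]))
  expect_equal(predict(dec, matrix(c(-0.5, 0.5, -2, 2), 1)),
               c(1L, 2L, 1L, 2L))
  expect_error(fit_decoder(d[, 1, drop = FALSE], 1, n_classes = 1),
               "at least 2")
})

test_that("log-likelihoods match the direct multivariate-normal density oracle", {
  set.seed(3)
  K <- 4; n <- 60
  d <- matrix(rnorm(K * n), K) + rep(c(0, 1, -1, 2), n / 4 * K)[1:(K * n)]
  lab <- rep(1:3, each = n / 3)
  dec <- fit_decoder(d, lab, n_classes = 3, delta_scale = 0)
  ll <- binsparse:::.decoder_loglik(dec, d[, 1:5, drop = FALSE])
  for (k in 1:3) {
    xk <- d[, lab == k, drop = FALSE]
    mu <- rowMeans(xk)
    C <- stats::cov(t(xk)) + diag(1e-12, K)
    for (j in 1:5) {
      x <- d[, j] - mu
      direct <- -0.5 * (t(x) %*% solve(C, x) +
                          determinant(C)$modulus + K * log(2 * pi))
      expect_equal(ll[j, k], as.numeric(direct), tolerance = 1e-6)
    }
  }
})

test_that("decoding matches a brute-force per-class density evaluation", {
  set.seed(4)
  K <- 3; per <- 50; n_classes <- 5
  mus <- matrix(rnorm(K * n_classes, sd = 2), K)
  d <- NULL; lab <- integer(0)
  for (k in seq_len(n_classes)) {
    d <- cbind(d, mus[, k] + matrix(rnorm(K * per, sd = 0.5), K))
    lab <- c(lab, rep(k, per))
  }
  dec <- fit_decoder(d, lab, n_classes = n_classes)
  pred <- predict(dec, d)
  ll <- binsparse:::.decoder_loglik(dec, d)
  brute <- apply(ll, 1, which.max)
  expect_equal(pred, brute)
  expect_gt(mean(pred == lab), 0.9)
})

test_that("mutual information has the right analytic values and bounds", {
  # errorless 18-class decoding with uniform classes
  perfect <- diag(18) / 18
  expect_equal(mutual_information(perfect), log2(18), tolerance = 1e-12)
  # independence: outer product of marginals
  set.seed(5)
  p <- runif(18); p <- p / sum(p)
  q <- runif(18); q <- q / sum(q)
  expect_equal(mutual_information(outer(p, q)), 0, tolerance = 1e-10)
  # direct 4-cell summation oracle
  cm <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  direct <- sum(cm * log2(cm / outer(rowSums(cm), colSums(cm))))
  expect_equal(mutual_information(cm), direct)
  expect_error(mutual_information(cm * 2), "normalized")
  # bounds and label-permutation invariance on random confusions
  for (r in 1:20) {
    M <- matrix(rexp(18 * 18), 18); M <- M / sum(M)
    mi <- mutual_information(M)
    H <- function(v) -sum(v[v > 0] * log2(v[v > 0]))
    expect_gte(mi, 0)
    expect_lte(mi, min(H(rowSums(M)), H(colSums(M))) + 1e-12)
    perm <- sample(18)
    expect_equal(mutual_information(M[perm, perm]), mi, tolerance = 1e-12)
  }
})

test_that("information curves respect the log2(18) ceiling and grow with K", {
  # well-separated synthetic population: 24 units with sigmoid gains;
  # enough epochs per sector that class covariances stay well estimated
  # after averaging (small-sample covariance error would otherwise mask
  # the monotonicity)
  pos <- sector_centers()
  set.seed(6)
  sector <- rep(1:18, each = 160)
  M <- 24
  s <- matrix(0, M, length(sector))
  for (i in 1:M) {
    side <- if (i %% 2) -1 else 1
    gain <- 1 / (1 + exp(-side * (pos - runif(1, -40, 40)) / 25))
    s[i, ] <- gain[sector] + rnorm(length(sector), sd = 0.35)
  }
  ic <- information_curves(s, sector, unit_counts = c(1, 4, 12),
                           D_values = c(1, 4), n_repeats = 5, seed = 7)
  expect_true(all(ic$MI_bits <= log2(18) + 1e-9))
  expect_true(all(ic$MI_bits >= 0))
  for (D in c(1, 4)) {
    mi_k <- ic$MI_bits[ic$D == D]
    expect_true(all(diff(mi_k) > -0.15))   # non-decreasing within MC error
  }
  # averaging over more samples helps at fixed K
  expect_gt(ic$MI_bits[ic$K == 12 & ic$D == 4],
            ic$MI_bits[ic$K == 12 & ic$D == 1])
})
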