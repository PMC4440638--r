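# Independent oracles used across tests.

# Greedy bipartite matching on an absolute-cosine similarity matrix:
# repeatedly take the globally best (row, column) pair. Returns the
# matched similarity per reference atom.
greedy_match <- function(ref, learned) {
  cs <- abs(crossprod(ref, learned))
  n <- ncol(ref)
  best <- numeric(n)
  for (i in seq_len(n)) {
    ix <- which(cs == max(cs), arr.ind = TRUE)[1, ]
    best[i] <- cs[ix[1], ix[2]]
    cs[ix[1], ] <- -1
    cs[, ix[2]] <- -1
  }
  best
}

# Central finite differences of a scalar function at x.
finite_diff <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Adjusted Rand index between two labelings (direct pair-counting).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Unit-norm random dictionary.
random_dictionary <- function(T, N) {
  theta <- matrix(stats::rnorm(T * N), T)
  sweep(theta, 2, sqrt(colSums(theta^2)), "/")
}

# Sparse heavy-tailed coefficients: Cauchy magnitudes (truncated),
# Bernoulli support.
sparse_cauchy <- function(N, E, p_active = 0.15, scale = 1) {
  C <- matrix(stats::rcauchy(N * E) * stats::rbinom(N * E, 1, p_active),
              N, E)
  C[abs(C) > 20] <- 0
  C * scale
}

# Planted layer-2 model plus data drawn from it. `coupled = TRUE` ties
# left/right amplitude dominance to the IPD-atom sign.
planted_layer2 <- function(seed, M = 8, n_amp = 32, P = 8, E = 4000,
                           coupled = FALSE, noise_a = 0.1,
                           noise_phi = 0.15) {
  set.seed(seed)
  if (coupled) {
    B0 <- matrix(rnorm(n_amp * M), n_amp)
    xi0 <- matrix(0, P, M)
    for (i in seq_len(M)) {
      left_dom <- i <= M / 2
      B0[, i] <- B0[, i] +
        rep(c(0.8, -0.8) * (if (left_dom) 1 else -1), each = n_amp / 2)
      xi0[, i] <- (if (left_dom) -1 else 1) *
        abs(rnorm(P, mean = 1, sd = 0.3))
    }
  } else {
    B0 <- matrix(rnorm(n_amp * M), n_amp)
    xi0 <- matrix(rnorm(P * M), P)
  }
  nr <- sqrt(colSums(B0^2) + colSums(xi0^2))
  B0 <- sweep(B0, 2, nr, "/")
  xi0 <- sweep(xi0, 2, nr, "/")
  S0 <- sparse_cauchy(M, E, p_active = 0.2)
  w0 <- runif(E, 0.8, 1.2)
  A <- B0 %*% S0 + noise_a * matrix(rnorm(n_amp * E), n_amp)
  DP <- wrap_angle(sweep(xi0 %*% S0, 2, w0, "*") +
                     noise_phi * matrix(rnorm(P * E), P))
  list(B0 = B0, xi0 = xi0, S0 = S0, w0 = w0,
       obs = structure(list(a = A, dphi = DP, selection = NULL),
                       class = "joint_obs"))
}

# A small analytic complex dictionary of integer-cycle cosine atoms.
cosine_dictionary <- function(T = 64, cycles = c(3, 5, 7, 9, 11, 13),
                              sampling_rate = 8000, phases = NULL) {
  tt <- 0:(T - 1)
  if (is.null(phases)) phases <- rep(0, length(cycles))
  theta <- mapply(function(k, ph) {
    v <- cos(2 * pi * k * tt / T + ph)
    v / sqrt(sum(v^2))
  }, cycles, phases)
  build_complex_dictionary(theta, sampling_rate)
}
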