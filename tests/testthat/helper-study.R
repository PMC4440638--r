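# Memoised desk-scale end-to-end runs shared by the acceptance tests:
# the full study is expensive, so each seed is computed at most once
# per test session.

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(seed) {
  key <- paste0("seed", seed)
  if (!exists(key, envir = .study_cache)) {
    assign(key, opponent_channel_study(seed = seed), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# Memoised layer-1 planted-recovery runs (shared between the unit test
# and the acceptance criterion).
.l1_cache <- new.env(parent = emptyenv())

cached_l1_recovery <- function(seed, T = 64, N = 16, E = 6000) {
  key <- paste0("seed", seed)
  if (!exists(key, envir = .l1_cache)) {
    set.seed(seed)
    theta0 <- random_dictionary(T, N)
    C <- sparse_cauchy(N, E)
    X <- theta0 %*% C + 0.05 * matrix(rnorm(T * E), T)
    fit <- learn_real_dictionary(X, N, lambda = 0.2, sigma_sq = 2,
                                 n_iter = 1500, batch_size = 100,
                                 seed = seed + 1)
    assign(key, list(theta0 = theta0, fit = fit,
                     match = greedy_match(theta0, fit$theta)),
           envir = .l1_cache)
  }
  get(key, envir = .l1_cache)
}

# Memoised layer-2 planted-recovery runs.
.l2_cache <- new.env(parent = emptyenv())

cached_l2_recovery <- function(seed, coupled = FALSE) {
  key <- paste0("seed", seed, "c", coupled)
  if (!exists(key, envir = .l2_cache)) {
    pl <- planted_layer2(seed, coupled = coupled)
    fit <- fit_layer2(pl$obs, M = 8,
                      hyper = layer2_hyper(sigma_sq = 0.3^2, kappa = 8),
                      n_iter = 1500, n_steps = 60, center = FALSE,
                      seed = seed + 100)
    assign(key, list(planted = pl, fit = fit,
                     match = greedy_match(rbind(pl$B0, pl$xi0),
                                          rbind(fit$B, fit$xi))),
           envir = .l2_cache)
  }
  get(key, envir = .l2_cache)
}
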