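# Layer 2: joint sparse generative model of concatenated log-amplitudes
# and interaural phase differences.
#
#   a_n      = sum_i s_i B_{i,n}          + Gaussian(0, sigma2) noise
#   dphi_m   = |w| sum_i s_i xi_{i,m}     + von Mises(kappa) noise
#
# Energy (negative log-posterior up to constants):
#   E2 = (1/sigma2^2) sum_n (a_n - ahat_n)^2
#        - kappa sum_m cos(dphi_m - dphihat_m)
#        + lambda2 sum_i log(1 + s_i^2)
#        + lambda_w (|w - mu_w| / alpha)^beta
# The circular term is the true negative log von Mises likelihood; its
# analytic gradients are used throughout (finite-difference checked).

#' Hyperparameters of the layer-2 model
#'
#' @param sigma_sq Gaussian noise variance of log-amplitudes (default 2).
#' @param kappa von Mises concentration of the IPD noise (default 2).
#' @param lambda2 Cauchy sparsity weight on coefficients (default 1).
#' @param lambda_w weight of the phase-multiplier prior (default 0.01).
#' @param alpha scale of the generalized-Gaussian prior on `w`
#'   (default 0.5).
#' @param beta shape of that prior (default 8; large values approximate
#'   a uniform band).
#' @param mu_w location of that prior (default 1; bounds `|w|` into a
#'   band away from zero).
#' @return list of class `layer2_hyper`.
#' @export
layer2_hyper <- function(sigma_sq = 2, kappa = 2, lambda2 = 1,
                         lambda_w = 0.01, alpha = 0.5, beta = 8, mu_w = 1) {
  stopifnot(sigma_sq > 0, kappa > 0, alpha > 0, beta >= 2)
  structure(list(sigma_sq = sigma_sq, kappa = kappa, lambda2 = lambda2,
                 lambda_w = lambda_w, alpha = alpha, beta = beta,
                 mu_w = mu_w),
            class = "layer2_hyper")
}

# Batched energies. S: M x E, w: length E, a: n_amp x E, dphi: P x E.
.l2_energy_batch <- function(S, w, a, dphi, B, xi, h) {
  Ra <- a - B %*% S
  V <- xi %*% S
  U <- dphi - V * rep(abs(w), each = nrow(V))
  colSums(Ra^2) / h$sigma_sq - h$kappa * colSums(cos(U)) +
    h$lambda2 * colSums(log1p(S^2)) +
    h$lambda_w * (abs(w - h$mu_w) / h$alpha)^h$beta
}

# Gradients wrt (S, w), stacked as rbind(S-grad, w-grad-row).
.l2_grad <- function(S, w, a, dphi, B, xi, h) {
  Ra <- a - B %*% S
  V <- xi %*% S
  U <- dphi - V * rep(abs(w), each = nrow(V))
  sinU <- sin(U)
  xs <- crossprod(xi, sinU)
  gS <- -(2 / h$sigma_sq) * crossprod(B, Ra) -
    h$kappa * xs * rep(abs(w), each = nrow(xs)) +
    2 * h$lambda2 * S / (1 + S^2)
  gw <- -h$kappa * sign(w) * colSums(V * sinU) +
    h$lambda_w * (h$beta / h$alpha) *
      (abs(w - h$mu_w) / h$alpha)^(h$beta - 1) * sign(w - h$mu_w)
  rbind(gS, gw)
}

#' Layer-2 energy of a code given an observation
#'
#' Negative log-posterior (up to constants) of a layer-2 code: Gaussian
#' log-amplitude residual, negative-cosine von Mises term for the IPDs,
#' Cauchy sparsity penalty on `s`, and a generalized-Gaussian penalty on
#' the phase multiplier `w`.
#'
#' @param s coefficient vector (length M).
#' @param w scalar phase multiplier.
#' @param a observed log-amplitude vector.
#' @param dphi observed wrapped IPD vector.
#' @param model a `layer2_model` (or any list with `B`, `xi`, `hyper`).
#' @return scalar energy.
#' @export
layer2_energy <- function(s, w, a, dphi, model) {
  as.numeric(.l2_energy_batch(matrix(s, ncol = 1), w, matrix(a, ncol = 1),
                              matrix(dphi, ncol = 1), model$B, model$xi,
                              model$hyper))
}

#' MAP inference of layer-2 codes
#'
#' Joint gradient descent on coefficients `s` and the per-epoch phase
#' multiplier `w`, batched over observations with per-observation
#' backtracking. Warm start: `s = 0`, `w = mu_w`.
#'
#' @param obs a `joint_obs` (or list with `a`, `dphi` matrices).
#' @param model a `layer2_model`.
#' @param n_steps gradient steps (default 50).
#' @return object of class `layer2_code`: `s` (`M x E`), `w` (length E),
#'   `energy` (per observation).
#' @export
infer_layer2 <- function(obs, model, n_steps = 50) {
  a <- as.matrix(obs$a); dphi <- as.matrix(obs$dphi)
  if (!is.null(model$a_center)) a <- a - model$a_center
  stopifnot_finite(a, "a"); stopifnot_finite(dphi, "dphi")
  M <- ncol(model$B); E <- ncol(a); h <- model$hyper
  P0 <- rbind(matrix(0, M, E), rep(h$mu_w, E))
  fit <- .descend(
    P0,
    grad_fn = function(P)
      .l2_grad(P[seq_len(M), , drop = FALSE], P[M + 1, ], a, dphi,
               model$B, model$xi, h),
    energy_fn = function(P) {
      e <- .l2_energy_batch(P[seq_len(M), , drop = FALSE], P[M + 1, ],
                            a, dphi, model$B, model$xi, h)
      if (!all(is.finite(e))) stop("non-finite layer-2 energy",
                                   call. = FALSE)
      e
    },
    n_steps = n_steps, step0 = h$sigma_sq / 4)
  structure(list(s = fit$P[seq_len(M), , drop = FALSE],
                 w = fit$P[M + 1, ], energy = fit$energy),
            class = "layer2_code")
}

#' @export
print.layer2_code <- function(x, ...) {
  cat(sprintf("layer-2 code: %d units x %d epochs, mean |s| %.3g, mean w %.3g\n",
              nrow(x$s), ncol(x$s), mean(abs(x$s)), mean(x$w)))
  invisible(x)
}

#' Fit the layer-2 joint amplitude/IPD model
#'
#' Learns coupled amplitude atoms `B` (log-amplitude patterns over both
#' ears) and IPD atoms `xi` by alternating batched MAP inference of
#' `(s, w)` with dictionary gradient updates. Each concatenated atom
#' `(B_i || xi_i)` is renormalized to unit L2 norm after every update.
#' The raw dictionary gradients are preconditioned per atom by the batch
#' coefficient energy (a diagonal Newton scaling), which makes the step
#' size invariant to how strongly an atom is used; atoms are initialized
#' from randomly drawn training observations.
#'
#' By default the log-amplitude observations are centered by their
#' training mean (the baseline carries no structure a sparse code
#' should spend coefficients on); the center is stored in the model and
#' applied automatically during inference.
#'
#' @param obs a `joint_obs` with training observations.
#' @param M number of atoms (default 256).
#' @param hyper a [layer2_hyper()].
#' @param n_iter number of dictionary gradient updates.
#' @param batch_size observations per update (default 100).
#' @param n_steps inference gradient steps per batch (default 50).
#' @param learning_rate initial preconditioned step (decays as
#'   `1/(1 + iter/n_iter)`).
#' @param center center log-amplitudes by their training mean
#'   (default TRUE).
#' @param seed integer seed.
#' @return object of class `layer2_model`: `B` (`n_amp x M`), `xi`
#'   (`P x M`), `hyper`, `a_center`, `selection` (from `obs`),
#'   `energy_trace`.
#' @export
fit_layer2 <- function(obs, M = 256, hyper = layer2_hyper(), n_iter = 2000,
                       batch_size = 100, n_steps = 50, learning_rate = 0.5,
                       center = TRUE, seed = 1L) {
  a <- as.matrix(obs$a); dphi <- as.matrix(obs$dphi)
  n_amp <- nrow(a); P <- nrow(dphi); E <- ncol(a)
  a_center <- if (center) rowMeans(a) else rep(0, n_amp)
  a <- a - a_center
  with_seed(seed, {
    take0 <- sample.int(E, M, replace = M > E)
    B <- a[, take0, drop = FALSE] +
      matrix(stats::rnorm(n_amp * M, sd = 0.01), n_amp)
    xi <- dphi[, take0, drop = FALSE] +
      matrix(stats::rnorm(P * M, sd = 0.01), P)
    nr <- sqrt(colSums(B^2) + colSums(xi^2))
    B <- sweep(B, 2, nr, "/"); xi <- sweep(xi, 2, nr, "/")
    trace <- numeric(n_iter)
    model <- list(B = B, xi = xi, hyper = hyper)
    for (it in seq_len(n_iter)) {
      take <- sample.int(E, batch_size, replace = batch_size > E)
      ab <- a[, take, drop = FALSE]; db <- dphi[, take, drop = FALSE]
      code <- infer_layer2(list(a = ab, dphi = db), model, n_steps)
      S <- code$s; w <- code$w
      Ra <- ab - model$B %*% S
      U <- db - sweep(model$xi %*% S, 2, abs(w), "*")
      lr <- learning_rate / (1 + it / n_iter)
      # descent directions with per-atom coefficient-energy scaling
      s2 <- rowSums(S^2)
      sw2 <- rowSums(sweep(S, 2, abs(w), "*")^2)
      dB <- sweep(Ra %*% t(S), 2, s2 + 1e-3 * max(s2) + 1e-12, "/")
      dxi <- sweep(sweep(sin(U), 2, abs(w), "*") %*% t(S), 2,
                   sw2 + 1e-3 * max(sw2) + 1e-12, "/")
      model$B <- model$B + lr * dB
      model$xi <- model$xi + lr * dxi
      nr <- sqrt(colSums(model$B^2) + colSums(model$xi^2))
      nr[nr < 1e-12] <- 1
      model$B <- sweep(model$B, 2, nr, "/")
      model$xi <- sweep(model$xi, 2, nr, "/")
      trace[it] <- mean(code$energy)
      if (it > 400 && it %% 100 == 0) {
        recent <- mean(trace[(it - 99):it])
        past <- mean(trace[(it - 399):(it - 300)])
        if (recent > 1.5 * abs(past) + past)
          stop("layer-2 learning diverged (energy increasing persistently)",
               call. = FALSE)
      }
    }
    structure(list(B = model$B, xi = model$xi, hyper = hyper, M = M,
                   a_center = a_center, selection = obs$selection,
                   energy_trace = trace),
              class = "layer2_model")
  })
}

#' Encode observations with a fitted layer-2 model
#'
#' @param object a `layer2_model`.
#' @param newdata a `joint_obs`.
#' @param n_steps inference gradient steps (default 50).
#' @param ... unused.
#' @return a `layer2_code`.
#' @export
predict.layer2_model <- function(object, newdata, n_steps = 50, ...) {
  infer_layer2(newdata, object, n_steps)
}

#' @export
print.layer2_model <- function(x, ...) {
  cat(sprintf("Layer-2 joint amplitude/IPD model: M = %d atoms (%d log-amplitudes + %d IPD channels)\n",
              ncol(x$B), nrow(x$B), nrow(x$xi)))
  h <- x$hyper
  cat(sprintf("  sigma2^2 = %g, kappa = %g, lambda2 = %g, lambda_w = %g, w-prior: mu = %g, alpha = %g, beta = %g\n",
              h$sigma_sq, h$kappa, h$lambda2, h$lambda_w, h$mu_w, h$alpha,
              h$beta))
  invisible(x)
}

#' @export
summary.layer2_model <- function(object, ...) {
  print(object)
  st <- layer2_atom_stats(object)
  cat(sprintf("  BSI: median %.2f; BAD range [%.2f, %.2f]; xi-average bimodality: %d left (<0), %d right (>0)\n",
              stats::median(st$bsi, na.rm = TRUE),
              min(st$bad), max(st$bad),
              sum(st$xi_mean < 0, na.rm = TRUE),
              sum(st$xi_mean > 0, na.rm = TRUE)))
  if (length(object$energy_trace))
    cat(sprintf("  final smoothed training energy: %.4g\n",
                mean(utils::tail(object$energy_trace, 100))))
  invisible(object)
}

#' @export
coef.layer2_model <- function(object, ...) {
  list(B = object$B, xi = object$xi)
}
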