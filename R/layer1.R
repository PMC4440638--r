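# Layer 1: real-valued sparse coding of mono sound epochs, Hilbert
# extension to a complex (phase/amplitude) dictionary, and MAP inference
# of per-ear amplitude and phase vectors.
#
# Model: x_t = sum_i c_i Theta_{i,t} + noise, Cauchy prior on c.
# Energy (negative log-posterior up to constants):
#   E_s = (1/sigma^2) sum_t (x_t - xhat_t)^2 + lambda sum_i log(1 + c_i^2)
# The complex stage replaces c_i Theta_i with
# a_i (cos(phi_i) A^re_i + sin(phi_i) A^im_i), a_i >= 0, and penalizes
# log(1 + a_i^2).

#' Sparse-coding energy of a real code
#'
#' Negative log-posterior (up to constants) of a real sparse code:
#' squared reconstruction error weighted by `1/sigma_sq` plus a Cauchy
#' sparsity penalty `lambda * sum(log(1 + c^2))`.
#'
#' @param x data vector (length T).
#' @param c coefficient vector (length N).
#' @param theta `T x N` dictionary matrix (atoms in columns).
#' @param lambda sparsity weight (default 0.2).
#' @param sigma_sq noise variance (default 2).
#' @return scalar energy.
#' @export
real_energy <- function(x, c, theta, lambda = 0.2, sigma_sq = 2) {
  r <- x - theta %*% c
  sum(r^2) / sigma_sq + lambda * sum(log1p(c^2))
}

# Batched versions: X is T x E, C is N x E. Return per-column energies.
.real_energy_batch <- function(X, C, theta, lambda, sigma_sq) {
  R <- X - theta %*% C
  colSums(R^2) / sigma_sq + lambda * colSums(log1p(C^2))
}

.real_grad <- function(X, C, theta, lambda, sigma_sq) {
  R <- X - theta %*% C
  -(2 / sigma_sq) * crossprod(theta, R) + 2 * lambda * C / (1 + C^2)
}

# Backtracking gradient descent on per-column objectives. `grad_fn(P)`
# returns the gradient (same shape as P), `energy_fn(P)` per-column
# energies, `project(P)` an optional feasibility projection. Step sizes
# are per column: halved on energy increase, grown 10% on acceptance.
.descend <- function(P, grad_fn, energy_fn, project = identity,
                     n_steps = 30, step0 = 0.5, max_halve = 12) {
  E <- energy_fn(P)
  step <- rep(step0, length(E))
  for (it in seq_len(n_steps)) {
    G <- grad_fn(P)
    if (!all(is.finite(G))) stop("non-finite gradient during inference",
                                 call. = FALSE)
    repeat {
      cand <- project(P - G * rep(step, each = nrow(P)))
      Ec <- energy_fn(cand)
      bad <- Ec > E + 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
      if (all(step < step0 / 2^max_halve)) break
      if (min(step[bad]) < step0 / 2^max_halve) {
        # frozen columns: keep their current point
        cand[, bad & step < step0 / 2^max_halve] <-
          P[, bad & step < step0 / 2^max_halve, drop = FALSE]
        Ec[bad & step < step0 / 2^max_halve] <-
          E[bad & step < step0 / 2^max_halve]
        bad <- Ec > E + 1e-12
        if (!any(bad)) break
      }
    }
    accept <- Ec <= E + 1e-12
    P[, accept] <- cand[, accept, drop = FALSE]
    E[accept] <- Ec[accept]
    step[accept] <- step[accept] * 1.1
  }
  list(P = P, energy = E)
}

# MAP inference of real coefficients for a batch of epochs.
.infer_real <- function(X, theta, lambda, sigma_sq, n_steps = 30) {
  C0 <- matrix(0, ncol(theta), ncol(X))
  fit <- .descend(C0,
                  grad_fn = function(C) .real_grad(X, C, theta, lambda, sigma_sq),
                  energy_fn = function(C) .real_energy_batch(X, C, theta, lambda, sigma_sq),
                  n_steps = n_steps, step0 = sigma_sq / 4)
  fit
}

#' Learn a real sparse dictionary of sound epochs
#'
#' Alternates MAP inference of sparse coefficients (batched gradient
#' descent with per-epoch backtracking) with gradient updates of the
#' dictionary; atoms are renormalized to unit L2 norm after each update
#' to prevent the amplitude/sparsity scale degeneracy.
#'
#' @param x `T x E` matrix of (PCA-filtered) mono epochs.
#' @param n_atoms number of atoms N (complete code: N = T).
#' @param lambda sparsity weight (default 0.2).
#' @param sigma_sq noise variance (default 2).
#' @param n_iter number of dictionary gradient updates.
#' @param batch_size epochs per update.
#' @param n_steps inference gradient steps per batch.
#' @param learning_rate initial dictionary step size (decays as
#'   `1/(1 + iter/n_iter)`).
#' @param seed integer seed (initialization and batch sampling).
#' @return list with `theta` (`T x N`, unit-norm columns) and
#'   `energy_trace` (mean batch energy per update).
#' @export
learn_real_dictionary <- function(x, n_atoms, lambda = 0.2, sigma_sq = 2,
                                  n_iter = 2000, batch_size = 100,
                                  n_steps = 30, learning_rate = 1, seed = 1L) {
  stopifnot(n_atoms <= nrow(x))
  with_seed(seed, {
    theta <- matrix(stats::rnorm(nrow(x) * n_atoms), nrow(x))
    theta <- sweep(theta, 2, sqrt(colSums(theta^2)), "/")
    trace <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      batch <- x[, sample.int(ncol(x), batch_size), drop = FALSE]
      inf <- .infer_real(batch, theta, lambda, sigma_sq, n_steps)
      C <- inf$P
      R <- batch - theta %*% C
      lr <- learning_rate / (1 + it / n_iter)
      theta <- theta + lr * (2 / sigma_sq) * (R %*% t(C)) / batch_size
      nrm <- sqrt(colSums(theta^2))
      nrm[nrm < 1e-12] <- 1
      theta <- sweep(theta, 2, nrm, "/")
      trace[it] <- mean(inf$energy)
      if (it > 400 && it %% 100 == 0) {
        recent <- mean(trace[(it - 99):it])
        past <- mean(trace[(it - 399):(it - 300)])
        if (recent > 1.5 * abs(past) + past)
          stop("dictionary learning diverged (energy increasing persistently)",
               call. = FALSE)
      }
    }
    list(theta = theta, energy_trace = trace)
  })
}

#' Extend a real dictionary to a complex (quadrature) dictionary
#'
#' Pairs each real atom with its discrete Hilbert transform, yielding a
#' complex dictionary whose codes separate instantaneous amplitude and
#' phase. Per-atom spectral metadata (peak frequency of the amplitude
#' spectrum and the number of cycles of that frequency within the
#' T-sample support) is attached; it drives IPD channel selection.
#'
#' @param theta `T x N` real dictionary (atoms in columns).
#' @param sampling_rate sampling rate in Hz.
#' @return object of class `complex_dictionary`: `A_re`, `A_im`
#'   (`T x N`), `peak_freq` (Hz), `n_cycles`, `sampling_rate`, `T`.
#' @export
build_complex_dictionary <- function(theta, sampling_rate = 8000) {
  theta <- as.matrix(theta)
  T <- nrow(theta)
  # peak frequency from an 8x zero-padded spectrum, so cycle counts
  # below one per support are resolvable (the bare T-point grid cannot
  # represent them)
  pad <- 8L
  spec <- Mod(stats::mvfft(rbind(theta, matrix(0, (pad - 1) * T,
                                               ncol(theta)))))
  nbin <- floor(pad * T / 2)
  dc_dom <- spec[1, ] >= apply(spec[2:(nbin + 1), , drop = FALSE], 2, max)
  if (any(dc_dom))
    warning(sum(dc_dom), " atom(s) have a dominant DC component; ",
            "Hilbert phase is poorly defined for them")
  peak_bin <- apply(spec[2:(nbin + 1), , drop = FALSE], 2, which.max)
  peak_freq <- peak_bin * sampling_rate / (pad * T)
  structure(list(A_re = theta, A_im = hilbert_transform(theta),
                 peak_freq = peak_freq, n_cycles = peak_freq * T / sampling_rate,
                 sampling_rate = sampling_rate, T = T),
            class = "complex_dictionary")
}

#' @export
print.complex_dictionary <- function(x, ...) {
  cat(sprintf("complex dictionary: %d atoms of %d samples @ %g Hz\n",
              ncol(x$A_re), x$T, x$sampling_rate))
  cat(sprintf("  peak frequencies %.0f-%.0f Hz\n",
              min(x$peak_freq), max(x$peak_freq)))
  invisible(x)
}

# -- complex (phase/amplitude) inference --------------------------------

.complex_recon <- function(A, Amp, Phi) {
  A$A_re %*% (Amp * cos(Phi)) + A$A_im %*% (Amp * sin(Phi))
}

.complex_energy_batch <- function(X, Amp, Phi, A, lambda, sigma_sq) {
  R <- X - .complex_recon(A, Amp, Phi)
  colSums(R^2) / sigma_sq + lambda * colSums(log1p(Amp^2))
}

.complex_grad <- function(X, Amp, Phi, A, lambda, sigma_sq, amp_floor = 1e-8) {
  R <- X - .complex_recon(A, Amp, Phi)
  u <- crossprod(A$A_re, R)
  v <- crossprod(A$A_im, R)
  ga <- -(2 / sigma_sq) * (cos(Phi) * u + sin(Phi) * v) +
    2 * lambda * Amp / (1 + Amp^2)
  gp <- -(2 / sigma_sq) * Amp * (cos(Phi) * v - sin(Phi) * u)
  gp[Amp < amp_floor] <- 0          # phase direction undefined at a ~ 0
  rbind(ga, gp)
}

#' Infer amplitudes and phases of epochs under a complex dictionary
#'
#' Joint MAP gradient descent over amplitude and phase (batched over
#' epochs, per-epoch backtracking). Amplitudes are projected to be
#' non-negative after every step and phases wrapped into (-pi, pi];
#' phase gradients are skipped for atoms with amplitude below 1e-8.
#' Phases are initialized at the matched-filter phase
#' `atan2(A_im' x, A_re' x)` and amplitudes at zero.
#'
#' @param x `T x E` matrix of (PCA-filtered) mono epochs, or a vector.
#' @param dict a `complex_dictionary`.
#' @param lambda sparsity weight (default 0.2).
#' @param sigma_sq noise variance (default 2).
#' @param n_steps gradient steps (default 20).
#' @return object of class `layer1_code`: `a` and `phi` (`N x E`),
#'   `energy` (per epoch), `resid_mse` (per epoch).
#' @export
infer_complex <- function(x, dict, lambda = 0.2, sigma_sq = 2, n_steps = 20) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  stopifnot_finite(X, "x")
  N <- ncol(dict$A_re)
  Phi0 <- atan2(crossprod(dict$A_im, X), crossprod(dict$A_re, X))
  P0 <- rbind(matrix(0, N, ncol(X)), Phi0)
  split_ap <- function(P) list(Amp = P[seq_len(N), , drop = FALSE],
                               Phi = P[N + seq_len(N), , drop = FALSE])
  fit <- .descend(
    P0,
    grad_fn = function(P) {
      s <- split_ap(P)
      .complex_grad(X, s$Amp, s$Phi, dict, lambda, sigma_sq)
    },
    energy_fn = function(P) {
      s <- split_ap(P)
      e <- .complex_energy_batch(X, s$Amp, s$Phi, dict, lambda, sigma_sq)
      if (!all(is.finite(e))) stop("non-finite energy during inference",
                                   call. = FALSE)
      e
    },
    project = function(P) {
      s <- split_ap(P)
      rbind(pmax(s$Amp, 0), wrap_angle(s$Phi))
    },
    n_steps = n_steps, step0 = sigma_sq / 4)
  s <- split_ap(fit$P)
  R <- X - .complex_recon(dict, s$Amp, s$Phi)
  structure(list(a = s$Amp, phi = s$Phi, energy = fit$energy,
                 resid_mse = colMeans(R^2)),
            class = "layer1_code")
}

#' @export
print.layer1_code <- function(x, ...) {
  cat(sprintf("layer-1 code: %d atoms x %d epochs, mean residual MSE %.4g\n",
              nrow(x$a), ncol(x$a), mean(x$resid_mse)))
  invisible(x)
}

# -- fitted-model interface ---------------------------------------------

#' Fit the first-layer complex sparse-coding model
#'
#' Learns a real sparse dictionary of mono sound epochs
#' ([learn_real_dictionary()]) and extends it with Hilbert-transform
#' quadrature partners ([build_complex_dictionary()]), producing the
#' phase/amplitude front end of the hierarchical model.
#'
#' @inheritParams learn_real_dictionary
#' @param sampling_rate sampling rate of the epochs, Hz.
#' @return object of class `layer1_model`: the `complex_dictionary`
#'   fields plus `lambda`, `sigma_sq` and the learning `energy_trace`.
#' @seealso [predict.layer1_model()] to encode epochs.
#' @export
fit_layer1 <- function(x, n_atoms = 128, lambda = 0.2, sigma_sq = 2,
                       n_iter = 2000, batch_size = 100, n_steps = 30,
                       learning_rate = 1, sampling_rate = 8000, seed = 1L) {
  fit <- learn_real_dictionary(x, n_atoms, lambda, sigma_sq, n_iter,
                               batch_size, n_steps, learning_rate, seed)
  dict <- build_complex_dictionary(fit$theta, sampling_rate)
  dict$lambda <- lambda
  dict$sigma_sq <- sigma_sq
  dict$energy_trace <- fit$energy_trace
  class(dict) <- c("layer1_model", "complex_dictionary")
  dict
}

#' Encode epochs with a fitted layer-1 model
#'
#' @param object a `layer1_model`.
#' @param newdata `T x E` matrix of mono epochs (columns), or a
#'   `binaural_epoch` pair list with `left`/`right` matrices, in which
#'   case both ears are encoded independently with the same dictionary.
#' @param n_steps inference gradient steps (default 20).
#' @param ... unused.
#' @return a `layer1_code`, or a list with `left`/`right` codes.
#' @export
predict.layer1_model <- function(object, newdata, n_steps = 20, ...) {
  if (is.list(newdata) && !is.null(newdata$left)) {
    list(left = infer_complex(newdata$left, object, object$lambda,
                              object$sigma_sq, n_steps),
         right = infer_complex(newdata$right, object, object$lambda,
                               object$sigma_sq, n_steps))
  } else {
    infer_complex(newdata, object, object$lambda, object$sigma_sq, n_steps)
  }
}

#' @export
print.layer1_model <- function(x, ...) {
  cat(sprintf("Layer-1 complex sparse code: %d atoms of %d samples @ %g Hz\n",
              ncol(x$A_re), x$T, x$sampling_rate))
  cat(sprintf("  lambda = %g, sigma^2 = %g\n", x$lambda, x$sigma_sq))
  cat(sprintf("  atom peak frequencies: %.0f-%.0f Hz\n",
              min(x$peak_freq), max(x$peak_freq)))
  invisible(x)
}

#' @export
summary.layer1_model <- function(object, ...) {
  cat("Layer-1 complex sparse-coding model\n")
  print(object)
  lowf <- sum(object$peak_freq < 750 & object$n_cycles >= 1)
  cat(sprintf("  %d atoms eligible as IPD channels (< 750 Hz, >= 1 cycle)\n",
              lowf))
  if (length(object$energy_trace))
    cat(sprintf("  final smoothed training energy: %.4g\n",
                mean(utils::tail(object$energy_trace, 100))))
  invisible(object)
}

#' @export
coef.layer1_model <- function(object, ...) object$A_re

#' Plot layer-1 atoms
#'
#' Draws a grid of real atoms (black) with their Hilbert-transform
#' quadrature partners (gray).
#'
#' @param x a `layer1_model` or `complex_dictionary`.
#' @param atoms indices of atoms to draw (default: up to 16, by
#'   ascending peak frequency).
#' @param ... passed to [graphics::plot()].
#' @export
plot.complex_dictionary <- function(x, atoms = NULL, ...) {
  if (is.null(atoms))
    atoms <- order(x$peak_freq)[seq_len(min(16, ncol(x$A_re)))]
  nr <- ceiling(sqrt(length(atoms)))
  op <- graphics::par(mfrow = c(nr, ceiling(length(atoms) / nr)),
                      mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (i in atoms) {
    graphics::plot(x$A_re[, i], type = "l", axes = FALSE, xlab = "",
                   ylab = "", main = sprintf("%.0f Hz", x$peak_freq[i]),
                   cex.main = 0.8, ...)
    graphics::lines(x$A_im[, i], col = "gray60")
  }
  invisible(x)
}
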