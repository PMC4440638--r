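# Epoch extraction and PCA-based low-pass preprocessing.

#' Extract random epochs from a binaural stream
#'
#' Draws `count` paired left/right epochs of `T` samples at uniformly
#' random start positions (with replacement). The left and right members
#' of a pair share the start sample, so interaural structure is
#' preserved.
#'
#' @param stream a [binaural_epoch()] (or any list with `left`/`right`
#'   sample vectors) holding the full recording.
#' @param T epoch length in samples (default 128, i.e. 16 ms at 8 kHz).
#' @param count number of epoch pairs to draw.
#' @param seed integer seed fixing the start positions.
#' @return list with `left` and `right` (each a `T x count` matrix whose
#'   columns are epochs), `starts`, `sampling_rate` and `T`.
#' @export
extract_epochs <- function(stream, T = 128, count, seed = 1L) {
  n <- length(stream$left)
  if (T > n) stop("epoch length T exceeds the audio length", call. = FALSE)
  with_seed(seed, {
    starts <- sample.int(n - T + 1, count, replace = TRUE)
    idx <- outer(seq_len(T) - 1L, starts, "+")
    list(left = matrix(stream$left[idx], nrow = T),
         right = matrix(stream$right[idx], nrow = T),
         starts = starts, sampling_rate = stream$sampling_rate, T = T)
  })
}

#' Pool paired epochs into a shuffled mono training set
#'
#' The first-layer dictionary is monaural: both ears' epochs are pooled
#' and shuffled into a single training matrix of `2 * count` columns.
#'
#' @param pairs result of [extract_epochs()].
#' @param seed integer seed for the shuffle.
#' @return `T x (2*count)` matrix of mono epochs.
#' @export
pool_epochs <- function(pairs, seed = 1L) {
  x <- cbind(pairs$left, pairs$right)
  with_seed(seed, x[, sample.int(ncol(x))])
}

# Columns of an epoch_set as T x n matrices, one per ear.
epoch_set_matrices <- function(es) {
  list(left = vapply(es$epochs, function(e) e$left,
                     numeric(es$epoch_length)),
       right = vapply(es$epochs, function(e) e$right,
                      numeric(es$epoch_length)))
}

#' Fit a PCA low-pass projector and filter epochs
#'
#' Fits principal components to mono epochs (columns of `x`) and
#' replaces each epoch by its reconstruction from the top
#' `T - n_reject` components. For natural audio, whose power falls with
#' frequency, rejecting the smallest-variance components is a low-pass
#' filter; epochs are reconstructed back into signal space so downstream
#' code is unchanged.
#'
#' @param x `T x E` matrix of mono epochs (E >= T).
#' @param n_reject number of trailing (smallest-eigenvalue) components
#'   to drop; default 18 out of T = 128.
#' @return list with `projector` (class `pca_projector`: orthonormal
#'   `components`, descending `eigenvalues`, `mean`, `n_reject`) and
#'   `x` (the filtered epochs).
#' @export
fit_project_pca <- function(x, n_reject = 18) {
  T <- nrow(x)
  if (n_reject >= T) stop("n_reject must be smaller than T", call. = FALSE)
  if (ncol(x) < T) stop("need at least T epochs to fit the PCA",
                        call. = FALSE)
  mu <- rowMeans(x)
  xc <- x - mu
  # covariance normalized by E so that the mean per-epoch squared
  # residual equals the sum of the rejected eigenvalues exactly
  C <- tcrossprod(xc) / ncol(x)
  eg <- eigen(C, symmetric = TRUE)
  proj <- structure(list(components = eg$vectors,
                         eigenvalues = pmax(eg$values, 0),
                         mean = mu, n_reject = as.integer(n_reject)),
                    class = "pca_projector")
  list(projector = proj, x = project_epochs(proj, x))
}

#' Apply a fitted PCA low-pass projector
#'
#' @param projector a `pca_projector` from [fit_project_pca()].
#' @param x `T x E` matrix of mono epochs.
#' @return filtered epochs, same shape as `x`.
#' @export
project_epochs <- function(projector, x) {
  keep <- seq_len(nrow(x) - projector$n_reject)
  V <- projector$components[, keep, drop = FALSE]
  V %*% crossprod(V, x - projector$mean) + projector$mean
}

#' @export
print.pca_projector <- function(x, ...) {
  T <- length(x$mean)
  kept <- sum(x$eigenvalues[seq_len(T - x$n_reject)])
  cat(sprintf("PCA low-pass projector: keeping %d of %d components (%.2f%% variance)\n",
              T - x$n_reject, T, 100 * kept / sum(x$eigenvalues)))
  invisible(x)
}
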