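# Population decoding of source sector from layer-2 coefficients:
# Gaussian class-conditional classifier, confusion matrices, plug-in
# mutual information, and single-unit / population information curves.

#' Average coefficient samples into response vectors
#'
#' Averages disjoint groups of `D` same-sector coefficient vectors,
#' an analogue of estimating a firing rate from repeated samples.
#'
#' @param s `K x E` matrix of coefficient samples (columns).
#' @param D averaging depth (number of samples per response vector).
#' @return `K x floor(E/D)` matrix of averaged response vectors.
#' @export
average_responses <- function(s, D) {
  s <- as.matrix(s)
  if (D > ncol(s)) stop("averaging depth D exceeds available samples",
                        call. = FALSE)
  n_groups <- ncol(s) %/% D
  idx <- matrix(seq_len(n_groups * D), nrow = D)
  matrix(vapply(seq_len(n_groups), function(g)
    rowMeans(s[, idx[, g], drop = FALSE]), numeric(nrow(s))),
    nrow = nrow(s))
}

#' Fit a Gaussian class-conditional sector decoder
#'
#' Models the response vector of each azimuth sector as a multivariate
#' Gaussian with class-specific mean and covariance; the class prior is
#' uniform. Covariances are ridge-regularized with
#' `delta = delta_scale * trace(C)/K` per class.
#'
#' @param d `K x n` matrix of training response vectors (columns).
#' @param label integer sector label per column (1..n_classes).
#' @param n_classes number of sectors (default 18).
#' @param delta_scale ridge factor (default 1e-3).
#' @return object of class `sector_decoder`: per-class `means`
#'   (`K x n_classes`), Cholesky factors, log-determinants and the
#'   uniform `prior`.
#' @export
fit_decoder <- function(d, label, n_classes = 18, delta_scale = 1e-3) {
  d <- as.matrix(d)
  K <- nrow(d)
  counts <- tabulate(label, n_classes)
  if (any(counts < 2))
    stop("every class needs at least 2 training samples", call. = FALSE)
  means <- matrix(0, K, n_classes)
  chols <- vector("list", n_classes)
  logdet <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    xk <- d[, label == k, drop = FALSE]
    means[, k] <- rowMeans(xk)
    C <- stats::cov(t(xk))
    delta <- delta_scale * sum(diag(C)) / K
    if (delta <= 0) delta <- 1e-12
    C <- C + diag(delta, K)
    R <- chol(C)
    chols[[k]] <- R
    logdet[k] <- 2 * sum(log(diag(R)))
  }
  structure(list(means = means, chols = chols, logdet = logdet,
                 prior = rep(1 / n_classes, n_classes),
                 n_classes = n_classes, K = K),
            class = "sector_decoder")
}

# Log class-conditional Gaussian densities (n x n_classes).
.decoder_loglik <- function(model, d) {
  d <- as.matrix(d)
  n <- ncol(d)
  ll <- matrix(0, n, model$n_classes)
  for (k in seq_len(model$n_classes)) {
    xc <- d - model$means[, k]
    z <- backsolve(model$chols[[k]], xc, transpose = TRUE)
    ll[, k] <- -0.5 * (colSums(z^2) + model$logdet[k] +
                         model$K * log(2 * pi))
  }
  ll
}

#' Decode sectors from response vectors
#'
#' Maximum-a-posteriori sector under the Gaussian class-conditional
#' model with its uniform prior; ties are broken toward the lowest
#' sector index.
#'
#' @param object a `sector_decoder`.
#' @param newdata `K x n` matrix of response vectors (columns).
#' @param ... unused.
#' @return integer vector of decoded sector indices.
#' @export
predict.sector_decoder <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot_finite(newdata, "newdata")
  ll <- .decoder_loglik(object, newdata) +
    rep(log(object$prior), each = ncol(newdata))
  apply(ll, 1, which.max)          # which.max: first (lowest) index wins
}

#' @export
print.sector_decoder <- function(x, ...) {
  cat(sprintf("Gaussian sector decoder: %d classes, %d units, uniform prior\n",
              x$n_classes, x$K))
  invisible(x)
}

#' Confusion matrix of decoded vs true sectors
#'
#' @param true,decoded integer sector vectors of equal length.
#' @param n_classes number of sectors (default 18).
#' @param normalize divide by the total count so entries sum to 1
#'   (default TRUE).
#' @return `n_classes x n_classes` matrix, decoded sectors in rows and
#'   true sectors in columns.
#' @export
confusion_matrix <- function(true, decoded, n_classes = 18,
                             normalize = TRUE) {
  stopifnot(length(true) == length(decoded))
  M <- matrix(0, n_classes, n_classes)
  for (i in seq_along(true))
    M[decoded[i], true[i]] <- M[decoded[i], true[i]] + 1
  if (normalize) M <- M / sum(M)
  M
}

#' Mutual information of a normalized confusion matrix
#'
#' Plug-in estimate (in bits) of the mutual information between decoded
#' and true sector from their joint distribution; zero cells contribute
#' zero. An optional Miller-Madow small-sample bias correction is
#' available but off by default.
#'
#' @param confusion non-negative matrix summing to 1.
#' @param n_samples sample count behind the matrix; only used by the
#'   Miller-Madow correction.
#' @param miller_madow apply the Miller-Madow correction (default
#'   FALSE).
#' @return mutual information in bits.
#' @export
mutual_information <- function(confusion, n_samples = NULL,
                               miller_madow = FALSE) {
  if (any(confusion < 0) || abs(sum(confusion) - 1) > 1e-8)
    stop("confusion matrix must be normalized (non-negative, sum 1)",
         call. = FALSE)
  pr <- rowSums(confusion); pc <- colSums(confusion)
  nz <- confusion > 0
  outer_p <- outer(pr, pc)
  mi <- sum(confusion[nz] * log2(confusion[nz] / outer_p[nz]))
  if (miller_madow) {
    if (is.null(n_samples)) stop("n_samples needed for Miller-Madow")
    mi <- mi + (sum(nz) - sum(pr > 0) - sum(pc > 0) + 1) /
      (2 * n_samples * log(2))
  }
  mi
}

# Stratified train/test split of labelled columns; returns index lists.
.stratified_split <- function(label, train_frac = 0.8) {
  train <- integer(0)
  for (k in sort(unique(label))) {
    idx <- which(label == k)
    n_tr <- max(1, round(train_frac * length(idx)))
    n_tr <- min(n_tr, length(idx) - 1)      # keep >= 1 test sample
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train),
       test = setdiff(seq_along(label), train))
}

# One decode experiment: average within sector, split, fit, decode.
# Returns list(mi, accuracy, confusion).
.decode_once <- function(s, sector, units, D, n_classes = 18,
                         train_frac = 0.8, delta_scale = 1e-3) {
  dmat <- NULL; lab <- integer(0)
  for (k in seq_len(n_classes)) {
    sk <- s[units, sector == k, drop = FALSE]
    if (ncol(sk) < D) return(NULL)
    dk <- average_responses(sk, D)
    dmat <- cbind(dmat, dk)
    lab <- c(lab, rep(k, ncol(dk)))
  }
  sp <- .stratified_split(lab, train_frac)
  dec <- fit_decoder(dmat[, sp$train, drop = FALSE], lab[sp$train],
                     n_classes, delta_scale)
  pred <- predict(dec, dmat[, sp$test, drop = FALSE])
  cm <- confusion_matrix(lab[sp$test], pred, n_classes)
  list(mi = mutual_information(cm),
       accuracy = mean(pred == lab[sp$test]),
       confusion = cm)
}

#' Single-unit spatial information
#'
#' Decodes the sector from each unit's coefficient alone (K = 1) and
#' returns the per-unit mutual information of the held-out confusion
#' matrix.
#'
#' @param s `M x E` matrix of layer-2 coefficients (or `layer2_code`).
#' @param sector integer sector index per epoch.
#' @param D averaging depth (default 1).
#' @param n_classes number of sectors (default 18).
#' @param seed integer seed (train/test split).
#' @return numeric vector of per-unit MI (bits).
#' @export
unit_information <- function(s, sector, D = 1, n_classes = 18, seed = 1L) {
  if (inherits(s, "layer2_code")) s <- s$s
  with_seed(seed, vapply(seq_len(nrow(s)), function(i) {
    r <- .decode_once(s, sector, i, D, n_classes)
    if (is.null(r)) NA_real_ else r$mi
  }, numeric(1)))
}

#' Population information curves
#'
#' Mutual information between decoded and true sector as a function of
#' the number of units K (random subsets, averaged over repeats) and of
#' the averaging depth D. For each cell the coefficients are averaged
#' over disjoint groups of D same-sector samples, split 80/20 with
#' stratification, a Gaussian decoder fitted on the training part and
#' the confusion matrix estimated on the held-out part.
#'
#' @param s `M x E` matrix of layer-2 coefficients (or `layer2_code`).
#' @param sector integer sector index per epoch.
#' @param unit_counts vector of population sizes K to probe.
#' @param D_values vector of averaging depths D to probe.
#' @param n_repeats random unit subsets per cell (default 10).
#' @param n_classes number of sectors (default 18).
#' @param seed integer seed.
#' @return data.frame with columns `K`, `D`, `MI_bits`, `accuracy`.
#' @export
information_curves <- function(s, sector, unit_counts = c(1, 2, 4, 8, 16),
                               D_values = c(1, 4, 16), n_repeats = 10,
                               n_classes = 18, seed = 1L) {
  if (inherits(s, "layer2_code")) s <- s$s
  with_seed(seed, {
    rows <- list()
    for (D in D_values) for (K in unit_counts) {
      mis <- acc <- numeric(0)
      for (r in seq_len(n_repeats)) {
        units <- sample.int(nrow(s), K)
        res <- .decode_once(s, sector, units, D, n_classes)
        if (is.null(res)) next
        mis <- c(mis, res$mi); acc <- c(acc, res$accuracy)
      }
      if (length(mis) == 0) {
        warning(sprintf("cell K=%d, D=%d skipped: insufficient samples",
                        K, D))
        next
      }
      rows[[length(rows) + 1]] <-
        data.frame(K = K, D = D, MI_bits = mean(mis),
                   accuracy = mean(acc))
    }
    do.call(rbind, rows)
  })
}
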