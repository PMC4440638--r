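# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(name, " contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Wrap an angle into (-pi, pi]
#'
#' Reduces any finite angle modulo \eqn{2\pi} into the half-open interval
#' \eqn{(-\pi, \pi]}. Vectorised; the boundary convention maps \eqn{-\pi}
#' to \eqn{+\pi}.
#'
#' @param x numeric vector, matrix or array of angles in radians.
#' @return object of the same shape with all values in \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
#' wrap_angle(-pi)         # pi
#' @export
wrap_angle <- function(x) {
  stopifnot_finite(x, "x")
  y <- x %% (2 * pi)          # [0, 2*pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

# Discrete analytic signal of each column of `x` (real matrix or vector):
# zero the negative-frequency bins, double the positive ones, inverse
# transform. Im() of the result is the Hilbert transform.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::mvfft(x) * h
  stats::mvfft(z, inverse = TRUE) / n
}

#' Discrete Hilbert transform
#'
#' Quadrature companion of a real signal via the analytic-signal
#' construction (zero negative-frequency bins, double positive bins,
#' inverse transform, take the imaginary part). Applied columnwise if
#' given a matrix.
#'
#' @param x real vector or matrix (signals in columns).
#' @return object of the same shape holding the Hilbert transform.
#' @examples
#' t <- 0:127
#' h <- hilbert_transform(cos(2 * pi * 8 * t / 128))  # ~ sin(2*pi*8*t/128)
#' @export
hilbert_transform <- function(x) {
  out <- Im(analytic_signal(x))
  if (is.matrix(x)) out else drop(out)
}

# Band-limited fractional delay of a signal by `d` samples (d >= 0, real),
# windowed-sinc interpolation (Hann window, `half` taps per side).
# Output has the same length as the input; the signal is shifted right.
frac_delay <- function(x, d, half = 16) {
  stopifnot(d >= 0)
  di <- floor(d)
  df <- d - di
  if (df > 1e-12) {
    k <- seq(-half, half)
    h <- sinc(k - df) * (0.5 + 0.5 * cos(pi * (k - df) / (half + 1)))
    h <- h / sum(h)
    # zero-phase-origin FIR: y[n] = sum_k h[k] x[n - k]
    xp <- c(rep(0, half), x, rep(0, half))
    y <- stats::filter(xp, h, method = "convolution", sides = 2)
    x <- as.numeric(y[(half + 1):(half + length(x))])
    x[!is.finite(x)] <- 0
  }
  if (di > 0) x <- c(rep(0, di), x[seq_len(length(x) - di)])
  x
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))

# Circular mean of angles given in degrees, result in (-180, 180].
circ_mean_deg <- function(deg) {
  r <- deg * pi / 180
  m <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (m <= -180) m <- m + 360
  m
}

#' Serialize / restore binsparse objects
#'
#' Thin wrappers around [saveRDS()]/[readRDS()] used as the package's
#' on-disk container for epoch sets, dictionaries and fitted models.
#'
#' @param object any binsparse object (model, epoch set, projector, ...).
#' @param path file path.
#' @return `read_binsparse` returns the restored object.
#' @export
write_binsparse <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_binsparse
#' @export
read_binsparse <- function(path) readRDS(path)
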