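# Post-hoc characterization of learned layer-2 atoms: spectrogram-based
# modulation spectra with centers of mass, binaural similarity (BSI),
# binaural amplitude dominance (BAD), and IPD-atom averages.

#' Spectrograms of first-layer atoms
#'
#' Magnitude spectrograms of the real parts of a complex dictionary,
#' evaluated on a log-spaced frequency grid. Window length 16 samples
#' (2 ms at 8 kHz) with a 12-sample overlap (hop 4), Hann-windowed; a
#' 128-sample atom tiles into 29 windows. Frequencies are log-spaced
#' between `f_min` and Nyquist.
#'
#' @param dict a `complex_dictionary` or `layer1_model`.
#' @param window window length in samples (default 16).
#' @param hop hop between windows (default 4, i.e. 12-sample overlap).
#' @param n_freq number of log-spaced frequencies (default 128).
#' @param f_min lowest analysis frequency in Hz (default 50).
#' @return object of class `atom_spectrograms`: list `spec` of
#'   `n_freq x n_windows` magnitude grids (one per atom), plus the
#'   `freqs` (Hz) and window-center `times` (s) axes.
#' @export
atom_spectrograms <- function(dict, window = 16, hop = 4, n_freq = 128,
                              f_min = 50) {
  T <- dict$T; fs <- dict$sampling_rate
  starts <- seq(1, T - window + 1, by = hop)
  freqs <- exp(seq(log(f_min), log(fs / 2), length.out = n_freq))
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1) / (window - 1))
  tt <- (seq_len(window) - 1) / fs
  K <- exp(-2i * pi * outer(freqs, tt))          # n_freq x window DFT kernel
  K <- K * rep(win, each = n_freq)
  spec <- lapply(seq_len(ncol(dict$A_re)), function(i) {
    frames <- vapply(starts, function(s) dict$A_re[s:(s + window - 1), i],
                     numeric(window))
    Mod(K %*% frames)
  })
  structure(list(spec = spec, freqs = freqs,
                 times = (starts - 1 + window / 2) / fs,
                 window = window, hop = hop, sampling_rate = fs),
            class = "atom_spectrograms")
}

#' Spectrogram of a layer-2 amplitude atom
#'
#' The spectrotemporal pattern encoded by one ear's half of an amplitude
#' atom `B_i`: the sum of the first-layer atom spectrograms linearly
#' weighted by `exp(B_{i,n})` (log-amplitude weights mapped back to the
#' amplitude domain).
#'
#' @param B_i a `2T`-length amplitude atom (left half then right half).
#' @param l1_spec an `atom_spectrograms` object for the first-layer
#'   dictionary.
#' @param ear `"L"` or `"R"`.
#' @return `n_freq x n_windows` non-negative spectrogram grid with the
#'   axis attributes `freqs` and `times`.
#' @export
atom_spectrogram <- function(B_i, l1_spec, ear = c("L", "R")) {
  ear <- match.arg(ear)
  N <- length(l1_spec$spec)
  stopifnot(length(B_i) == 2 * N)
  half <- if (ear == "L") B_i[seq_len(N)] else B_i[N + seq_len(N)]
  wts <- exp(half)
  out <- Reduce(`+`, Map(function(s, w) w * s, l1_spec$spec, wts))
  attr(out, "freqs") <- l1_spec$freqs
  attr(out, "times") <- l1_spec$times
  out
}

#' Modulation transfer function and its center of mass
#'
#' The MTF is the magnitude of the 2D discrete Fourier transform of a
#' spectrogram, restricted to the non-negative quadrant (temporal and
#' spectral modulation frequencies both >= 0). The center of mass is
#' the MTF-mass-weighted mean coordinate on physical axes: temporal
#' modulation in Hz (from the window hop duration) and spectral
#' modulation in cycles/octave (from the log-frequency spacing).
#'
#' @param spec non-negative spectrogram grid from [atom_spectrogram()]
#'   (frequencies in rows, windows in columns).
#' @param hop_duration seconds between window centers; taken from the
#'   `times` attribute when present.
#' @param octaves total octave span of the frequency axis; taken from
#'   the `freqs` attribute when present.
#' @return list with `C_t` (Hz), `C_f` (cycles/octave) and the quadrant
#'   `mtf` grid.
#' @export
modulation_centroid <- function(spec, hop_duration = NULL, octaves = NULL) {
  stopifnot(all(spec >= 0))
  if (is.null(hop_duration)) {
    tm <- attr(spec, "times")
    hop_duration <- if (is.null(tm)) 4 / 8000 else tm[2] - tm[1]
  }
  if (is.null(octaves)) {
    fr <- attr(spec, "freqs")
    octaves <- if (is.null(fr)) log2(4000 / 50) else
      log2(fr[length(fr)] / fr[1])
  }
  nf <- nrow(spec); nt <- ncol(spec)
  mtf <- Mod(stats::fft(spec))
  qf <- seq_len(floor(nf / 2) + 1)               # spectral modulation >= 0
  qt <- seq_len(floor(nt / 2) + 1)               # temporal modulation >= 0
  q <- mtf[qf, qt, drop = FALSE]
  tot <- sum(q)
  if (tot <= 0) stop("all-zero modulation spectrum", call. = FALSE)
  t_axis <- (qt - 1) / (nt * hop_duration)       # Hz
  f_axis <- (qf - 1) / octaves                   # cycles per octave
  list(C_t = sum(q * rep(t_axis, each = length(qf))) / tot,
       C_f = sum(q * f_axis) / tot,
       mtf = q, t_axis = t_axis, f_axis = f_axis)
}

#' Binaural similarity index
#'
#' Pearson correlation between the left- and right-ear halves of an
#' amplitude atom. Values near 1 mean the unit encodes the same
#' spectrotemporal pattern in both ears.
#'
#' @param B_i a `2T`-length amplitude atom.
#' @return correlation in \[-1, 1\]; `NA` (with a warning) if either
#'   half has zero variance.
#' @export
bsi <- function(B_i) {
  n <- length(B_i) / 2
  l <- B_i[seq_len(n)]; r <- B_i[n + seq_len(n)]
  if (stats::sd(l) < 1e-14 || stats::sd(r) < 1e-14) {
    warning("zero-variance half; BSI undefined")
    return(NA_real_)
  }
  stats::cor(l, r)
}

#' Binaural amplitude dominance
#'
#' Log-ratio of the L2 norms of the elementwise-exponentiated left and
#' right halves of an amplitude atom: positive values indicate left-ear
#' dominance, negative right-ear dominance.
#'
#' @param B_i a `2T`-length amplitude atom (log-amplitude units).
#' @return real dominance score.
#' @export
bad <- function(B_i) {
  n <- length(B_i) / 2
  log(sqrt(sum(exp(2 * B_i[seq_len(n)]))) /
        sqrt(sum(exp(2 * B_i[n + seq_len(n)]))))
}

#' Average of a normalized IPD atom
#'
#' Divides an IPD atom by its maximal absolute entry and returns the
#' mean: values near -1 indicate a consistently left-preferring
#' (negative-IPD) atom, near +1 right-preferring.
#'
#' @param xi_i an IPD atom (length P).
#' @return mean of the normalized entries, in \[-1, 1\]; `NA` with a
#'   warning for a zero atom.
#' @export
ipd_atom_average <- function(xi_i) {
  m <- max(abs(xi_i))
  if (m < 1e-14) {
    warning("zero IPD atom; average undefined")
    return(NA_real_)
  }
  mean(xi_i / m)
}

#' Per-atom summary statistics of a layer-2 model
#'
#' Tabulates, for every layer-2 atom, the modulation-spectrum centers of
#' mass per ear (when a first-layer dictionary is supplied), the
#' binaural similarity index, the binaural amplitude dominance and the
#' normalized IPD-atom average.
#'
#' @param model a `layer2_model`.
#' @param l1_model optional `layer1_model`/`complex_dictionary`; if
#'   given, modulation centroids are computed (slower).
#' @return data.frame with one row per atom: `atom`, optionally
#'   `C_t_L`, `C_f_L`, `C_t_R`, `C_f_R`, then `bsi`, `bad`, `xi_mean`.
#' @export
layer2_atom_stats <- function(model, l1_model = NULL) {
  M <- ncol(model$B)
  out <- data.frame(atom = seq_len(M))
  if (!is.null(l1_model)) {
    sg <- atom_spectrograms(l1_model)
    cent <- function(i, ear)
      modulation_centroid(atom_spectrogram(model$B[, i], sg, ear))
  cl <- lapply(seq_len(M), cent, ear = "L")
    cr <- lapply(seq_len(M), cent, ear = "R")
    out$C_t_L <- vapply(cl, `[[`, numeric(1), "C_t")
    out$C_f_L <- vapply(cl, `[[`, numeric(1), "C_f")
    out$C_t_R <- vapply(cr, `[[`, numeric(1), "C_t")
    out$C_f_R <- vapply(cr, `[[`, numeric(1), "C_f")
  }
  out$bsi <- apply(model$B, 2, bsi)
  out$bad <- apply(model$B, 2, bad)
  out$xi_mean <- apply(model$xi, 2, ipd_atom_average)
  out
}
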