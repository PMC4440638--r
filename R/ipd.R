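# Interaural phase differences: computation from per-ear layer-1 phases
# and selection of the low-frequency IPD channels.
#
# Sign convention: Delta_phi = wrap(phi_L - phi_R). Under the layer-1
# phase convention (x ~ a cos(omega t - phi)) a source in the left
# hemifield reaches the left ear first, giving the smaller left phase,
# hence a negative IPD.

#' Interaural phase difference
#'
#' Elementwise wrapped difference of left- and right-ear phase vectors:
#' `wrap_angle(phi_L - phi_R)`. Negative values indicate a left-leading
#' (left hemifield) source.
#'
#' @param phi_L,phi_R equal-shaped vectors or matrices of wrapped phases
#'   (radians).
#' @return wrapped IPDs in (-pi, pi], same shape.
#' @export
compute_ipd <- function(phi_L, phi_R) {
  stopifnot(length(phi_L) == length(phi_R))
  wrap_angle(phi_L - phi_R)
}

#' Select low-frequency IPD channels
#'
#' Fine-structure phase is an unambiguous localization cue only in low
#' frequency channels. A dictionary atom is selected as an IPD channel
#' if (i) the peak of its amplitude spectrum lies below `f_max` and
#' (ii) it completes at least `min_cycles` cycles of that frequency
#' within its T-sample support.
#'
#' @param dict a `complex_dictionary` (or `layer1_model`).
#' @param f_max upper frequency bound in Hz (default 750).
#' @param min_cycles minimal cycle count (default 1).
#' @return object of class `ipd_selection`: `channels` (indices into
#'   the dictionary, sorted by peak frequency), `P`, `f_max`,
#'   `min_cycles`.
#' @export
select_channels <- function(dict, f_max = 750, min_cycles = 1) {
  ok <- which(dict$peak_freq < f_max & dict$n_cycles >= min_cycles)
  if (length(ok) == 0)
    stop("no dictionary atom satisfies the IPD channel criteria ",
         sprintf("(peak < %g Hz, >= %g cycles)", f_max, min_cycles),
         call. = FALSE)
  ok <- ok[order(dict$peak_freq[ok])]
  structure(list(channels = ok, P = length(ok), f_max = f_max,
                 min_cycles = min_cycles),
            class = "ipd_selection")
}

#' @export
print.ipd_selection <- function(x, ...) {
  cat(sprintf("IPD channel selection: P = %d channels (peak < %g Hz, >= %g cycles)\n",
              x$P, x$f_max, x$min_cycles))
  invisible(x)
}

#' Assemble joint layer-2 observations from per-ear layer-1 codes
#'
#' Concatenates left- and right-ear log-amplitudes into a single
#' `2N`-vector per epoch (amplitude floor `eps` applied before the log)
#' and computes wrapped IPDs in the selected channels. Optionally gates
#' IPDs by amplitude: channels where both ears' amplitudes fall below
#' `amp_gate` carry noise phase; with a gate they are replaced by 0
#' (the circular mean of noise). The gate is off by default.
#'
#' @param code_left,code_right `layer1_code`s of the two ears.
#' @param selection an `ipd_selection`.
#' @param eps amplitude floor before the log (default 1e-6).
#' @param amp_gate optional amplitude threshold; `NULL` (default)
#'   disables gating.
#' @return object of class `joint_obs`: `a` (`2N x E` log-amplitudes,
#'   left on top), `dphi` (`P x E` wrapped IPDs), `selection`.
#' @export
make_joint_obs <- function(code_left, code_right, selection, eps = 1e-6,
                           amp_gate = NULL) {
  a <- rbind(log(pmax(code_left$a, eps)), log(pmax(code_right$a, eps)))
  ch <- selection$channels
  dphi <- compute_ipd(code_left$phi[ch, , drop = FALSE],
                      code_right$phi[ch, , drop = FALSE])
  if (!is.null(amp_gate)) {
    weak <- code_left$a[ch, , drop = FALSE] < amp_gate &
      code_right$a[ch, , drop = FALSE] < amp_gate
    dphi[weak] <- 0
  }
  structure(list(a = a, dphi = dphi, selection = selection),
            class = "joint_obs")
}

#' @export
print.joint_obs <- function(x, ...) {
  cat(sprintf("joint observations: %d log-amplitudes + %d IPDs x %d epochs\n",
              nrow(x$a), nrow(x$dphi), ncol(x$a)))
  invisible(x)
}
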