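# Synthetic binaural scene generation.
#
# Azimuth convention: degrees in (-180, 180], 0 = straight ahead,
# positive = right hemifield, negative = left. A source on the right
# reaches the right ear first and is attenuated/low-passed at the left
# (far) ear; symmetric for the left.

#' Scene configuration for the binaural simulator
#'
#' Bundles the physical and statistical parameters of the synthetic
#' auditory scene: sampling rate, spherical-head geometry used by the
#' Woodworth interaural-time-delay model, head-shadow filter parameters,
#' and the levels/rates of the three source classes (ambient broadband
#' noise, transient clicks, harmonic voice-like source).
#'
#' @param sampling_rate sampling rate in Hz.
#' @param head_radius head radius in meters (default 0.095 m, i.e. a
#'   60 cm head circumference divided by 2*pi).
#' @param speed_of_sound speed of sound in m/s.
#' @param ild_max_db maximal broadband head-shadow attenuation of the far
#'   ear, in dB, reached at +/-90 degrees.
#' @param shadow_fc_min lowest cutoff (Hz) of the first-order low-pass
#'   head-shadow filter, reached at +/-90 degrees.
#' @param ambient_level RMS level of the ambient noise bed.
#' @param transient_rate expected number of transient clicks per second.
#' @param transient_level peak level of transient clicks.
#' @param voice_level RMS level of the harmonic voice-like source.
#' @param voice_f0 range (Hz) from which the voice fundamental is drawn.
#' @param seed integer seed fixing the generated streams bit-exactly.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(sampling_rate = 8000, head_radius = 0.095,
                         speed_of_sound = 343, ild_max_db = 6,
                         shadow_fc_min = 1200, ambient_level = 0.05,
                         transient_rate = 4, transient_level = 0.5,
                         voice_level = 0.3, voice_f0 = c(120, 220),
                         seed = 1L) {
  stopifnot(sampling_rate > 0, head_radius > 0, speed_of_sound > 0,
            ild_max_db >= 0, shadow_fc_min > 0, length(voice_f0) == 2)
  structure(list(sampling_rate = sampling_rate, head_radius = head_radius,
                 speed_of_sound = speed_of_sound, ild_max_db = ild_max_db,
                 shadow_fc_min = shadow_fc_min, ambient_level = ambient_level,
                 transient_rate = transient_rate,
                 transient_level = transient_level,
                 voice_level = voice_level, voice_f0 = voice_f0,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Binaural scene configuration\n")
  cat(sprintf("  sampling rate: %g Hz, head radius: %g m (ITD max %.0f us)\n",
              x$sampling_rate, x$head_radius,
              1e6 * itd_seconds(90, x)))
  cat(sprintf("  head shadow: up to %g dB, low-pass down to %g Hz\n",
              x$ild_max_db, x$shadow_fc_min))
  cat(sprintf("  sources: ambient %g, transients %g/s @ %g, voice %g (f0 %g-%g Hz)\n",
              x$ambient_level, x$transient_rate, x$transient_level,
              x$voice_level, x$voice_f0[1], x$voice_f0[2]))
  invisible(x)
}

# Woodworth spherical-head ITD (seconds, unsigned) for an azimuth in
# degrees: (r/c)(sin th + th) on the front quadrant, mirrored behind.
itd_seconds <- function(azimuth, config) {
  eff <- pmin(abs(azimuth), 180 - abs(azimuth)) * pi / 180
  (config$head_radius / config$speed_of_sound) * (sin(eff) + eff)
}

# Lateralization factor in [0, 1]: 0 on the midline/front-back axis,
# 1 at +/-90 degrees. Drives shadow gain and cutoff.
lateral_factor <- function(azimuth) {
  sin(pmin(abs(azimuth), 180 - abs(azimuth)) * pi / 180)
}

# First-order low-pass (one-pole) with cutoff fc, unity DC gain.
one_pole_lowpass <- function(x, fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

#' Render a mono source at an azimuth into a binaural epoch
#'
#' Places a mono waveform on the horizontal plane. The far ear receives
#' the waveform delayed by the Woodworth spherical-head interaural time
#' difference (fractional delay by windowed-sinc interpolation) and
#' attenuated by a frequency-dependent head shadow: a first-order
#' low-pass whose cutoff and broadband gain depend on |azimuth|.
#' Azimuths 0 and +/-180 yield identical channels (no pinna model, so
#' front and back are symmetric).
#'
#' @param waveform finite numeric vector of mono samples.
#' @param azimuth source azimuth in degrees, in (-180, 180].
#' @param config a [scene_config()].
#' @return an object of class `binaural_epoch`: list with elements
#'   `left`, `right`, `sampling_rate`, `azimuth`.
#' @export
render_source <- function(waveform, azimuth, config = scene_config()) {
  stopifnot_finite(waveform, "waveform")
  if (length(azimuth) != 1 || azimuth <= -180 || azimuth > 180)
    stop("azimuth must be a single value in (-180, 180]", call. = FALSE)
  fs <- config$sampling_rate
  lat <- lateral_factor(azimuth)
  if (lat < 1e-12) {          # midline (0 or +/-180): identical channels
    return(binaural_epoch(waveform, waveform, fs, azimuth))
  }
  d <- itd_seconds(azimuth, config) * fs       # far-ear delay in samples
  gain <- 10^(-config$ild_max_db * lat / 20)
  fc <- config$shadow_fc_min +
    (fs / 2 - config$shadow_fc_min) * (1 - lat)
  far <- gain * one_pole_lowpass(frac_delay(waveform, d), fc, fs)
  if (azimuth > 0) binaural_epoch(far, waveform, fs, azimuth)
  else             binaural_epoch(waveform, far, fs, azimuth)
}

#' Construct a binaural epoch
#'
#' @param left,right equal-length numeric sample vectors.
#' @param sampling_rate sampling rate in Hz.
#' @param azimuth optional azimuth label in degrees.
#' @return object of class `binaural_epoch`.
#' @export
binaural_epoch <- function(left, right, sampling_rate = 8000, azimuth = NA) {
  stopifnot(length(left) == length(right))
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 sampling_rate = sampling_rate, azimuth = azimuth),
            class = "binaural_epoch")
}

#' @export
print.binaural_epoch <- function(x, ...) {
  cat(sprintf("binaural epoch: %d samples @ %g Hz (%.1f ms)%s\n",
              length(x$left), x$sampling_rate,
              1000 * length(x$left) / x$sampling_rate,
              if (is.na(x$azimuth)) "" else
                sprintf(", azimuth %g deg", x$azimuth)))
  invisible(x)
}

#' Sector centers of the 18-sector azimuth grid
#'
#' The circle is tiled by 18 non-overlapping 20-degree sectors with
#' centers at -170, -150, ..., +170 degrees.
#' @return numeric vector of 18 sector-center angles in degrees.
#' @export
sector_centers <- function() seq(-170, 170, by = 20)

#' Sector index of an azimuth
#'
#' @param azimuth azimuth(s) in degrees, in (-180, 180].
#' @return integer sector index in 1..18; sector k covers
#'   (-180 + 20(k-1), -180 + 20k].
#' @export
sector_of <- function(azimuth) {
  stopifnot(all(azimuth > -180 & azimuth <= 180))
  as.integer(ceiling((azimuth + 180) / 20))
}

#' Circling-source test recording
#'
#' Emulates the spatial-tuning test protocol: a mono source circles the
#' listener `n_turns` times at a constant angular rate; the recording is
#' divided into 18 sectors of 20 degrees, and epochs drawn from
#' equal-angle intervals across turns are pooled into the same sector.
#' Within each sector the azimuth advances in 4-degree sub-steps.
#'
#' @param source_waveform mono source samples; recycled circularly if
#'   shorter than the full sweep.
#' @param n_turns number of full circles (>= 1).
#' @param config a [scene_config()].
#' @param epoch_length epoch length T in samples.
#' @param epochs_per_sector number of epochs to draw per sector
#'   (pooled over turns; default 3000).
#' @param dwell seconds spent in each 20-degree sector per turn.
#' @param seed integer seed for epoch-start sampling.
#' @return an object of class `epoch_set`: list of `binaural_epoch`s plus
#'   parallel `azimuth` and `sector` vectors and `positions`
#'   (= [sector_centers()]).
#' @export
circling_recording <- function(source_waveform, n_turns, config = scene_config(),
                               epoch_length = 128, epochs_per_sector = 3000,
                               dwell = 0.5, seed = config$seed) {
  stopifnot(n_turns >= 1)
  fs <- config$sampling_rate
  dwell_n <- round(dwell * fs)
  if (epoch_length > dwell_n)
    stop("epoch length exceeds the dwell time per sector", call. = FALSE)
  n_sub <- 5                                   # 4-degree azimuth sub-steps
  sub_n <- ceiling(dwell_n / n_sub)
  centers <- sector_centers()
  with_seed(seed, {
    per_turn <- distribute_counts(epochs_per_sector, n_turns)
    epochs <- vector("list", 18 * epochs_per_sector)
    azim <- numeric(length(epochs)); sect <- integer(length(epochs))
    pos <- 1L; src_pos <- 0L
    for (turn in seq_len(n_turns)) {
      for (k in 1:18) {
        sub_az <- centers[k] + seq(-8, 8, by = 4)   # 5 sub-steps, 4 deg apart
        chunkL <- chunkR <- numeric(0)
        chunk_az <- numeric(0)
        for (a in sub_az) {
          w <- take_circular(source_waveform, src_pos, sub_n)
          src_pos <- src_pos + sub_n
          be <- render_source(w, a, config)
          chunkL <- c(chunkL, be$left); chunkR <- c(chunkR, be$right)
          chunk_az <- c(chunk_az, rep(a, sub_n))
        }
        n_draw <- per_turn[turn]
        starts <- sample.int(length(chunkL) - epoch_length + 1, n_draw,
                             replace = TRUE)
        for (s in starts) {
          idx <- s:(s + epoch_length - 1)
          epochs[[pos]] <- binaural_epoch(chunkL[idx], chunkR[idx], fs,
                                          chunk_az[s])
          azim[pos] <- chunk_az[s]; sect[pos] <- k
          pos <- pos + 1L
        }
      }
    }
    structure(list(epochs = epochs, azimuth = azim, sector = sect,
                   positions = centers, sampling_rate = fs,
                   epoch_length = epoch_length),
              class = "epoch_set")
  })
}

# Split `total` into `k` near-equal integer parts (differ by at most 1).
distribute_counts <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1, extra), rep(0, k - extra))
}

# Read `n` samples starting at offset `pos` (0-based), recycling the
# source circularly.
take_circular <- function(x, pos, n) {
  idx <- (pos + seq_len(n) - 1) %% length(x) + 1
  x[idx]
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch set: %d epochs of %d samples @ %g Hz, %d sectors\n",
              length(x$epochs), x$epoch_length, x$sampling_rate,
              length(unique(x$sector))))
  invisible(x)
}

#' Synthetic binaural training stream
#'
#' Generates a "walk"-like unlabelled binaural stream: an ambient
#' broadband noise bed, Poisson transient clicks, and an intermittent
#' harmonic voice-like source, each rendered at azimuths drawn uniformly
#' over the full circle (hence symmetrically over both hemifields).
#' Bit-exactly reproducible under the config seed.
#'
#' @param duration stream duration in seconds (> 0).
#' @param config a [scene_config()].
#' @param seed integer seed (defaults to the config seed).
#' @return a `binaural_epoch` holding the full-length stream.
#' @export
make_training_stream <- function(duration, config = scene_config(),
                                 seed = config$seed) {
  stopifnot(duration > 0)
  fs <- config$sampling_rate
  seg_n <- round(0.5 * fs)                       # 0.5 s scene segments
  n_seg <- ceiling(duration * fs / seg_n)
  with_seed(seed, {
    L <- R <- numeric(n_seg * seg_n)
    for (g in seq_len(n_seg)) {
      at <- (g - 1) * seg_n
      seg <- render_segment(seg_n, config)
      L[at + seq_len(seg_n)] <- seg$left
      R[at + seq_len(seg_n)] <- seg$right
    }
    n <- round(duration * fs)
    binaural_epoch(L[seq_len(n)], R[seq_len(n)], fs)
  })
}

rand_azimuth <- function() stats::runif(1, -180 + 1e-9, 180)

# One 0.5 s scene segment: ambient bed + transients + optional voice.
render_segment <- function(seg_n, config) {
  fs <- config$sampling_rate
  # ambient: gently low-passed white noise, broadband up to ~Nyquist
  amb <- one_pole_lowpass(stats::rnorm(seg_n), 2500, fs)
  amb <- config$ambient_level * amb / max(stats::sd(amb), 1e-12)
  out <- render_source(amb, rand_azimuth(), config)
  # transients: decaying noise bursts at own azimuths
  n_tr <- stats::rpois(1, config$transient_rate * seg_n / fs)
  for (i in seq_len(n_tr)) {
    len <- round(stats::runif(1, 0.005, 0.02) * fs)
    burst <- stats::rnorm(len) * exp(-seq_len(len) / (0.2 * len))
    burst <- config$transient_level * burst / max(abs(burst))
    at <- sample.int(seg_n - len, 1)
    b <- render_source(burst, rand_azimuth(), config)
    idx <- at + seq_len(len)
    out$left[idx] <- out$left[idx] + b$left
    out$right[idx] <- out$right[idx] + b$right
  }
  # harmonic voice-like source, present in half the segments
  if (stats::runif(1) < 0.5) {
    f0 <- stats::runif(1, config$voice_f0[1], config$voice_f0[2])
    t <- seq_len(seg_n) / fs
    nh <- floor((fs / 2 * 0.9) / f0)
    amp <- (1 / seq_len(nh))                    # 1/k harmonic rolloff
    ph <- stats::runif(nh, 0, 2 * pi)
    v <- colSums(amp * sin(outer(f0 * seq_len(nh), 2 * pi * t) +
                             ph))
    env <- sin(pi * seq_len(seg_n) / seg_n)^2   # on/off envelope
    v <- config$voice_level * env * v / max(stats::sd(v), 1e-12)
    b <- render_source(v, rand_azimuth(), config)
    out$left <- out$left + b$left
    out$right <- out$right + b$right
  }
  out
}
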