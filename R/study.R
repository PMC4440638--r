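# End-to-end desk-scale study: synthetic scene -> layer 1 -> IPD
# selection -> layer 2 -> spatial tuning, opponent-channel clustering
# and population decoding.

#' Run the full opponent-channel study on a synthetic scene
#'
#' Generates a synthetic binaural "walk" training stream, trains the
#' two-layer sparse-coding model on it, probes the model with a
#' synthetic circling broadband source divided into 18 azimuth sectors,
#' and computes spatial tuning curves, opponent-channel clusters,
#' centroid and maximal-slope statistics, and decoding information.
#'
#' The defaults are a desk-scale configuration (T = 64 sample epochs,
#' 32 first-layer atoms, M = 64 second-layer atoms, 500 epochs per
#' sector) that runs in minutes; the paper-scale configuration
#' (T = 128, 128 atoms, M = 256, 3000 epochs per sector, hundreds of
#' thousands of updates) uses the same code path.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param T epoch length in samples.
#' @param n_atoms number of first-layer atoms.
#' @param M number of second-layer atoms.
#' @param duration training-stream duration in seconds.
#' @param n_epochs number of training epoch pairs.
#' @param n_reject PCA components to reject (default: same proportion
#'   as 18 of 128).
#' @param epochs_per_sector circling-protocol epochs per sector.
#' @param n_iter1,n_iter2 dictionary update counts for the two layers.
#' @param config a [scene_config()] (its seed is overridden by `seed`).
#' @param verbose print stage progress.
#' @return a list of class `opponent_study` with elements `layer1`,
#'   `selection`, `layer2`, `tuning`, `clusters`, `centroid_deg`,
#'   `max_slope_deg` (per kept unit), `mean_ipd_left` (mean selected-
#'   channel IPD over left-hemifield test epochs), `unit_mi`,
#'   `info_curves`, `codes` (`s` matrix and `sector` labels), and the
#'   run parameters.
#' @export
opponent_channel_study <- function(seed = 1L, T = 64, n_atoms = 32, M = 64,
                                   duration = 60, n_epochs = 15000,
                                   n_reject = round(18 / 128 * T),
                                   epochs_per_sector = 500,
                                   n_iter1 = 3000, n_iter2 = 3000,
                                   config = scene_config(),
                                   verbose = FALSE) {
  seed <- as.integer(seed)
  config$seed <- seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("rendering %gs synthetic walk ...", duration)
  stream <- make_training_stream(duration, config, seed = seed)
  pairs <- extract_epochs(stream, T = T, count = n_epochs, seed = seed + 1L)
  mono <- pool_epochs(pairs, seed = seed + 2L)
  # one global gain standardizing epochs to unit RMS, so the sparse
  # prior operates at the intended coefficient scale
  gain <- 1 / sqrt(mean(mono^2))
  mono <- gain * mono

  say("PCA low-pass (rejecting %d of %d components) ...", n_reject, T)
  pca <- fit_project_pca(mono, n_reject = n_reject)

  say("training layer 1 (%d atoms, %d updates) ...", n_atoms, n_iter1)
  l1 <- fit_layer1(pca$x, n_atoms = n_atoms, n_iter = n_iter1,
                   sampling_rate = config$sampling_rate, seed = seed + 3L)
  sel <- select_channels(l1)
  say("selected %d IPD channels", sel$P)

  say("encoding %d training pairs ...", n_epochs)
  train_left <- project_epochs(pca$projector, gain * pairs$left)
  train_right <- project_epochs(pca$projector, gain * pairs$right)
  codes <- predict(l1, list(left = train_left, right = train_right))
  obs <- make_joint_obs(codes$left, codes$right, sel)

  say("training layer 2 (M = %d, %d updates) ...", M, n_iter2)
  l2 <- fit_layer2(obs, M = M, n_iter = n_iter2, n_steps = 30,
                   seed = seed + 4L)

  say("rendering circling probe (%d epochs/sector) ...", epochs_per_sector)
  probe_src <- with_seed(seed + 5L,
                         one_pole_lowpass(stats::rnorm(8 * config$sampling_rate),
                                          2000, config$sampling_rate))
  es <- circling_recording(probe_src, n_turns = 4, config = config,
                           epoch_length = T,
                           epochs_per_sector = epochs_per_sector,
                           seed = seed + 6L)
  mats <- epoch_set_matrices(es)
  # probe gain chosen like the training gain: unit RMS over the pooled
  # probe epochs, so layer-1 operates at its calibrated scale
  pgain <- 1 / sqrt(mean(c(mats$left^2, mats$right^2)))
  test_left <- project_epochs(pca$projector, pgain * mats$left)
  test_right <- project_epochs(pca$projector, pgain * mats$right)
  tcodes <- predict(l1, list(left = test_left, right = test_right))
  tobs <- make_joint_obs(tcodes$left, tcodes$right, sel)
  tcode2 <- predict(l2, tobs)

  left_epochs <- es$azimuth > -180 & es$azimuth < 0
  mean_ipd_left <- mean(tobs$dphi[, left_epochs])

  say("tuning curves, clustering, decoding ...")
  ts <- estimate_tuning(tcode2$s, es$sector)
  cl <- cluster_curves(ts, k = 2, seed = seed + 7L)
  centroid_deg <- apply(ts$curves, 1, curve_centroid,
                        positions = ts$positions)
  side <- ifelse(cl$labels == 1, "left", "right")
  max_slope_deg <- vapply(seq_len(nrow(ts$curves)), function(i)
    max_slope_position(ts$curves[i, ], ts$positions, side[i]), numeric(1))

  umi <- unit_information(tcode2$s, es$sector, seed = seed + 8L)
  ic <- information_curves(tcode2$s, es$sector,
                           unit_counts = c(1, 2, 4, 8, 16, 32, M),
                           D_values = c(1, 4, 16), n_repeats = 5,
                           seed = seed + 9L)

  structure(list(layer1 = l1, selection = sel, layer2 = l2,
                 pca = pca$projector, tuning = ts, clusters = cl,
                 centroid_deg = centroid_deg,
                 max_slope_deg = max_slope_deg,
                 mean_ipd_left = mean_ipd_left,
                 unit_mi = umi, info_curves = ic,
                 codes = list(s = tcode2$s, sector = es$sector),
                 params = list(seed = seed, T = T, n_atoms = n_atoms,
                               M = M, epochs_per_sector = epochs_per_sector)),
            class = "opponent_study")
}

#' @export
print.opponent_study <- function(x, ...) {
  p <- x$params
  cat(sprintf("Opponent-channel study (seed %d): T = %d, %d layer-1 atoms, M = %d\n",
              p$seed, p$T, p$n_atoms, p$M))
  cat(sprintf("  IPD channels: %d; clusters: %d / %d units\n",
              x$selection$P, sum(x$clusters$labels == 1),
              sum(x$clusters$labels == 2)))
  os <- opponent_summary(x)
  for (j in 1:2)
    cat(sprintf("  cluster %d centroid mean: %+.0f deg\n", j,
                os$centroid_mean_deg[j]))
  cat(sprintf("  max-slope positions (|rho|-filtered, n = %d): mode %+.0f deg, median |.| %.0f deg\n",
              os$n_units, os$slope_mode_deg, os$median_abs_slope_deg))
  cat(sprintf("  mean IPD, left-hemifield probes: %+.3f rad\n",
              x$mean_ipd_left))
  cat(sprintf("  median single-unit MI: %.2f bits; best population MI: %.2f bits\n",
              stats::median(x$unit_mi, na.rm = TRUE),
              max(x$info_curves$MI_bits)))
  invisible(x)
}

#' Opponent-channel summary of a study
#'
#' Convenience checks of the study outcome: whether the two tuning-curve
#' clusters place their centroid distributions in opposite hemifields
#' and whether the maximal-slope positions concentrate at the midline.
#' Following the tuning-analysis protocol, the statistics are computed
#' on the strongly position-correlated units (`|rho| > rho_min`); if
#' fewer than `min_units` qualify (or one cluster loses all members)
#' the full population is used instead.
#'
#' @param study an `opponent_study`.
#' @param rho_min position-correlation filter (default 0.75).
#' @param min_units minimal filtered population size (default 6).
#' @return list with `centroid_mean_deg` (per cluster), `opposite`
#'   (logical: centroid means in opposite hemifields),
#'   `slope_mode_deg` (mode of the maximal-slope positions over the
#'   20-degree grid), `median_abs_slope_deg`, and `n_units` used.
#' @export
opponent_summary <- function(study, rho_min = 0.75, min_units = 6) {
  lab <- study$clusters$labels
  keep <- abs(study$tuning$rho) > rho_min
  if (sum(keep) < min_units || length(unique(lab[keep])) < 2)
    keep <- rep(TRUE, length(lab))
  cm <- vapply(1:2, function(j)
    circ_mean_deg(study$centroid_deg[keep & lab == j]), numeric(1))
  sl <- study$max_slope_deg[keep]
  tab <- table(sl)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  list(centroid_mean_deg = cm,
       opposite = prod(sign(cm)) < 0,
       slope_mode_deg = modes[which.min(abs(modes))],
       median_abs_slope_deg = stats::median(abs(sl)),
       n_units = sum(keep))
}
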