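# Spatial tuning: position-conditional response statistics of layer-2
# units on the 18-sector circling protocol, normalization to tuning
# curves, opponent-channel clustering, and centroid / maximal-slope
# statistics.

#' Estimate spatial tuning curves
#'
#' For each layer-2 unit, the raw tuning curve is the mean coefficient
#' `s_i` over epochs in each azimuth sector; it is normalized to \[0, 1\]
#' by subtracting the minimum and dividing by the resulting maximum.
#' Units whose raw curve is constant across sectors (max = min) have no
#' defined normalization and are excluded (and flagged).
#'
#' @param s `M x E` matrix of layer-2 coefficients (or a `layer2_code`).
#' @param sector integer sector index per epoch (1..length(positions)).
#' @param positions sector-center angles in degrees (default
#'   [sector_centers()]).
#' @return object of class `tuning_set`: `positions`, `mu_raw`
#'   (units x sectors), `curves` (normalized, kept units only), `rho`
#'   (Pearson correlation of each kept curve with position), `units`
#'   (kept unit indices), `excluded` (flagged unit indices).
#' @export
estimate_tuning <- function(s, sector, positions = sector_centers()) {
  if (inherits(s, "layer2_code")) s <- s$s
  stopifnot(ncol(s) == length(sector))
  K <- length(positions)
  got <- sort(unique(sector))
  if (length(got) < 2) stop("need at least 2 sectors", call. = FALSE)
  mu <- vapply(seq_len(K), function(k) {
    idx <- sector == k
    if (sum(idx) == 0) return(rep(NA_real_, nrow(s)))
    rowMeans(s[, idx, drop = FALSE])
  }, numeric(nrow(s)))                     # units x sectors
  rng <- apply(mu, 1, function(v) diff(range(v)))
  keep <- which(is.finite(rng) & rng > 1e-12)
  excluded <- setdiff(seq_len(nrow(s)), keep)
  if (length(excluded))
    warning(length(excluded),
            " unit(s) with constant conditional mean excluded")
  curves <- t(apply(mu[keep, , drop = FALSE], 1, function(v)
    (v - min(v)) / (max(v) - min(v))))
  rho <- apply(curves, 1, position_correlation, positions = positions)
  structure(list(positions = positions, mu_raw = mu, curves = curves,
                 rho = rho, units = keep, excluded = excluded),
            class = "tuning_set")
}

#' Correlation of a tuning curve with sound position
#'
#' Pearson correlation between curve values and sector-center angles in
#' degrees (linear angle). |rho| close to 1 flags monotone lateralized
#' curves.
#'
#' @param curve normalized tuning-curve values.
#' @param positions sector-center angles in degrees.
#' @return correlation coefficient.
#' @export
position_correlation <- function(curve, positions = sector_centers()) {
  stopifnot(length(curve) == length(positions), length(curve) >= 3)
  stats::cor(curve, positions)
}

#' Cluster tuning curves into opponent channels
#'
#' Euclidean k-means (multiple restarts) on normalized tuning curves.
#' Cluster labels are relabelled deterministically so that cluster 1 is
#' the one whose centroid has more mass in the left hemifield.
#'
#' @param tuning a `tuning_set` (or a units-x-sectors curve matrix).
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 10).
#' @return list with `labels` (per kept unit, values 1..k), `centroids`
#'   (k x sectors matrix of per-cluster mean curves), `positions`.
#' @export
cluster_curves <- function(tuning, k = 2, seed = 1L, nstart = 10) {
  curves <- if (inherits(tuning, "tuning_set")) tuning$curves else tuning
  positions <- if (inherits(tuning, "tuning_set")) tuning$positions
               else sector_centers()
  if (nrow(curves) < k) stop("fewer curves than clusters", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(curves, centers = k, nstart = nstart))
  labels <- km$cluster
  cent <- km$centers
  if (k == 2) {
    leftness <- cent %*% ifelse(positions < 0, 1, -1)
    ord <- order(-leftness)                 # 1 = left-preferring cluster
    labels <- match(labels, ord)
    cent <- cent[ord, , drop = FALSE]
  }
  # centroid = mean of members (k-means property, recomputed for clarity)
  cent <- t(vapply(seq_len(k), function(j)
    colMeans(curves[labels == j, , drop = FALSE]), numeric(ncol(curves))))
  list(labels = labels, centroids = cent, positions = positions)
}

#' Tuning-curve centroid
#'
#' Circular mean of the sector-center angles where the normalized
#' activation is at least `threshold` (default 0.75; always non-empty
#' because the curve maximum is 1).
#'
#' @param curve normalized tuning curve (min 0, max 1).
#' @param positions sector-center angles in degrees.
#' @param threshold activation threshold (default 0.75).
#' @return centroid angle in degrees, in (-180, 180].
#' @export
curve_centroid <- function(curve, positions = sector_centers(),
                           threshold = 0.75) {
  qual <- curve >= threshold
  stopifnot(any(qual))
  circ_mean_deg(positions[qual])
}

#' Position of maximal slope toward the midline
#'
#' Discrete slopes are differences of adjacent normalized curve values
#' over the 20-degree step, including the wraparound pair
#' (+170 to -170). For left-hemifield (cluster 1) units the position of
#' the minimal signed slope is returned, for right-hemifield units the
#' maximal; the returned angle is the circular midpoint of the adjacent
#' pair. Ties are broken toward the midline (smaller |angle|).
#'
#' @param curve normalized tuning curve.
#' @param positions sector-center angles in degrees.
#' @param cluster_side `"left"` or `"right"`.
#' @return midpoint angle in degrees of the extremal-slope pair.
#' @export
max_slope_position <- function(curve, positions = sector_centers(),
                               cluster_side = c("left", "right")) {
  cluster_side <- match.arg(cluster_side)
  stopifnot(length(curve) >= 2)
  n <- length(curve)
  nxt <- c(2:n, 1)
  step <- 360 / n
  slope <- (curve[nxt] - curve) / step
  mid <- vapply(seq_len(n), function(k)
    circ_mean_deg(c(positions[k], positions[k] +
                      wrap_deg(positions[nxt[k]] - positions[k]))),
    numeric(1))
  val <- if (cluster_side == "left") slope else -slope
  best <- which(abs(val - min(val)) < 1e-12)
  mid[best[which.min(abs(mid[best]))]]
}

wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' @export
print.tuning_set <- function(x, ...) {
  cat(sprintf("tuning curves: %d units over %d sectors (%d excluded); %d with |rho| > 0.75\n",
              nrow(x$curves), length(x$positions), length(x$excluded),
              sum(abs(x$rho) > 0.75)))
  invisible(x)
}

#' Plot tuning curves
#'
#' Overlays normalized tuning curves (gray) with an optional cluster
#' partition, drawing the per-cluster mean curves in black.
#'
#' @param x a `tuning_set`.
#' @param clusters optional result of [cluster_curves()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tuning_set <- function(x, clusters = NULL, ...) {
  if (is.null(clusters)) {
    graphics::matplot(x$positions, t(x$curves), type = "l", lty = 1,
                      col = "gray70", xlab = "azimuth (deg)",
                      ylab = "normalized response", ...)
    graphics::lines(x$positions, colMeans(x$curves), lwd = 2)
  } else {
    k <- nrow(clusters$centroids)
    op <- graphics::par(mfrow = c(1, k))
    on.exit(graphics::par(op))
    for (j in seq_len(k)) {
      graphics::matplot(x$positions,
                        t(x$curves[clusters$labels == j, , drop = FALSE]),
                        type = "l", lty = 1, col = "gray70",
                        xlab = "azimuth (deg)",
                        ylab = "normalized response",
                        main = sprintf("cluster %d", j), ...)
      graphics::lines(x$positions, clusters$centroids[j, ], lwd = 2)
    }
  }
  invisible(x)
}
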