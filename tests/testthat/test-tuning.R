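# Tuning-curve estimation, clustering, centroid and slope statistics.

# mirror-image sigmoid families used as planted opponent channels
sigmoid_curve <- function(positions, side, noise = 0, center = 0) {
  v <- 1 / (1 + exp(-(side * (positions - center)) / 30))
  v <- v + noise * rnorm(length(v))
  (v - min(v)) / (max(v) - min(v))
}

test_that("tuning curves are sector means normalized to [0, 1]", {
  pos <- sector_centers()
  set.seed(1)
  sector <- rep(1:18, each = 40)
  M <- 3
  s <- matrix(0, M, length(sector))
  # unit 1 responds only in sector 5 (-90 deg)
  s[1, sector == 5] <- 2 + rnorm(40, sd = 0.01)
  # unit 2: linear-in-angle mean
  s[2, ] <- pos[sector] / 100 + rnorm(length(sector), sd = 0.01)
  # unit 3: constant (degenerate)
  s[3, ] <- 1
  expect_warning(ts <- estimate_tuning(s, sector), "constant")
  expect_equal(ts$excluded, 3)
  expect_equal(which.max(ts$curves[1, ]), 5L)
  expect_gt(min(ts$curves[1, -5]), -1e-9)
  expect_lt(max(ts$curves[1, -5]), 0.05)
  expect_true(all(abs(apply(ts$curves, 1, min)) < 1e-12))
  expect_true(all(abs(apply(ts$curves, 1, max) - 1) < 1e-12))
  expect_gt(ts$rho[2], 0.99)
})

test_that("position correlation matches the textbook formula and its symmetries", {
  pos <- sector_centers()
  lin <- (pos + 170) / 340
  expect_equal(position_correlation(lin, pos), 1)
  mirror <- 1 - abs(pos) / 180
  expect_equal(position_correlation(mirror, pos), 0, tolerance = 1e-12)
  set.seed(2)
  v <- runif(18)
  expect_equal(position_correlation(v, pos),
               sum((v - mean(v)) * (pos - mean(pos))) /
                 sqrt(sum((v - mean(v))^2) * sum((pos - mean(pos))^2)))
})

test_that("k-means separates planted mirror-image sigmoid families perfectly", {
  pos <- sector_centers()
  set.seed(3)
  n_per <- 15
  curves <- rbind(
    t(replicate(n_per, sigmoid_curve(pos, side = -1, noise = 0.03))),
    t(replicate(n_per, sigmoid_curve(pos, side = +1, noise = 0.03))))
  truth <- rep(1:2, each = n_per)
  cl <- cluster_curves(curves, k = 2, seed = 4)
  expect_equal(adjusted_rand(cl$labels, truth), 1)
  expect_setequal(unique(cl$labels), 1:2)
  # centroid equals the mean of its members
  expect_equal(cl$centroids[1, ], colMeans(curves[cl$labels == 1, ]))
  # deterministic orientation: cluster 1 prefers the left hemifield
  expect_gt(sum(cl$centroids[1, pos < 0]), sum(cl$centroids[1, pos > 0]))
  expect_error(cluster_curves(curves[1, , drop = FALSE], k = 2), "fewer")
})

test_that("curve centroids are circular means of the high-activation sectors", {
  pos <- sector_centers()
  one_hot <- function(k) replace(rep(0, 18), k, 1)
  expect_equal(curve_centroid(one_hot(5), pos), -90)
  two <- rep(0, 18); two[pos %in% c(-110, -70)] <- 1
  expect_equal(curve_centroid(two, pos), -90)
  # wraparound: +170 and -170 average to 180, not 0
  wrap <- rep(0, 18); wrap[pos %in% c(-170, 170)] <- 1
  expect_equal(curve_centroid(wrap, pos), 180)
})

test_that("maximal slope positions sit at the steepest adjacent pair, ties toward midline", {
  pos <- sector_centers()
  # left-tuned step curve dropping from 1 to 0 between -10 and +10
  step_curve <- as.numeric(pos < 0)
  expect_equal(max_slope_position(step_curve, pos, "left"), 0)
  # monotone linear curve: constant slope everywhere except the
  # wraparound pair; tie broken to the pair nearest 0
  lin <- (pos + 170) / 340
  expect_equal(max_slope_position(lin, pos, "right"), 0)
  # noisy sigmoids centered at 0: within one sector of the midline
  set.seed(5)
  hits <- replicate(100, {
    cv <- sigmoid_curve(pos, side = 1, noise = 0.02)
    max_slope_position(cv, pos, "right")
  })
  expect_gte(mean(abs(hits) <= 20), 0.95)
})

test_that("reflecting the azimuths mirrors tuning curves and swaps clusters", {
  pos <- sector_centers()
  set.seed(6)
  sector <- rep(1:18, each = 30)
  M <- 12
  s <- matrix(0, M, length(sector))
  for (i in 1:M) {
    side <- if (i <= 6) -1 else 1
    gain <- sigmoid_curve(pos, side = side, noise = 0)
    s[i, ] <- gain[sector] + rnorm(length(sector), sd = 0.05)
  }
  ts <- estimate_tuning(s, sector)
  # reflect: azimuth -> -azimuth maps sector k -> 19 - k
  ts_ref <- estimate_tuning(s, 19 - sector)
  expect_equal(ts_ref$curves, ts$curves[, 18:1], ignore_attr = TRUE)
  cl <- cluster_curves(ts, seed = 7)
  cl_ref <- cluster_curves(ts_ref, seed = 7)
  expect_equal(cl$labels, 3 - cl_ref$labels)
})
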