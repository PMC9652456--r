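test_that("peri-event windows have the right size and exclusions", {
  spec <- noiseless_spec(n_excited = 1, n_nonresponding = 1, n_inhibited = 1)
  ev <- apply_schedule(c(5, 30, 50), duration_s = 70)
  g <- generate_traces(ev, spec, frame_rate_hz = 30, seed = 1)
  tens <- build_peri_event_tensor(g$traces, ev)
  # 23 s at 30 Hz -> 690 timepoints; press at 5 s lacks its 10-s pre window
  expect_equal(dim(tens$values)[3], 690)
  expect_equal(tens$n_excluded, 1)
  expect_equal(dim(tens$values)[2], 2)
  # noiseless inhibited neuron: post-press trial-averaged z-score < 0
  avg <- trial_average(tens)
  post <- tens$timepoints_s >= 0 & tens$timepoints_s < 3
  expect_lt(mean(avg[3, post]), 0)
  expect_gt(mean(avg[1, post]), 0)

  expect_error(build_peri_event_tensor(g$traces,
                                       apply_schedule(numeric(0),
                                                      duration_s = 70)),
               "no usable events")
})

test_that("tensor aligns a delta-function spike to the press frame", {
  fr <- 10
  n_frames <- 2000
  set.seed(11)
  for (i in 1:10) {
    press <- runif(1, 15, 180)
    press_frame <- round(press * fr) + 1
    m <- matrix(0, 1, n_frames)
    m[1, press_frame] <- 1
    tr <- trace_matrix(m, fr)
    ev <- apply_schedule(press, duration_s = n_frames / fr)
    tens <- build_peri_event_tensor(tr, ev, zscore = FALSE)
    # the spike must land at the first timepoint of the mid segment
    expect_equal(which(tens$values[1, 1, ] == 1), round(10 * fr) + 1)
  }
})

test_that("scree knee picks the curvature maximum with a floor of 2", {
  # synthesize data whose covariance spectrum matches a chosen EVR curve
  evr_data <- function(evr, n = 120, seed = 1) {
    withr::with_seed(seed, {
      p <- length(evr)
      basis <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
      z <- matrix(rnorm(n * p), n, p)
      z <- scale(z, center = TRUE, scale = FALSE)
      z <- qr.Q(qr(z))[, seq_len(p)]         # orthonormal scores
      z %*% diag(sqrt(evr)) %*% t(basis)
    })
  }
  # the worked curvature example: knee at component 2
  r <- c(0.5, 0.3, 0.1, 0.05, 0.03)
  x <- evr_data(r / sum(r))
  sel <- select_n_components(x)
  expect_equal(sel$n_components, 2)
  expect_equal(sel$explained_variance_ratio[1:5], r / sum(r),
               tolerance = 1e-6)
  # hand-enumerated curvature agrees
  curv <- r[1:3] - 2 * r[2:4] + r[3:5]
  expect_equal(which.max(curv), 2)

  # exactly 3-dimensional noiseless data: nothing beyond 3 components
  x3 <- evr_data(c(0.6, 0.25, 0.15))
  sel3 <- select_n_components(cbind(x3, x3))   # rank 3 in 6 columns
  expect_lte(sel3$n_components, 3)
  expect_lt(sum(sel3$explained_variance_ratio[-(1:3)]), 1e-9)

  # isotropic noise: flat curve, enforced minimum with a warning
  xw <- withr::with_seed(5, matrix(rnorm(200 * 50), 200, 50))
  expect_warning(selw <- select_n_components(xw), "no clear")
  expect_equal(selw$n_components, 2)

  expect_error(select_n_components(matrix(1, 2, 5)), "3 neurons")
})

test_that("PCA reconstruction with all components is exact", {
  x <- withr::with_seed(2, matrix(rnorm(40 * 12), 40, 12))
  sel <- select_n_components(x, min_curvature = 0)
  rec <- sel$pca$x %*% t(sel$pca$rotation) +
    matrix(sel$pca$center, 40, 12, byrow = TRUE)
  expect_equal(rec, x, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("spectral clustering separates blobs and validates inputs", {
  blobs <- withr::with_seed(3, rbind(
    matrix(rnorm(60, 0, 0.1), 30, 2),
    matrix(rnorm(60, 5, 0.1), 30, 2),
    cbind(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1))))
  truth <- rep(1:3, each = 30)
  cl <- cluster_ensembles(blobs, k = 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1.0)
  # stability under row permutation (up to label swap)
  perm <- withr::with_seed(4, sample(90))
  cl2 <- cluster_ensembles(blobs[perm, ], k = 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl2$cluster, truth[perm]), 1.0)

  expect_error(cluster_ensembles(blobs, k = 1), "k must be")
  expect_error(cluster_ensembles(blobs, k = 3, knn = 95), "knn")
  # two far clusters with tiny knn: disconnected graph advises larger knn
  far <- rbind(matrix(0, 10, 2) + rnorm(20, sd = .01),
               matrix(50, 10, 2) + rnorm(20, sd = .01),
               matrix(c(0, 90), 10, 2, byrow = TRUE) + rnorm(20, sd = .01),
               matrix(c(90, 0), 10, 2, byrow = TRUE) + rnorm(20, sd = .01))
  expect_error(cluster_ensembles(far, k = 3, knn = 3, seed = 1),
               "increase knn")
})

test_that("planted ensembles are recovered and categorized from data alone", {
  ari <- numeric(3)
  for (i in 1:3) {
    cfg <- session_config(press_rate_active = 0.8, seed = 100 + i)
    ev <- generate_events(cfg)
    g <- generate_traces(ev, ensemble_spec_scaled(120), frame_rate_hz = 10,
                         seed = i)
    det <- detect_ensembles(g$traces, ev, k = 3, seed = i)
    ari[i] <- mclust::adjustedRandIndex(det$cluster, g$truth$labels)
    expect_setequal(det$cluster_category,
                    c("excited", "non_responding", "inhibited"))
  }
  expect_gte(median(ari), 0.8)
})

test_that("cluster categories follow the z threshold", {
  spec <- ensemble_spec(n_excited = 4, n_nonresponding = 4, n_inhibited = 4,
                        noise_sd = 0.05, amp_jitter_cv = 0,
                        tonic_decline_frac = 0)
  ev <- apply_schedule(seq(30, 570, by = 60), duration_s = 600)
  g <- generate_traces(ev, spec, frame_rate_hz = 10, seed = 2)
  tens <- build_peri_event_tensor(g$traces, ev)
  clustering <- list(cluster = rep(1:3, each = 4), k = 3)
  cats <- categorize_clusters(clustering, tens)
  expect_equal(cats$cluster_category,
               c("excited", "non_responding", "inhibited"))
  expect_equal(cats$category, rep(cats$cluster_category, each = 4))
  # an infinite threshold makes everything non-responding
  cats_inf <- categorize_clusters(clustering, tens, theta = Inf)
  expect_true(all(cats_inf$cluster_category == "non_responding"))
})

test_that("tonic bins recover planted decline and normalize correctly", {
  fr <- 2
  # constant traces -> every normalized bin is 1
  tr <- trace_matrix(matrix(3, 4, 1800 * fr), fr)
  tb <- tonic_bins(tr)
  expect_true(all(abs(tb$bins - 1) < 1e-12))
  # 45-min session at 3-min bins -> 15 bins
  expect_equal(ncol(tonic_bins(trace_matrix(matrix(2, 1, 2700 * fr),
                                            fr))$bins), 15)

  # planted 30% decline, noiseless: last/first close to 0.7 (bin means sit
  # at bin centres, so the exact noiseless ratio is ~0.713)
  spec <- ensemble_spec(n_excited = 0, n_nonresponding = 5, n_inhibited = 0,
                        tonic_decline_frac = 0.3, noise_sd = 0,
                        amp_jitter_cv = 0)
  ev <- apply_schedule(numeric(0), duration_s = 3600)
  g <- generate_traces(ev, spec, frame_rate_hz = fr, seed = 1)
  tb <- tonic_bins(g$traces)
  expect_equal(mean(tb$first_last$ratio), 0.7, tolerance = 0.02)

  # both normalization modes give unit population first bin
  tbp <- tonic_bins(g$traces, normalize = "population_baseline")
  expect_equal(mean(tbp$bins[, 1]), 1)

  expect_error(tonic_bins(trace_matrix(matrix(1, 1, 100), fr)), "2 bins")
})
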