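# epoch feature sets built directly, bypassing trace extraction
manual_features <- function(x, y) {
  structure(list(x = x, y = factor(y, levels = c("baseline", "pre_press")),
                 epoch_start_s = seq_len(nrow(x)), epoch_s = 1),
            class = "epoch_feature_set")
}

test_that("epoch features are balanced, clean of presses, deterministic", {
  spec <- ensemble_spec_scaled(20, noise_sd = 0.1)
  cfg <- session_config(press_rate_active = 0.8, seed = 5)
  ev <- generate_events(cfg)
  g <- generate_traces(ev, spec, frame_rate_hz = 10, seed = 5)
  f <- build_epoch_features(g$traces, ev, seed = 9)
  n_press <- sum(active_press_times_test(ev) >= 1)
  expect_equal(table(f$y)[["pre_press"]], n_press)
  expect_equal(table(f$y)[["baseline"]], n_press)
  # baseline epochs avoid [-10, +13] s around every press
  base_starts <- f$epoch_start_s[f$y == "baseline"]
  for (tp in active_press_times_test(ev))
    expect_true(all(base_starts + 1 <= tp - 10 | base_starts >= tp + 13))
  # baselines do not overlap each other
  expect_true(all(diff(sort(base_starts)) >= 1))
  # determinism
  f2 <- build_epoch_features(g$traces, ev, seed = 9)
  expect_identical(f$epoch_start_s, f2$epoch_start_s)

  # a press in the first second is excluded from the epochs
  ev_early <- apply_schedule(c(0.5, 100, 200, 300, 400, 500),
                             duration_s = 600)
  f3 <- build_epoch_features(trace_matrix(matrix(1, 2, 6000), 10), ev_early,
                             seed = 1)
  expect_equal(sum(f3$y == "pre_press"), 5)

  expect_error(build_epoch_features(g$traces,
                                    apply_schedule(c(100, 200),
                                                   duration_s = 3600),
                                    seed = 1),
               "insufficient")
})

test_that("decoder is perfect on separable data and at chance on null data", {
  # planted separable neuron: pre-press -1, baseline 0, no noise
  n <- 40
  x <- cbind(c(rep(0, n), rep(-1, n)))
  y <- rep(c("baseline", "pre_press"), each = n)
  f <- manual_features(x, y)
  expect_equal(decode(f, "per_neuron", seed = 1), 1.0)
  expect_equal(decode(f, "population", seed = 1), 1.0)

  # feature independent of label: accuracy within the binomial 95% CI of 0.5
  xr <- withr::with_seed(8, cbind(rnorm(2 * n)))
  fr <- manual_features(xr, y)
  acc <- decode(fr, "per_neuron", seed = 2)
  ci <- 1.96 * sqrt(0.25 / (2 * n))
  expect_lt(abs(acc - 0.5), ci + 0.05)

  # affine rescaling of a feature column leaves accuracy unchanged
  xs <- withr::with_seed(9, cbind(rnorm(2 * n, sd = 2),
                                  c(rnorm(n), rnorm(n, 1))))
  fs <- manual_features(xs, y)
  a0 <- decode(fs, "per_neuron", seed = 3)
  fs2 <- fs; fs2$x <- sweep(sweep(fs$x, 2, c(2, -3), "*"), 2, c(5, -1), "+")
  expect_equal(decode(fs2, "per_neuron", seed = 3), a0)

  expect_error(decode(manual_features(x, rep("baseline", 2 * n))),
               "single class")
})

test_that("population decoding beats the best single neuron on planted data", {
  # several weakly informative neurons: the population pools them
  gap <- 0.6
  diffs <- vapply(1:20, function(s) {
    x <- withr::with_seed(500 + s, {
      n <- 30
      sig <- matrix(rnorm(2 * n * 5, sd = 1), 2 * n, 5)
      sig[(n + 1):(2 * n), ] <- sig[(n + 1):(2 * n), ] + gap
      sig
    })
    y <- rep(c("baseline", "pre_press"), each = 30)
    f <- manual_features(x, y)
    pop <- decode(f, "population", seed = 1)
    best <- max(decode(f, "per_neuron", seed = 1))
    pop - best
  }, numeric(1))
  expect_gte(mean(diffs), -0.05)   # within fold noise of the best neuron
})

test_that("shuffle null centres on chance and subtracts by group", {
  n <- 100
  x <- withr::with_seed(21, matrix(rnorm(2 * n * 6), 2 * n, 6))
  y <- rep(c("baseline", "pre_press"), each = n)
  f <- manual_features(x, y)
  null <- shuffle_null(f, "per_neuron", n_shuffles = 100, seed = 4)
  expect_equal(dim(null), c(100, 6))
  expect_lt(abs(mean(null) - 0.5), 0.02)      # n = 200 samples
  # determinism
  null2 <- shuffle_null(f, "per_neuron", n_shuffles = 100, seed = 4)
  expect_identical(null, null2)
  expect_error(shuffle_null(f, n_shuffles = 0), "n_shuffles")

  # score arithmetic: real accuracy minus the group null mean
  acc <- c(0.9, 0.5)
  nullm <- rbind(c(0.5, 0.6), c(0.5, 0.4))
  grp <- c("a", "b")
  sc <- shuffle_subtracted_scores(acc, nullm, grp)
  expect_equal(unname(sc), c(0.9 - 0.5, 0.5 - 0.5))
  # neuron at its null mean scores 0
  expect_equal(unname(shuffle_subtracted_scores(0.5, cbind(c(0.4, 0.6)))),
               0)
  expect_error(shuffle_subtracted_scores(acc, nullm, c("a")), "one label")
})

test_that("pure-noise neurons have scores centred on zero across seeds", {
  scores <- vapply(1:15, function(s) {
    n <- 40
    x <- withr::with_seed(s, cbind(rnorm(2 * n)))
    y <- rep(c("baseline", "pre_press"), each = n)
    f <- manual_features(x, y)
    acc <- decode(f, "per_neuron", seed = s)
    null <- shuffle_null(f, "per_neuron", n_shuffles = 30, seed = s)
    shuffle_subtracted_scores(acc, null)
  }, numeric(1))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("ensembles with larger planted amplitude decode better", {
  # inhibited amplitude dominates: its shuffle-subtracted score should win
  spec <- ensemble_spec(n_excited = 10, n_nonresponding = 10,
                        n_inhibited = 10, amp_excited = 0.15,
                        amp_inhibited = -0.6, noise_sd = 0.2)
  wins <- vapply(1:10, function(s) {
    cfg <- session_config(press_rate_active = 0.8, seed = 300 + s)
    ev <- generate_events(cfg)
    g <- generate_traces(ev, spec, frame_rate_hz = 10, seed = s)
    f <- build_epoch_features(g$traces, ev, seed = s)
    acc <- decode(f, "per_neuron", seed = s)
    null <- shuffle_null(f, "per_neuron", n_shuffles = 20, seed = s)
    sc <- shuffle_subtracted_scores(acc, null, g$truth$labels)
    means <- tapply(sc, g$truth$labels, mean)
    unname(which.max(means) == which(names(means) == "inhibited"))
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
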