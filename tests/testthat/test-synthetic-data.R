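test_that("event generation is deterministic and respects rates and caps", {
  # zero rates -> empty session
  cfg <- session_config(press_rate_active = 0, press_rate_inactive = 0,
                        duration_s = 3600, seed = 1)
  expect_equal(nrow(generate_events(cfg)), 0)

  # same seed -> identical logs
  cfg <- session_config(press_rate_active = 1.5, seed = 7)
  expect_identical(as.data.frame(generate_events(cfg)),
                   as.data.frame(generate_events(cfg)))

  # cap of 10 sucrose droplets binds at 1 press/min over an hour
  cfg <- session_config(press_rate_active = 1, reward_cap = 10,
                        duration_s = 3600, seed = 3)
  s <- summarize_session(generate_events(cfg))
  expect_lte(s$rewards_delivered, 10)

  expect_error(session_config(duration_s = -5), "duration_s")
})

test_that("trace generator plants exact noiseless structure", {
  spec <- noiseless_spec(n_excited = 1, n_nonresponding = 1, n_inhibited = 1,
                         amp_inhibited = -0.5)
  ev <- apply_schedule(30, duration_s = 60)
  g <- generate_traces(ev, spec, frame_rate_hz = 10, seed = 1)
  expect_equal(dim(g$traces), c(3, 600))
  expect_equal(g$truth$labels,
               c("excited", "non_responding", "inhibited"))
  # response shape has unit peak, so the inhibited trace dips exactly by amp
  expect_equal(min(g$traces[3, ]) - spec$baseline_f, -0.5)
  expect_equal(max(g$traces[1, ]) - spec$baseline_f, 0.5)
  # non-responders stay flat
  expect_equal(sd(g$traces[2, ]), 0)

  # planted tonic decline: last/first frame ratio equals 1 - frac
  spec <- noiseless_spec(tonic_decline_frac = 0.3)
  ev0 <- apply_schedule(numeric(0), duration_s = 120)
  g <- generate_traces(ev0, spec, frame_rate_hz = 10, seed = 1)
  expect_equal(g$traces[1, 1200] / g$traces[1, 1], 0.7)

  # full drug attenuation abolishes responses
  spec <- noiseless_spec(n_excited = 2, n_nonresponding = 1, n_inhibited = 2,
                         drug_attenuation = 1)
  g <- generate_traces(apply_schedule(30, duration_s = 60), spec,
                       frame_rate_hz = 10, seed = 1)
  expect_equal(max(abs(g$traces - spec$baseline_f)), 0)

  expect_error(ensemble_spec(noise_sd = -0.1), "noise_sd")
  expect_error(ensemble_spec(drug_attenuation = 1.5), "drug_attenuation")
})

test_that("default composition scales the 79/153/73 proportions", {
  s <- ensemble_spec_scaled(305)
  expect_equal(c(s$n_excited, s$n_nonresponding, s$n_inhibited),
               c(79, 153, 73))
  s <- ensemble_spec_scaled(100)
  expect_equal(s$n_excited + s$n_nonresponding + s$n_inhibited, 100)
})

test_that("movie rendering is exact and handles drift and empty sets", {
  spec <- noiseless_spec(n_excited = 1, n_nonresponding = 2, n_inhibited = 1)
  ev <- apply_schedule(10, duration_s = 30)
  g <- generate_traces(ev, spec, frame_rate_hz = 5, seed = 1)
  mv <- generate_movie(g$traces, frame_size_px = c(64, 64),
                       roi_radius_px = 3, seed = 2)
  # uniform disks: extracted means equal trace values everywhere
  ex <- extract_traces(mv$movie, mv$rois)
  expect_equal(unclass(ex), unclass(g$traces), tolerance = 1e-9)

  # planted integer drift is recovered with opposite sign
  mv <- generate_movie(g$traces, frame_size_px = c(64, 64), roi_radius_px = 3,
                       drift = list(dx = 2, dy = -1, from_frame = 80),
                       seed = 2)
  reg <- register_movie(mv$movie, reference = "first_frame")
  expect_true(all(reg$shifts[80:150, "dx"] == -2))
  expect_true(all(reg$shifts[80:150, "dy"] == 1))

  # zero neurons -> pure background and an empty mask set
  empty <- trace_matrix(matrix(numeric(0), 0, 10), 5)
  mv <- generate_movie(empty, frame_size_px = c(32, 32), seed = 1)
  expect_equal(max(abs(mv$movie$frames)), 0)
  expect_equal(mv$rois$n_rois, 0)

  # overlapping explicit centroids are rejected
  expect_error(
    generate_movie(trace_matrix(matrix(1, 2, 5), 5),
                   frame_size_px = c(32, 32), roi_radius_px = 3,
                   centroids = rbind(c(10, 10), c(12, 10))),
    "overlap")
})

test_that("tracked pairs share labelled cells with planted attenuation", {
  specA <- ensemble_spec_scaled(60, noise_sd = 0.02, amp_jitter_cv = 0,
                                tonic_decline_frac = 0)
  specB <- ensemble_spec_scaled(60, noise_sd = 0.02, amp_jitter_cv = 0,
                                tonic_decline_frac = 0,
                                drug_attenuation = 0.8)
  tp <- generate_tracked_pair(specA, specB, overlap_n = 20,
                              cfgA = session_config(seed = 21),
                              cfgB = session_config(seed = 22),
                              frame_rate_hz = 5, seed = 5)
  expect_equal(nrow(tp$identity_map), 20)
  expect_false(any(duplicated(tp$identity_map$idB)))  # injective
  # shared excited/inhibited cells have 80% smaller planted amplitude in B
  sh <- tp$identity_map$idA
  resp <- sh[tp$sessionA$truth$labels[sh] != "non_responding"]
  expect_equal(tp$sessionB$truth$amp[resp],
               0.2 * tp$sessionA$truth$amp[resp], tolerance = 1e-12)

  # zero overlap -> empty identity map; zero jitter -> identical centroids
  tp0 <- generate_tracked_pair(specA, specB, overlap_n = 0,
                               frame_rate_hz = 5, seed = 5)
  expect_equal(nrow(tp0$identity_map), 0)
  tpj <- generate_tracked_pair(specA, specB, overlap_n = 10, jitter_px = 0,
                               frame_rate_hz = 5, seed = 5)
  expect_equal(tpj$sessionA$centroids[tpj$identity_map$idA, ],
               tpj$sessionB$centroids[tpj$identity_map$idB, ])

  expect_error(generate_tracked_pair(specA, specB, overlap_n = 61,
                                     frame_rate_hz = 5),
               "overlap_n")
})

test_that("I-V generator follows Ohm's law and plants rectification", {
  ohm <- generate_iv_curve(iv_curve_spec(conductance_nS = 1, reversal_mV = 0))
  expect_equal(iv_current_at_test(ohm, 50), 50)
  expect_equal(iv_current_at_test(ohm, -70), -70)

  rect <- generate_iv_curve(iv_curve_spec(rectification_mode =
                                            "inward_rectifying",
                                          rect_scale = 0.1))
  expect_equal(iv_current_at_test(rect, 50), 5)
  expect_equal(iv_current_at_test(rect, -70), -70)  # negative limb untouched

  noisy1 <- generate_iv_curve(iv_curve_spec(noise_sd = 5), seed = 9)
  noisy2 <- generate_iv_curve(iv_curve_spec(noise_sd = 5), seed = 9)
  expect_identical(noisy1, noisy2)

  expect_error(generate_iv_curve(iv_curve_spec(), voltages_mV = numeric(0)),
               "non-empty")
  expect_error(iv_curve_spec(conductance_nS = 0), "conductance")
})
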