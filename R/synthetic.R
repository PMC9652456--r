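#' Session configuration for the synthetic behavior generator
#'
#' Describes one head-fixed operant session: its phase, duration, reward cap
#' and the Poisson press rates on the two levers. Candidate press times are a
#' homogeneous Poisson process subsequently thinned/flagged by the operant
#' schedule ([apply_schedule()]).
#'
#' @param phase Behavioral phase (see [phase_schedule()]).
#' @param duration_s Session length in seconds (default 3600; suppression
#'   sessions are typically 2700).
#' @param reward_cap Cap on sucrose deliveries or `NULL`.
#' @param press_rate_active,press_rate_inactive Press rates, presses/min.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `session_config`.
#' @export
session_config <- function(phase = "acquisition", duration_s = 3600,
                           reward_cap = NULL, press_rate_active = 1,
                           press_rate_inactive = 0.2, seed = 1L) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(press_rate_active, "press_rate_active", min = 0)
  check_number(press_rate_inactive, "press_rate_inactive", min = 0)
  structure(list(phase = phase, duration_s = duration_s,
                 reward_cap = reward_cap,
                 press_rate_active = press_rate_active,
                 press_rate_inactive = press_rate_inactive,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Planted ensemble composition and response model
#'
#' Specifies the synthetic population: how many neurons are excited,
#' non-responding or inhibited around active lever presses, the response
#' amplitudes and timing, within-session tonic decline, and noise. The
#' default composition mirrors the reported 79 excited / 153 non-responding /
#' 73 inhibited out of 305 imaged projection neurons; use
#' [ensemble_spec_scaled()] to scale it to another population size.
#'
#' The peri-press response is a boxcar of height `amp` over
#' `[response_onset_s, response_onset_s + response_dur_s]` relative to the
#' press, convolved with a single-exponential calcium indicator kernel
#' (`tau_s`, GCaMP6m-like) and rescaled to unit peak, so a neuron's planted
#' peak response equals its amplitude exactly. The default onset is -2 s:
#' responses begin during lever approach, before the press itself, which is
#' what makes a 1-s pre-press epoch decodable.
#'
#' @param n_excited,n_nonresponding,n_inhibited Neuron counts (>= 0).
#' @param amp_excited Peak response of excited neurons, dF/F units (> 0).
#' @param amp_inhibited Peak response of inhibited neurons, dF/F units (< 0).
#' @param response_onset_s Response onset relative to the press, seconds
#'   (negative = anticipatory).
#' @param response_dur_s Boxcar duration, seconds.
#' @param tonic_decline_frac Fractional decline of baseline fluorescence from
#'   the first to the last frame of the session (0 = flat).
#' @param noise_sd Gaussian noise SD per frame, dF/F units.
#' @param amp_jitter_cv Trial-to-trial amplitude jitter, coefficient of
#'   variation (multiplicative Gaussian, truncated at 0). The single-trial
#'   variability of these neurons is uncharacterised; 0.2 is a conventional
#'   choice, not a claim about the data.
#' @param drug_attenuation Fraction in \[0, 1\] by which excited and
#'   inhibited response amplitudes are attenuated (1 = fully abolished);
#'   models acute drug effects on ensemble dynamics.
#' @param baseline_f Baseline fluorescence level, arbitrary units.
#' @param tau_s Calcium kernel decay constant, seconds.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_excited = 79, n_nonresponding = 153,
                          n_inhibited = 73, amp_excited = 0.5,
                          amp_inhibited = -0.5, response_onset_s = -2,
                          response_dur_s = 4, tonic_decline_frac = 0.2,
                          noise_sd = 0.2, amp_jitter_cv = 0.2,
                          drug_attenuation = 0, baseline_f = 1,
                          tau_s = 0.6) {
  for (nm in c("n_excited", "n_nonresponding", "n_inhibited"))
    check_number(get(nm), nm, min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(amp_jitter_cv, "amp_jitter_cv", min = 0)
  check_number(drug_attenuation, "drug_attenuation", min = 0)
  if (drug_attenuation > 1) abort_config("drug_attenuation must be <= 1")
  check_number(response_dur_s, "response_dur_s", min = 0, strict_min = TRUE)
  check_number(tau_s, "tau_s", min = 0, strict_min = TRUE)
  if (amp_excited < 0) abort_config("amp_excited must be >= 0")
  if (amp_inhibited > 0) abort_config("amp_inhibited must be <= 0")
  structure(list(n_excited = as.integer(n_excited),
                 n_nonresponding = as.integer(n_nonresponding),
                 n_inhibited = as.integer(n_inhibited),
                 amp_excited = amp_excited, amp_inhibited = amp_inhibited,
                 response_onset_s = response_onset_s,
                 response_dur_s = response_dur_s,
                 tonic_decline_frac = tonic_decline_frac,
                 noise_sd = noise_sd, amp_jitter_cv = amp_jitter_cv,
                 drug_attenuation = drug_attenuation,
                 baseline_f = baseline_f, tau_s = tau_s),
            class = "ensemble_spec")
}

#' Ensemble spec scaled to a population size
#'
#' Keeps the default 79/153/73-of-305 composition, scaled to `n_total`
#' neurons (largest-remainder rounding so the counts sum exactly).
#'
#' @param n_total Total neurons.
#' @param ... Passed to [ensemble_spec()].
#' @export
ensemble_spec_scaled <- function(n_total = 305, ...) {
  props <- c(79, 153, 73) / 305
  raw <- props * n_total
  n <- floor(raw)
  rem <- n_total - sum(n)
  if (rem > 0) {
    ord <- order(raw - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  ensemble_spec(n_excited = n[1], n_nonresponding = n[2], n_inhibited = n[3],
                ...)
}

#' Fluorescence trace matrix
#'
#' @param mat Numeric matrix, neurons x frames.
#' @param frame_rate_hz Acquisition frame rate, Hz.
#' @return The matrix with class `trace_matrix` and a `frame_rate_hz`
#'   attribute.
#' @export
trace_matrix <- function(mat, frame_rate_hz) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  check_number(frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  structure(mat, class = c("trace_matrix", "matrix", "array"),
            frame_rate_hz = frame_rate_hz)
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d frames @ %g Hz\n",
              nrow(x), ncol(x), attr(x, "frame_rate_hz")))
  invisible(x)
}

frame_rate <- function(traces) {
  fr <- attr(traces, "frame_rate_hz")
  if (is.null(fr)) stop("traces carry no frame_rate_hz attribute",
                        call. = FALSE)
  fr
}

active_press_times <- function(events) {
  events$time_s[events$event_type == "press_active"]
}

#' Generate a synthetic behavioral session
#'
#' Draws candidate press times on both levers as homogeneous Poisson
#' processes at the configured rates, then runs them through the operant
#' schedule for the session's phase so reinforcement flags, cue, sucrose and
#' timeout events are all mutually consistent.
#'
#' @param cfg A [session_config()].
#' @param schedule Optional [schedule_config()]; defaults to
#'   `phase_schedule(cfg$phase, cfg$reward_cap)`.
#' @return An `event_log`.
#' @export
generate_events <- function(cfg, schedule = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  if (is.null(schedule))
    schedule <- phase_schedule(cfg$phase, reward_cap = cfg$reward_cap)
  withr::with_seed(cfg$seed, {
    n_a <- rpois(1, cfg$press_rate_active / 60 * cfg$duration_s)
    n_i <- rpois(1, cfg$press_rate_inactive / 60 * cfg$duration_s)
    t_a <- sort(runif(n_a, 0, cfg$duration_s))
    t_i <- sort(runif(n_i, 0, cfg$duration_s))
  })
  apply_schedule(t_a, t_i, cfg = schedule, duration_s = cfg$duration_s,
                 phase = cfg$phase)
}

# Unit-peak peri-press response shape: boxcar over [onset, onset+dur]
# convolved with exp(-t/tau), sampled at the frame rate. Returns the shape
# values and the frame offset of its first sample relative to the press frame.
response_shape <- function(spec, frame_rate_hz) {
  dt <- 1 / frame_rate_hz
  n_box <- max(1L, round(spec$response_dur_s * frame_rate_hz))
  n_tail <- ceiling(6 * spec$tau_s * frame_rate_hz)
  kern <- exp(-(0:n_tail) * dt / spec$tau_s)
  shape <- stats::convolve(c(rep(1, n_box), rep(0, n_tail)), rev(kern),
                           type = "open")[seq_len(n_box + n_tail)]
  shape <- shape / max(shape)
  list(values = shape,
       offset = round(spec$response_onset_s * frame_rate_hz))
}

#' Generate synthetic fluorescence traces with planted ground truth
#'
#' Each neuron's trace is `baseline * (1 - tonic_decline_frac * t/T)` plus an
#' ensemble-specific peri-press transient at every active lever press plus
#' i.i.d. Gaussian noise. Excited and inhibited amplitudes are scaled by
#' `(1 - drug_attenuation)` and jittered per trial per neuron.
#'
#' @param events An `event_log` (active presses define trial times).
#' @param spec An [ensemble_spec()].
#' @param frame_rate_hz Frame rate (default 30, the study's resonant-scanner
#'   rate; lower rates run faster and are adequate for testing).
#' @param seed Integer seed.
#' @return A list with `traces` (a [trace_matrix()]) and `truth` — a list of
#'   per-neuron `labels` (`excited`/`non_responding`/`inhibited`), per-neuron
#'   `amp` (planted peak amplitude after attenuation), `tonic_decline_frac`,
#'   and `press_times`.
#' @export
generate_traces <- function(events, spec, frame_rate_hz = 30, seed = 1L) {
  stopifnot(inherits(events, "event_log"), inherits(spec, "ensemble_spec"))
  check_number(frame_rate_hz, "frame_rate_hz", min = 0, strict_min = TRUE)
  duration_s <- attr(events, "duration_s")
  n_frames <- floor(duration_s * frame_rate_hz)
  if (n_frames < 2) abort_config("session too short for the frame rate")
  labels <- rep(c("excited", "non_responding", "inhibited"),
                times = c(spec$n_excited, spec$n_nonresponding,
                          spec$n_inhibited))
  n <- length(labels)
  if (n == 0) abort_config("ensemble spec has zero neurons")
  amp <- numeric(n)
  att <- 1 - spec$drug_attenuation
  amp[labels == "excited"] <- spec$amp_excited * att
  amp[labels == "inhibited"] <- spec$amp_inhibited * att

  decline <- 1 - spec$tonic_decline_frac * (0:(n_frames - 1)) / (n_frames - 1)
  traces <- matrix(rep(spec$baseline_f * decline, each = n), n, n_frames)

  press <- active_press_times(events)
  shape <- response_shape(spec, frame_rate_hz)
  withr::with_seed(as.integer(seed), {
    for (tp in press) {
      j0 <- round(tp * frame_rate_hz) + 1L + shape$offset
      idx <- j0:(j0 + length(shape$values) - 1L)
      keep <- idx >= 1L & idx <= n_frames
      if (!any(keep)) next
      jit <- if (spec$amp_jitter_cv > 0)
        pmax(0, 1 + spec$amp_jitter_cv * rnorm(n)) else rep(1, n)
      traces[, idx[keep]] <- traces[, idx[keep]] +
        (amp * jit) %o% shape$values[keep]
    }
    if (spec$noise_sd > 0)
      traces <- traces + matrix(rnorm(n * n_frames, sd = spec$noise_sd),
                                n, n_frames)
  })
  list(traces = trace_matrix(traces, frame_rate_hz),
       truth = list(labels = labels, amp = amp,
                    tonic_decline_frac = spec$tonic_decline_frac,
                    press_times = press))
}

# non-overlapping random disk centroids inside the frame
place_centroids <- function(n, frame_size_px, roi_radius_px) {
  if (n == 0) return(matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("row", "col"))))
  h <- frame_size_px[1]; w <- frame_size_px[2]
  min_sep <- 2 * roi_radius_px + 2
  pts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  for (tries in seq_len(20000L)) {
    cand <- c(runif(1, roi_radius_px + 1, h - roi_radius_px),
              runif(1, roi_radius_px + 1, w - roi_radius_px))
    ok <- placed == 0L ||
      all(sqrt(rowSums((pts[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2)) >= min_sep)
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- cand
      if (placed == n) return(round(pts))
    }
  }
  stop("ROI layout error: could not place ", n,
       " non-overlapping ROIs of radius ", roi_radius_px,
       " in a ", h, "x", w, " frame", call. = FALSE)
}

disk_pixels <- function(centroid, radius, h, w) {
  rr <- max(1, floor(centroid[1] - radius)):min(h, ceiling(centroid[1] + radius))
  cc <- max(1, floor(centroid[2] - radius)):min(w, ceiling(centroid[2] + radius))
  grid <- expand.grid(row = rr, col = cc)
  d <- sqrt((grid$row - centroid[1])^2 + (grid$col - centroid[2])^2)
  grid[d <= radius, , drop = FALSE]
}

#' Render traces into a synthetic movie stack with ROI masks
#'
#' Each frame is a constant background plus, for every neuron, a disk of
#' radius `roi_radius_px` whose intensity equals the neuron's trace value at
#' that frame. An optional rigid drift translates all content (but not the
#' masks) by an integer pixel offset from a given frame onward, for testing
#' registration.
#'
#' @param traces A [trace_matrix()].
#' @param frame_size_px Length-2 integer vector (rows, cols).
#' @param roi_radius_px Disk radius, pixels.
#' @param centroids Optional n x 2 matrix of ROI centroids (row, col); placed
#'   randomly without overlap when `NULL`. Overlapping ROIs are an error.
#' @param background Background intensity.
#' @param drift `NULL`, or a list `list(dx =, dy =, from_frame =)` — content
#'   shifts by `dx` columns and `dy` rows for frames `>= from_frame`.
#' @param seed Seed for random centroid placement.
#' @return A list with `movie` (a [movie_stack()]) and `rois`
#'   (a [roi_mask_set()] drawn at the undrifted positions).
#' @export
generate_movie <- function(traces, frame_size_px = c(128, 128),
                           roi_radius_px = 3, centroids = NULL,
                           background = 0, drift = NULL, seed = 1L) {
  n <- nrow(traces); n_frames <- ncol(traces)
  h <- frame_size_px[1]; w <- frame_size_px[2]
  if (is.null(centroids)) {
    withr::with_seed(as.integer(seed),
                     centroids <- place_centroids(n, frame_size_px,
                                                  roi_radius_px))
  } else {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != n) abort_config("need one centroid per neuron")
  }
  if (n > 1) {
    dmin <- min(stats::dist(centroids))
    if (dmin <= 2 * roi_radius_px)
      stop("ROI layout error: overlapping ROIs at radius ", roi_radius_px,
           call. = FALSE)
  }
  label_img <- matrix(0L, h, w)
  pix <- vector("list", n)
  for (i in seq_len(n)) {
    px <- disk_pixels(centroids[i, ], roi_radius_px, h, w)
    pix[[i]] <- px
    label_img[cbind(px$row, px$col)] <- i
  }
  frames <- array(background, dim = c(h, w, n_frames))
  for (k in seq_len(n_frames)) {
    dy <- 0L; dx <- 0L
    if (!is.null(drift) && k >= drift$from_frame) {
      dy <- as.integer(drift$dy); dx <- as.integer(drift$dx)
    }
    for (i in seq_len(n)) {
      r <- pix[[i]]$row + dy; c <- pix[[i]]$col + dx
      keep <- r >= 1 & r <= h & c >= 1 & c <= w
      frames[cbind(r[keep], c[keep], k)] <- traces[i, k]
    }
  }
  list(movie = movie_stack(frames, frame_rate(traces)),
       rois = roi_mask_set(label_img, centroids))
}

#' Generate a pair of sessions sharing tracked cells
#'
#' Builds two full synthetic sessions (events + traces + ground truth) whose
#' populations share `overlap_n` cells: shared cells keep their ensemble
#' label and field-of-view centroid (plus optional jitter) across sessions,
#' while `specB` may alter amplitudes (e.g. `drug_attenuation` for a drug
#' test day). Both specs must describe the same population composition.
#'
#' @param specA,specB [ensemble_spec()]s with identical neuron counts.
#' @param overlap_n Number of shared (tracked) cells.
#' @param cfgA,cfgB [session_config()]s for the two sessions.
#' @param frame_rate_hz Frame rate for both sessions.
#' @param jitter_px SD of centroid jitter between sessions, pixels.
#' @param frame_size_px Field-of-view size for centroid placement.
#' @param seed Integer seed.
#' @return A list with `sessionA`, `sessionB` (each: `events`, `traces`,
#'   `truth`, `centroids`) and `identity_map` — a data frame (`idA`, `idB`)
#'   of shared-cell indices (injective).
#' @export
generate_tracked_pair <- function(specA, specB, overlap_n,
                                  cfgA = session_config(seed = 11L),
                                  cfgB = session_config(seed = 12L),
                                  frame_rate_hz = 10, jitter_px = 1,
                                  frame_size_px = c(256, 256), seed = 1L) {
  stopifnot(inherits(specA, "ensemble_spec"), inherits(specB, "ensemble_spec"))
  counts <- function(s) c(s$n_excited, s$n_nonresponding, s$n_inhibited)
  if (!all(counts(specA) == counts(specB)))
    abort_config("specA and specB must have identical neuron counts")
  n <- sum(counts(specA))
  if (overlap_n > n) abort_config("overlap_n exceeds population size")
  eventsA <- generate_events(cfgA)
  eventsB <- generate_events(cfgB)
  seed <- as.integer(seed)
  sesA <- generate_traces(eventsA, specA, frame_rate_hz, seed = seed + 1L)
  sesB <- generate_traces(eventsB, specB, frame_rate_hz, seed = seed + 2L)
  withr::with_seed(seed, {
    # one joint layout for the union of cells: distinct physical cells never
    # overlap within the field of view, across sessions included
    all_cent <- place_centroids(2L * n - overlap_n, frame_size_px, 3)
    centA <- all_cent[seq_len(n), , drop = FALSE]
    shared <- if (overlap_n > 0) sort(sample.int(n, overlap_n)) else integer(0)
    # session B: shared cells keep identity (same row index => same label,
    # since compositions match) up to small centroid jitter; the remaining
    # cells are different neurons at fresh positions
    centB <- centA
    if (n > overlap_n)
      centB[setdiff(seq_len(n), shared), ] <-
        all_cent[(n + 1L):(2L * n - overlap_n), , drop = FALSE]
    if (overlap_n > 0) {
      jit <- matrix(rnorm(2 * overlap_n, sd = jitter_px), ncol = 2)
      centB[shared, ] <- centA[shared, , drop = FALSE] + round(jit)
    }
  })
  sesA$centroids <- centA
  sesB$centroids <- centB
  list(sessionA = c(list(events = eventsA), sesA),
       sessionB = c(list(events = eventsB), sesB),
       identity_map = data.frame(idA = shared, idB = shared))
}

#' I-V curve specification
#'
#' @param conductance_nS Chord conductance, nS (> 0).
#' @param reversal_mV Reversal potential, mV.
#' @param rectification_mode `"ohmic"` (linear I-V) or `"inward_rectifying"`
#'   (positive-limb currents scaled down, as at synapses enriched with
#'   calcium-permeable AMPA receptors).
#' @param rect_scale Scale factor applied to currents at voltages above the
#'   reversal potential in rectifying mode (default 0.2).
#' @param noise_sd Gaussian current noise, pA.
#' @return An object of class `iv_curve_spec`.
#' @export
iv_curve_spec <- function(conductance_nS = 1, reversal_mV = 0,
                          rectification_mode = c("ohmic", "inward_rectifying"),
                          rect_scale = 0.2, noise_sd = 0) {
  check_number(conductance_nS, "conductance_nS", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  structure(list(conductance_nS = conductance_nS, reversal_mV = reversal_mV,
                 rectification_mode = match.arg(rectification_mode),
                 rect_scale = rect_scale, noise_sd = noise_sd),
            class = "iv_curve_spec")
}

#' Generate a synthetic peak-current I-V curve
#'
#' Ohmic mode: `I(V) = g (V - V_rev)` (pA, with g in nS and V in mV).
#' Inward-rectifying mode additionally scales currents on the positive limb
#' (`V > V_rev`) by `rect_scale < 1`.
#'
#' @param spec An [iv_curve_spec()].
#' @param voltages_mV Holding voltages; default the standard series
#'   -80 to +50 mV.
#' @param seed Seed for the noise.
#' @return An `iv_curve`: data frame (`voltage_mV`, `current_pA`).
#' @export
generate_iv_curve <- function(spec,
                              voltages_mV = c(-80, -70, -50, -30, -10,
                                              10, 30, 50),
                              seed = 1L) {
  stopifnot(inherits(spec, "iv_curve_spec"))
  if (length(voltages_mV) == 0) abort_config("voltages_mV must be non-empty")
  i <- spec$conductance_nS * (voltages_mV - spec$reversal_mV)
  if (spec$rectification_mode == "inward_rectifying")
    i[voltages_mV > spec$reversal_mV] <-
      i[voltages_mV > spec$reversal_mV] * spec$rect_scale
  if (spec$noise_sd > 0)
    withr::with_seed(as.integer(seed),
                     i <- i + rnorm(length(i), sd = spec$noise_sd))
  iv_curve(voltages_mV, i)
}

#' Generate a synthetic drug-wash amplitude series
#'
#' Peak oeEPSC amplitudes sampled at a fixed sweep interval; after drug
#' onset the amplitude decays exponentially towards
#' `baseline_pA * floor_frac`.
#'
#' @param duration_s Total recording length, seconds.
#' @param sweep_interval_s Seconds between sweeps (default 12).
#' @param baseline_pA Pre-drug amplitude.
#' @param drug_on_s Drug application time, seconds.
#' @param floor_frac Asymptotic amplitude as a fraction of baseline.
#' @param tau_s Decay constant of the drug effect, seconds.
#' @param noise_sd Gaussian amplitude noise, pA.
#' @param seed Seed.
#' @return A `wash_series`: data frame (`time_s`, `amplitude_pA`) with a
#'   `drug_on_s` attribute.
#' @export
generate_wash_series <- function(duration_s = 1500, sweep_interval_s = 12,
                                 baseline_pA = 100, drug_on_s = 300,
                                 floor_frac = 0.3, tau_s = 180,
                                 noise_sd = 0, seed = 1L) {
  tt <- seq(0, duration_s, by = sweep_interval_s)
  amp <- ifelse(tt < drug_on_s, baseline_pA,
                baseline_pA * (floor_frac + (1 - floor_frac) *
                                 exp(-(tt - drug_on_s) / tau_s)))
  if (noise_sd > 0)
    withr::with_seed(as.integer(seed),
                     amp <- amp + rnorm(length(amp), sd = noise_sd))
  wash_series(tt, amp, drug_on_s = drug_on_s)
}
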