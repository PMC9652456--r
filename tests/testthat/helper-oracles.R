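# Independent oracles used across tests. These re-derive expected values by
# brute force and stay independent of the package implementation.

# Brute-force operant schedule: walk the timeline in 1-ms steps carrying a
# timeout countdown and a reward counter. Press times must sit on the ms
# grid. Ties at timeout end count as reinforced (half-open timeout).
oracle_schedule_ms <- function(press_ms, duration_ms, timeout_ms, cap = NULL,
                               delivers = TRUE) {
  press_ms <- sort(as.integer(press_ms))
  n <- length(press_ms)
  reinforced <- logical(n)
  timeout_left <- 0L
  rewards <- 0L
  pi <- 1L
  for (t in 0:duration_ms) {
    if (timeout_left > 0L) timeout_left <- timeout_left - 1L
    while (pi <= n && press_ms[pi] == t) {
      ok <- delivers && timeout_left == 0L &&
        (is.null(cap) || rewards < cap)
      reinforced[pi] <- ok
      if (ok) {
        timeout_left <- timeout_ms
        if (!is.null(cap)) rewards <- rewards + 1L
      }
      pi <- pi + 1L
    }
    if (pi > n && timeout_left == 0L) break
  }
  list(reinforced = reinforced, rewards = if (is.null(cap))
    sum(reinforced) else rewards)
}

# Exhaustive minimum-total-gated-distance one-to-one assignment (n <= 8):
# distances beyond max_dist all cost the same cap, pairs above the
# threshold are dropped afterwards (mirrors the matching contract).
brute_force_match <- function(centroidsA, centroidsB, max_dist) {
  a <- as.matrix(centroidsA); b <- as.matrix(centroidsB)
  na <- nrow(a); nb <- nrow(b)
  d_raw <- as.matrix(stats::dist(rbind(a, b)))[seq_len(na), na + seq_len(nb),
                                               drop = FALSE]
  d <- pmin(d_raw, max_dist + 1)
  if (na <= nb) {
    perms <- gtools_permutations(nb, na)
    best <- NULL; best_cost <- Inf
    for (r in seq_len(nrow(perms))) {
      cost <- sum(d[cbind(seq_len(na), perms[r, ])])
      if (cost < best_cost) { best_cost <- cost; best <- perms[r, ] }
    }
    pairs <- data.frame(idA = seq_len(na), idB = best,
                        dist = d[cbind(seq_len(na), best)])
  } else {
    perms <- gtools_permutations(na, nb)
    best <- NULL; best_cost <- Inf
    for (r in seq_len(nrow(perms))) {
      cost <- sum(d[cbind(perms[r, ], seq_len(nb))])
      if (cost < best_cost) { best_cost <- cost; best <- perms[r, ] }
    }
    pairs <- data.frame(idA = best, idB = seq_len(nb),
                        dist = d[cbind(best, seq_len(nb))])
  }
  pairs <- pairs[pairs$dist <= max_dist, , drop = FALSE]
  pairs <- pairs[order(pairs$idA), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# all ordered k-permutations of 1..n (small n only)
gtools_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (j in seq_len(k - 1)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(out[r, ], length(rest), j, byrow = TRUE), rest)
    }))
  }
  unname(out)
}

# quiet noiseless spec for constructions (overrides allowed)
noiseless_spec <- function(...) {
  args <- list(noise_sd = 0, amp_jitter_cv = 0, tonic_decline_frac = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ensemble_spec, args)
}

iv_current_at_test <- function(curve, v) curve$current_pA[curve$voltage_mV == v]

active_press_times_test <- function(ev) ev$time_s[ev$event_type == "press_active"]
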