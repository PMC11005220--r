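# Shared fixtures and independent oracles, built in code at test time.

# Minimal recording with arbitrary channels at a given start clock time.
make_rec <- function(channels, start = "2024-01-01 07:00:00",
                     interval_min = 18, id = "m1", group = "test",
                     age = 20, weight = 30) {
  recording(animal_id = id, group = group, age_weeks = age,
            body_weight_g = weight,
            start_time = as.POSIXct(start, tz = "UTC"),
            interval_min = interval_min, channels = channels)
}

# A clean cosine series: n samples, dt minutes, mesor M, amplitude A,
# acrophase phi (minutes), period tau.
cosine_series <- function(n = 240, dt = 18, M = 10, A = 3, phi = 300,
                          tau = 1423, t0 = 0) {
  t <- t0 + (seq_len(n) - 1) * dt
  M + A * cos(2 * pi * (t - phi) / tau)
}

# Exhaustive single-split CART oracle: best SSE decrease over all features
# and all midpoints, plus each feature's own best decrease (distinct
# features can tie exactly when they isolate the same observations).
# Independent of the forest engine.
brute_force_split <- function(X, y) {
  X <- as.matrix(X)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  root <- sse(y)
  per_feature <- vapply(seq_len(ncol(X)), function(j) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) return(-Inf)
    cuts <- (u[-1] + u[-length(u)]) / 2
    max(vapply(cuts, function(cc)
      root - sse(y[X[, j] <= cc]) - sse(y[X[, j] > cc]), 0))
  }, numeric(1))
  delta <- max(per_feature)
  list(delta = delta, per_feature = per_feature,
       optimal_features = which(per_feature >= delta - 1e-9))
}

# Deterministic little cohort for clock tests: 17 animals over 5 ages
# (3,3,3,4,4), mirroring the study's model-set size.
seventeen_ages <- function() rep(c(6, 20, 56, 64, 80), times = c(3, 3, 3, 4, 4))

# Simulate a ladder cohort and reduce it to a feature table.
ladder_features <- function(n_per_group, seed, period_min = 1423) {
  coh <- simulate_cohort(default_ladder_spec(n_per_group, seed = seed))
  rhy <- lapply(coh$recordings, cosinor_fit_recording,
                period_min = period_min)
  list(features = build_feature_table(coh$recordings, rhy),
       truth = coh$truth)
}
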