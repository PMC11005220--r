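# Synthetic metabolic-cage cohort generator.
#
# Encodes the murine aging trajectory of energy metabolism: mean daily
# energy expenditure peaks at 6 weeks and halves by 80 weeks; the
# respiratory exchange ratio sits near 0.75 through mid-life and rises to
# ~0.85 by 80 weeks; the circadian EE rhythm (common optimal period
# ~1423 min) dampens in amplitude and drifts in phase with age; activity,
# feeding and drinking are dark-phase-dominant and decline with age.
# Interventions are modeled as a pure effective-age shift: a treated
# animal is generated from the profile of a younger age but labeled with
# its chronological age.

.PROFILE_AGES <- c(6, 20, 56, 64, 80)
.PROFILE_ANCHORS <- data.frame(
  age_weeks            = .PROFILE_AGES,
  mean_EE_kcal_h       = c(0.50, 0.42, 0.33, 0.30, 0.25),
  mean_RER             = c(0.75, 0.75, 0.75, 0.78, 0.85),
  rhythm_amplitude_frac = 0.30 - 0.15 * (.PROFILE_AGES - 6) / 74,
  acrophase_min        = 1000 + 60 * (.PROFILE_AGES - 6) / 74,
  activity_scale       = 1.00 - 0.50 * (.PROFILE_AGES - 6) / 74,
  feed_g_day           = 4.0 - 0.8 * (.PROFILE_AGES - 6) / 74,
  drink_ml_day         = 5.0 - 1.0 * (.PROFILE_AGES - 6) / 74,
  mean_weight_g        = c(20, 28, 35, 37, 40))

#' Default age-to-phenotype profiles
#'
#' Anchored at the study ages 6, 20, 56, 64 and 80 weeks, with mean EE at
#' 80 weeks exactly half of the 6-week value and mean RER 0.75 through 56
#' weeks rising to 0.85 at 80 weeks. Queried ages between anchors are
#' monotone (linear) interpolations; ages outside the ladder are clamped
#' to the nearest anchor.
#'
#' @param ages ages (weeks) at which to evaluate the profiles.
#' @return data.frame, one row per age: `age_weeks`, `mean_EE_kcal_h`,
#'   `mean_RER`, `rhythm_amplitude_frac`, `acrophase_min`,
#'   `activity_scale`, `feed_g_day`, `drink_ml_day`, `mean_weight_g`.
#' @export
default_age_profiles <- function(ages = .PROFILE_AGES) {
  stopifnot(all(ages > 0))
  out <- data.frame(age_weeks = as.numeric(ages))
  for (col in setdiff(names(.PROFILE_ANCHORS), "age_weeks"))
    out[[col]] <- stats::approx(.PROFILE_ANCHORS$age_weeks,
                                .PROFILE_ANCHORS[[col]],
                                xout = ages, rule = 2)$y
  out
}

#' Specify a synthetic cohort
#'
#' @param groups data.frame with columns `label`, `age_weeks`, `n`,
#'   `intervention_shift_weeks` (effective age = age - shift; 0 for
#'   untreated groups).
#' @param period_min circadian period of the generated EE rhythm in
#'   minutes (default 1423).
#' @param interval_min sampling step in minutes (default 18).
#' @param duration_h generated window length in hours (default 72); must
#'   cover at least two full periods.
#' @param noise_sd_frac stationary SD of the AR(1) noise as a fraction of
#'   the channel mean (default 0.05).
#' @param ar1_rho lag-1 autocorrelation of the noise in `[0, 1)`
#'   (default 0.3).
#' @param lights_on_hour lights-on clock hour (default 7).
#' @param seed master seed; every animal's draws derive from
#'   `(seed, animal index)`.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(groups, period_min = 1423, interval_min = 18,
                        duration_h = 72, noise_sd_frac = 0.05,
                        ar1_rho = 0.3, lights_on_hour = 7, seed = 1) {
  groups <- as.data.frame(groups)
  need <- c("label", "age_weeks", "n", "intervention_shift_weeks")
  miss <- setdiff(need, names(groups))
  if ("intervention_shift_weeks" %in% miss) {
    groups$intervention_shift_weeks <- 0
    miss <- setdiff(miss, "intervention_shift_weeks")
  }
  if (length(miss))
    stop("groups is missing column(s): ", paste(miss, collapse = ", "))
  if (any(groups$n < 1)) stop("parameter error: every group needs n >= 1")
  if (period_min <= 0) stop("parameter error: period_min must be > 0")
  if (duration_h * 60 < 2 * period_min)
    stop("parameter error: duration must cover at least two full periods")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("parameter error: ar1_rho in [0,1)")
  structure(list(groups = groups, period_min = period_min,
                 interval_min = interval_min, duration_h = duration_h,
                 noise_sd_frac = noise_sd_frac, ar1_rho = ar1_rho,
                 lights_on_hour = lights_on_hour, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The default five-age study ladder
#'
#' Untreated groups at 6, 20, 56, 64 and 80 weeks.
#'
#' @param n_per_group animals per age group (default 4).
#' @param seed master seed.
#' @param ... further arguments passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
default_ladder_spec <- function(n_per_group = 4, seed = 1, ...) {
  cohort_spec(data.frame(label = paste0(.PROFILE_AGES, "w"),
                         age_weeks = .PROFILE_AGES,
                         n = n_per_group,
                         intervention_shift_weeks = 0),
              seed = seed, ...)
}

# Stationary AR(1) Gaussian noise with SD `sd` and lag-1 correlation `rho`.
.ar1_noise <- function(n, sd, rho) {
  if (sd <= 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) e[i] <- rho * e[i - 1] + innov[i - 1]
  }
  e
}

# Dark:light 3:1 per-sample weights, normalised to sum to 1.
.phase_weights <- function(dark) {
  w <- ifelse(dark, 3, 1)
  w / sum(w)
}

# Per-channel daily totals at activity_scale = 1.
.ACTIVITY_BASE <- c(XT = 12000, YT = 8000, Z = 1500, DistD = 50000,
                    SumR = 5000, SumL = 5000)
.BITE_G <- 0.05  # feeder resolution, g per event
.SIP_ML <- 0.05  # lickometer resolution, ml per event

#' Simulate one animal's cage recording
#'
#' Energy expenditure follows
#' `EE(t) = M (1 + A cos(2 pi (t - phi) / tau)) + eps(t)` with mesor `M`,
#' relative amplitude `A` and lights-on-referenced acrophase `phi` from the
#' age profile, period `tau` from the cohort spec, and `eps` stationary
#' AR(1) Gaussian noise with SD `noise_sd_frac * M`. VO2 and VCO2 are
#' derived by inverting the Weir relation,
#' `VO2 = 1000 EE / (3.941 + 1.106 RER)`, `VCO2 = RER * VO2`, so the
#' recorded gas exchange, RER and EE are mutually consistent by
#' construction. Activity, feeding and drinking channels are non-negative
#' Poisson event draws weighted 3:1 toward the dark phase and scaled by
#' the profile's `activity_scale`. The recording starts at lights-on.
#'
#' @param profile one-row data.frame as returned by
#'   [default_age_profiles()].
#' @param spec a [cohort_spec()].
#' @param animal_seed integer; together with `spec$seed` it fully
#'   determines the draws.
#' @param animal_id,group identifiers stored in the recording.
#' @param age_weeks chronological age label (defaults to the profile age;
#'   differs for intervention arms).
#' @return a `cage_recording`.
#' @export
simulate_recording <- function(profile, spec, animal_seed = 1,
                               animal_id = "sim_01", group = "sim",
                               age_weeks = profile$age_weeks) {
  stopifnot(inherits(spec, "cohort_spec"), nrow(profile) == 1)
  if (profile$rhythm_amplitude_frac > 1 || profile$rhythm_amplitude_frac < 0)
    stop("parameter error: rhythm_amplitude_frac must lie in [0, 1]")
  n <- round(spec$duration_h * 60 / spec$interval_min)
  dt <- spec$interval_min
  t_abs <- (seq_len(n) - 1) * dt            # minutes after lights-on
  dark <- (t_abs %% 1440) >= 720
  M <- profile$mean_EE_kcal_h
  A <- profile$rhythm_amplitude_frac
  tau <- spec$period_min
  phi <- profile$acrophase_min

  with_seed(mix_seed(spec$seed, animal_seed), {
    rer <- profile$mean_RER +
      .ar1_noise(n, spec$noise_sd_frac * profile$mean_RER, spec$ar1_rho)
    rer <- pmin(pmax(rer, 0.65), 1.05)
    ee <- M * (1 + A * cos(2 * pi * (t_abs - phi) / tau)) +
      .ar1_noise(n, spec$noise_sd_frac * M, spec$ar1_rho)
    ee <- pmax(ee, 1e-9)
    vo2 <- 1000 * ee / (3.941 + 1.106 * rer)
    vco2 <- rer * vo2

    w <- .phase_weights(dark)
    days <- spec$duration_h / 24
    act <- lapply(names(.ACTIVITY_BASE), function(ch) {
      lam <- .ACTIVITY_BASE[[ch]] * profile$activity_scale * days * w
      as.numeric(stats::rpois(n, lam))
    })
    names(act) <- names(.ACTIVITY_BASE)
    speed <- act$DistD / (dt * 60)  # cm/s over the sample interval
    feed <- stats::rpois(n, profile$feed_g_day * days * w / .BITE_G) * .BITE_G
    drink <- stats::rpois(n, profile$drink_ml_day * days * w / .SIP_ML) * .SIP_ML
    weight <- max(profile$mean_weight_g * (1 + stats::rnorm(1, 0, 0.05)),
                  0.5 * profile$mean_weight_g)

    recording(
      animal_id = animal_id, group = group, age_weeks = age_weeks,
      body_weight_g = weight,
      start_time = as.POSIXct("2024-01-01", tz = "UTC") +
        spec$lights_on_hour * 3600,
      interval_min = dt,
      channels = list(VO2 = vo2, VCO2 = vco2, RER = rer, EE = ee,
                      XT = act$XT, YT = act$YT, Z = act$Z,
                      DistD = act$DistD, Speed = speed,
                      Drink = drink, Feed = feed,
                      SumR = act$SumR, SumL = act$SumL),
      lights_on_hour = spec$lights_on_hour)
  })
}

#' Simulate a whole cohort with ground truth
#'
#' Intervention groups (`intervention_shift_weeks > 0`) are generated from
#' the age profile at `age_weeks - shift` (their effective metabolic age)
#' but labeled with their chronological `age_weeks`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `recordings` (named list of `cage_recording`) and
#'   `truth` (data.frame: one row per animal with its generating profile,
#'   effective age and realized seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  truth <- list()
  counter <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    eff_age <- grp$age_weeks - grp$intervention_shift_weeks
    if (eff_age <= 0)
      stop("parameter error: intervention shift exceeds chronological age")
    profile <- default_age_profiles(eff_age)
    for (j in seq_len(grp$n)) {
      counter <- counter + 1L
      id <- sprintf("%s_%02d", grp$label, j)
      recs[[id]] <- simulate_recording(
        profile, spec, animal_seed = counter, animal_id = id,
        group = grp$label, age_weeks = grp$age_weeks)
      truth[[id]] <- cbind(
        data.frame(animal_id = id, group = grp$label,
                   age_weeks = grp$age_weeks,
                   effective_age_weeks = eff_age,
                   animal_seed = counter,
                   body_weight_g = recs[[id]]$body_weight_g),
        profile[, setdiff(names(profile), "age_weeks")])
    }
  }
  list(recordings = recs,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
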