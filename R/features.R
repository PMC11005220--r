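# Reduction of recordings to the per-animal candidate-predictor table.

#' Canonical clock feature columns
#'
#' The 14 candidate predictors of the metabolic age clock, in their
#' canonical order: body weight, adjusted phase and amplitude of the daily
#' EE rhythm, daily means of the gas-exchange channels, and daily totals
#' of the activity, feeding and drinking channels (`XT_YT` = XT + YT,
#' `SumR_L` = SumR + SumL).
#'
#' @return character vector of length 14.
#' @export
feature_columns <- function() {
  c("Weight", "Adjphase", "VO2", "EE", "RER", "VCO2", "Z", "Feed",
    "Amplitude", "XT_YT", "Drink", "DistD", "SumR_L", "Speed")
}

#' Daily-average summary of every channel
#'
#' Rate-like channels (`VO2`, `VCO2`, `RER`, `EE`, `Speed`) are averaged
#' arithmetically over all samples; cumulative/event channels (`XT`, `YT`,
#' `Z`, `DistD`, `Drink`, `Feed`, `SumR`, `SumL`) are totalled and divided
#' by the number of recorded days. Missing samples are excluded from the
#' means (they are never interpolated here); for cumulative channels the
#' observed total is rescaled by the fraction of non-missing samples.
#'
#' @param rec a `cage_recording` trimmed to a whole number of days.
#' @param rate_channels,cumulative_channels override the default
#'   classification.
#' @return named numeric vector, one entry per channel.
#' @export
daily_means <- function(rec, rate_channels = .RATE_CHANNELS,
                        cumulative_channels = .CUMULATIVE_CHANNELS) {
  span_min <- n_samples(rec) * rec$interval_min
  days <- span_min / 1440
  if (abs(days - round(days)) * 1440 > rec$interval_min)
    stop(sprintf(
      "windowing error: %.2f-day span is not a whole number of days", days))
  days <- round(days)
  out <- vapply(names(rec$channels), function(ch) {
    v <- rec$channels[[ch]]
    if (ch %in% cumulative_channels) {
      obs <- mean(!is.na(v))
      if (obs == 0) return(NA_real_)
      sum(v, na.rm = TRUE) / obs / days
    } else {
      mean(v, na.rm = TRUE)  # rate-like by default
    }
  }, numeric(1))
  out
}

#' Assemble the per-animal feature table
#'
#' One row per animal: the 14 candidate predictors (see
#' [feature_columns()]) plus `age_weeks` and `group` labels and an
#' `animal_id` column. `Amplitude` and `Adjphase` come from each animal's
#' EE rhythm fit; `Weight` from recording metadata; everything else from
#' [daily_means()]. Rows are ordered by `animal_id`.
#'
#' @param recordings list of `cage_recording`.
#' @param rhythms named list (by animal id) of `rhythm_params` for the EE
#'   channel, e.g. from [cosinor_fit_recording()].
#' @return data.frame with attribute `feature_cols` naming the 14 feature
#'   columns.
#' @export
build_feature_table <- function(recordings, rhythms) {
  ids <- vapply(recordings, function(r) r$animal_id, "")
  names(recordings) <- ids
  rows <- lapply(sort(ids), function(id) {
    rec <- recordings[[id]]
    rp <- rhythms[[id]]
    if (is.null(rp))
      stop(sprintf("assembly error: no EE rhythm fit for animal '%s'", id))
    if (is.na(rec$body_weight_g))
      stop(sprintf("assembly error: missing body weight for animal '%s'", id))
    dm <- daily_means(rec)
    need <- c("VO2", "VCO2", "RER", "EE", "XT", "YT", "Z", "DistD",
              "Speed", "Drink", "Feed", "SumR", "SumL")
    miss <- setdiff(need, names(dm))
    if (length(miss))
      stop(sprintf("assembly error: animal '%s' lacks channel(s) %s",
                   id, paste(miss, collapse = ", ")))
    data.frame(
      animal_id = id,
      Weight = rec$body_weight_g,
      Adjphase = rp$adjphase_min,
      VO2 = dm[["VO2"]], EE = dm[["EE"]], RER = dm[["RER"]],
      VCO2 = dm[["VCO2"]], Z = dm[["Z"]], Feed = dm[["Feed"]],
      Amplitude = rp$amplitude,
      XT_YT = dm[["XT"]] + dm[["YT"]],
      Drink = dm[["Drink"]], DistD = dm[["DistD"]],
      SumR_L = dm[["SumR"]] + dm[["SumL"]],
      Speed = dm[["Speed"]],
      age_weeks = rec$age_weeks, group = rec$group,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (anyNA(out[, feature_columns()]))
    stop("assembly error: missing values in feature columns")
  attr(out, "feature_cols") <- feature_columns()
  out
}

#' Light/dark-resolved daily means
#'
#' Reporting variant of [daily_means()] restricted to one photoperiod
#' phase (the dark phase is the active period of the mouse). These values
#' are not part of the 14-predictor clock set.
#'
#' @param rec a `cage_recording`.
#' @param phase `"light"` or `"dark"`.
#' @return named numeric vector of per-phase means (rates) and per-phase
#'   daily totals (cumulative channels).
#' @export
phase_means <- function(rec, phase = c("dark", "light")) {
  phase <- match.arg(phase)
  keep <- annotate_phases(rec) == phase
  span_min <- n_samples(rec) * rec$interval_min
  days <- round(span_min / 1440)
  vapply(names(rec$channels), function(ch) {
    v <- rec$channels[[ch]][keep]
    if (ch %in% .CUMULATIVE_CHANNELS) {
      obs <- mean(!is.na(v))
      if (obs == 0) return(NA_real_)
      sum(v, na.rm = TRUE) / obs / days
    } else mean(v, na.rm = TRUE)
  }, numeric(1))
}
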